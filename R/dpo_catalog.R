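## dpo_catalog: plasmid-derived DNA-polymerase (dpo) gene fragments.
## Fragments annotated across genomes are single-linkage clustered into a
## named catalog (dpo1..dpoN); each genome is then profiled by homology
## search of the catalog exemplars, and presence is summarized per clade.

## union-find for single-linkage clustering
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) { p[uf_find(p, i)] <- uf_find(p, j); p }

#' Build a named catalog of dpo fragments
#'
#' All dpo-annotated segments across the genomes are clustered by
#' single-linkage at `merge_id` global-alignment identity; the longest
#' member of each cluster becomes the exemplar. Fragments present in the
#' `naming_genome` are named `dpo1..` by genomic position there; remaining
#' clusters are named in discovery order.
#'
#' @param genomes list of [annotated_genome()] objects.
#' @param merge_id single-linkage identity threshold (default 0.90).
#' @param naming_genome strain_id of the genome whose fragment positions
#'   define the names (default: the first genome carrying dpo features; use
#'   a basal-clade representative for stable naming).
#' @return list of fragments, each with `fragment_id`, `exemplar_seq`,
#'   `canonical_rank`.
#' @export
build_dpo_catalog <- function(genomes, merge_id = 0.90,
                              naming_genome = NULL) {
  members <- list()
  for (g in genomes) {
    for (f in features_of(g, "dpo")) {
      members[[length(members) + 1L]] <-
        list(strain_id = g$strain_id, seq = feature_seq(g, f),
             pos = feature_span(f)[1])
    }
  }
  if (length(members) == 0L) {
    warning("no dpo evidence in any genome; empty catalog")
    return(list())
  }
  ## deduplicate identical sequences before pairwise alignment
  seqs <- vapply(members, `[[`, character(1), "seq")
  uniq <- !duplicated(seqs)
  useq <- seqs[uniq]
  umap <- match(seqs, useq)
  n <- length(useq)
  p <- uf_new(n)
  if (n > 1L) {
    lens <- nchar(useq)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (min(lens[i], lens[j]) / max(lens[i], lens[j]) < merge_id) next
      if (align_identity(useq[i], useq[j]) >= merge_id) p <- uf_union(p, i, j)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(p, i), integer(1))
  cluster_of_member <- match(roots[umap], unique(roots))
  k <- length(unique(roots))
  ## exemplar = longest member per cluster
  exemplars <- vapply(seq_len(k), function(cl) {
    cs <- seqs[cluster_of_member == cl]
    cs[which.max(nchar(cs))]
  }, character(1))
  ## naming
  strain_ids <- vapply(members, `[[`, character(1), "strain_id")
  if (is.null(naming_genome)) naming_genome <- strain_ids[1]
  rank <- rep(NA_real_, k)
  in_naming <- which(strain_ids == naming_genome)
  for (i in in_naming) {
    cl <- cluster_of_member[i]
    rank[cl] <- min(rank[cl], members[[i]]$pos, na.rm = TRUE)
  }
  first_seen <- vapply(seq_len(k), function(cl)
    min(which(cluster_of_member == cl)), integer(1))
  ## clusters seen in the naming genome first (by position), then the rest
  ord <- order(ifelse(is.na(rank), Inf, rank), first_seen)
  lapply(seq_len(k), function(r) {
    cl <- ord[r]
    list(fragment_id = paste0("dpo", r), exemplar_seq = exemplars[cl],
         canonical_rank = r)
  })
}

## seed-and-align homology search of one exemplar in a genome sequence;
## returns data.frame(start, end, strand, identity, coverage), 0-based
find_fragment_hits <- function(exemplar, genome_seq, k = 12,
                               min_identity = 0.75, min_cover = 0.60,
                               genome_kmers = NULL) {
  L <- nchar(genome_seq)
  hits <- data.frame(start = integer(0), end = integer(0),
                     strand = character(0), identity = numeric(0),
                     coverage = numeric(0))
  if (L < k || nchar(exemplar) < k) return(hits)
  gk <- genome_kmers %||% substring(genome_seq, 1:(L - k + 1L), k:L)
  for (strand in c("+", "-")) {
    ex <- if (strand == "+") exemplar else revcomp(exemplar)
    ek <- substring(ex, 1:(nchar(ex) - k + 1L), k:nchar(ex))
    m <- match(gk, ek)
    gpos <- which(!is.na(m)) - 1L          # 0-based genome seed starts
    if (!length(gpos)) next
    epos <- m[!is.na(m)] - 1L
    diag <- gpos - epos
    ord <- order(diag, gpos)
    gpos <- gpos[ord]; diag <- diag[ord]
    ## cluster seeds into candidate loci (band 30 nt, gap < exemplar length)
    brk <- c(TRUE, diff(diag) > 30L | diff(gpos) > nchar(ex))
    grp <- cumsum(brk)
    for (gid in unique(grp)) {
      w0 <- max(0L, diag[grp == gid][1] - 50L)
      w1 <- min(L, w0 + nchar(ex) + 100L)
      window <- substr(genome_seq, w0 + 1L, w1)
      mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                      mismatch = -1,
                                                      baseOnly = FALSE)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(ex), Biostrings::DNAString(window),
        type = "global-local", substitutionMatrix = mat,
        gapOpening = 12, gapExtension = 0.5)
      matches <- Biostrings::nmatch(aln)
      identity <- matches / Biostrings::nchar(aln)
      coverage <- (matches + Biostrings::nmismatch(aln)) / nchar(ex)
      if (identity < min_identity || coverage < min_cover) next
      sstart <- w0 + Biostrings::start(Biostrings::subject(aln)) - 1L
      send <- w0 + Biostrings::end(Biostrings::subject(aln))
      hits <- rbind(hits, data.frame(start = sstart, end = send,
                                     strand = strand, identity = identity,
                                     coverage = coverage))
    }
  }
  ## merge overlapping hits on the same locus, keep the best
  if (nrow(hits) > 1L) {
    hits <- hits[order(-hits$identity), , drop = FALSE]
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(hits))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(hits))) {
        if (j == i || !keep[j]) next
        if (hits$start[j] < hits$end[i] && hits$end[j] > hits$start[i])
          keep[j] <- FALSE
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits[order(hits$start), , drop = FALSE]
}

#' Profile a genome against the dpo catalog
#'
#' Each catalog exemplar is searched on both strands; hits at
#' `assign_id` identity over at least `min_cover` of the exemplar length
#' are reported in genomic order. Hits lying inside an inverted-repeat copy
#' are flagged `in_repeat` (excluded from clade summaries by default, as
#' only the fragments between the repeats and the MIR are clade-diagnostic).
#'
#' @param g an [annotated_genome()].
#' @param catalog output of [build_dpo_catalog()].
#' @param assign_id assignment identity threshold (default 0.75).
#' @param min_cover minimum exemplar coverage (default 0.60).
#' @param repeats optional output of [detect_inverted_repeats()] for the
#'   `in_repeat` flag.
#' @return data.frame with columns `strain_id`, `fragment_id`, `start`,
#'   `end`, `strand`, `identity`, `in_repeat`, ordered by position.
#' @export
profile_genome_dpo <- function(g, catalog, assign_id = 0.75,
                               min_cover = 0.60, repeats = NULL) {
  if (length(catalog) == 0L) stop("empty dpo catalog")
  out <- list()
  k <- 12L
  gk <- substring(g$sequence, 1:(nchar(g$sequence) - k + 1L),
                  k:nchar(g$sequence))
  for (fr in catalog) {
    h <- find_fragment_hits(fr$exemplar_seq, g$sequence, k = k,
                            min_identity = assign_id, min_cover = min_cover,
                            genome_kmers = gk)
    if (nrow(h))
      out[[length(out) + 1L]] <- cbind(
        data.frame(strain_id = g$strain_id, fragment_id = fr$fragment_id,
                   stringsAsFactors = FALSE), h)
  }
  prof <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
          else data.frame(strain_id = character(0), fragment_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), identity = numeric(0),
                          coverage = numeric(0))
  ## overlapping hits claimed by two fragments: keep higher identity
  if (nrow(prof) > 1L) {
    prof <- prof[order(-prof$identity), , drop = FALSE]
    keep <- rep(TRUE, nrow(prof))
    for (i in seq_len(nrow(prof))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(prof))) {
        if (j == i || !keep[j]) next
        if (prof$fragment_id[j] != prof$fragment_id[i] &&
            prof$start[j] < prof$end[i] && prof$end[j] > prof$start[i]) {
          warning("overlapping dpo hits in ", g$strain_id, ": keeping ",
                  prof$fragment_id[i], " over ", prof$fragment_id[j])
          keep[j] <- FALSE
        }
      }
    }
    prof <- prof[keep, , drop = FALSE]
  }
  prof$in_repeat <- logical(nrow(prof))
  if (!is.null(repeats) && nrow(prof)) {
    L <- genome_length(g)
    for (rp in repeats) {
      for (cp in list(rp$copy_a, rp$copy_b)) {
        lo <- cp[1] %% L; len <- cp[2] - cp[1]
        mid <- (prof$start + prof$end) / 2
        prof$in_repeat <- prof$in_repeat | (((mid - lo) %% L) < len)
      }
    }
  }
  prof <- prof[order(prof$start), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}

#' Summarize dpo fragment presence per clade
#'
#' @param profiles list of data.frames from [profile_genome_dpo()] (or one
#'   combined data.frame).
#' @param meta data.frame with `strain_id` and `clade` columns; strains
#'   without a clade are grouped under `"unknown"`.
#' @param catalog the catalog (fixes fragment column order).
#' @param include_in_repeat count hits inside the inverted repeats too.
#' @return list with `fraction` (clade x fragment matrix of presence
#'   fractions) and `consensus` (logical matrix, fraction >= 0.5).
#' @export
clade_dpo_summary <- function(profiles, meta, catalog,
                              include_in_repeat = FALSE) {
  prof <- if (is.data.frame(profiles)) profiles
          else do.call(rbind, c(profiles, list(make.row.names = FALSE)))
  if (!include_in_repeat && nrow(prof))
    prof <- prof[!prof$in_repeat, , drop = FALSE]
  frags <- vapply(catalog, `[[`, character(1), "fragment_id")
  clade <- meta$clade
  clade[is.na(clade) | clade == ""] <- "unknown"
  clades <- sort(unique(clade))
  frac <- matrix(0, length(clades), length(frags),
                 dimnames = list(clades, frags))
  for (cl in clades) {
    strains <- meta$strain_id[clade == cl]
    for (fr in frags) {
      got <- vapply(strains, function(s)
        any(prof$strain_id == s & prof$fragment_id == fr), logical(1))
      frac[cl, fr] <- mean(got)
    }
  }
  list(fraction = frac, consensus = frac >= 0.5)
}
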