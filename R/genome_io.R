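## genome_io: annotated circular mitogenome container, orientation
## normalization, composition statistics, and FASTA/table I/O.
## GenBank flat-file I/O lives in genbank.R.

#' Construct a genome feature
#'
#' Segments are 0-based half-open intervals on the forward strand, given in
#' 5'-to-3' order of the gene (for `-` strand features that means descending
#' genomic coordinates).
#'
#' @param name feature name, e.g. `"cox1"`, `"trnA"`, `"dpo3"`.
#' @param kind one of `"CDS"`, `"rRNA"`, `"tRNA"`, `"intron"`, `"dpo"`,
#'   `"other"`.
#' @param strand `"+"` or `"-"`.
#' @param segments two-column integer matrix (`start`, `end`), 0-based
#'   half-open; a plain vector `c(start, end)` is accepted for single
#'   segments.
#' @param qualifiers named character vector of qualifiers; intron features
#'   must carry a `host_gene` qualifier.
#' @return a `feature` object (list).
#' @export
feature <- function(name, kind, strand, segments, qualifiers = character(0)) {
  kind <- match.arg(kind, c("CDS", "rRNA", "tRNA", "intron", "dpo", "other"))
  strand <- match.arg(strand, c("+", "-"))
  if (is.null(dim(segments))) segments <- matrix(segments, ncol = 2, byrow = TRUE)
  segments <- canon_segments(segments)
  stopifnot(all(segments[, 2] > segments[, 1]))
  qualifiers <- if (length(qualifiers))
    setNames(as.character(qualifiers), names(qualifiers)) else character(0)
  structure(list(name = name, kind = kind, strand = strand,
                 segments = segments, qualifiers = qualifiers),
            class = "feature")
}

#' Construct an annotated genome
#'
#' @param strain_id strain identifier.
#' @param sequence forward-strand nucleotide string; only A/C/G/T/N allowed.
#' @param features list of [feature()] objects.
#' @param circular logical; mitogenomes are circular.
#' @param metadata list with optional elements `clade`, `variety`, `origin`,
#'   `cultivar_status`.
#' @return an `annotated_genome` object.
#' @export
annotated_genome <- function(strain_id, sequence, features = list(),
                             circular = TRUE, metadata = list()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence for strain ", strain_id)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence of ", strain_id,
         " contains ambiguity codes other than N; only A/C/G/T/N supported")
  g <- structure(list(strain_id = strain_id, sequence = sequence,
                      circular = isTRUE(circular), features = features,
                      metadata = metadata),
                 class = "annotated_genome")
  validate_genome(g)
  g
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %s, %d features\n",
              x$strain_id, nchar(x$sequence),
              if (x$circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

genome_length <- function(g) nchar(g$sequence)

## canonical unnamed-row segment matrix
canon_segments <- function(m) {
  m <- matrix(as.integer(m), ncol = 2)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

validate_genome <- function(g) {
  L <- genome_length(g)
  for (f in g$features) {
    if (any(f$segments < 0L) || any(f$segments > L))
      stop("feature ", f$name, " of ", g$strain_id,
           " has segments outside [0, ", L, ")")
    if (f$kind == "intron" && !("host_gene" %in% names(f$qualifiers)))
      stop("intron feature ", f$name, " of ", g$strain_id,
           " lacks a host_gene qualifier")
  }
  invisible(g)
}

## all features of a given kind / name
features_of <- function(g, kind = NULL, name = NULL) {
  keep <- vapply(g$features, function(f) {
    (is.null(kind) || f$kind %in% kind) && (is.null(name) || f$name == name)
  }, logical(1))
  g$features[keep]
}

## genomic span of a feature (min start, max end over segments)
feature_span <- function(f) c(min(f$segments[, 1]), max(f$segments[, 2]))

## extract a feature's sequence in gene orientation (5'->3')
feature_seq <- function(g, f) {
  parts <- apply(f$segments, 1L, function(r) seq_slice(g$sequence, r[1], r[2]))
  s <- paste(parts, collapse = "")
  if (f$strand == "-") revcomp(s) else s
}

#' Rotate and strand-normalize a genome on an anchor gene
#'
#' The circular genome is rotated so the anchor gene's first base sits at
#' position 0; if the anchor lies on the `-` strand the whole genome is
#' reverse-complemented first. All features are remapped consistently;
#' features that come to span the origin are split into two segments.
#'
#' @param g an [annotated_genome()].
#' @param anchor_gene gene used as the origin; default `"cox1"` (the longest
#'   single-copy mitochondrial gene in these genomes).
#' @return the normalized genome.
#' @export
normalize_orientation <- function(g, anchor_gene = "cox1") {
  anchors <- features_of(g, kind = c("CDS", "rRNA", "tRNA"), name = anchor_gene)
  if (length(anchors) != 1L) {
    avail <- sort(unique(vapply(
      features_of(g, kind = c("CDS", "rRNA")), `[[`, character(1), "name")))
    stop("anchor gene '", anchor_gene, "' found ", length(anchors),
         " times in ", g$strain_id, "; available genes: ",
         paste(avail, collapse = ", "))
  }
  if (anchors[[1]]$strand == "-") g <- revcomp_genome(g)
  anchor <- features_of(g, kind = c("CDS", "rRNA", "tRNA"),
                        name = anchor_gene)[[1]]
  off <- anchor$segments[1L, 1L]
  rotate_genome(g, off)
}

## reverse-complement genome and remap all features
revcomp_genome <- function(g) {
  L <- genome_length(g)
  g$sequence <- revcomp(g$sequence)
  g$features <- lapply(g$features, function(f) {
    seg <- f$segments
    ## row order preserved: still 5'->3' in gene orientation
    f$segments <- canon_segments(cbind(L - seg[, 2], L - seg[, 1]))
    f$strand <- if (f$strand == "+") "-" else "+"
    f
  })
  g
}

## rotate a circular genome so that position `off` becomes position 0
rotate_genome <- function(g, off) {
  L <- genome_length(g)
  off <- ((off %% L) + L) %% L
  if (off == 0L) return(g)
  g$sequence <- paste0(seq_slice(g$sequence, off, L), seq_slice(g$sequence, 0, off))
  g$features <- lapply(g$features, function(f) {
    segs <- list()
    for (i in seq_len(nrow(f$segments))) {
      s <- (f$segments[i, 1] - off) %% L
      e <- s + (f$segments[i, 2] - f$segments[i, 1])
      if (e <= L) segs[[length(segs) + 1L]] <- c(s, e)
      else {  # wraps the new origin: split, keeping gene order
        parts <- list(c(s, L), c(0L, e - L))
        if (f$strand == "-") parts <- rev(parts)
        for (p in parts) segs[[length(segs) + 1L]] <- p
      }
    }
    seg <- matrix(as.integer(unlist(segs)), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("start", "end")))
    f$segments <- merge_adjacent_segments(seg, f$strand)
    f
  })
  g
}

## re-join segments that were split only by an origin shift
merge_adjacent_segments <- function(seg, strand) {
  if (nrow(seg) < 2L) return(seg)
  out <- seg[1, , drop = FALSE]
  for (i in 2:nrow(seg)) {
    last <- nrow(out)
    joinable <- if (strand == "+") out[last, 2] == seg[i, 1]
                else seg[i, 2] == out[last, 1]
    if (joinable) {
      out[last, 1] <- min(out[last, 1], seg[i, 1])
      out[last, 2] <- max(out[last, 2], seg[i, 2])
    } else out <- rbind(out, seg[i, , drop = FALSE])
  }
  canon_segments(out)
}

#' Composition statistics of a genome
#'
#' AT content is computed over non-N bases; GC skew is (G - C)/(G + C) on
#' the forward strand (0 with a warning when G + C = 0).
#'
#' @param g an [annotated_genome()].
#' @return list with `length`, `at_content`, `gc_skew`, `n_count`.
#' @export
compute_genome_stats <- function(g) {
  s <- if (inherits(g, "annotated_genome")) g$sequence else toupper(g)
  if (nchar(s) == 0L) stop("empty sequence")
  cnt <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                      levels = c("A", "C", "G", "T", "N")))
  a <- cnt[["A"]]; c_ <- cnt[["C"]]; gg <- cnt[["G"]]; t <- cnt[["T"]]
  acgt <- a + c_ + gg + t
  if (acgt == 0L) stop("sequence contains no unambiguous bases")
  skew <- if (gg + c_ == 0L) {
    warning("G + C = 0; GC skew set to 0")
    0
  } else (gg - c_) / (gg + c_)
  list(length = nchar(s), at_content = (a + t) / acgt, gc_skew = skew,
       n_count = as.integer(cnt[["N"]]))
}

## ---- FASTA + annotation-table dialect -----------------------------------

#' Write a genome as FASTA plus annotation table
#'
#' The table dialect is TSV with columns `strain_id`, `feature_name`,
#' `kind`, `strand`, `segments` (semicolon-joined `start-end` pairs, 0-based
#' half-open) and `qualifiers` (semicolon-joined `key=value`).
#'
#' @param g an [annotated_genome()].
#' @param fasta_path,table_path output paths.
#' @export
write_genome_table <- function(g, fasta_path, table_path) {
  dna <- Biostrings::DNAStringSet(setNames(g$sequence, g$strain_id))
  Biostrings::writeXStringSet(dna, fasta_path)
  rows <- lapply(g$features, function(f) {
    data.frame(strain_id = g$strain_id, feature_name = f$name, kind = f$kind,
               strand = f$strand,
               segments = paste(sprintf("%d-%d", f$segments[, 1],
                                        f$segments[, 2]), collapse = ";"),
               qualifiers = paste(sprintf("%s=%s", names(f$qualifiers),
                                          f$qualifiers), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.table(tab, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(g)
}

#' Read a genome from FASTA plus annotation table
#'
#' @param fasta_path,table_path input paths (see [write_genome_table()]).
#' @param circular logical.
#' @return an [annotated_genome()].
#' @export
read_genome_table <- function(fasta_path, table_path, circular = TRUE) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L) stop("expected a single FASTA record in ", fasta_path)
  tab <- read.delim(table_path, stringsAsFactors = FALSE)
  need <- c("strain_id", "feature_name", "kind", "strand", "segments")
  if (!all(need %in% names(tab)))
    stop("annotation table ", table_path, " lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    segs <- do.call(rbind, lapply(strsplit(tab$segments[i], ";")[[1]],
                                  function(p) as.integer(strsplit(p, "-")[[1]])))
    q <- character(0)
    if (!is.null(tab$qualifiers) && nzchar(tab$qualifiers[i])) {
      kv <- strsplit(strsplit(tab$qualifiers[i], ";")[[1]], "=", fixed = TRUE)
      q <- setNames(vapply(kv, `[`, character(1), 2),
                    vapply(kv, `[`, character(1), 1))
    }
    feature(tab$feature_name[i], tab$kind[i], tab$strand[i], segs, q)
  })
  annotated_genome(names(dna)[1], as.character(dna[[1]]), feats,
                   circular = circular)
}

#' Read a strain metadata table
#'
#' TSV with columns `strain_id`, `clade`, `variety`, `origin`,
#' `cultivar_status`; missing columns are filled with `"unknown"`.
#'
#' @param path TSV path.
#' @return data.frame keyed by `strain_id`.
#' @export
read_strain_metadata <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if (!"strain_id" %in% names(m)) stop("metadata table lacks strain_id column")
  if (anyDuplicated(m$strain_id))
    stop("duplicated strain_id in metadata: ",
         paste(unique(m$strain_id[duplicated(m$strain_id)]), collapse = ", "))
  for (col in c("clade", "variety", "origin", "cultivar_status"))
    if (is.null(m[[col]])) m[[col]] <- "unknown"
  ok <- c("bisporus", "burnettii", "eurotetrasporus", "outgroup", "unknown")
  bad <- setdiff(unique(m$variety), ok)
  if (length(bad)) stop("unknown variety values: ", paste(bad, collapse = ", "))
  m
}
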