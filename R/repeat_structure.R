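## repeat_structure: inverted-repeat (IRS) detection by exact k-mer
## seeding on anti-diagonals plus mismatch-tolerant extension, and the
## orientation call of the MIR segment between the two repeat copies.

#' Detect inverted repeat pairs in a circular genome
#'
#' Seed-and-extend search: exact k-mer matches between the sequence and its
#' reverse complement are grouped by anti-diagonal (an ungapped inverted
#' repeat keeps `start_a + start_b` constant), chained, extended outwards
#' tolerating isolated mismatches, and scored by global alignment of copy A
#' against the reverse complement of copy B. Circularity is respected by
#' searching the doubled sequence; a copy that spans the origin is reported
#' with `end > genome length` (interpret modulo the length).
#'
#' @param g an [annotated_genome()] (or a plain sequence string).
#' @param min_len minimum repeat length in nt (>= 50).
#' @param min_identity minimum alignment identity of the two copies.
#' @param k seed k-mer size.
#' @return list of repeat pairs, each a list with `copy_a`, `copy_b`
#'   (0-based half-open `c(start, end)`), `length` and `identity`, ranked by
#'   `length * identity` (ties by smaller `copy_a` start).
#' @export
detect_inverted_repeats <- function(g, min_len = 500, min_identity = 0.95,
                                    k = 21) {
  stopifnot(min_len >= 50)
  s <- if (inherits(g, "annotated_genome")) g$sequence else toupper(g)
  circular <- !inherits(g, "annotated_genome") || g$circular
  L <- nchar(s)
  if (L < 2L * k) return(list())
  s2 <- if (circular) paste0(s, s) else s
  n2 <- nchar(s2)

  ## seed pairs (i, j): 0-based starts of a k-mer and of the k-mer whose
  ## reverse complement it equals
  kf <- substring(s2, 1:(n2 - k + 1L), k:n2)
  rc2 <- revcomp(s2)
  kr <- substring(rc2, 1:(n2 - k + 1L), k:n2)
  ## k-mer at rc position q (0-based) sits on the forward strand at
  ## j = n2 - q - k
  common <- intersect(kf, kr)
  common <- setdiff(common, common[grepl("N", common, fixed = TRUE)])
  if (length(common) == 0L) return(list())
  fpos <- split(0:(n2 - k), factor(kf, levels = common))
  rpos <- split(0:(n2 - k), factor(kr, levels = common))
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (km in common) {
    fi <- fpos[[km]]; qj <- rpos[[km]]
    if (!length(fi) || !length(qj)) next
    if (length(fi) * length(qj) > 2000L) next   # low-complexity guard
    jj <- n2 - qj - k
    grid <- expand.grid(i = fi, j = jj)
    keep <- grid$j >= grid$i                     # canonical orientation
    pairs_i <- c(pairs_i, grid$i[keep]); pairs_j <- c(pairs_j, grid$j[keep])
  }
  if (!length(pairs_i)) return(list())

  ## group seeds by anti-diagonal d = i + j, allowing a small band for
  ## indels, then chain seeds with bounded gaps along i
  d <- pairs_i + pairs_j
  ord <- order(d, pairs_i)
  pairs_i <- pairs_i[ord]; pairs_j <- pairs_j[ord]; d <- d[ord]
  band <- 16L; max_gap <- 200L
  groups <- list(); gi <- 0L
  cur <- NULL
  for (t in seq_along(d)) {
    if (is.null(cur) || d[t] - cur$dmax > band) {
      if (!is.null(cur)) { gi <- gi + 1L; groups[[gi]] <- cur }
      cur <- list(i0 = pairs_i[t], i1 = pairs_i[t], j0 = pairs_j[t],
                  j1 = pairs_j[t], dmax = d[t])
    } else {
      cur$i0 <- min(cur$i0, pairs_i[t]); cur$i1 <- max(cur$i1, pairs_i[t])
      cur$j0 <- min(cur$j0, pairs_j[t]); cur$j1 <- max(cur$j1, pairs_j[t])
      cur$dmax <- max(cur$dmax, d[t])
    }
  }
  if (!is.null(cur)) { gi <- gi + 1L; groups[[gi]] <- cur }

  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  s2c <- strsplit(s2, "", fixed = TRUE)[[1]]
  res <- list()
  for (grp in groups) {
    a0 <- grp$i0; a1 <- grp$i1 + k; b0 <- grp$j0; b1 <- grp$j1 + k
    if (a1 - a0 < min_len - 50L) next
    ## extend outward (a0-1 pairs with b1, a1 pairs with b0-1), stopping
    ## after a window of heavy mismatch and trimming back to the last match
    ext <- function(astep, bstep, apos, bpos) {
      flags <- logical(0); n_ext <- 0L
      while (TRUE) {
        na <- apos + astep; nb <- bpos + bstep
        if (na < 0L || na >= n2 || nb < 0L || nb >= n2) break
        ok <- comp[[s2c[na + 1L]]] == s2c[nb + 1L]
        flags <- c(flags, ok)
        w <- tail(flags, 12L)
        if (sum(!w) > 4L) break
        apos <- na; bpos <- nb; n_ext <- n_ext + 1L
      }
      ## trim back so the extension ends on a clean run of matches, keeping
      ## chance base-pairing in the flanks from inflating the repeat
      while (n_ext > 0L &&
             !all(flags[max(1L, n_ext - 5L):n_ext])) n_ext <- n_ext - 1L
      n_ext
    }
    el <- ext(-1L, +1L, a0, b1 - 1L)
    er <- ext(+1L, -1L, a1 - 1L, b0)
    a0 <- a0 - el; b1 <- b1 + el; a1 <- a1 + er; b0 <- b0 - er
    if (b0 < a1) next                              # overlapping copies
    if (circular && (a0 >= L || b1 - a0 > L)) next # duplicate/overlong image
    len <- a1 - a0
    if (len < min_len || (b1 - b0) < min_len) next
    ident <- align_identity(substr(s2, a0 + 1L, a1),
                            revcomp(substr(s2, b0 + 1L, b1)))
    if (ident < min_identity) next
    res[[length(res) + 1L]] <- list(copy_a = c(a0, a1), copy_b = c(b0, b1),
                                    length = len, identity = ident)
  }
  if (!length(res)) return(list())

  ## drop pairs nested inside a longer reported pair; deterministic ranking
  score <- vapply(res, function(r) r$length * r$identity, numeric(1))
  starts <- vapply(res, function(r) r$copy_a[1], numeric(1))
  res <- res[order(-score, starts)]
  kept <- list()
  for (r in res) {
    nested <- any(vapply(kept, function(q) {
      r$copy_a[1] >= q$copy_a[1] && r$copy_a[2] <= q$copy_a[2] &&
        r$copy_b[1] >= q$copy_b[1] && r$copy_b[2] <= q$copy_b[2]
    }, logical(1)))
    if (!nested) kept[[length(kept) + 1L]] <- r
  }
  if (length(kept) > 5L)
    warning(length(kept), " repeat pairs pass thresholds; ",
            "consider raising min_len or min_identity")
  kept
}

#' Call the orientation of the segment between the inverted repeats (MIR)
#'
#' The MIR segment is the arc strictly between the two copies of the
#' dominant (longest) repeat pair that contains the marker genes (ties go to
#' the shorter arc). Orientation is the strand of `rps3` relative to the
#' strand of the anchor gene: same strand is `forward`, opposite is
#' `reverse`. If two marker-gene homologs are annotated on opposite strands
#' the call is `duplicated_both`.
#'
#' @param g an [annotated_genome()].
#' @param repeats output of [detect_inverted_repeats()].
#' @param marker_genes genes expected inside the MIR.
#' @param orient_gene marker whose strand defines the orientation.
#' @param anchor_gene gene whose strand is the reference (default `cox1`).
#' @return list with `segment`, `orientation`, `markers_found`, `evidence`.
#' @export
call_mir <- function(g, repeats,
                     marker_genes = c("nad2", "nad3", "rrnL", "rps3"),
                     orient_gene = "rps3", anchor_gene = "cox1") {
  if (length(repeats) == 0L) stop("no IRS detected in ", g$strain_id)
  L <- genome_length(g)
  dom <- repeats[[which.max(vapply(repeats, `[[`, numeric(1), "length"))]]
  ## two arcs strictly between the copies (on the circle)
  arc1 <- c(dom$copy_a[2], dom$copy_b[1])               # a-end .. b-start
  arc2 <- c(dom$copy_b[2], dom$copy_a[1] + L)           # b-end .. a-start (wraps)
  in_arc <- function(p, arc) {
    p <- p %% L
    lo <- arc[1] %% L; hi <- arc[2] - arc[1]
    ((p - lo) %% L) < hi
  }
  centers <- function(f) mean(feature_span(f))
  mk_feats <- Filter(function(f) f$name %in% marker_genes, g$features)
  hits1 <- Filter(function(f) in_arc(centers(f), arc1), mk_feats)
  hits2 <- Filter(function(f) in_arc(centers(f), arc2), mk_feats)
  n1 <- length(unique(vapply(hits1, `[[`, character(1), "name")))
  n2_ <- length(unique(vapply(hits2, `[[`, character(1), "name")))
  if (n1 == 0L && n2_ == 0L)
    stop("no marker gene inside either candidate MIR segment of ",
         g$strain_id, " (arcs [", arc1[1], ",", arc1[2], ") and [",
         arc2[1] %% L, ",", arc2[2] %% L, "))")
  pick1 <- if (n1 != n2_) n1 > n2_ else (arc1[2] - arc1[1]) <= (arc2[2] - arc2[1])
  segment <- if (pick1) arc1 else arc2
  hits <- if (pick1) hits1 else hits2

  anchors <- features_of(g, name = anchor_gene)
  if (length(anchors) == 0L) stop("anchor gene ", anchor_gene, " not annotated")
  anchor_strand <- anchors[[1]]$strand

  evidence <- setNames(vapply(hits, `[[`, character(1), "strand"),
                       vapply(hits, `[[`, character(1), "name"))
  ## duplicated MIR: an orientation marker annotated on both strands
  ori_all <- features_of(g, name = orient_gene)
  ori_strands <- unique(vapply(ori_all, `[[`, character(1), "strand"))
  if (length(ori_all) >= 2L && length(ori_strands) == 2L) {
    orientation <- "duplicated_both"
  } else {
    ori_in <- evidence[names(evidence) == orient_gene]
    strand <- if (length(ori_in)) ori_in[[1]] else {
      ## fall back to the majority marker strand
      names(sort(table(unname(evidence)), decreasing = TRUE))[1]
    }
    orientation <- if (strand == anchor_strand) "forward" else "reverse"
  }
  list(segment = segment, orientation = orientation,
       markers_found = unique(names(evidence)), evidence = evidence)
}
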