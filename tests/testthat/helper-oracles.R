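## Independent oracles used by the tests. These deliberately do not share
## code with the package implementation.

## Needleman-Wunsch global alignment identity (linear gap penalty),
## identity = matches / alignment length. For short sequences only.
nw_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    d <- S[i, j] + if (x[i] == y[j]) match else mismatch
    S[i + 1, j + 1] <- max(d, S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  ## traceback counting matches and columns
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (x[i] == y[j]) match else mismatch)) {
      matches <- matches + (x[i] == y[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else j <- j - 1
    cols <- cols + 1L
  }
  matches / cols
}

## fraction of identical bases between two equal-length strings
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

## single-pass base-count oracle for composition statistics
count_stats_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  a <- sum(ch == "A"); c_ <- sum(ch == "C")
  g <- sum(ch == "G"); t <- sum(ch == "T")
  list(length = nchar(s), at_content = (a + t) / (a + c_ + g + t),
       gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else 0,
       n_count = sum(ch == "N"))
}

## exhaustive scan: does `s` contain any exact inverted repeat pair of
## length exactly `len` (two non-overlapping copies)? O(n^2) by design.
has_exact_inverted_repeat <- function(s, len) {
  n <- nchar(s)
  if (n < 2 * len) return(FALSE)
  subs <- substring(s, 1:(n - len + 1), len:n)
  rc <- vapply(subs, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1))
  for (i in seq_along(subs)) {
    j <- which(subs == rc[i])
    if (any(j >= i + len)) return(TRUE)
  }
  FALSE
}

## --- exhaustive Dollo oracle ----------------------------------------------

## tips below each node, computed by simple recursion (independent of the
## package's postorder accumulation)
oracle_tips_below <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_tips_below, tree = tree))
}

## path of edge rows from `anc` down to tip `tip`
oracle_edge_path <- function(tree, anc, tip) {
  path <- integer(0)
  node <- tip
  while (node != anc) {
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) return(NULL)   # anc not an ancestor
    path <- c(path, e)
    node <- tree$edge[e, 1]
  }
  path
}

## exhaustive minimal loss-edge sets under single-gain Dollo: enumerate
## every subset of edges inside the gain subtree and keep those reproducing
## the leaf pattern with minimal size
oracle_dollo <- function(tree, presence) {
  nt <- length(tree$tip.label)
  pres <- presence[tree$tip.label]
  if (!any(pres)) return(list(gain = NA, min_sets = list(integer(0))))
  ptips <- which(pres)
  mrca <- if (length(ptips) == 1) ptips else ape::getMRCA(tree, ptips)
  tips <- oracle_tips_below(tree, mrca)
  paths <- lapply(tips, function(tp) oracle_edge_path(tree, mrca, tp))
  names(paths) <- tree$tip.label[tips]
  edges <- sort(unique(unlist(paths)))
  best <- Inf; sets <- list()
  for (mask in 0:(2^length(edges) - 1)) {
    S <- edges[bitwAnd(mask, 2^(seq_along(edges) - 1)) > 0]
    if (length(S) > best) next
    ok <- TRUE
    for (tp in names(paths)) {
      lost <- length(intersect(paths[[tp]], S)) > 0
      if (lost == pres[[tp]]) { ok <- FALSE; break }
    }
    if (!ok) next
    if (length(S) < best) { best <- length(S); sets <- list(S) }
    else sets <- c(sets, list(S))
  }
  gain <- if (mrca == nt + 1) 0L else which(tree$edge[, 2] == mrca)
  list(gain = gain, min_sets = sets, min_size = best)
}

## independent block-merged event count: per-site exhaustive Dollo, then
## blocks counted directly from the definition (no shared code)
oracle_min_events <- function(tree, m) {
  nt <- length(tree$tip.label)
  m <- m[tree$tip.label, , drop = FALSE]
  genes <- sub("\\|.*", "", colnames(m))
  ords <- as.numeric(sub(".*\\|", "", colnames(m)))
  recs <- lapply(seq_len(ncol(m)), function(j)
    oracle_dollo(tree, setNames(m[, j], rownames(m))))
  ## presence of site j at internal node n
  present_at <- function(j, n) {
    pres <- m[, j]
    if (!any(pres)) return(FALSE)
    ptips <- which(pres)
    mrca <- if (length(ptips) == 1) ptips else ape::getMRCA(tree, ptips)
    intree <- n %in% c(mrca, setdiff(unique(unlist(lapply(
      oracle_tips_below(tree, mrca), function(tp) {
        path <- oracle_edge_path(tree, mrca, tp)
        c(tree$edge[path, 1], tree$edge[path, 2])
      }))), integer(0)))
    if (!intree) return(FALSE)
    any(m[intersect(oracle_tips_below(tree, n), seq_len(nt)), j])
  }
  count <- 0L
  changes <- list()
  for (j in seq_len(ncol(m))) {
    r <- recs[[j]]
    if (!is.na(r$gain) && r$gain != 0L)
      changes[[length(changes) + 1L]] <- c(edge = r$gain, site = j, loss = 0)
    for (e in r$min_sets[[1]])
      changes[[length(changes) + 1L]] <- c(edge = e, site = j, loss = 1)
  }
  if (!length(changes)) return(0L)
  ch <- do.call(rbind, changes)
  for (key in unique(paste(ch[, "edge"], genes[ch[, "site"]], ch[, "loss"]))) {
    rows <- ch[paste(ch[, "edge"], genes[ch[, "site"]], ch[, "loss"]) == key,
               , drop = FALSE]
    e <- rows[1, "edge"]; gn <- genes[rows[1, "site"]]
    parent <- tree$edge[e, 1]
    site_ords <- sort(ords[rows[, "site"]])
    blocks <- 1L
    if (length(site_ords) > 1) for (i in 2:length(site_ords)) {
      between <- which(genes == gn & ords > site_ords[i - 1] &
                         ords < site_ords[i])
      barrier <- any(vapply(between, function(b) present_at(b, parent),
                            logical(1)))
      if (barrier) blocks <- blocks + 1L
    }
    count <- count + blocks
  }
  count
}

## the four neighboring-intron loss groups on a toy tree where each lost
## group is monophyletic
four_event_fixture <- function() {
  tree <- ape::read.tree(text = paste0(
    "(((china1,china2),(france1,other1)),((cal1,(cal2,cal3)),",
    "(cult1,cult2)),(other2,other3));"))
  tree <- ape::root(ape::unroot(tree), "other3", resolve.root = TRUE)
  sites <- c(paste0("cob|", 1:6), paste0("cox2|", 1:6), paste0("cox1|", 1:18))
  m <- matrix(TRUE, length(tree$tip.label), length(sites),
              dimnames = list(tree$tip.label, sites))
  m[, paste0("cox2|", 2:5)] <- FALSE   # ancestrally empty between 1 and 6
  m[c("china1", "china2"), paste0("cob|", 4:6)] <- FALSE
  m["france1", c("cox2|1", "cox2|6")] <- FALSE
  m[c("cal1", "cal2", "cal3"), paste0("cox1|", 3:6)] <- FALSE
  m[c("cult1", "cult2"), paste0("cox1|", 16:17)] <- FALSE
  list(tree = tree, matrix = m)
}
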