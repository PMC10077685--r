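## event_inference: minimum intron gain/loss events on a rooted phylogeny.
## Model: Dollo parsimony — a single gain on the stem of the most recent
## common ancestor of all carriers, plus the minimal set of loss branches.
## Losses of neighboring introns of one gene on one branch merge into a
## single block event when no intervening site of that gene is present in
## the branch's parent state (so sites separated only by empty sites are
## "neighboring", as for the cox2 intron 1 + 6 pair).

## tips (indices) below each node, as a list over 1..(Ntip+Nnode)
tips_below <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(nt)) below[[i]] <- i
  tr <- stats::reorder(tree, "postorder")
  for (r in seq_len(nrow(tr$edge))) {
    u <- tr$edge[r, 1]; v <- tr$edge[r, 2]
    below[[u]] <- c(below[[u]], below[[v]])
  }
  below
}

## all nodes (incl. tips) in the subtree rooted at `node`
nodes_below <- function(tree, node) {
  out <- node
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  for (k in kids) out <- c(out, nodes_below(tree, k))
  out
}

#' Dollo reconstruction for a single presence/absence site
#'
#' Places one gain on the edge above the MRCA of all presence leaves (edge
#' id 0 denotes the root stem, i.e. ancestral presence) and the minimal set
#' of loss edges below it covering exactly the absence leaves.
#'
#' @param tree rooted `phylo`.
#' @param presence named logical vector over all tip labels.
#' @return list with `gain_edge` (row of `tree$edge`; 0 = root stem; `NA`
#'   if the site is absent everywhere), `loss_edges` (integer vector of
#'   edge rows), `present_node` (logical over nodes: state at each node).
#' @export
dollo_loss_branches <- function(tree, presence) {
  nt <- length(tree$tip.label)
  stopifnot(all(tree$tip.label %in% names(presence)))
  pres <- presence[tree$tip.label]
  nn <- nt + tree$Nnode
  if (!any(pres))
    return(list(gain_edge = NA_integer_, loss_edges = integer(0),
                present_node = rep(FALSE, nn)))
  root <- nt + 1L
  ptips <- which(pres)
  mrca <- if (length(ptips) == 1L) ptips else ape::getMRCA(tree, ptips)
  gain_edge <- if (mrca == root) 0L else which(tree$edge[, 2] == mrca)
  below <- tips_below(tree)
  has_pres <- vapply(seq_len(nn), function(n) any(below[[n]] %in% ptips),
                     logical(1))
  sub <- nodes_below(tree, mrca)
  loss_edges <- which(tree$edge[, 2] %in% sub & tree$edge[, 1] %in% sub &
                        !has_pres[tree$edge[, 2]] & has_pres[tree$edge[, 1]])
  present_node <- vapply(seq_len(nn), function(n)
    (n %in% sub) && has_pres[n], logical(1))
  list(gain_edge = gain_edge, loss_edges = loss_edges,
       present_node = present_node)
}

## Fitch small-parsimony change count for one binary site (sensitivity mode)
fitch_changes <- function(tree, presence) {
  nt <- length(tree$tip.label)
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- presence[[tree$tip.label[i]]]
  tr <- stats::reorder(tree, "postorder")
  changes <- 0L
  ## a node is ready once the last edge below it has been visited
  last_row <- tapply(seq_len(nrow(tr$edge)), tr$edge[, 1], max)
  for (r in seq_len(nrow(tr$edge))) {
    u <- tr$edge[r, 1]
    if (r != last_row[[as.character(u)]]) next
    kids <- tr$edge[tr$edge[, 1] == u, 2]
    s <- sets[[kids[1]]]
    for (k in kids[-1]) {
      inter <- intersect(s, sets[[k]])
      if (length(inter)) s <- inter
      else { s <- union(s, sets[[k]]); changes <- changes + 1L }
    }
    sets[[u]] <- s
  }
  changes
}

#' Infer the minimum number of intron gain/loss events on a phylogeny
#'
#' Per-site Dollo reconstructions are computed, then losses (and sub-root
#' gains) sharing a branch and a gene merge into block events under the
#' ancestral-context adjacency rule. Gains on the root stem are ancestral
#' presence, not events.
#'
#' @param tree rooted `phylo` with tips = strain ids.
#' @param m presence matrix: logical, or a character state matrix where
#'   `"0"` means absent; columns named `gene|ordinal`.
#' @param intron_subset optional column subset.
#' @param model `"dollo"` (default) or `"fitch"` (per-site change counts,
#'   no block merging; sensitivity check only).
#' @return list with `events` (data.frame `branch`, `gene`, `sites`,
#'   `kind`) and `count`.
#' @export
infer_min_events <- function(tree, m, intron_subset = NULL,
                             model = c("dollo", "fitch")) {
  model <- match.arg(model)
  if (!is.logical(m)) {
    mm <- m != "0"
    dimnames(mm) <- dimnames(m)
    m <- mm
  }
  if (!is.null(intron_subset)) m <- m[, intron_subset, drop = FALSE]
  missing <- setdiff(tree$tip.label, rownames(m))
  if (length(missing))
    stop("matrix lacks strains present in the tree: ",
         paste(missing, collapse = ", "))
  m <- m[tree$tip.label, , drop = FALSE]
  parts <- strsplit(colnames(m), "|", fixed = TRUE)
  gene <- vapply(parts, `[`, character(1), 1)
  ordinal <- as.numeric(vapply(parts, `[`, character(1), 2))

  if (model == "fitch") {
    cnt <- sum(vapply(seq_len(ncol(m)), function(j)
      fitch_changes(tree, setNames(m[, j], rownames(m))), integer(1)))
    return(list(events = NULL, count = cnt))
  }

  rec <- lapply(seq_len(ncol(m)), function(j)
    dollo_loss_branches(tree, setNames(m[, j], rownames(m))))

  ## collect per-site changes: (edge, site, kind)
  ch <- list()
  for (j in seq_len(ncol(m))) {
    r <- rec[[j]]
    if (!is.na(r$gain_edge) && r$gain_edge != 0L)
      ch[[length(ch) + 1L]] <- data.frame(edge = r$gain_edge, site = j,
                                          kind = "gain")
    for (e in r$loss_edges)
      ch[[length(ch) + 1L]] <- data.frame(edge = e, site = j, kind = "loss")
  }
  if (!length(ch))
    return(list(events = data.frame(branch = integer(0), gene = character(0),
                                    sites = character(0), kind = character(0)),
                count = 0L))
  ch <- do.call(rbind, ch)

  ## presence of site j at the parent node of edge e
  parent_state <- function(e, j) rec[[j]]$present_node[tree$edge[e, 1]]

  events <- list()
  for (key in unique(paste(ch$edge, gene[ch$site], ch$kind))) {
    grp <- ch[paste(ch$edge, gene[ch$site], ch$kind) == key, , drop = FALSE]
    e <- grp$edge[1]; gn <- gene[grp$site[1]]; kind <- grp$kind[1]
    ords <- sort(ordinal[grp$site])
    gene_sites <- which(gene == gn)
    blocks <- list(); cur <- ords[1]
    if (length(ords) > 1L) for (i in 2:length(ords)) {
      between <- gene_sites[ordinal[gene_sites] > ords[i - 1] &
                              ordinal[gene_sites] < ords[i]]
      barrier <- any(vapply(between, function(j) parent_state(e, j),
                            logical(1)))
      if (barrier) { blocks[[length(blocks) + 1L]] <- cur; cur <- ords[i] }
      else cur <- c(cur, ords[i])
    }
    blocks[[length(blocks) + 1L]] <- cur
    for (b in blocks)
      events[[length(events) + 1L]] <- data.frame(
        branch = e, gene = gn,
        sites = paste(fmt_ordinal(b), collapse = ";"),
        kind = kind, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, c(events, list(make.row.names = FALSE)))
  ev <- ev[order(ev$branch, ev$gene, ev$sites), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, count = nrow(ev))
}
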