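## idp_classifier: intron distribution pattern (IDP) classes.
## States are fully categorical — type, subtype and insert signature, not
## bare presence — so patterns distinguished only by, e.g., a subtype A/B
## difference at one site still separate.

#' Build the strains-by-sites state matrix from intron observations
#'
#' Cell states are `"0"` for absence, otherwise
#' `type[:subtype][+insN@off...]`. Absence is a state, never missing data.
#'
#' @param observations combined data.frame from [map_introns()] over all
#'   strains (rows may come from several calls).
#' @param include_novel keep sites flagged novel (default drops them: the
#'   registry frame defines the classification).
#' @return character matrix, rows = strains, columns = sites in
#'   gene/ordinal order.
#' @export
build_state_matrix <- function(observations, include_novel = FALSE) {
  obs <- observations
  if (!include_novel) obs <- obs[!obs$novel, , drop = FALSE]
  state <- ifelse(!obs$present, "0",
                  paste0(obs$type_label,
                         ifelse(obs$subtype_label %in% c("none", ""), "",
                                paste0(":", obs$subtype_label)),
                         ifelse(nzchar(obs$inserts),
                                paste0("+", obs$inserts), "")))
  key <- unique(obs[order(obs$gene, obs$ordinal), c("gene", "ordinal")])
  cols <- site_key(key$gene, key$ordinal)
  strains <- unique(obs$strain_id)
  m <- matrix("0", length(strains), length(cols),
              dimnames = list(strains, cols))
  m[cbind(match(obs$strain_id, strains), match(obs$site, cols))] <- state
  m
}

#' Select variable intronic sites
#'
#' @param m state matrix from [build_state_matrix()].
#' @param scope strain subset (default all rows).
#' @return site (column) names with at least two distinct states within
#'   scope, in registry order.
#' @export
select_variable_sites <- function(m, scope = NULL) {
  if (is.null(scope)) scope <- rownames(m)
  stopifnot(length(scope) > 0L, all(scope %in% rownames(m)))
  sub <- m[scope, , drop = FALSE]
  colnames(sub)[apply(sub, 2L, function(col) length(unique(col)) >= 2L)]
}

## post-order leaf sequence of a rooted tree
postorder_tips <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  child <- tr$edge[, 2]
  tips <- child[child <= length(tr$tip.label)]
  tr$tip.label[tips]
}

#' Assign strains to IDP classes
#'
#' Strains with identical state vectors over the variable sites form one
#' class. Labels `IDP1..IDPk` follow first-member occurrence in the tree's
#' post-order leaf sequence when a tree is given, else first occurrence in
#' matrix row order, so the partition itself is input-order invariant.
#'
#' @param m state matrix.
#' @param variable_sites column subset (default: [select_variable_sites()]).
#' @param ordering_tree optional rooted `phylo` whose leaves cover the
#'   strains.
#' @param scope strains to classify (default all; the reference analysis
#'   excludes outgroup strains so the class frame is species-internal).
#' @return list with `assignment` (named strain -> label), `classes`
#'   (data.frame: `label`, `n_members`, `members`, `cox1_intron_count`).
#' @export
assign_idp_classes <- function(m, variable_sites = NULL,
                               ordering_tree = NULL, scope = NULL) {
  if (is.null(scope)) scope <- rownames(m)
  if (is.null(variable_sites)) variable_sites <- select_variable_sites(m, scope)
  stopifnot(all(variable_sites %in% colnames(m)))
  sub <- m[scope, variable_sites, drop = FALSE]
  keys <- if (length(variable_sites) == 0L)
    setNames(rep("", length(scope)), scope)   # no variation: one class
  else setNames(apply(sub, 1L, paste, collapse = "\r"), rownames(sub))
  ord_strains <- scope
  if (!is.null(ordering_tree)) {
    tips <- postorder_tips(ordering_tree)
    missing <- setdiff(scope, tips)
    if (length(missing))
      stop("ordering tree lacks leaves for strains: ",
           paste(missing, collapse = ", "))
    ord_strains <- tips[tips %in% scope]
  }
  first_key <- unique(unname(keys[ord_strains]))
  assignment <- setNames(paste0("IDP", match(keys, first_key)), names(keys))
  cox1_cols <- grep("^cox1\\|", colnames(m), value = TRUE)
  classes <- do.call(rbind, lapply(seq_along(first_key), function(i) {
    mem <- names(assignment)[assignment == paste0("IDP", i)]
    data.frame(label = paste0("IDP", i), n_members = length(mem),
               members = paste(mem, collapse = ","),
               cox1_intron_count =
                 if (length(cox1_cols)) sum(m[mem[1], cox1_cols] != "0")
                 else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  list(assignment = assignment, classes = classes,
       variable_sites = variable_sites)
}

#' Adjusted Rand index between two partitions
#'
#' Standard permutation-model form computed from the contingency table.
#'
#' @param a,b named label vectors over the same elements.
#' @return numeric ARI (1 for identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(setequal(names(a), names(b)))
  b <- b[names(a)]
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

#' Congruence between the IDP partition and the clade partition
#'
#' @param idp named strain -> IDP label vector.
#' @param clades named strain -> clade vector over the same strains.
#' @return list with `n_classes`, `single_clade_class_count`, `class_spread`
#'   (clades per IDP class), and `ari`.
#' @export
idp_clade_congruence <- function(idp, clades) {
  if (!setequal(names(idp), names(clades)))
    stop("IDP and clade partitions cover different strain sets")
  clades <- clades[names(idp)]
  spread <- tapply(clades, idp, function(x) length(unique(x)))
  list(n_classes = length(spread),
       single_clade_class_count = sum(spread == 1L),
       class_spread = spread,
       ari = adjusted_rand_index(idp, clades))
}

#' Collapse SNP rows into haplotypes
#'
#' @param aln character matrix (strains x sites); missing states are `NA`.
#' @param missing_policy `"drop_columns"` removes every column containing a
#'   missing state before grouping; `"strict"` treats missing as its own
#'   state.
#' @return list with `n_haplotypes`, `assignment` (strain -> haplotype id),
#'   `n_sites_used`.
#' @export
collapse_haplotypes <- function(aln,
                                missing_policy = c("drop_columns", "strict")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.matrix(aln))
  if (missing_policy == "drop_columns") {
    keep <- colSums(is.na(aln)) == 0L
    if (!any(keep)) stop("no columns left after dropping missing columns")
    aln <- aln[, keep, drop = FALSE]
  } else {
    aln[is.na(aln)] <- "?"
  }
  keys <- apply(aln, 1L, paste, collapse = "\r")
  hap <- as.integer(factor(keys, levels = unique(keys)))
  names(hap) <- rownames(aln)
  list(n_haplotypes = length(unique(hap)), assignment = hap,
       n_sites_used = ncol(aln))
}

#' Classify SNP positions by annotation region
#'
#' Positions inside an exonic segment of a CDS/rRNA/tRNA are `exon`; else
#' inside an intron feature, `intron`; else `intergenic`.
#'
#' @param positions 1-based genomic positions (VCF convention), or a
#'   data.frame with a `POS` column.
#' @param genome an [annotated_genome()].
#' @return list with `fractions` (named, sums to 1), `counts`, `region`
#'   (per-position assignment).
#' @export
classify_snp_regions <- function(positions, genome) {
  if (is.data.frame(positions)) positions <- positions$POS
  positions <- as.integer(positions)
  L <- genome_length(genome)
  bad <- which(positions < 1L | positions > L)
  if (length(bad))
    stop("variant position out of range [1, ", L, "] at record ",
         paste(bad, collapse = ", "))
  seg_table <- function(kinds) {
    fs <- features_of(genome, kinds)
    if (!length(fs)) return(matrix(numeric(0), ncol = 2))
    do.call(rbind, lapply(fs, function(f) f$segments))
  }
  exons <- seg_table(c("CDS", "rRNA", "tRNA"))
  intr <- seg_table("intron")
  p0 <- positions - 1L
  inside <- function(tab) {
    if (nrow(tab) == 0L) return(rep(FALSE, length(p0)))
    vapply(p0, function(p) any(tab[, 1] <= p & p < tab[, 2]), logical(1))
  }
  region <- ifelse(inside(exons), "exon",
                   ifelse(inside(intr), "intron", "intergenic"))
  counts <- table(factor(region, levels = c("exon", "intron", "intergenic")))
  fractions <- setNames(as.numeric(counts) / length(region), names(counts))
  list(fractions = fractions, counts = counts, region = region)
}
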