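test_that("variable-site selection equals a column-scan oracle", {
  m <- matrix("1", 4, 3, dimnames = list(paste0("S", 1:4),
                                         c("cox1|1", "cox1|2", "cob|1")))
  expect_length(select_variable_sites(m), 0L)
  m[2, "cox1|2"] <- "0"
  expect_equal(select_variable_sites(m), "cox1|2")
  ## random categorical matrix vs distinct-count oracle
  set.seed(41)
  r <- matrix(sample(c("0", "1", "2"), 20 * 8, replace = TRUE), 20, 8,
              dimnames = list(sprintf("S%02d", 1:20),
                              paste0("cox1|", 1:8)))
  oracle <- colnames(r)[vapply(seq_len(ncol(r)), function(j)
    length(unique(r[, j])) >= 2, logical(1))]
  expect_equal(select_variable_sites(r), oracle)
})

test_that("IDP classes partition strains by identical state vectors", {
  m <- matrix("1", 5, 2, dimnames = list(paste0("S", 1:5),
                                         c("cox1|1", "cox1|2")))
  one <- assign_idp_classes(m)
  expect_equal(length(unique(one$assignment)), 1L)
  expect_equal(sum(one$classes$n_members), 5L)

  ## 20 strains, 5 planted vectors -> unique-row oracle
  set.seed(42)
  vecs <- matrix(sample(c("0", "1", "2:A", "2:B"), 5 * 6, replace = TRUE),
                 5, 6)
  while (anyDuplicated(apply(vecs, 1, paste, collapse = "/")))
    vecs <- matrix(sample(c("0", "1", "2:A", "2:B"), 5 * 6,
                          replace = TRUE), 5, 6)
  pick <- sample(1:5, 20, replace = TRUE)
  pick[1:5] <- 1:5                        # every vector represented
  m2 <- vecs[pick, ]
  dimnames(m2) <- list(sprintf("S%02d", 1:20), paste0("cox1|", 1:6))
  got <- assign_idp_classes(m2)
  expect_equal(nrow(got$classes), 5L)
  oracle <- as.integer(factor(apply(m2, 1, paste, collapse = "/"),
                              levels = unique(apply(m2, 1, paste,
                                                    collapse = "/"))))
  expect_equal(adjusted_rand_index(got$assignment,
                                   setNames(as.character(oracle),
                                            rownames(m2))), 1)
})

test_that("the partition is invariant to strain input order", {
  set.seed(43)
  m <- matrix(sample(c("0", "1"), 12 * 4, replace = TRUE), 12, 4,
              dimnames = list(sprintf("S%02d", 1:12), paste0("cob|", 1:4)))
  a <- assign_idp_classes(m)$assignment
  perm <- sample(rownames(m))
  b <- assign_idp_classes(m[perm, ])$assignment
  expect_equal(adjusted_rand_index(a, b), 1)
})

test_that("restricting to a strain subset never adds classes", {
  set.seed(44)
  m <- matrix(sample(c("0", "1", "2"), 15 * 5, replace = TRUE), 15, 5,
              dimnames = list(sprintf("S%02d", 1:15), paste0("cox1|", 1:5)))
  full <- assign_idp_classes(m)
  for (i in 1:5) {
    sub <- sample(rownames(m), 8)
    subcl <- assign_idp_classes(m, scope = sub)
    expect_lte(nrow(subcl$classes),
               length(unique(full$assignment[sub])) + 0L)
    expect_equal(nrow(subcl$classes), length(unique(full$assignment[sub])))
  }
})

test_that("tree-based label ordering is deterministic and validated", {
  m <- matrix(c("1", "1", "0", "0"), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), "cox1|1"))
  tree <- ape::read.tree(text = "((c,d),(a,b));")
  got <- assign_idp_classes(m, ordering_tree = tree)
  ## labels follow first occurrence in the tree's post-order leaf sequence
  tips <- mitostruct:::postorder_tips(tree)
  expect_equal(unname(got$assignment[tips[1]]), "IDP1")
  ## deterministic across calls and row permutations
  got2 <- assign_idp_classes(m[c("d", "a", "c", "b"), , drop = FALSE],
                             ordering_tree = tree)
  expect_identical(got$assignment[sort(names(got$assignment))],
                   got2$assignment[sort(names(got2$assignment))])
  bad <- ape::read.tree(text = "((c,d),(a,x));")
  expect_error(assign_idp_classes(m, ordering_tree = bad), "lacks leaves")
})

test_that("congruence counts and ARI match oracles", {
  idp <- setNames(rep(c("IDP1", "IDP2", "IDP3"), each = 4),
                  sprintf("S%02d", 1:12))
  same <- setNames(idp, names(idp))
  r <- idp_clade_congruence(idp, same)
  expect_equal(r$ari, 1)
  expect_equal(r$single_clade_class_count, 3L)

  split <- setNames(rep(c("A", "B"), 6), names(idp))   # each class spread 2
  r2 <- idp_clade_congruence(idp, split)
  expect_true(all(r2$class_spread == 2))
  expect_equal(r2$single_clade_class_count, 0L)

  ## random partitions vs contingency-table oracle and mclust
  set.seed(45)
  for (i in 1:5) {
    a <- setNames(sample(paste0("I", 1:4), 50, replace = TRUE),
                  sprintf("S%02d", 1:50))
    b <- setNames(sample(paste0("C", 1:3), 50, replace = TRUE),
                  sprintf("S%02d", 1:50))
    tab <- table(a, b)
    sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2)); n2 <- choose(50, 2)
    oracle <- (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
    expect_equal(adjusted_rand_index(a, b), oracle)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a[sort(names(a))],
                                           b[sort(names(b))]))
  }
})

test_that("haplotype collapsing honors the missing-data policy", {
  aln <- matrix(c("A", "A", "C", "G",
                  "T", "T", "T", "A",
                  "G", "G", "G", "G"), 4, 3,
                dimnames = list(paste0("S", 1:4), NULL))
  got <- collapse_haplotypes(aln)
  expect_equal(got$n_haplotypes, 3L)      # rows 1 and 2 identical
  all_diff <- matrix(as.character(1:9), 3, 3,
                     dimnames = list(paste0("S", 1:3), NULL))
  expect_equal(collapse_haplotypes(all_diff)$n_haplotypes, 3L)

  ## planted missing cells: drop_columns equals the manually filtered oracle
  set.seed(46)
  m <- matrix(sample(c("A", "C"), 10 * 6, replace = TRUE), 10, 6,
              dimnames = list(sprintf("S%02d", 1:10), NULL))
  m[2, 3] <- NA; m[7, 5] <- NA
  got2 <- collapse_haplotypes(m, "drop_columns")
  oracle_m <- m[, colSums(is.na(m)) == 0]
  oracle_n <- length(unique(apply(oracle_m, 1, paste, collapse = "")))
  expect_equal(got2$n_haplotypes, oracle_n)
  expect_equal(got2$n_sites_used, 4L)
  ## strict mode treats missing as its own state
  strict <- collapse_haplotypes(m, "strict")
  expect_gte(strict$n_haplotypes, got2$n_haplotypes)
  ## all columns missing -> error
  allna <- matrix(NA_character_, 2, 2,
                  dimnames = list(c("a", "b"), NULL))
  expect_error(collapse_haplotypes(allna), "no columns left")
})

test_that("SNP positions are classified by annotation region", {
  g <- intron_gene_genome(exon_len = 1000, spliced_pos = 400,
                          intron_len = 200, seed = 47)
  ## layout: 200 lead + [200,600) exon + [600,800) intron + [800,1400) exon
  r <- classify_snp_regions(c(300, 700, 50), g)
  expect_equal(r$region, c("exon", "intron", "intergenic"))
  expect_equal(sum(r$fractions), 1)
  expect_error(classify_snp_regions(10^6, g), "out of range")

  ## 100 random positions vs an interval-membership oracle
  set.seed(48)
  pos <- sample(nchar(g$sequence), 100)
  got <- classify_snp_regions(pos, g)
  exon_iv <- do.call(rbind, lapply(mitostruct:::features_of(
    g, c("CDS", "rRNA", "tRNA")), function(f) f$segments))
  intr_iv <- do.call(rbind, lapply(mitostruct:::features_of(g, "intron"),
                                   function(f) f$segments))
  oracle <- vapply(pos - 1, function(p) {
    if (any(exon_iv[, 1] <= p & p < exon_iv[, 2])) "exon"
    else if (any(intr_iv[, 1] <= p & p < intr_iv[, 2])) "intron"
    else "intergenic"
  }, character(1))
  expect_equal(got$region, oracle)
})
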