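test_that("registry sites have strictly increasing spliced positions", {
  ## host gene carrying 19 introns (a large cox1-style intron reservoir)
  pos <- sort(sample(seq(50, 1950, by = 10), 19))
  g <- intron_gene_genome(exon_len = 2000, spliced_pos = pos, seed = 21)
  reg <- build_site_registry(g)
  expect_equal(nrow(reg$sites), 19L)
  expect_equal(reg$sites$gene, rep("cox1", 19))
  expect_equal(reg$sites$ordinal, 1:19)
  expect_true(all(diff(reg$sites$spliced_pos) > 0))
  expect_equal(reg$sites$spliced_pos, pos)
})

test_that("genes without introns contribute no sites", {
  g <- intron_gene_genome(spliced_pos = integer(0), seed = 22)
  reg <- build_site_registry(g)
  expect_equal(nrow(reg$sites), 0L)
})

test_that("augmentation is idempotent within tolerance and stable beyond", {
  g <- intron_gene_genome(spliced_pos = c(500, 1200), seed = 23)
  reg <- build_site_registry(g)
  reg2 <- augment_registry(reg, "cox1", 503, tol = 6)
  expect_equal(nrow(reg2$sites), 2L)      # within tol: unchanged
  reg3 <- augment_registry(reg, "cox1", 800, tol = 6)
  expect_equal(nrow(reg3$sites), 3L)
  novel <- reg3$sites[reg3$sites$novel, ]
  expect_equal(novel$ordinal, 1.5)        # fractional: no renumbering
  expect_equal(reg3$sites$ordinal[!reg3$sites$novel], c(1, 2))
})

test_that("mapping the reference onto its own registry reproduces the catalog", {
  cache <- sim_cache()
  reg <- sim_registry(cache$truth, cache$realized$reference)
  obs <- map_introns(cache$realized$reference, reg)
  expect_true(all(obs$present))
  expect_equal(nrow(obs), nrow(reg$sites))
  expect_true(all(obs$type_label == "1"))
})

test_that("a deleted intron yields present=FALSE at exactly that site", {
  g <- intron_gene_genome(spliced_pos = c(300, 900, 1500), seed = 24)
  reg <- build_site_registry(g)
  g_del <- intron_gene_genome(spliced_pos = c(300, 1500), seed = 24)
  ## same seed: identical exon; introns regenerated in order, so re-map by
  ## position only (classification off)
  obs <- map_introns(g_del, reg, classify = FALSE)
  expect_equal(obs$present[obs$ordinal == 2], FALSE)
  expect_equal(sum(obs$present), 2L)
})

test_that("site assignment tolerates heavy exon substitution", {
  cache <- sim_cache()
  truth <- cache$truth
  ## rebuild one leaf with 5% exon noise; substitutions never move spliced
  ## coordinates, so assignments must equal the truth state's sites
  p <- truth$params; p$exon_noise <- 0.05
  tr2 <- truth; tr2$params <- p
  id <- rownames(truth$leaf_states)[1]
  g <- mitostruct:::build_sim_genome(tr2, id, truth$leaf_states[id, ],
                                     truth$dpo_profiles[[id]],
                                     truth$mir_orientation[[id]])
  reg <- sim_registry(truth, cache$realized$reference)
  obs <- map_introns(g, reg)
  want_present <- truth$leaf_states[id, obs$site] != "0"
  expect_equal(unname(obs$present), unname(want_present))
})

test_that("two introns mapping to one site is rejected", {
  g <- intron_gene_genome(spliced_pos = c(500, 504), seed = 25)
  reg0 <- build_site_registry(intron_gene_genome(spliced_pos = 500,
                                                 seed = 25))
  expect_error(map_introns(g, reg0, tol = 6), "map to one site")
})

test_that("type classification assigns by identity and registers new types", {
  set.seed(26)
  ex1 <- rseq(500)
  exemplars <- list(list(type_label = "23-2", exemplar_seq = ex1,
                         subtype_variants = NULL))
  got <- classify_intron_type(exemplars, ex1)
  expect_equal(got$type_label, "23-2")
  expect_equal(got$identity, 1.0)
  ## ~70% identity (substitution only): below the 0.90 threshold
  far <- mitostruct:::mutate_seq(ex1, 0.35)
  oracle_id <- hamming_identity(far, ex1)
  expect_lt(oracle_id, 0.9)
  got2 <- classify_intron_type(exemplars, far, id_threshold = 0.90)
  expect_true(got2$is_new)
  expect_match(got2$type_label, "^new")
  expect_lt(abs(got2$identity - oracle_id), 0.02)
})

test_that("subtypes are called from declared variant columns", {
  set.seed(27)
  ex1 <- rseq(600)
  variants <- data.frame(position = c(101L, 201L),
                         ref_state = c(substr(ex1, 101, 101),
                                       substr(ex1, 201, 202)),
                         alt_state = c(setdiff(c("A", "C", "G", "T"),
                                               substr(ex1, 101, 101))[1],
                                       "-"),
                         stringsAsFactors = FALSE)
  exemplars <- list(list(type_label = "1", exemplar_seq = ex1,
                         subtype_variants = variants))
  expect_equal(classify_intron_type(exemplars, ex1)$subtype_label, "A")
  ## apply the SNP and the 2-bp deletion -> subtype B, same type
  b <- mitostruct:::apply_subtype_b(ex1, variants)
  gotb <- classify_intron_type(exemplars, b)
  expect_equal(gotb$type_label, "1")
  expect_equal(gotb$subtype_label, "B")
})

test_that("anomaly screen finds planted inserts and truncations", {
  set.seed(28)
  ex <- rseq(900)
  expect_equal(nrow(detect_intron_anomalies(ex, ex)$inserts), 0L)
  expect_false(detect_intron_anomalies(ex, ex)$degenerate)
  ## a 1238 nt foreign segment planted internally
  obs <- paste0(substr(ex, 1, 500), rseq(1238), substr(ex, 501, 900))
  an <- detect_intron_anomalies(obs, ex)
  expect_equal(nrow(an$inserts), 1L)
  expect_equal(an$inserts$length, 1238L)
  expect_lt(abs(an$inserts$offset - 500L), 10L)
  ## 40% truncated at the 3' end
  an2 <- detect_intron_anomalies(substr(ex, 1, 540), ex)
  expect_true(an2$degenerate)
})

test_that("observations cover exactly the registry sites for each strain", {
  cache <- sim_cache()
  reg <- sim_registry(cache$truth, cache$realized$reference)
  for (g in cache$realized$genomes[1:2]) {
    obs <- map_introns(g, reg)
    expect_equal(sort(obs$site), sort(site_key <- with(reg$sites,
      mitostruct:::site_key(gene, ordinal))))
    expect_false(any(duplicated(obs$site)))
  }
})
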