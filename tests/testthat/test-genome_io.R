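test_that("GenBank join and complement locations parse to half-open segments", {
  gb <- c(
    "LOCUS       TOY              1200 bp    DNA     circular     UNA 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     source          1..1200",
    "     CDS             join(1..200,501..900)",
    "                     /gene=\"cox1\"",
    "     CDS             complement(join(951..1000,1051..1100))",
    "                     /gene=\"nad3\"",
    "ORIGIN")
  seq <- paste(rep("acgt", 300), collapse = "")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(gb, paste("        1", seq), "//"), path)
  g <- read_genbank(path)
  expect_equal(nchar(g$sequence), 1200L)
  cox1 <- mitostruct:::features_of(g, name = "cox1")[[1]]
  expect_equal(nrow(cox1$segments), 2L)
  expect_equal(cox1$strand, "+")
  ## 1-based inclusive 1..200 -> [0, 200); 501..900 -> [500, 900)
  expect_equal(unname(cox1$segments[, "start"]), c(0L, 500L))
  expect_equal(unname(cox1$segments[, "end"]), c(200L, 900L))
  ## complement(join(951..1000, 1051..1100)): forward-strand half-open
  ## segments [950,1000) and [1050,1100), gene order 5'->3' = descending
  nad3 <- mitostruct:::features_of(g, name = "nad3")[[1]]
  expect_equal(nad3$strand, "-")
  expect_equal(unname(nad3$segments[, "start"]), c(1050L, 950L))
  expect_equal(unname(nad3$segments[, "end"]), c(1100L, 1000L))
})

test_that("write -> read round-trips a simulated genome losslessly", {
  g <- sim_cache()$realized$genomes[[1]]
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g, g2)
  ## read -> write -> read is a fixed point
  path2 <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g2, path2)
  expect_identical(read_genbank(path2), g2)
  ## fasta+table dialect round-trips too
  fp <- withr::local_tempfile(fileext = ".fasta")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_genome(g, fp, format = "fasta+table", table_path = tp)
  g3 <- read_annotated_genome(fp, format = "fasta+table", table_path = tp)
  expect_identical(g3$sequence, g$sequence)
  expect_identical(g3$features, g$features)
})

test_that("constructor rejects bad input with informative errors", {
  expect_error(annotated_genome("x", "ACGTR"), "ambiguity")
  expect_error(annotated_genome("x", ""), "empty")
  expect_error(
    annotated_genome("x", "ACGTACGT",
                     list(feature("i1", "intron", "+", c(0, 4)))),
    "host_gene")
})

test_that("normalize_orientation anchors rotation and strand", {
  g <- sim_cache()$realized$genomes[[2]]
  n0 <- normalize_orientation(g)
  ## anchor starts at position 0 on +
  anchor <- mitostruct:::features_of(n0, name = "cox1")[[1]]
  expect_equal(unname(anchor$segments[1, 1]), 0L)
  expect_equal(anchor$strand, "+")
  ## rotation invariance
  expect_identical(normalize_orientation(mitostruct:::rotate_genome(g, 100)),
                   n0)
  expect_identical(normalize_orientation(mitostruct:::rotate_genome(g, 31123)),
                   n0)
  ## strand invariance
  expect_identical(normalize_orientation(mitostruct:::revcomp_genome(g)), n0)
  ## missing anchor lists available genes
  expect_error(normalize_orientation(g, "cox9"), "cox9.*available genes",
               perl = TRUE)
})

test_that("composition statistics match direct arithmetic and an oracle", {
  s1 <- compute_genome_stats(annotated_genome("a", "ACGT"))
  expect_equal(s1$at_content, 0.5)
  expect_equal(s1$gc_skew, 0)
  s2 <- compute_genome_stats(annotated_genome("b", "GGGGCC"))
  expect_equal(s2$at_content, 0)
  expect_equal(s2$gc_skew, (4 - 2) / 6)
  ## 10 kb pseudo-random sequence vs single-pass counting oracle
  set.seed(20240917)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.28, 0.02)), collapse = "")
  got <- compute_genome_stats(annotated_genome("c", s))
  expect_equal(got, count_stats_oracle(s))
})

test_that("stats are rotation invariant; reverse complement flips GC skew", {
  g <- sim_cache()$realized$genomes[[3]]
  s <- compute_genome_stats(g)
  expect_identical(compute_genome_stats(mitostruct:::rotate_genome(g, 7777)),
                   s)
  src <- compute_genome_stats(mitostruct:::revcomp_genome(g))
  expect_equal(src$gc_skew, -s$gc_skew)
  expect_equal(src$at_content, s$at_content)
})

test_that("metadata table validates strain ids and varieties", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tclade\tvariety",
               "S1\tcladeA\tbisporus", "S2\tcladeB\tburnettii"), path)
  m <- read_strain_metadata(path)
  expect_equal(m$cultivar_status, c("unknown", "unknown"))
  writeLines(c("strain_id\tvariety", "S1\tbisporus", "S1\tbisporus"), path)
  expect_error(read_strain_metadata(path), "duplicated")
  writeLines(c("strain_id\tvariety", "S1\tvar_x"), path)
  expect_error(read_strain_metadata(path), "variety")
})
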