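## Fixtures built in code: tiny annotated genomes assembled base by base so
## expected coordinates are known exactly.

rseq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## genome with one host gene carrying the given introns at known spliced
## positions; returns the genome plus the expected spliced positions
intron_gene_genome <- function(gene = "cox1", exon_len = 2000,
                               spliced_pos = c(500, 1200),
                               intron_len = 300, seed = 1,
                               strain_id = "FIX") {
  set.seed(seed)
  exon <- rseq(exon_len)
  introns <- lapply(seq_along(spliced_pos), function(i)
    list(ordinal = i, spliced_pos = spliced_pos[i], seq = rseq(intron_len)))
  blk <- mitostruct:::blk_gene(gene, "CDS", exon, introns)
  lead <- rseq(200); trail <- rseq(200)
  feats <- lapply(blk$features, function(f) {
    f$segments <- f$segments + 200L
    f
  })
  annotated_genome(strain_id, paste0(lead, blk$seq, trail), feats)
}

## genome with an anchor gene, an inverted-repeat pair, and marker genes in
## between; marker strands controlled by `orientation`
mir_fixture_genome <- function(orientation = c("forward", "reverse",
                                               "duplicated_both"),
                               seed = 3) {
  orientation <- match.arg(orientation)
  set.seed(seed)
  anchor <- rseq(900)
  irs <- rseq(800)
  markers <- c("nad2", "nad3", "rrnL", "rps3")
  mseq <- lapply(markers, function(x) rseq(400))
  spacer <- function(n = 300) rseq(n)
  parts <- list(anchor, spacer(), irs, spacer())
  feats <- list(feature("cox1", "CDS", "+", c(0L, 900L)))
  pos <- 900L + 300L
  feats <- c(feats, list(feature("irsA", "other", "+", c(pos, pos + 800L))))
  pos <- pos + 800L + 300L
  mstrand <- if (orientation == "reverse") "-" else "+"
  for (i in seq_along(markers)) {
    s <- if (mstrand == "-") mitostruct::revcomp(mseq[[i]]) else mseq[[i]]
    parts <- c(parts, list(s))
    feats <- c(feats, list(feature(markers[i], if (markers[i] == "rrnL")
      "rRNA" else "CDS", mstrand, c(pos, pos + 400L))))
    pos <- pos + 400L
  }
  parts <- c(parts, list(spacer()))
  pos <- pos + 300L
  parts <- c(parts, list(mitostruct::revcomp(irs)))
  feats <- c(feats, list(feature("irsB", "other", "-", c(pos, pos + 800L))))
  pos <- pos + 800L
  if (orientation == "duplicated_both") {
    parts <- c(parts, list(spacer(), mitostruct::revcomp(mseq[[4]])))
    feats <- c(feats, list(feature("rps3", "CDS", "-",
                                   c(pos + 300L, pos + 700L))))
    pos <- pos + 700L
  }
  parts <- c(parts, list(spacer(2000)))
  annotated_genome("MIRFIX", paste(unlist(parts), collapse = ""), feats)
}

## genomes carrying planted dpo fragments in a random background
dpo_fixture_genome <- function(strain_id, fragments, exemplars, seed = 5) {
  set.seed(seed + nchar(strain_id) + sum(utf8ToInt(strain_id)))
  parts <- list(rseq(2000))
  feats <- list(feature("cox1", "CDS", "+", c(0L, 500L)))
  pos <- 2000L
  for (fid in fragments) {
    s <- exemplars[[fid]]
    parts <- c(parts, list(s, rseq(500)))
    feats <- c(feats, list(feature(fid, "dpo", "+", c(pos, pos + nchar(s)),
                                   c(note = "dpo fragment"))))
    pos <- pos + nchar(s) + 500L
  }
  parts <- c(parts, list(rseq(1000)))
  annotated_genome(strain_id, paste(unlist(parts), collapse = ""), feats)
}

## cached small simulation shared across test files
sim_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- simulate_evolution(params = sim_params(n_leaves = 6, seed = 42))
      cache <<- list(truth = truth, realized = realize_genomes(truth))
    }
    cache
  }
})
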