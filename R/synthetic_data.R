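## synthetic_data: seeded simulator of mitogenome structural evolution.
## A reduced-scale circular genome (~50 kb, AT ~0.71) carries the standard
## gene inventory (15 protein genes, 2 rRNAs, 20 tRNAs), a planted pair of
## inverted repeats of 8 tRNAs flanking an invertible MIR segment
## (nad2/nad3/rrnL/rps3 + 9 tRNAs), up to 8 dpo fragment slots between the
## first repeat and the MIR, and 21 intron insertion sites over the 7
## intron-hosting genes. Intron presence evolves by Poisson gain, loss and
## correlated block loss along a tree; dpo fragments gain/lose per lineage;
## the MIR flips orientation. Every process is reproducible from the seed.

#' Simulation parameters
#'
#' Rates are events per site (or fragment) per unit branch length; trees
#' are scaled to unit height. Defaults emulate a population where intron
#' loss dominates gain, losses occasionally extend to neighboring sites,
#' and MIR inversions are rare enough to be clade-consistent.
#'
#' @param n_leaves number of strains to simulate.
#' @param seed integer seed; every random draw derives from it.
#' @param gain_rate,loss_rate intron gain/loss rates.
#' @param block_loss_prob probability a loss extends to the next present
#'   site of the gene (per additional site).
#' @param dpo_gain_rate,dpo_loss_rate dpo fragment turnover rates.
#' @param inversion_rate MIR flips per unit branch length.
#' @param at_content_target genome AT fraction.
#' @param exon_noise,intron_noise per-base substitution probabilities
#'   applied per leaf (intron noise never touches declared subtype
#'   variant columns).
#' @param root_orientation MIR orientation at the root.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_leaves = 8, seed = 1, gain_rate = 0.05,
                       loss_rate = 0.15, block_loss_prob = 0.4,
                       dpo_gain_rate = 0.1, dpo_loss_rate = 0.2,
                       inversion_rate = 0.1, at_content_target = 0.71,
                       exon_noise = 0.01, intron_noise = 0.003,
                       root_orientation = "reverse") {
  stopifnot(n_leaves >= 2, gain_rate >= 0, loss_rate >= 0,
            dpo_gain_rate >= 0, dpo_loss_rate >= 0, inversion_rate >= 0,
            block_loss_prob >= 0, block_loss_prob <= 1,
            at_content_target > 0, at_content_target < 1)
  structure(as.list(environment()), class = "sim_params")
}

## gene inventory of the reduced scaffold; sites are spread evenly over the
## spliced gene
scaffold_genes <- function() {
  data.frame(
    name = c("cox1", "nad5", "cob", "cox2", "nad4", "nad1", "cox3",
             "atp6", "atp8", "atp9", "nad4L", "nad6", "rrnS",
             "nad2", "nad3", "rps3", "rrnL"),
    kind = c(rep("CDS", 12), "rRNA", "CDS", "CDS", "CDS", "rRNA"),
    exon_len = c(1600L, 1200L, 1100L, 700L, 1000L, 900L, 800L,
                 700L, 150L, 220L, 270L, 600L, 1400L,
                 1400L, 350L, 1300L, 2800L),
    n_introns = c(8L, 2L, 4L, 2L, 1L, 2L, 2L, rep(0L, 10)),
    region = c(rep("core", 13), rep("mir", 4)),
    stringsAsFactors = FALSE)
}

scaffold_sites <- function(genes = scaffold_genes()) {
  rows <- list()
  for (i in which(genes$n_introns > 0L)) {
    n <- genes$n_introns[i]
    pos <- as.integer(round(genes$exon_len[i] * seq_len(n) / (n + 1L)))
    rows[[length(rows) + 1L]] <- data.frame(
      gene = genes$name[i], ordinal = seq_len(n), spliced_pos = pos,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## number of intron types per site: a few multi-type sites mirror sites
## carrying two or three divergent introns; cox1 site 5 type 1 also gets
## declared subtype variant columns (a SNP and a 2-bp deletion)
scaffold_site_types <- function(sites) {
  n_types <- rep(1L, nrow(sites))
  n_types[sites$gene == "cox1" & sites$ordinal == 3L] <- 2L
  n_types[sites$gene == "cox1" & sites$ordinal == 5L] <- 2L
  n_types[sites$gene == "cox1" & sites$ordinal == 6L] <- 3L
  n_types
}

irs_trnas <- function() paste0("trn", c("E", "F", "G", "H", "I", "K", "L", "M"))
mir_trnas <- function() paste0("trn", c("N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
free_trnas <- function() paste0("trn", c("A", "C", "D"))

n_dpo_fragments <- 8L
dpo_root_set <- c(1L, 2L, 4L, 5L, 6L)   # basal-clade style composition

## coalescent tree on n leaves, scaled to unit height, tips S01..Snn
sim_tree <- function(n_leaves) {
  tr <- ape::rcoal(n_leaves, tip.label = sprintf("S%02d", seq_len(n_leaves)))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

## clade labels: split the largest root-ward group until k groups exist
clades_from_tree <- function(tree, k = 3L) {
  nt <- length(tree$tip.label)
  below <- tips_below(tree)
  groups <- as.list(tree$edge[tree$edge[, 1] == nt + 1L, 2])
  while (length(groups) < k) {
    sizes <- vapply(groups, function(n) length(below[[n]]), integer(1))
    internal <- vapply(groups, function(n) n > nt, logical(1))
    cand <- which(internal & sizes > 1L)
    if (!length(cand)) break
    pick <- cand[which.max(sizes[cand])]
    node <- groups[[pick]]
    kids <- as.list(tree$edge[tree$edge[, 1] == node, 2])
    groups <- c(groups[-pick], kids)
  }
  lab <- setNames(rep(NA_character_, nt), tree$tip.label)
  ord <- order(vapply(groups, function(n) min(below[[n]]), integer(1)))
  for (i in seq_along(ord)) {
    tips <- below[[groups[[ord[i]]]]]
    lab[tree$tip.label[tips]] <- paste0("clade", i)
  }
  lab
}

#' Simulate mitogenome structural evolution along a tree
#'
#' @param tree rooted `phylo` or `NULL` (a seeded coalescent tree on
#'   `n_leaves` is generated).
#' @param params a [sim_params()] list.
#' @return a `sim_truth` object: the tree, scaffold tables, per-leaf intron
#'   state matrix, MIR orientations, dpo profiles, the event log, the true
#'   IDP partition, and the generated type/dpo exemplar sequences.
#' @export
simulate_evolution <- function(tree = NULL, params = sim_params()) {
  set.seed(params$seed)
  genes <- scaffold_genes()
  sites <- scaffold_sites(genes)
  n_types <- scaffold_site_types(sites)
  keys <- site_key(sites$gene, sites$ordinal)

  ## intron type exemplars: type 1 random, further types ~30-35% diverged
  intron_len <- sample(350:800, nrow(sites), replace = TRUE)
  exemplars <- list()
  for (i in seq_len(nrow(sites))) {
    ex <- list()
    ex[["1"]] <- random_seq(intron_len[i], params$at_content_target)
    for (t in seq_len(n_types[i] - 1L) + 1L)
      ex[[as.character(t)]] <- mutate_seq(ex[["1"]], 0.35)
    exemplars[[keys[i]]] <- ex
  }
  ## subtype variant columns on cox1 site 5 type 1: one SNP, one 2-bp del
  sub_key <- site_key("cox1", 5)
  ex1 <- exemplars[[sub_key]][["1"]]
  snp_ref <- substr(ex1, 101, 101)
  snp_alt <- setdiff(c("A", "C", "G", "T"), snp_ref)[1]
  subtype_variants <- data.frame(
    position = c(101L, 201L),
    ref_state = c(snp_ref, substr(ex1, 201, 202)),
    alt_state = c(snp_alt, "-"), stringsAsFactors = FALSE)

  dpo_exemplars <- setNames(
    lapply(sample(250:400, n_dpo_fragments, replace = TRUE), random_seq,
           at = params$at_content_target),
    paste0("dpo", seq_len(n_dpo_fragments)))

  if (is.null(tree)) tree <- sim_tree(params$n_leaves)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  nt <- length(tree$tip.label)
  root <- nt + 1L

  ## root state
  root_state <- rep("1", nrow(sites))
  root_state[keys == sub_key] <- "1:A"
  node_state <- vector("list", nt + tree$Nnode)
  node_dpo <- vector("list", nt + tree$Nnode)
  node_mir <- character(nt + tree$Nnode)
  node_state[[root]] <- root_state
  node_dpo[[root]] <- seq_len(n_dpo_fragments) %in% dpo_root_set
  node_mir[root] <- params$root_orientation

  events <- list()
  log_event <- function(edge, kind, gene, ords, detail = "") {
    events[[length(events) + 1L]] <<- data.frame(
      edge = edge, kind = kind, gene = gene,
      sites = paste(ords, collapse = ";"), detail = detail,
      stringsAsFactors = FALSE)
  }

  tr <- stats::reorder(tree, "cladewise")    # parents before children
  for (r in seq_len(nrow(tr$edge))) {
    u <- tr$edge[r, 1]; v <- tr$edge[r, 2]; t <- tr$edge.length[r]
    st <- node_state[[u]]; dp <- node_dpo[[u]]; mir <- node_mir[u]
    e_id <- which(tree$edge[, 1] == u & tree$edge[, 2] == v)

    ## intron losses with block extension
    n_loss <- rpois(1L, params$loss_rate * t * sum(st != "0"))
    for (s in seq_len(n_loss)) {
      present <- which(st != "0")
      if (!length(present)) break
      seed_site <- if (length(present) == 1L) present else sample(present, 1L)
      block <- seed_site
      for (dir in c(-1L, 1L)) {
        cur <- seed_site
        repeat {
          gidx <- which(sites$gene == sites$gene[cur])
          nxt <- if (dir > 0L)
            gidx[gidx > max(block) & st[gidx] != "0"][1]
          else rev(gidx[gidx < min(block) & st[gidx] != "0"])[1]
          if (is.na(nxt) || runif(1) >= params$block_loss_prob) break
          block <- sort(c(block, nxt)); cur <- nxt
        }
      }
      st[block] <- "0"
      log_event(e_id, "loss", sites$gene[seed_site], sites$ordinal[block])
    }
    ## intron gains
    n_gain <- rpois(1L, params$gain_rate * t * sum(st == "0"))
    for (s in seq_len(n_gain)) {
      absent <- which(st == "0")
      if (!length(absent)) break
      site <- if (length(absent) == 1L) absent else sample(absent, 1L)
      typ <- as.character(sample(seq_len(n_types[site]), 1L))
      stv <- typ
      if (keys[site] == sub_key && typ == "1")
        stv <- paste0(typ, ":", sample(c("A", "B"), 1L))
      st[site] <- stv
      log_event(e_id, "gain", sites$gene[site], sites$ordinal[site], stv)
    }
    ## dpo turnover
    n_dl <- rpois(1L, params$dpo_loss_rate * t * sum(dp))
    for (s in seq_len(n_dl)) {
      on <- which(dp); if (!length(on)) break
      f <- if (length(on) == 1L) on else sample(on, 1L)
      dp[f] <- FALSE
      log_event(e_id, "dpo_loss", paste0("dpo", f), integer(0))
    }
    n_dg <- rpois(1L, params$dpo_gain_rate * t * sum(!dp))
    for (s in seq_len(n_dg)) {
      off <- which(!dp); if (!length(off)) break
      f <- if (length(off) == 1L) off else sample(off, 1L)
      dp[f] <- TRUE
      log_event(e_id, "dpo_gain", paste0("dpo", f), integer(0))
    }
    ## MIR inversions
    n_flip <- rpois(1L, params$inversion_rate * t)
    if (n_flip %% 2L == 1L) {
      mir <- if (mir == "forward") "reverse" else "forward"
    }
    if (n_flip > 0L) log_event(e_id, "inversion", "MIR", n_flip)

    node_state[[v]] <- st; node_dpo[[v]] <- dp; node_mir[v] <- mir
  }

  leaf_states <- do.call(rbind, lapply(seq_len(nt), function(i)
    node_state[[i]]))
  dimnames(leaf_states) <- list(tree$tip.label, keys)
  mir_orientation <- setNames(node_mir[seq_len(nt)], tree$tip.label)
  dpo_profiles <- setNames(lapply(seq_len(nt), function(i)
    paste0("dpo", which(node_dpo[[i]]))), tree$tip.label)

  ## true IDP partition over variable sites
  varsites <- which(apply(leaf_states, 2L, function(col)
    length(unique(col)) > 1L))
  vkeys <- apply(leaf_states[, varsites, drop = FALSE], 1L, paste,
                 collapse = "\r")
  idp <- setNames(paste0("IDP", as.integer(factor(vkeys,
                                                  levels = unique(vkeys)))),
                  tree$tip.label)

  structure(list(
    params = params, tree = tree, genes = genes, sites = sites,
    site_keys = keys, exemplars = exemplars,
    subtype_variants = list(key = sub_key, type = "1",
                            variants = subtype_variants),
    dpo_exemplars = dpo_exemplars, root_state = root_state,
    leaf_states = leaf_states, mir_orientation = mir_orientation,
    dpo_profiles = dpo_profiles,
    events = if (length(events))
      do.call(rbind, c(events, list(make.row.names = FALSE)))
    else data.frame(edge = integer(0), kind = character(0),
                    gene = character(0), sites = character(0),
                    detail = character(0)),
    idp_truth = idp,
    clades = clades_from_tree(tree, k = min(3L, nt))),
    class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("<sim_truth> %d leaves, %d intron sites, %d events, ",
                     "%d IDP classes\n"),
              length(x$tree$tip.label), nrow(x$sites), nrow(x$events),
              length(unique(x$idp_truth))))
  invisible(x)
}

## apply declared subtype-B edits to a type-1 exemplar (SNP + deletion)
apply_subtype_b <- function(seq, variants) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  drop <- integer(0)
  for (i in seq_len(nrow(variants))) {
    p <- variants$position[i]; w <- nchar(variants$ref_state[i])
    if (variants$alt_state[i] == "-") drop <- c(drop, p:(p + w - 1L))
    else ch[p:(p + w - 1L)] <- strsplit(variants$alt_state[i], "")[[1]]
  }
  if (length(drop)) ch <- ch[-drop]
  paste(ch, collapse = "")
}

## intron sequence for one observed state ("type" or "type:sub"), with
## per-leaf noise that never touches the variant columns
realize_intron <- function(truth, key, state, noise) {
  parts <- strsplit(state, ":", fixed = TRUE)[[1]]
  typ <- parts[1]
  s <- truth$exemplars[[key]][[typ]]
  protect <- integer(0)
  if (key == truth$subtype_variants$key && typ == truth$subtype_variants$type) {
    v <- truth$subtype_variants$variants
    protect <- unlist(lapply(seq_len(nrow(v)), function(i)
      v$position[i]:(v$position[i] + nchar(v$ref_state[i]) - 1L)))
    if (length(parts) > 1L && parts[2] == "B") s <- apply_subtype_b(s, v)
  }
  mutate_seq(s, noise, protect = protect)
}

## ---- genome assembly -----------------------------------------------------

## a block is list(seq=, features=list of local-coordinate feature())
blk_plain <- function(seq) list(seq = seq, features = list())

blk_gene <- function(name, kind, exon_seq, introns = list(),
                     intron_class = "groupI") {
  if (length(introns) == 0L)
    return(list(seq = exon_seq,
                features = list(feature(name, kind, "+",
                                        c(0L, nchar(exon_seq))))))
  sp <- vapply(introns, `[[`, numeric(1), "spliced_pos")
  ord <- order(sp)
  introns <- introns[ord]; sp <- sp[ord]
  segs <- list(); ifeat <- list(); cursor <- 0L; consumed <- 0L
  parts <- character(0)
  for (i in seq_along(introns)) {
    exon <- substr(exon_seq, consumed + 1L, sp[i])
    parts <- c(parts, exon)
    segs[[length(segs) + 1L]] <- c(cursor, cursor + nchar(exon))
    cursor <- cursor + nchar(exon)
    iseq <- introns[[i]]$seq
    parts <- c(parts, iseq)
    ifeat[[length(ifeat) + 1L]] <- feature(
      sprintf("%s-i%s", name, fmt_ordinal(introns[[i]]$ordinal)),
      "intron", "+", c(cursor, cursor + nchar(iseq)),
      c(host_gene = name, intron_class = intron_class))
    cursor <- cursor + nchar(iseq)
    consumed <- sp[i]
  }
  exon <- substr(exon_seq, consumed + 1L, nchar(exon_seq))
  parts <- c(parts, exon)
  segs[[length(segs) + 1L]] <- c(cursor, cursor + nchar(exon))
  seq <- paste(parts, collapse = "")
  gene_feat <- feature(name, kind, "+",
                       matrix(unlist(segs), ncol = 2, byrow = TRUE))
  list(seq = seq, features = c(list(gene_feat), ifeat))
}

blk_concat <- function(blocks, spacer_fun = NULL) {
  seqs <- character(0); feats <- list(); off <- 0L
  for (b in blocks) {
    seqs <- c(seqs, b$seq)
    for (f in b$features) {
      f$segments <- f$segments + off
      feats[[length(feats) + 1L]] <- f
    }
    off <- off + nchar(b$seq)
  }
  list(seq = paste(seqs, collapse = ""), features = feats)
}

## reverse-complement a block in place
blk_flip <- function(b) {
  Lb <- nchar(b$seq)
  b$seq <- revcomp(b$seq)
  b$features <- lapply(b$features, function(f) {
    f$segments <- canon_segments(
      cbind(Lb - f$segments[, 2], Lb - f$segments[, 1])[
        rev(seq_len(nrow(f$segments))), , drop = FALSE])
    f$strand <- if (f$strand == "+") "-" else "+"
    f
  })
  b
}

## backbone sequences shared by all leaves (deterministic from the seed)
sim_backbone <- function(truth) {
  params <- truth$params
  set.seed(params$seed + 1L)
  genes <- truth$genes
  at <- params$at_content_target
  exon_seqs <- setNames(lapply(genes$exon_len, random_seq, at = at),
                        genes$name)
  trna <- setNames(lapply(seq_len(20L), function(i) random_seq(72L, at)),
                   c(free_trnas(), irs_trnas(), mir_trnas()))
  spacer <- function() random_seq(sample(500:700, 1L), at)
  n_spacers <- 40L
  spacers <- replicate(n_spacers, spacer())
  list(exon_seqs = exon_seqs, trna = trna, spacers = spacers)
}

## build one annotated genome from a leaf's truth state
build_sim_genome <- function(truth, strain_id, state, dpo_set, orientation,
                             noisy = TRUE) {
  params <- truth$params
  bb <- sim_backbone(truth)
  set.seed(str_seed(strain_id, params$seed))
  exon_noise <- if (noisy) params$exon_noise else 0
  intron_noise <- if (noisy) params$intron_noise else 0

  genes <- truth$genes; sites <- truth$sites; keys <- truth$site_keys
  spi <- 0L
  next_spacer <- function() {
    spi <<- (spi %% length(bb$spacers)) + 1L
    blk_plain(bb$spacers[spi])
  }
  gene_block <- function(name) {
    gi <- which(genes$name == name)
    exon <- mutate_seq(bb$exon_seqs[[name]], exon_noise)
    idx <- which(sites$gene == name)
    idx <- idx[state[idx] != "0"]
    introns <- lapply(idx, function(i) list(
      ordinal = sites$ordinal[i], spliced_pos = sites$spliced_pos[i],
      seq = realize_intron(truth, keys[i], state[i], intron_noise)))
    blk_gene(name, genes$kind[gi], exon, introns)
  }
  trna_block <- function(name)
    list(seq = bb$trna[[name]],
         features = list(feature(name, "tRNA", "+",
                                 c(0L, nchar(bb$trna[[name]])))))

  irs <- blk_concat(lapply(irs_trnas(), trna_block))
  mir_inner <- blk_concat(c(lapply(mir_trnas(), trna_block),
                            lapply(c("nad2", "nad3", "rrnL", "rps3"),
                                   gene_block)))
  if (orientation == "reverse") mir_inner <- blk_flip(mir_inner)

  dpo_blocks <- list()
  for (f in sort(as.integer(sub("^dpo", "", dpo_set)))) {
    fid <- paste0("dpo", f)
    s <- truth$dpo_exemplars[[fid]]
    dpo_blocks[[length(dpo_blocks) + 1L]] <-
      list(seq = s, features = list(feature(fid, "dpo", "+", c(0L, nchar(s)),
                                            c(note = "dpo fragment"))))
    dpo_blocks[[length(dpo_blocks) + 1L]] <- blk_plain(random_seq(100L,
      params$at_content_target))
  }

  core <- c("cox1", "nad5", "cob", "cox2", "nad4", "nad1", "cox3",
            "atp6", "atp8", "atp9", "nad4L", "nad6")
  blocks <- list(gene_block("cox1"))
  for (g in core[-1]) blocks <- c(blocks, list(next_spacer(), gene_block(g)))
  for (g in free_trnas()) blocks <- c(blocks, list(next_spacer(),
                                                   trna_block(g)))
  blocks <- c(blocks, list(next_spacer(), gene_block("rrnS"),
                           next_spacer(), irs, next_spacer()))
  blocks <- c(blocks, dpo_blocks)
  blocks <- c(blocks, list(next_spacer(), mir_inner, next_spacer(),
                           blk_flip(irs), next_spacer()))
  asm <- blk_concat(blocks)
  annotated_genome(strain_id, asm$seq, asm$features, circular = TRUE)
}

#' Materialize simulated genomes in memory
#'
#' @param truth a `sim_truth` from [simulate_evolution()].
#' @param noisy apply per-leaf substitution noise (the reference genome is
#'   always emitted noise-free).
#' @return list with `genomes` (per leaf), `reference` (root-state genome,
#'   strain id `"REF"`), and `metadata` (data.frame).
#' @export
realize_genomes <- function(truth, noisy = TRUE) {
  leaves <- rownames(truth$leaf_states)
  genomes <- lapply(leaves, function(id)
    build_sim_genome(truth, id, truth$leaf_states[id, ],
                     truth$dpo_profiles[[id]], truth$mir_orientation[[id]],
                     noisy = noisy))
  names(genomes) <- leaves
  reference <- build_sim_genome(truth, "REF", truth$root_state,
                                paste0("dpo", seq_len(n_dpo_fragments)),
                                truth$params$root_orientation, noisy = FALSE)
  metadata <- data.frame(strain_id = leaves,
                         clade = unname(truth$clades[leaves]),
                         variety = "bisporus", origin = "simulated",
                         cultivar_status = "wild", stringsAsFactors = FALSE)
  list(genomes = genomes, reference = reference, metadata = metadata)
}

#' Emit simulated genomes and ground truth to disk
#'
#' Writes one GenBank and one FASTA file per leaf, the noise-free reference
#' genome, the strain metadata table, the reference registry JSON (site
#' table, type exemplars, declared subtype variant columns) and the truth
#' JSON. Re-running with the same seed reproduces every file byte for byte.
#'
#' @param truth a `sim_truth`.
#' @param outdir output directory (created if needed).
#' @param noisy apply per-leaf substitution noise.
#' @return invisibly, the list from [realize_genomes()].
#' @export
emit_genomes <- function(truth, outdir, noisy = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rg <- realize_genomes(truth, noisy = noisy)
  for (id in names(rg$genomes)) {
    write_genbank(rg$genomes[[id]], file.path(outdir, paste0(id, ".gbk")))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(rg$genomes[[id]]$sequence, id)),
      file.path(outdir, paste0(id, ".fasta")))
  }
  write_genbank(rg$reference, file.path(outdir, "reference.gbk"))
  write.table(rg$metadata, file.path(outdir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  reg <- sim_registry(truth, rg$reference)
  write_registry_json(reg, file.path(outdir, "registry.json"))
  write_tree_newick(truth$tree, file.path(outdir, "tree.nwk"))
  truth_out <- list(
    leaf_states = as.data.frame(truth$leaf_states),
    mir_orientation = as.list(truth$mir_orientation),
    dpo_profiles = truth$dpo_profiles,
    idp_truth = as.list(truth$idp_truth),
    clades = as.list(truth$clades),
    events = truth$events)
  jsonlite::write_json(truth_out, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rg)
}

#' Registry implied by a simulation's reference genome
#'
#' Builds the site registry from the reference annotation, then registers
#' the simulation's additional type exemplars and the declared subtype
#' variant columns.
#'
#' @param truth a `sim_truth`.
#' @param reference the reference genome (default: rebuilt from truth).
#' @return an `intron_site_registry`.
#' @export
sim_registry <- function(truth, reference = NULL) {
  if (is.null(reference))
    reference <- realize_genomes(truth, noisy = FALSE)$reference
  reg <- build_site_registry(reference)
  for (i in seq_len(nrow(truth$sites))) {
    key <- truth$site_keys[i]
    for (typ in names(truth$exemplars[[key]])) {
      if (typ == "1") next
      reg <- register_type_exemplar(reg, truth$sites$gene[i],
                                    truth$sites$ordinal[i], typ,
                                    truth$exemplars[[key]][[typ]])
    }
  }
  sv <- truth$subtype_variants
  gene <- strsplit(sv$key, "|", fixed = TRUE)[[1]][1]
  ordn <- as.numeric(strsplit(sv$key, "|", fixed = TRUE)[[1]][2])
  ex <- reg$exemplars[[sv$key]]
  lab <- vapply(ex, `[[`, character(1), "type_label")
  exseq <- ex[[which(lab == sv$type)]]$exemplar_seq
  register_type_exemplar(reg, gene, ordn, sv$type, exseq, sv$variants)
}

write_tree_newick <- function(tree, path) ape::write.tree(tree, file = path)

#' Serialize / load a site registry as JSON
#'
#' @param registry an `intron_site_registry`.
#' @param path JSON path.
#' @export
write_registry_json <- function(registry, path) {
  ex <- list()
  for (key in names(registry$exemplars)) {
    for (e in registry$exemplars[[key]]) {
      ex[[length(ex) + 1L]] <- list(
        site = key, type_label = e$type_label,
        exemplar_seq = e$exemplar_seq,
        subtype_variants = e$subtype_variants)
    }
  }
  jsonlite::write_json(list(sites = registry$sites, exemplars = ex), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(registry)
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  sites <- obj$sites
  sites$ordinal <- as.numeric(sites$ordinal)
  reg <- structure(list(sites = sites, exemplars = list()),
                   class = "intron_site_registry")
  exl <- obj$exemplars
  for (i in seq_len(nrow(exl))) {
    key <- exl$site[i]
    gene <- strsplit(key, "|", fixed = TRUE)[[1]][1]
    ordn <- as.numeric(strsplit(key, "|", fixed = TRUE)[[1]][2])
    sv <- exl$subtype_variants[[i]]
    if (is.null(sv) || (is.data.frame(sv) && nrow(sv) == 0L)) sv <- NULL
    reg <- register_type_exemplar(reg, gene, ordn, exl$type_label[i],
                                  exl$exemplar_seq[i], sv)
  }
  reg
}
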