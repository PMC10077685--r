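## Pipeline orchestration: run every stage on a directory of annotated
## genomes and write the per-stage TSV/JSON reports plus a provenance
## record, so a run is reproducible byte for byte from its inputs and
## configuration.

#' Pipeline configuration
#'
#' All thresholds of the individual stages in one place; defaults match
#' the stage functions.
#'
#' @param anchor_gene normalization anchor.
#' @param tol intron-site homology tolerance (nt).
#' @param id_threshold intron type assignment identity.
#' @param insert_min,cover_min intron anomaly thresholds.
#' @param min_len,min_identity inverted-repeat detection thresholds.
#' @param merge_id,assign_id,dpo_min_cover dpo clustering/search thresholds.
#' @param missing_policy haplotype collapsing policy.
#' @param seed seed recorded in provenance (the pipeline itself draws no
#'   random numbers).
#' @return named list.
#' @export
pipeline_config <- function(anchor_gene = "cox1", tol = 6,
                            id_threshold = 0.90, insert_min = 15,
                            cover_min = 0.80, min_len = 500,
                            min_identity = 0.95, merge_id = 0.90,
                            assign_id = 0.75, dpo_min_cover = 0.60,
                            missing_policy = "drop_columns", seed = 1L) {
  stopifnot(tol >= 0, id_threshold > 0, id_threshold <= 1, min_len >= 50,
            min_identity > 0, min_identity <= 1)
  as.list(environment())
}

#' Run the full structural-analysis pipeline
#'
#' Stages, in order: composition stats, inverted repeats and MIR
#' orientation, intron mapping and state matrix, dpo catalog/profiles and
#' clade summary, IDP classes and clade congruence, and (when a tree is
#' given) minimum-event inference. Each stage writes a TSV/JSON report to
#' `outdir`; a combined `summary.json` carries the headline numbers and a
#' provenance record.
#'
#' @param input_dir directory with `<strain>.gbk` files, `reference.gbk`,
#'   `metadata.tsv`, and optionally `registry.json` and `tree.nwk` (the
#'   layout written by [emit_genomes()]). Alternatively pass loaded objects
#'   via `genomes`/`reference`/`metadata`/`registry`/`tree`.
#' @param outdir report directory (created).
#' @param config a [pipeline_config()].
#' @param genomes,reference,metadata,registry,tree in-memory inputs that
#'   override `input_dir`.
#' @param stages character subset of
#'   `c("stats","repeats","introns","dpo","idp","events")`.
#' @return invisibly, a list with every stage's result.
#' @export
run_pipeline <- function(input_dir = NULL, outdir,
                         config = pipeline_config(), genomes = NULL,
                         reference = NULL, metadata = NULL, registry = NULL,
                         tree = NULL,
                         stages = c("stats", "repeats", "introns", "dpo",
                                    "idp", "events")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(input_dir)) {
    paths <- sort(list.files(input_dir, pattern = "\\.gbk$",
                             full.names = TRUE))
    paths <- paths[basename(paths) != "reference.gbk"]
    if (length(paths) == 0L && is.null(genomes))
      stop("no genomes found in ", input_dir)
    if (is.null(genomes)) genomes <- lapply(paths, read_genbank)
    rp <- file.path(input_dir, "reference.gbk")
    if (is.null(reference) && file.exists(rp)) reference <- read_genbank(rp)
    mp <- file.path(input_dir, "metadata.tsv")
    if (is.null(metadata) && file.exists(mp))
      metadata <- read_strain_metadata(mp)
    gp <- file.path(input_dir, "registry.json")
    if (is.null(registry) && file.exists(gp))
      registry <- read_registry_json(gp)
    tp <- file.path(input_dir, "tree.nwk")
    if (is.null(tree) && file.exists(tp)) tree <- ape::read.tree(tp)
  }
  if (is.null(genomes) || length(genomes) == 0L) stop("no genomes found")
  names(genomes) <- vapply(genomes, `[[`, character(1), "strain_id")

  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list()

  genomes <- run_stage("normalize", function()
    lapply(genomes, normalize_orientation, anchor_gene = config$anchor_gene))
  if (!is.null(reference))
    reference <- run_stage("normalize", function()
      normalize_orientation(reference, anchor_gene = config$anchor_gene))

  if ("stats" %in% stages) {
    out$stats <- run_stage("stats", function() {
      do.call(rbind, lapply(genomes, function(g) {
        s <- compute_genome_stats(g)
        data.frame(strain_id = g$strain_id, length = s$length,
                   at_content = s$at_content, gc_skew = s$gc_skew,
                   n_count = s$n_count)
      }))
    })
    write.table(out$stats, file.path(outdir, "stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  repeats_by_strain <- NULL
  if (any(c("repeats", "dpo") %in% stages)) {
    repeats_by_strain <- run_stage("repeats", function()
      lapply(genomes, detect_inverted_repeats, min_len = config$min_len,
             min_identity = config$min_identity))
  }
  if ("repeats" %in% stages) {
    out$mir <- run_stage("repeats", function() {
      do.call(rbind, lapply(names(genomes), function(id) {
        rp <- repeats_by_strain[[id]]
        mir <- call_mir(genomes[[id]], rp, anchor_gene = config$anchor_gene)
        dom <- rp[[which.max(vapply(rp, `[[`, numeric(1), "length"))]]
        data.frame(strain_id = id, irs_a = dom$copy_a[1],
                   irs_b = dom$copy_b[1], irs_len = dom$length,
                   identity = dom$identity, mir_start = mir$segment[1],
                   mir_end = mir$segment[2], orientation = mir$orientation,
                   markers = paste(mir$markers_found, collapse = ","))
      }))
    })
    write.table(out$mir, file.path(outdir, "repeats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  obs_all <- NULL
  if (any(c("introns", "idp", "events") %in% stages)) {
    if (is.null(registry)) {
      if (is.null(reference))
        stop("pipeline stage 'introns' failed: no registry and no reference")
      registry <- run_stage("introns", function()
        build_site_registry(reference))
    }
    out$observations <- run_stage("introns", function() {
      obs <- list()
      for (id in names(genomes)) {
        o <- map_introns(genomes[[id]], registry, tol = config$tol,
                         id_threshold = config$id_threshold,
                         insert_min = config$insert_min,
                         cover_min = config$cover_min)
        registry <<- attr(o, "registry")
        obs[[id]] <- o
      }
      do.call(rbind, c(obs, list(make.row.names = FALSE)))
    })
    obs_all <- out$observations
    out$state_matrix <- build_state_matrix(obs_all)
    write.table(data.frame(strain_id = rownames(out$state_matrix),
                           out$state_matrix, check.names = FALSE),
                file.path(outdir, "introns.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if ("dpo" %in% stages) {
    out$dpo <- run_stage("dpo", function() {
      catalog <- build_dpo_catalog(genomes, merge_id = config$merge_id)
      if (length(catalog) == 0L)
        return(list(catalog = catalog, profiles = NULL, summary = NULL))
      profiles <- lapply(names(genomes), function(id)
        profile_genome_dpo(genomes[[id]], catalog,
                           assign_id = config$assign_id,
                           min_cover = config$dpo_min_cover,
                           repeats = repeats_by_strain[[id]]))
      prof <- do.call(rbind, c(profiles, list(make.row.names = FALSE)))
      summ <- if (!is.null(metadata))
        clade_dpo_summary(prof, metadata, catalog) else NULL
      list(catalog = catalog, profiles = prof, summary = summ)
    })
    if (!is.null(out$dpo$profiles))
      write.table(out$dpo$profiles, file.path(outdir, "dpo_profiles.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$dpo$summary))
      write.table(data.frame(clade = rownames(out$dpo$summary$fraction),
                             out$dpo$summary$fraction, check.names = FALSE),
                  file.path(outdir, "dpo_clades.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }

  if ("idp" %in% stages) {
    out$idp <- run_stage("idp", function()
      assign_idp_classes(out$state_matrix, ordering_tree = tree))
    write.table(out$idp$classes, file.path(outdir, "idp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(metadata)) {
      clades <- setNames(metadata$clade, metadata$strain_id)
      common <- intersect(names(out$idp$assignment), names(clades))
      out$congruence <- run_stage("idp", function()
        idp_clade_congruence(out$idp$assignment[common], clades[common]))
      jsonlite::write_json(
        list(n_classes = out$congruence$n_classes,
             single_clade_class_count =
               out$congruence$single_clade_class_count,
             ari = out$congruence$ari),
        file.path(outdir, "congruence.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  if ("events" %in% stages && !is.null(tree)) {
    out$events <- run_stage("events", function()
      infer_min_events(tree, out$state_matrix))
    write.table(out$events$events, file.path(outdir, "events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    n_strains = length(genomes),
    n_idp_classes = if (!is.null(out$idp)) nrow(out$idp$classes) else NULL,
    n_events = if (!is.null(out$events)) out$events$count else NULL,
    provenance = list(
      package_version = as.character(utils::packageVersion("mitostruct")),
      config = config))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
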