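## intron_atlas: homologous intron insertion sites in spliced (intron-less
## gene) coordinates. The registry is built from a reference genome; every
## query genome's introns are mapped onto it, typed against per-site
## exemplars by global-alignment identity, and screened for insertions and
## degeneration relative to the assigned exemplar.

fmt_ordinal <- function(o) {
  ifelse(o == round(o), as.character(as.integer(round(o))), as.character(o))
}

site_key <- function(gene, ordinal) {
  sprintf("%s|%s", gene, fmt_ordinal(ordinal))
}

#' Spliced-coordinate position of an intron within its host gene
#'
#' The spliced position is the number of exonic bases 5' of the intron in
#' gene orientation, i.e. the insertion point in the intron-less transcript.
#'
#' @param host host-gene [feature()] whose segments are the exons.
#' @param intron intron [feature()].
#' @return integer spliced position.
#' @export
spliced_position <- function(host, intron) {
  ispan <- feature_span(intron)
  hspan <- feature_span(host)
  if (ispan[1] < hspan[1] || ispan[2] > hspan[2])
    stop("intron ", intron$name, " [", ispan[1], ",", ispan[2],
         ") lies outside host gene ", host$name,
         " [", hspan[1], ",", hspan[2], ")")
  pos <- 0L
  for (i in seq_len(nrow(host$segments))) {
    seg <- host$segments[i, ]
    five_prime <- if (host$strand == "+") seg[2] <= ispan[1]
                  else seg[1] >= ispan[2]
    if (five_prime) pos <- pos + (seg[2] - seg[1])
  }
  as.integer(pos)
}

#' Build the registry of homologous intron insertion sites
#'
#' One site per intron feature of the reference; ordinals are assigned
#' 5'-to-3' within each host gene. The reference intron's own sequence is
#' registered as the exemplar of its type (qualifier `intron_type`, default
#' `"1"`); intron class is read from qualifier `intron_class` when present.
#'
#' @param reference an [annotated_genome()] with intron features carrying
#'   `host_gene` qualifiers.
#' @return an `intron_site_registry` object.
#' @export
build_site_registry <- function(reference) {
  introns <- features_of(reference, "intron")
  rows <- list(); exemplars <- list()
  for (f in introns) {
    host_name <- f$qualifiers[["host_gene"]]
    hosts <- features_of(reference, kind = c("CDS", "rRNA"), name = host_name)
    if (length(hosts) != 1L)
      stop("host gene '", host_name, "' of intron ", f$name,
           " found ", length(hosts), " times in reference")
    sp <- spliced_position(hosts[[1]], f)
    cls <- if ("intron_class" %in% names(f$qualifiers))
      f$qualifiers[["intron_class"]] else "unknown"
    typ <- if ("intron_type" %in% names(f$qualifiers))
      f$qualifiers[["intron_type"]] else "1"
    rows[[length(rows) + 1L]] <- data.frame(
      gene = host_name, spliced_pos = sp, intron_class = cls,
      stringsAsFactors = FALSE)
    exemplars[[length(exemplars) + 1L]] <-
      list(gene = host_name, spliced_pos = sp, type_label = typ,
           exemplar_seq = feature_seq(reference, f))
  }
  if (length(rows)) {
    sites <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    sites <- sites[order(sites$gene, sites$spliced_pos), , drop = FALSE]
    sites$ordinal <- stats::ave(sites$spliced_pos, sites$gene,
                                FUN = seq_along)
    sites$novel <- FALSE
  } else {
    sites <- data.frame(gene = character(0), spliced_pos = integer(0),
                        intron_class = character(0), ordinal = numeric(0),
                        novel = logical(0))
  }
  sites <- sites[, c("gene", "ordinal", "spliced_pos", "intron_class", "novel")]
  rownames(sites) <- NULL
  reg <- structure(list(sites = sites, exemplars = list()),
                   class = "intron_site_registry")
  for (e in exemplars) {
    ord <- sites$ordinal[sites$gene == e$gene &
                           sites$spliced_pos == e$spliced_pos][1]
    reg <- register_type_exemplar(reg, e$gene, ord, e$type_label,
                                  e$exemplar_seq)
  }
  reg
}

#' @export
print.intron_site_registry <- function(x, ...) {
  cat(sprintf("<intron_site_registry> %d sites in %d genes (%d novel)\n",
              nrow(x$sites), length(unique(x$sites$gene)),
              sum(x$sites$novel)))
  invisible(x)
}

#' Register a type exemplar (and optionally its subtype variant columns)
#'
#' @param registry an `intron_site_registry`.
#' @param gene,ordinal the site.
#' @param type_label type name, e.g. `"23-2"`.
#' @param exemplar_seq exemplar nucleotide sequence.
#' @param subtype_variants optional data.frame with columns `position`
#'   (1-based in the exemplar), `ref_state`, `alt_state`; `alt_state` may be
#'   `"-"` for a deletion. Strains matching all `ref_state`s get subtype
#'   `"A"`, all `alt_state`s get `"B"`.
#' @return the updated registry.
#' @export
register_type_exemplar <- function(registry, gene, ordinal, type_label,
                                   exemplar_seq, subtype_variants = NULL) {
  key <- site_key(gene, ordinal)
  cur <- registry$exemplars[[key]]
  if (is.null(cur)) cur <- list()
  labels <- vapply(cur, `[[`, character(1), "type_label")
  hit <- which(labels == type_label)
  entry <- list(type_label = type_label, exemplar_seq = exemplar_seq,
                subtype_variants = subtype_variants)
  if (length(hit)) cur[[hit]] <- entry else cur[[length(cur) + 1L]] <- entry
  registry$exemplars[[key]] <- cur
  registry
}

#' Add a novel insertion site to the registry
#'
#' If a site of the gene already lies within `tol` of `spliced_pos` the
#' registry is returned unchanged. A genuinely new site is inserted at its
#' spliced position with a fractional ordinal between its neighbors, so
#' existing ordinals never change.
#'
#' @param registry an `intron_site_registry`.
#' @param gene host gene.
#' @param spliced_pos spliced-coordinate insertion point.
#' @param tol homology tolerance in nt.
#' @return the (possibly augmented) registry.
#' @export
augment_registry <- function(registry, gene, spliced_pos, tol = 6) {
  s <- registry$sites
  same <- s$gene == gene & abs(s$spliced_pos - spliced_pos) <= tol
  if (any(same)) return(registry)
  gsites <- s[s$gene == gene, , drop = FALSE]
  prev <- gsites[gsites$spliced_pos < spliced_pos, , drop = FALSE]
  nxt <- gsites[gsites$spliced_pos > spliced_pos, , drop = FALSE]
  ordinal <- if (nrow(prev) && nrow(nxt))
    (max(prev$ordinal) + min(nxt$ordinal)) / 2
  else if (nrow(prev)) max(prev$ordinal) + 0.5
  else if (nrow(nxt)) min(nxt$ordinal) - 0.5
  else 1
  registry$sites <- rbind(s, data.frame(gene = gene, ordinal = ordinal,
                                        spliced_pos = spliced_pos,
                                        intron_class = "unknown",
                                        novel = TRUE))
  registry$sites <- registry$sites[order(registry$sites$gene,
                                         registry$sites$spliced_pos), ,
                                   drop = FALSE]
  rownames(registry$sites) <- NULL
  registry
}

#' Classify an intron sequence against a site's type exemplars
#'
#' Global-alignment identity to every registered exemplar is computed; the
#' sequence is assigned to the best exemplar at or above `id_threshold`
#' (ties broken toward the lexicographically smaller type label), otherwise
#' it is reported as a new type. Within a type, the subtype is the joint
#' state at the type's declared variant columns.
#'
#' @param exemplars list of exemplar entries for the site (see
#'   [register_type_exemplar()]).
#' @param seq intron sequence (gene orientation).
#' @param id_threshold assignment threshold (default 0.90).
#' @return list with `type_label`, `subtype_label`, `identity`, `is_new`.
#' @export
classify_intron_type <- function(exemplars, seq, id_threshold = 0.90) {
  stopifnot(nchar(seq) > 0L)
  if (length(exemplars) == 0L)
    return(list(type_label = "new1", subtype_label = "none",
                identity = NA_real_, is_new = TRUE))
  labels <- vapply(exemplars, `[[`, character(1), "type_label")
  ids <- vapply(exemplars, function(e) align_identity(e$exemplar_seq, seq),
                numeric(1))
  ord <- order(-ids, labels)
  best <- ord[1]
  if (ids[best] < id_threshold) {
    n_new <- sum(grepl("^new", labels))
    return(list(type_label = paste0("new", n_new + 1L),
                subtype_label = "none", identity = ids[best], is_new = TRUE))
  }
  ex <- exemplars[[best]]
  sub <- if (is.null(ex$subtype_variants)) "none"
         else call_subtype(ex$exemplar_seq, seq, ex$subtype_variants)
  list(type_label = labels[best], subtype_label = sub,
       identity = ids[best], is_new = FALSE)
}

## joint state at declared variant columns, via exemplar->query alignment
call_subtype <- function(exemplar_seq, seq, variants) {
  aln <- align_global(exemplar_seq, seq)
  pc <- strsplit(aln$pattern, "", fixed = TRUE)[[1]]
  sc <- strsplit(aln$subject, "", fixed = TRUE)[[1]]
  expos <- cumsum(pc != "-")            # exemplar coordinate per column
  observed <- vapply(seq_len(nrow(variants)), function(i) {
    p <- variants$position[i]
    w <- nchar(variants$ref_state[i])
    cols <- which(expos >= p & expos <= p + w - 1L & pc != "-")
    obs <- paste(sc[cols][sc[cols] != "-"], collapse = "")
    if (obs == "") "-" else obs
  }, character(1))
  if (all(observed == variants$ref_state)) "A"
  else if (all(observed == variants$alt_state)) "B"
  else paste(observed, collapse = "/")
}

#' Screen an intron against its type exemplar for inserts and degeneration
#'
#' Contiguous query-only alignment segments of at least `insert_min` nt are
#' reported as inserts (offset in exemplar coordinates); exemplar coverage
#' below `cover_min` flags the intron as degenerate (partially deleted).
#'
#' @param seq observed intron sequence.
#' @param exemplar_seq assigned type exemplar.
#' @param insert_min minimum insert length (nt).
#' @param cover_min minimum exemplar coverage.
#' @return list with `inserts` (data.frame `offset`, `length`), `coverage`,
#'   `degenerate`.
#' @export
detect_intron_anomalies <- function(seq, exemplar_seq, insert_min = 15,
                                    cover_min = 0.80) {
  aln <- align_global(exemplar_seq, seq)
  pc <- strsplit(aln$pattern, "", fixed = TRUE)[[1]]
  sc <- strsplit(aln$subject, "", fixed = TRUE)[[1]]
  nex <- sum(pc != "-")
  ## runs of exemplar-gap columns = insertions in the query
  r <- rle(pc == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  expos <- cumsum(pc != "-")
  ins <- data.frame(offset = integer(0), length = integer(0))
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= insert_min) {
      off <- if (starts[i] == 1L) 0L else expos[starts[i] - 1L]
      ins <- rbind(ins, data.frame(offset = off, length = r$lengths[i]))
    }
  }
  deleted <- sum(sc == "-" & pc != "-")
  coverage <- (nex - deleted) / nex
  list(inserts = ins, coverage = coverage,
       degenerate = coverage < cover_min)
}

#' Map a genome's introns onto the site registry
#'
#' Each query intron's spliced position (computed in the query's own
#' coordinates) is matched to the registry site of the same gene within
#' `tol` nt; unmatched introns become flagged novel sites. Every registry
#' site of a gene annotated in the query yields one observation
#' (`present = FALSE` when no intron maps there).
#'
#' @param query an [annotated_genome()].
#' @param registry an `intron_site_registry`.
#' @param tol spliced-coordinate tolerance in nt (default 6).
#' @param classify call type/subtype and anomalies against exemplars.
#' @param id_threshold type-assignment identity threshold.
#' @param insert_min,cover_min see [detect_intron_anomalies()].
#' @return data.frame of observations (one row per site), with the possibly
#'   augmented registry attached as attribute `"registry"`.
#' @export
map_introns <- function(query, registry, tol = 6, classify = TRUE,
                        id_threshold = 0.90, insert_min = 15,
                        cover_min = 0.80) {
  introns <- features_of(query, "intron")
  ## spliced positions of the query's own introns
  qobs <- lapply(introns, function(f) {
    host_name <- f$qualifiers[["host_gene"]]
    hosts <- features_of(query, kind = c("CDS", "rRNA"), name = host_name)
    if (length(hosts) != 1L)
      stop("host gene '", host_name, "' of intron ", f$name, " in ",
           query$strain_id, " found ", length(hosts), " times")
    list(gene = host_name, sp = spliced_position(hosts[[1]], f),
         seq = feature_seq(query, f), name = f$name)
  })
  ## assign to registry sites
  assigned <- rep(NA_character_, length(qobs))
  for (i in seq_along(qobs)) {
    s <- registry$sites
    cand <- which(s$gene == qobs[[i]]$gene &
                    abs(s$spliced_pos - qobs[[i]]$sp) <= tol)
    if (length(cand)) {
      best <- cand[which.min(abs(s$spliced_pos[cand] - qobs[[i]]$sp))]
      assigned[i] <- site_key(s$gene[best], s$ordinal[best])
    }
  }
  dup <- assigned[!is.na(assigned)][duplicated(assigned[!is.na(assigned)])]
  if (length(dup)) {
    culprit <- which(assigned %in% dup)
    stop("two introns of ", query$strain_id, " map to one site ",
         paste(unique(dup), collapse = ", "), ": ",
         paste(vapply(qobs[culprit], `[[`, character(1), "name"),
               collapse = ", "))
  }
  ## novel sites
  for (i in which(is.na(assigned))) {
    registry <- augment_registry(registry, qobs[[i]]$gene, qobs[[i]]$sp, tol)
    s <- registry$sites
    hit <- which(s$gene == qobs[[i]]$gene &
                   abs(s$spliced_pos - qobs[[i]]$sp) <= tol)
    assigned[i] <- site_key(s$gene[hit[1]], s$ordinal[hit[1]])
  }

  genes_annotated <- unique(vapply(features_of(query, c("CDS", "rRNA")),
                                   `[[`, character(1), "name"))
  s <- registry$sites[registry$sites$gene %in% genes_annotated, , drop = FALSE]
  rows <- lapply(seq_len(nrow(s)), function(r) {
    key <- site_key(s$gene[r], s$ordinal[r])
    i <- match(key, assigned)
    out <- data.frame(strain_id = query$strain_id, gene = s$gene[r],
                      ordinal = s$ordinal[r], site = key,
                      present = !is.na(i), type_label = "absent",
                      subtype_label = "none", identity = NA_real_,
                      length = 0L, inserts = "", degenerate = FALSE,
                      novel = s$novel[r], stringsAsFactors = FALSE)
    if (!is.na(i)) {
      sq <- qobs[[i]]$seq
      out$length <- nchar(sq)
      if (classify) {
        ex <- registry$exemplars[[key]]
        cl <- classify_intron_type(ex %||% list(), sq, id_threshold)
        out$type_label <- cl$type_label
        out$subtype_label <- cl$subtype_label
        out$identity <- cl$identity
        if (cl$is_new)
          registry <<- register_type_exemplar(registry, s$gene[r],
                                              s$ordinal[r], cl$type_label, sq)
        if (!cl$is_new) {
          exi <- ex[[which(vapply(ex, `[[`, character(1), "type_label") ==
                             cl$type_label)]]
          an <- detect_intron_anomalies(sq, exi$exemplar_seq, insert_min,
                                        cover_min)
          out$inserts <- paste(sprintf("ins%d@%d", an$inserts$length,
                                       an$inserts$offset), collapse = ";")
          out$degenerate <- an$degenerate
        }
      } else out$type_label <- "present"
    }
    out
  })
  obs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(obs, "registry") <- registry
  obs
}
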