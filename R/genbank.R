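## Minimal GenBank flat-file reader/writer for annotated mitogenomes.
## Covers the subset of the format the pipeline needs: LOCUS (length,
## circular flag), a FEATURES table with join()/complement() locations and
## quoted qualifiers, and ORIGIN sequence blocks. Coordinates are 1-based
## inclusive on disk and 0-based half-open in memory.

gb_kind_to_key <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                    intron = "intron", dpo = "misc_feature",
                    other = "misc_feature")

#' Read an annotated genome
#'
#' @param path input file.
#' @param format `"genbank"` or `"fasta+table"`; for the latter, `path` is
#'   the FASTA file and `table_path` must name the annotation table.
#' @param table_path annotation table (fasta+table format only).
#' @return an [annotated_genome()].
#' @export
read_annotated_genome <- function(path, format = c("genbank", "fasta+table"),
                                  table_path = NULL) {
  format <- match.arg(format)
  if (format == "fasta+table") {
    if (is.null(table_path)) stop("fasta+table format needs table_path")
    return(read_genome_table(path, table_path))
  }
  read_genbank(path)
}

#' Write an annotated genome
#'
#' @param g an [annotated_genome()].
#' @param path output file.
#' @param format `"genbank"` or `"fasta+table"`.
#' @param table_path annotation table path (fasta+table format only).
#' @export
write_annotated_genome <- function(g, path,
                                   format = c("genbank", "fasta+table"),
                                   table_path = NULL) {
  format <- match.arg(format)
  if (format == "fasta+table") {
    if (is.null(table_path)) stop("fasta+table format needs table_path")
    return(write_genome_table(g, path, table_path))
  }
  write_genbank(g, path)
}

#' @rdname read_annotated_genome
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L)
    stop("malformed GenBank record in ", path, ": expected one LOCUS line")
  strain_id <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i])), "[ \t]+")[[1]][1]
  circular <- grepl("circular", lines[locus_i])

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) != 1L)
    stop("malformed GenBank record in ", path, ": missing ORIGIN")

  ## sequence block
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > orig_i][1] else length(lines) + 1L
  seq_lines <- lines[(orig_i + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feats <- list()
  if (length(feat_i) == 1L) {
    block <- lines[(feat_i + 1L):(orig_i - 1L)]
    ## group physical lines into logical feature/qualifier entries
    cur_key <- NULL; cur_loc <- NULL; quals <- character(0); pending_q <- NULL
    flush_feature <- function() {
      if (is.null(cur_key)) return()
      feats[[length(feats) + 1L]] <<- gb_make_feature(cur_key, cur_loc, quals,
                                                      path)
    }
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {            # new feature line
        flush_feature()
        cur_key <- trimws(substr(ln, 1, 20))
        cur_loc <- trimws(substr(ln, 21, nchar(ln)))
        quals <- character(0); pending_q <- NULL
      } else if (grepl("^ {21}/", trimws(ln, "right"))) {  # qualifier
        q <- sub("^ +/", "", ln)
        eq <- regexpr("=", q, fixed = TRUE)
        if (eq > 0) {
          key <- substr(q, 1, eq - 1)
          val <- gsub('^"|"$', "", substr(q, eq + 1, nchar(q)))
        } else { key <- q; val <- "" }
        quals[key] <- val
        pending_q <- key
      } else if (!is.null(cur_key) && grepl("^ {21}", ln)) {  # continuation
        cont <- trimws(ln)
        if (is.null(pending_q)) cur_loc <- paste0(cur_loc, cont)
        else quals[pending_q] <- paste0(quals[pending_q], gsub('"$', "", cont))
      }
    }
    flush_feature()
  }
  feats <- Filter(Negate(is.null), feats)
  annotated_genome(strain_id, sequence, feats, circular = circular)
}

## parse one feature entry into a feature object (or NULL for `source`)
gb_make_feature <- function(key, loc, quals, path) {
  if (key == "source") return(NULL)
  strand <- "+"
  loc2 <- loc
  if (grepl("^complement\\(", loc2)) {
    strand <- "-"
    loc2 <- sub("^complement\\((.*)\\)$", "\\1", loc2)
  }
  loc2 <- sub("^join\\((.*)\\)$", "\\1", loc2)
  parts <- strsplit(loc2, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", trimws(p)))[[1]]
    if (length(m) != 3L) {
      m1 <- regmatches(p, regexec("^(\\d+)$", trimws(p)))[[1]]
      if (length(m1) == 2L) return(c(as.integer(m1[2]) - 1L, as.integer(m1[2])))
      stop("cannot parse location '", loc, "' of feature ", key, " in ", path)
    }
    c(as.integer(m[2]) - 1L, as.integer(m[3]))   # 1-based incl -> 0-based half-open
  })
  segs <- do.call(rbind, segs)
  if (strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  qget <- function(k) if (k %in% names(quals)) quals[[k]] else NULL
  name <- qget("gene") %||% qget("product") %||% qget("label") %||% key
  kind <- switch(key,
    CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA", intron = "intron",
    misc_feature = if (identical(qget("note"), "dpo fragment")) "dpo" else "other",
    "other")
  quals <- quals[setdiff(names(quals), c("gene"))]
  feature(name, kind, strand, segs, quals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_annotated_genome
#' @export
write_genbank <- function(g, path) {
  L <- genome_length(g)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %-16s %d bp    DNA     %s     UNA 01-JAN-2024",
     g$strain_id, L, if (g$circular) "circular" else "linear")
  wl("DEFINITION  %s mitochondrion, complete genome.", g$strain_id)
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", L)
  for (f in g$features) {
    segs <- f$segments[order(f$segments[, 1]), , drop = FALSE]
    spans <- sprintf("%d..%d", segs[, 1] + 1L, segs[, 2])
    loc <- if (length(spans) > 1L) sprintf("join(%s)", paste(spans, collapse = ","))
           else spans
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    wl("     %-15s %s", gb_kind_to_key[[f$kind]], loc)
    wl("                     /gene=\"%s\"", f$name)
    if (f$kind == "dpo" && !identical(unname(f$qualifiers["note"]),
                                      "dpo fragment"))
      wl("                     /note=\"dpo fragment\"")
    for (qn in names(f$qualifiers))
      wl("                     /%s=\"%s\"", qn, f$qualifiers[[qn]])
  }
  wl("ORIGIN")
  s <- tolower(g$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl("%9d %s", st, paste(tens, collapse = " "))
  }
  wl("//")
  invisible(g)
}
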