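TSV_COLUMNS <- c("entry_id", "category", "internal_id", "psimod_id",
                 "resid_id", "name", "chain", "seq_id", "insertion",
                 "component_code", "partner_description")

.na_dash <- function(x) ifelse(is.na(x) | !nzchar(x), "-", x)

## human-readable description of the bonds a residue participates in:
## "SG-SG 2.05 (CYS A 8)" — own atom, partner atom, distance, partner residue
.partner_description <- function(ident, res_uid) {
  b <- ident$bonds
  if (is.null(b) || nrow(b) == 0L) return("-")
  own1 <- b$res_uid1 == res_uid
  own2 <- b$res_uid2 == res_uid
  rows <- which(own1 | own2)
  if (length(rows) == 0L) return("-")
  parts <- vapply(rows, function(i) {
    if (own1[i])
      sprintf("%s-%s %.2f (%s %s %s%s)", b$atom1[i], b$atom2[i],
              b$distance[i], b$code2[i], b$chain2[i], b$seq2[i], b$ins2[i])
    else
      sprintf("%s-%s %.2f (%s %s %s%s)", b$atom2[i], b$atom1[i],
              b$distance[i], b$code1[i], b$chain1[i], b$seq1[i], b$ins1[i])
  }, character(1))
  paste(parts, collapse = "; ")
}

.report_rows <- function(report) {
  rows <- lapply(report$identifications, function(ident) {
    r <- ident$residues
    data.frame(
      entry_id = report$entry_id,
      category = ident$category,
      internal_id = ident$def_id,
      psimod_id = .na_dash(ident$psimod_id),
      resid_id = .na_dash(ident$resid_id),
      name = ident$name,
      chain = r$chain,
      seq_id = r$seq_id,
      insertion = .na_dash(r$insert),
      component_code = r$code,
      partner_description = vapply(r$res_uid, function(u)
        .partner_description(ident, u), character(1)),
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(
      replicate(length(TSV_COLUMNS), character(0), simplify = FALSE),
      TSV_COLUMNS), stringsAsFactors = FALSE)
    return(df)
  }
  do.call(rbind, rows)
}

#' Write a modification report as TSV
#'
#' One row per (identification, residue): a two-residue cross-link
#' contributes two rows.  Distances in the partner description are printed
#' to 2 decimals (Angstrom).  Output is UTF-8 with a header row and a
#' stable row order, so identical inputs give byte-identical files.
#'
#' @param report A `mod_report` from [identify_all()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(report, path) {
  stopifnot(inherits(report, "mod_report"))
  df <- .report_rows(report)
  con <- file(path, open = "wb")  # binary mode: fixed LF line endings
  on.exit(close(con))
  writeLines(paste(TSV_COLUMNS, collapse = "\t"), con, sep = "\n")
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")),
               con, sep = "\n")
  invisible(path)
}

#' Read back a TSV modification report
#'
#' @param path Path written by [write_tsv()].
#' @return Data frame with one row per (identification, residue).
#' @export
parse_tsv <- function(path) {
  utils::read.delim(path, colClasses = c(seq_id = "integer"),
                    stringsAsFactors = FALSE)
}

#' Write a modification report as JSON
#'
#' JSON mirror of the TSV annotation for programmatic use, including the
#' full bond records (atoms, residues, distances, thresholds).
#'
#' @inheritParams write_tsv
#' @return Invisibly, `path`.
#' @export
write_json <- function(report, path) {
  stopifnot(inherits(report, "mod_report"))
  payload <- list(
    entry_id = report$entry_id,
    scan_summary = report$scan_summary,
    identifications = lapply(report$identifications, function(ident) {
      list(def_id = ident$def_id,
           category = ident$category,
           name = ident$name,
           psimod_id = if (is.na(ident$psimod_id)) NULL else ident$psimod_id,
           resid_id = if (is.na(ident$resid_id)) NULL else ident$resid_id,
           residues = ident$residues[, c("res_uid", "code", "chain", "seq_id",
                                         "insert", "is_polymer",
                                         "polymer_index")],
           bonds = if (nrow(ident$bonds))
             ident$bonds[, c("res_uid1", "atom1", "res_uid2", "atom2",
                             "distance", "threshold")]
           else NULL)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Map identifications onto a per-chain sequence track
#'
#' Produces the annotation lane displayed along a chain's sequence: one
#' mark per in-chain residue of each identification, carrying the total
#' number of residues involved in that modification (the "number of edges"
#' of the displayed icon).  Identifications spanning several chains
#' contribute only their residues on the requested chain.
#'
#' @param report A `mod_report`.
#' @param model The [parse_structure()] model the report was computed from.
#' @param chain_id Author chain identifier.
#' @return List of class `sequence_track`: `chain_id`, `length` (polymer
#'   length) and `marks` (data frame with `polymer_index`,
#'   `identification` (index into the report), `def_id`, `n_residues`).
#' @export
sequence_track <- function(report, model, chain_id) {
  res <- model$residues
  sel <- res$chain == chain_id & res$is_polymer
  if (!any(sel)) stop("no polymer chain with id '", chain_id, "'")
  len <- sum(sel)

  marks <- list()
  for (k in seq_along(report$identifications)) {
    ident <- report$identifications[[k]]
    r <- ident$residues
    here <- r$chain == chain_id & r$is_polymer %in% TRUE
    if (!any(here)) next
    marks[[length(marks) + 1L]] <- data.frame(
      polymer_index = r$polymer_index[here],
      identification = k,
      def_id = ident$def_id,
      ## icon-edge count: polymer residues involved in the modification
      n_residues = sum(r$is_polymer %in% TRUE),
      stringsAsFactors = FALSE)
  }
  marks <- if (length(marks)) do.call(rbind, marks)
           else data.frame(polymer_index = integer(), identification = integer(),
                           def_id = character(), n_residues = integer(),
                           stringsAsFactors = FALSE)
  marks <- marks[order(marks$polymer_index, marks$identification), , drop = FALSE]
  rownames(marks) <- NULL
  structure(list(chain_id = chain_id, length = len, marks = marks),
            class = "sequence_track")
}

#' @export
print.sequence_track <- function(x, ...) {
  cat(sprintf("Sequence track, chain %s (%d residues): %d mark(s)\n",
              x$chain_id, x$length, nrow(x$marks)))
  invisible(x)
}

#' Batch-scan a set of structure files
#'
#' Parses and scans each file, writes per-entry TSV and/or JSON annotation
#' into `out_dir`, and tallies how many entries contain each definition
#' (entries, not occurrences).  A failing entry is logged to stderr and
#' skipped; the batch never aborts on a single bad file.
#'
#' @param paths Character vector of structure file paths (at least one).
#' @param cfg A [scan_config()].
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json")`.
#' @return List of class `batch_summary`: `n_entries`, `n_failures`,
#'   `failures` (named character vector of error messages),
#'   `by_definition` (data frame def_id/category/n_entries) and
#'   `by_category` (data frame category/n_entries).  Also written to
#'   `out_dir/summary.tsv`.
#' @export
scan_batch <- function(paths, cfg = scan_config(), out_dir,
                       formats = c("tsv", "json")) {
  if (length(paths) < 1L) stop("scan_batch requires at least one path")
  formats <- match.arg(formats, c("tsv", "json"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  defs <- cfg$dictionary$definitions
  def_entries <- stats::setNames(integer(length(defs)), names(defs))
  cat_entries <- stats::setNames(integer(length(MOD_CATEGORIES)), MOD_CATEGORIES)
  failures <- character(0)
  n_ok <- 0L

  for (p in paths) {
    t0 <- proc.time()[["elapsed"]]
    rep <- tryCatch({
      model <- parse_structure(p)
      identify_all(model, cfg)
    }, error = function(e) e)
    if (inherits(rep, "error")) {
      failures[basename(p)] <- conditionMessage(rep)
      message(sprintf("[scan] FAILED %s: %s", basename(p),
                      conditionMessage(rep)))
      next
    }
    n_ok <- n_ok + 1L
    stem <- tools::file_path_sans_ext(basename(p))
    if ("tsv" %in% formats)
      write_tsv(rep, file.path(out_dir, paste0(stem, ".tsv")))
    if ("json" %in% formats)
      write_json(rep, file.path(out_dir, paste0(stem, ".json")))

    ids <- vapply(rep$identifications, function(i) i$def_id, character(1))
    cats <- vapply(rep$identifications, function(i) i$category, character(1))
    def_entries[unique(ids)] <- def_entries[unique(ids)] + 1L
    cat_entries[unique(cats)] <- cat_entries[unique(cats)] + 1L
    message(sprintf("[scan] %s: %d identification(s) (%.2fs)", basename(p),
                    length(rep$identifications),
                    proc.time()[["elapsed"]] - t0))
  }

  by_def <- data.frame(
    def_id = names(defs),
    category = vapply(defs, function(d) d$category, character(1)),
    n_entries = unname(def_entries),
    stringsAsFactors = FALSE)
  rownames(by_def) <- NULL
  by_cat <- data.frame(category = MOD_CATEGORIES,
                       n_entries = unname(cat_entries),
                       stringsAsFactors = FALSE)

  summ <- structure(list(n_entries = n_ok, n_failures = length(failures),
                         failures = failures, by_definition = by_def,
                         by_category = by_cat),
                    class = "batch_summary")
  utils::write.table(by_def, file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("Batch scan: %d entries scanned, %d failure(s)\n",
              x$n_entries, x$n_failures))
  hit <- x$by_definition[x$by_definition$n_entries > 0L, , drop = FALSE]
  if (nrow(hit))
    for (i in seq_len(nrow(hit)))
      cat(sprintf("  %-24s %d entrie(s)\n", hit$def_id[i], hit$n_entries[i]))
  invisible(x)
}
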