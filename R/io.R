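#' Read peptides from FASTA or plain text
#'
#' A file starting with `>` is parsed as FASTA (via Biostrings); anything
#' else is read as one peptide per line, blank lines and `#` comments
#' skipped.
#'
#' @param path Input file.
#' @return A tibble with columns `name` and `peptide`.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) abort(paste0("Peptide file not found: ", path))
  first <- readLines(path, n = 1)
  if (length(first) == 1 && startsWith(first, ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("Reading FASTA needs the Biostrings package.")
    }
    seqs <- Biostrings::readAAStringSet(path)
    tbl <- tibble::tibble(name = names(seqs),
                          peptide = unname(as.character(seqs)))
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    tbl <- tibble::tibble(
      name = sprintf("peptide_%d", seq_along(lines)),
      peptide = toupper(lines)
    )
  }
  if (nrow(tbl) == 0) abort(paste0("No peptides found in ", path, "."))
  tbl
}

#' Predict cores for a table of peptides
#'
#' Vectorized convenience over [predict_core()]: one row in, one row out,
#' ready to pipe into further dplyr verbs or [readr::write_tsv()].
#'
#' @param peptides A tibble with a `peptide` column (and optionally `name`).
#' @inheritParams score_window
#' @return A tibble with `name`, `peptide`, `core`, `offset`, `score`,
#'   `margin`.
#' @export
predict_cores <- function(peptides, profiles, include_pocket1 = TRUE) {
  purrr::map_dfr(seq_len(nrow(peptides)), function(i) {
    pred <- predict_core(peptides$peptide[i], profiles, include_pocket1)
    g <- glance(pred)
    tibble::tibble(
      name = peptides$name[i] %||% sprintf("peptide_%d", i),
      peptide = pred$peptide, core = pred$core, offset = pred$offset,
      score = g$best_score, margin = g$margin
    )
  })
}

#' Write an evaluation report
#'
#' Writes the per-record table as TSV (with the run parameters echoed in
#' `#`-comment header lines for provenance) and, optionally, a JSON summary.
#'
#' @param evaluation A `core_evaluation` from [evaluate_cores()].
#' @param path Output TSV path.
#' @param json_path Optional JSON summary path.
#' @param params Named list of parameter values to echo into the header.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(evaluation, path, json_path = NULL, params = list()) {
  header <- c(
    sprintf("# total_errors: %d", attr(evaluation, "total_errors")),
    sprintf("# include_pocket1: %s", attr(evaluation, "include_pocket1")),
    purrr::imap_chr(params, function(v, k) sprintf("# %s: %s", k, format(v)))
  )
  writeLines(header, path)
  readr::write_tsv(tibble::as_tibble(evaluation), path, append = TRUE,
                   col_names = TRUE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      c(list(n = nrow(evaluation),
             total_errors = attr(evaluation, "total_errors")), params),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

#' Write a sweep table
#'
#' Long-format TSV (`mode`, `alpha`, `errors`, `n`) with the fixed gamma
#' parameters echoed as `#`-comment header lines.
#'
#' @param sweep A `dr_sweep` from [alpha_sweep()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  writeLines(c(
    sprintf("# shape: %g", attr(sweep, "shape")),
    sprintf("# scale: %g", attr(sweep, "scale"))
  ), path)
  readr::write_tsv(tibble::as_tibble(sweep), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}
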