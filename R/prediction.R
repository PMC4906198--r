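#' Score one 9-mer window against anchor pocket profiles
#'
#' A candidate binding core places its residue j into pocket j. The window
#' score is the sum, over the scored anchor pockets, of the pocket profile's
#' value for the residue sitting in it. Non-anchor pockets (2, 3, 5, 8)
#' contribute nothing, following the TEPITOPE convention. An unknown residue
#' `X` contributes 0 at whatever position it occupies (benchmark peptides are
#' sometimes X-flanked where density was missing).
#'
#' @param window A 9-character window string.
#' @param profiles A `dr_profile_set` (or named list of 20-value profiles
#'   keyed `"1"`, `"4"`, `"6"`, `"7"`, `"9"`).
#' @param include_pocket1 Score pocket 1 as well (default `TRUE`); when
#'   `FALSE` only pockets 4, 6, 7, 9 are summed.
#' @return A single numeric score.
#' @examples
#' prof <- setNames(rep(0, 20), drpocket_alphabet())
#' prof["A"] <- 1
#' profs <- setNames(rep(list(prof), 5), c("1", "4", "6", "7", "9"))
#' score_window("AAAAAAAAA", profs)
#' @export
score_window <- function(window, profiles, include_pocket1 = TRUE) {
  if (nchar(window) != 9) abort("`window` must be exactly 9 residues.")
  pockets <- scored_pockets(profiles, include_pocket1)
  res <- strsplit(toupper(window), "")[[1]]
  total <- 0
  for (p in pockets) {
    r <- res[p]
    if (r == "X") next
    prof <- profiles[[as.character(p)]]
    if (!r %in% names(prof)) {
      abort(paste0("Residue '", r, "' not covered by the pocket-", p, " profile."))
    }
    total <- total + as.numeric(prof[[r]])
  }
  total
}

scored_pockets <- function(profiles, include_pocket1) {
  pockets <- if (include_pocket1) ANCHOR_POCKETS else SYNTH_POCKETS
  missing <- setdiff(as.character(pockets), names(profiles))
  if (length(missing) > 0) {
    abort(paste0("Missing profile(s) for anchor pocket(s) ",
                 paste(missing, collapse = ", "), "."))
  }
  pockets
}

#' Predict the binding core of a peptide
#'
#' Slides a 9-residue window over the peptide (all `nchar - 8` positions),
#' scores each window with [score_window()], and returns the best-scoring
#' window as the predicted binding core. Ties are broken towards the leftmost
#' window, so predictions are deterministic.
#'
#' @param peptide Peptide string, length >= 9.
#' @inheritParams score_window
#' @return A `core_prediction`: a list with `peptide`, `core`, `offset`
#'   (0-based window start) and `window_scores` (one per window).
#' @export
predict_core <- function(peptide, profiles, include_pocket1 = TRUE) {
  peptide <- toupper(peptide)
  n <- nchar(peptide)
  if (n < 9) abort("Peptide must be at least 9 residues long.")
  starts <- seq_len(n - 8)
  windows <- stringr::str_sub(peptide, starts, starts + 8)
  scores <- vapply(windows, score_window, numeric(1),
                   profiles = profiles, include_pocket1 = include_pocket1,
                   USE.NAMES = FALSE)
  best <- which.max(scores)  # first maximum = leftmost tie-break
  structure(
    list(
      peptide = peptide,
      core = windows[best],
      offset = best - 1L,
      window_scores = scores
    ),
    class = "core_prediction",
    include_pocket1 = include_pocket1
  )
}

#' @export
print.core_prediction <- function(x, ...) {
  cat("<core_prediction> ", x$peptide, "\n  core ", x$core,
      " at offset ", x$offset, " (", length(x$window_scores),
      " windows)\n", sep = "")
  invisible(x)
}

#' Tidy a core prediction into its window scores
#'
#' @param x A `core_prediction`.
#' @param ... Unused.
#' @return A tibble with columns `offset`, `window`, `score`, `predicted`.
#' @export
tidy.core_prediction <- function(x, ...) {
  starts <- seq_along(x$window_scores)
  tibble::tibble(
    offset = starts - 1L,
    window = stringr::str_sub(x$peptide, starts, starts + 8),
    score = x$window_scores,
    predicted = starts - 1L == x$offset
  )
}

#' @rdname tidy.core_prediction
#' @return `glance()` returns a one-row tibble with `peptide`, `core`,
#'   `offset`, `n_windows`, `best_score`, `margin` (gap to the runner-up).
#' @export
glance.core_prediction <- function(x, ...) {
  s <- sort(x$window_scores, decreasing = TRUE)
  tibble::tibble(
    peptide = x$peptide, core = x$core, offset = x$offset,
    n_windows = length(x$window_scores),
    best_score = s[1],
    margin = if (length(s) > 1) s[1] - s[2] else NA_real_
  )
}

#' @rdname tidy.core_prediction
#' @param object A `core_prediction`.
#' @export
autoplot.core_prediction <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$score,
                                  fill = .data$predicted)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "window offset", y = "window score",
                  title = object$peptide)
}

#' Evaluate core predictions against annotated complexes
#'
#' Predicts the binding core for every record of a complex table and compares
#' it with the annotated core by exact 9-mer string equality (identical
#' 9-mers at different offsets are indistinguishable, so offsets are not
#' compared). An allele the predictor cannot resolve yields a per-record note
#' and counts as an error rather than aborting the run.
#'
#' @param records A tibble with columns `pdb_id`, `allele`, `peptide`,
#'   `core` (see [load_complexes()]).
#' @param predictor Either a function `allele -> dr_profile_set`, or a named
#'   list of profile sets keyed by allele name.
#' @inheritParams score_window
#' @return A `core_evaluation`: a tibble with one row per record (`pdb_id`,
#'   `allele`, `peptide`, `annotated`, `predicted`, `correct`, `note`), with
#'   `total_errors` and parameter attributes; `glance()` summarises it.
#' @export
evaluate_cores <- function(records, predictor, include_pocket1 = TRUE) {
  if (nrow(records) == 0) abort("`records` is empty.")
  resolve <- if (is.function(predictor)) {
    predictor
  } else {
    function(allele) {
      if (!allele %in% names(predictor)) {
        abort(paste0("No profiles for allele ", allele, "."))
      }
      predictor[[allele]]
    }
  }
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    pred <- tryCatch(
      {
        profs <- resolve(rec$allele)
        list(core = predict_core(rec$peptide, profs, include_pocket1)$core,
             note = NA_character_)
      },
      error = function(e) list(core = NA_character_, note = conditionMessage(e))
    )
    tibble::tibble(
      pdb_id = rec$pdb_id, allele = rec$allele, peptide = rec$peptide,
      annotated = rec$core, predicted = pred$core,
      correct = !is.na(pred$core) & pred$core == rec$core,
      note = pred$note
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("core_evaluation", class(out)),
    total_errors = sum(!out$correct),
    include_pocket1 = include_pocket1
  )
}

#' @export
print.core_evaluation <- function(x, ...) {
  cat("<core_evaluation> ", nrow(x), " records, ",
      attr(x, "total_errors"), " error(s)\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Summarise a core evaluation
#'
#' @param x A `core_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `errors`, `accuracy`.
#' @export
glance.core_evaluation <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    errors = sum(!x$correct),
    accuracy = mean(x$correct)
  )
}

#' Count prediction errors in a static prediction table
#'
#' Joins bundled (or user) per-complex predictions against the annotated
#' cores and counts exact-match errors per method. Used to recompute the
#' benchmark's headline error counts from the shipped reference columns.
#'
#' @param records Complex table with `pdb_id` and `core`.
#' @param predictions Long tibble with `pdb_id`, `method`, `predicted_core`.
#' @return A tibble with one row per method: `method`, `n`, `errors`.
#' @export
count_reference_errors <- function(records, predictions) {
  dplyr::inner_join(predictions, records[, c("pdb_id", "core")], by = "pdb_id") |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      errors = sum(.data$predicted_core != .data$core),
      .groups = "drop"
    )
}

#' Sweep the weight exponent alpha across scoring modes
#'
#' Re-runs the full evaluation once per (mode, alpha) cell with all other
#' parameters fixed, returning a long table of total error counts -- the
#' experiment used to pick the combination rule and sharpening exponent.
#'
#' @param records Complex table (as for [evaluate_cores()]).
#' @param registry Raw-profile registry covering pockets 4, 6, 7, 9.
#' @param queries Named list keyed by allele: each element a query list as
#'   accepted by [synthesize_allele()].
#' @param pocket1_profile Shared pocket-1 profile (20 named scores).
#' @param modes Subset of `c("K1", "K2", "K3")`.
#' @param alphas Positive alpha values; default the canonical sweep
#'   `c(1, 2, 3, 4, 5, 10, 15, 20)`.
#' @param shape,scale Gamma weight parameters.
#' @inheritParams score_window
#' @inheritParams synthesize_allele
#' @return A `dr_sweep` tibble with columns `mode`, `alpha`, `errors`, `n`.
#' @export
alpha_sweep <- function(records, registry, queries, pocket1_profile,
                        modes = c("K1", "K2", "K3"),
                        alphas = c(1, 2, 3, 4, 5, 10, 15, 20),
                        shape = 1, scale = 1, include_pocket1 = TRUE,
                        matrix = read_substitution_matrix(),
                        seq_bandwidth = NULL, spa_bandwidth = NULL) {
  if (length(alphas) == 0 || any(alphas <= 0)) {
    abort("`alphas` must be a non-empty vector of positive values.")
  }
  modes <- match.arg(modes, several.ok = TRUE)
  grid <- tidyr::expand_grid(mode = modes, alpha = alphas)
  cells <- purrr::map(seq_len(nrow(grid)), function(i) {
    mode <- grid$mode[i]
    alpha <- grid$alpha[i]
    sets <- purrr::map(queries, function(q) {
      synthesize_allele(
        q, registry, pocket1_profile = pocket1_profile, mode = mode,
        alpha = alpha, shape = shape, scale = scale, matrix = matrix,
        seq_bandwidth = seq_bandwidth, spa_bandwidth = spa_bandwidth
      )
    })
    ev <- evaluate_cores(records, sets, include_pocket1 = include_pocket1)
    tibble::tibble(mode = mode, alpha = alpha,
                   errors = attr(ev, "total_errors"), n = nrow(ev))
  })
  out <- dplyr::bind_rows(cells)
  structure(out, class = c("dr_sweep", class(out)),
            shape = shape, scale = scale)
}

#' @export
print.dr_sweep <- function(x, ...) {
  cat("<dr_sweep> ", dplyr::n_distinct(x$mode), " mode(s) x ",
      dplyr::n_distinct(x$alpha), " alpha value(s)\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Plot an alpha sweep
#'
#' @param object A `dr_sweep` from [alpha_sweep()].
#' @param ... Unused.
#' @return A ggplot: error count against alpha, one line per mode.
#' @export
autoplot.dr_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$alpha, .data$errors,
                                       colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "prediction errors",
                  colour = "scoring")
}

#' The canonical profile-column amino-acid order
#'
#' @return The 20 one-letter amino acids in the alphabetical order used for
#'   profile columns throughout the package.
#' @export
drpocket_alphabet <- function() AA_ALPHABET
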