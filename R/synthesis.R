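#' Read or write a raw pocket-profile registry
#'
#' A registry pairs, per pocket, the distinct pocket pseudosequences of the
#' reference alleles with their quantitative 20-value profiles (TEPITOPE-style
#' matrices). The TSV dialect has columns `allele`, `pocket`, `pseudoseq`,
#' then twenty score columns named by one-letter amino acid in alphabetical
#' order (`A` ... `Y`).
#'
#' @param path File path.
#' @return `read_profile_registry()` returns a validated registry tibble.
#' @export
read_profile_registry <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_registry(tbl)
}

#' @rdname read_profile_registry
#' @param registry A registry tibble.
#' @export
write_profile_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  readr::write_tsv(
    dplyr::select(registry, dplyr::all_of(c("allele", "pocket", "pseudoseq", AA_ALPHABET))),
    path
  )
  invisible(path)
}

#' Validate a registry tibble
#'
#' Checks the 20-score-column contract, pseudosequence uniqueness within each
#' pocket and equal pseudosequence lengths per pocket.
#'
#' @param registry A registry tibble.
#' @return The registry, invisibly validated (with `pocket` as integer).
#' @export
validate_registry <- function(registry) {
  need <- c("allele", "pocket", "pseudoseq")
  missing_cols <- setdiff(c(need, AA_ALPHABET), names(registry))
  if (length(missing_cols) > 0) {
    abort(paste0("Registry is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  registry$pocket <- as.integer(registry$pocket)
  scores <- as.matrix(registry[, AA_ALPHABET])
  if (nrow(registry) > 0 && (!is.numeric(scores) || anyNA(scores))) {
    abort("Registry score columns must be numeric and complete.")
  }
  by_pocket <- split(registry$pseudoseq, registry$pocket)
  for (p in names(by_pocket)) {
    ps <- by_pocket[[p]]
    if (anyDuplicated(ps)) {
      abort(paste0("Pocket ", p, " registry has duplicated pseudosequences."))
    }
    if (length(unique(nchar(ps))) > 1) {
      abort(paste0("Pocket ", p, " pseudosequences differ in length."))
    }
  }
  tibble::as_tibble(registry)
}

registry_profile_matrix <- function(registry) {
  m <- as.matrix(registry[, AA_ALPHABET])
  rownames(m) <- registry$allele
  m
}

#' Synthesize a pocket profile from ranked similarities
#'
#' Reorders the registry's raw profiles by descending similarity to the query
#' (stable in registry order on ties) and combines them elementwise with the
#' rank weights: `profile = sum_i w_i * p_(i)` where `p_(i)` is the profile of
#' the i-th most similar entry. Because the weights attach to ranks, any
#' strictly monotone transform of the similarity values yields the same
#' profile.
#'
#' @param simvec A `dr_similarity` from [similarity_vector()] (sorted or not;
#'   it is stably sorted here).
#' @param registry The registry the similarities were computed against.
#' @param weights A `dr_weights` of length `nrow(registry)` (or a plain
#'   non-negative numeric vector summing to 1).
#'
#' @return A `dr_profile`: a named numeric vector of 20 scores with the
#'   pocket index, parameters and a provenance tibble (rank, entry, allele,
#'   combined similarity, weight) as attributes.
#' @export
synthesize_profile <- function(simvec, registry, weights) {
  registry <- validate_registry(registry)
  w <- as.numeric(weights)
  if (length(w) != nrow(registry)) {
    abort("`weights` length must equal the registry size.")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    abort("`weights` must be non-negative and sum to 1.")
  }
  if (nrow(simvec) != nrow(registry) ||
      !setequal(simvec$entry, seq_len(nrow(registry)))) {
    abort("`simvec` must cover every registry entry exactly once.")
  }
  sorted <- sort_similarity(as_raw_similarity(simvec))
  profiles <- registry_profile_matrix(registry)[sorted$entry, , drop = FALSE]
  scores <- as.numeric(w %*% profiles)
  names(scores) <- AA_ALPHABET
  provenance <- tibble::tibble(
    rank = sorted$rank, entry = sorted$entry, allele = sorted$allele,
    combined = sorted$combined, weight = w
  )
  structure(scores,
    class = "dr_profile",
    pocket = attr(simvec, "pocket"), mode = attr(simvec, "mode"),
    weights = weights, provenance = provenance
  )
}

# Re-sorting an already-descending vector is harmless; restore raw entry
# ordering first so stability is defined by registry order either way.
as_raw_similarity <- function(simvec) {
  if (!inherits(simvec, "dr_similarity")) abort("Expected a `dr_similarity`.")
  out <- restore_sim_attrs(
    simvec[order(simvec$entry), setdiff(names(simvec), "rank")], simvec
  )
  attr(out, "ordering") <- "raw"
  out
}

#' @export
print.dr_profile <- function(x, ...) {
  cat("<dr_profile> pocket ", attr(x, "pocket"), "\n", sep = "")
  print(as.numeric(x) |> setNames(names(x)), ...)
  invisible(x)
}

#' Tidy a synthesized pocket profile
#'
#' @param x A `dr_profile`.
#' @param ... Unused.
#' @return A tibble with columns `residue` and `score`.
#' @export
tidy.dr_profile <- function(x, ...) {
  tibble::tibble(residue = names(x), score = as.numeric(x))
}

#' Synthesize the full anchor-profile set for a query allele
#'
#' Runs the per-pocket pipeline (similarity, rank weights, weighted profile
#' average) for the four synthesized anchor pockets 4, 6, 7 and 9, and
#' attaches the shared pocket-1 profile unchanged: pocket 1 is conserved
#' across HLA-DR molecules, so a single configured profile serves all
#' alleles.
#'
#' @param query A named list with one element per pocket (`"4"`, `"6"`,
#'   `"7"`, `"9"`), each a list with `pseudoseq` (string) and optional
#'   `coords` (n x 3 matrix). See [allele_query()] for a convenience
#'   constructor.
#' @param registry A registry tibble covering pockets 4, 6, 7, 9 (with an
#'   optional `coords` list-column).
#' @param pocket1_profile A named numeric vector of 20 scores for pocket 1,
#'   or `NULL` only when `include_pocket1 = FALSE` downstream; synthesis
#'   requires it by default.
#' @param mode Similarity combination rule (`"K1"`, `"K2"`, `"K3"`).
#' @param alpha,shape,scale Gamma rank-weight parameters (defaults 3, 1, 1).
#' @param matrix Substitution matrix.
#' @param seq_bandwidth,spa_bandwidth Optional bandwidth overrides.
#' @param require_pocket1 Error when `pocket1_profile` is missing (default
#'   `TRUE`).
#'
#' @return A `dr_profile_set`: a named list of profiles (`"1"`, `"4"`, `"6"`,
#'   `"7"`, `"9"`) usable by [score_window()] and [predict_core()].
#' @export
synthesize_allele <- function(query, registry, pocket1_profile = NULL,
                              mode = c("K1", "K2", "K3"),
                              alpha = 3, shape = 1, scale = 1,
                              matrix = read_substitution_matrix(),
                              seq_bandwidth = NULL, spa_bandwidth = NULL,
                              require_pocket1 = TRUE) {
  mode <- match.arg(mode)
  registry <- validate_registry(registry)
  if (require_pocket1) {
    if (is.null(pocket1_profile)) {
      abort("No pocket-1 profile configured; supply `pocket1_profile` or set `require_pocket1 = FALSE`.")
    }
    pocket1_profile <- check_profile_vector(pocket1_profile)
  }
  out <- list()
  if (!is.null(pocket1_profile)) out[["1"]] <- pocket1_profile
  for (p in SYNTH_POCKETS) {
    q <- query[[as.character(p)]]
    if (is.null(q) || is.null(q$pseudoseq)) {
      abort(paste0("Query lacks a pseudosequence for pocket ", p, "."))
    }
    reg_p <- registry[registry$pocket == p, , drop = FALSE]
    if (nrow(reg_p) == 0) abort(paste0("Registry has no entries for pocket ", p, "."))
    sv <- similarity_vector(
      q$pseudoseq, reg_p, coords = q$coords, mode = mode, matrix = matrix,
      seq_bandwidth = seq_bandwidth, spa_bandwidth = spa_bandwidth
    )
    w <- gamma_weights(nrow(reg_p), shape = shape, scale = scale, alpha = alpha)
    out[[as.character(p)]] <- synthesize_profile(sv, reg_p, w)
  }
  structure(out,
    class = "dr_profile_set",
    mode = mode, alpha = alpha, shape = shape, scale = scale
  )
}

check_profile_vector <- function(profile) {
  profile <- unlist(profile)
  if (length(profile) != 20 || !is.numeric(profile) || anyNA(profile)) {
    abort("A pocket profile must be 20 complete numeric scores.")
  }
  if (is.null(names(profile))) {
    names(profile) <- AA_ALPHABET
  } else if (!setequal(names(profile), AA_ALPHABET)) {
    abort("Profile names must be the 20 one-letter amino acids.")
  }
  profile[AA_ALPHABET]
}

#' Construct a per-pocket query for profile synthesis
#'
#' @param pseudoseqs A tibble with columns `pocket` and `pseudoseq` (e.g. from
#'   [extract_pseudosequences()]), covering pockets 4, 6, 7, 9.
#' @param structures Optional named list of coordinate matrices keyed by
#'   pocket (`"4"`, ...).
#' @return A query list for [synthesize_allele()].
#' @export
allele_query <- function(pseudoseqs, structures = NULL) {
  out <- list()
  for (i in seq_len(nrow(pseudoseqs))) {
    p <- as.character(pseudoseqs$pocket[i])
    out[[p]] <- list(
      pseudoseq = pseudoseqs$pseudoseq[i],
      coords = structures[[p]]
    )
  }
  out
}

#' @export
print.dr_profile_set <- function(x, ...) {
  cat("<dr_profile_set> pockets: ", paste(names(x), collapse = ", "),
      sprintf(" (mode %s, alpha %g)\n", attr(x, "mode") %||% "-",
              attr(x, "alpha") %||% NA_real_), sep = "")
  invisible(x)
}

#' Tidy a profile set into a long tibble
#'
#' @param x A `dr_profile_set`.
#' @param ... Unused.
#' @return A tibble with columns `pocket`, `residue`, `score`.
#' @export
tidy.dr_profile_set <- function(x, ...) {
  purrr::map_dfr(names(x), function(p) {
    tibble::tibble(pocket = as.integer(p), residue = AA_ALPHABET,
                   score = as.numeric(check_profile_vector(x[[p]])))
  })
}
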