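#' Specification for synthetic fixtures
#'
#' Collects the knobs of the synthetic-data generator: registry size,
#' pseudosequence length, the per-entry coordinate perturbation scale, the
#' score gap guaranteed for planted binding cores, and the peptide length.
#' All generation is seed-deterministic.
#'
#' @param seed Integer RNG seed.
#' @param m Registry size (entries per pocket).
#' @param n Pseudosequence length.
#' @param coordinate_noise Non-negative perturbation unit in Angstrom; entry
#'   `i`'s coordinates are the shared template displaced by an exact-RMS
#'   magnitude of `i * coordinate_noise`, so the structural-similarity
#'   ordering against the template is known by construction.
#' @param profile_contrast Positive score gap the planted core must hold over
#'   every competing window.
#' @param peptide_length Planted-peptide length, at least 9.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, m = 5L, n = 6L, coordinate_noise = 0.5,
                         profile_contrast = 2, peptide_length = 15L) {
  stopifnot_spec(m >= 1, "m must be >= 1")
  stopifnot_spec(n >= 1, "n must be >= 1")
  stopifnot_spec(coordinate_noise >= 0, "coordinate_noise must be >= 0")
  stopifnot_spec(profile_contrast > 0, "profile_contrast must be > 0")
  stopifnot_spec(peptide_length >= 9, "peptide_length must be >= 9")
  structure(
    list(
      seed = as.integer(seed), m = as.integer(m), n = as.integer(n),
      coordinate_noise = coordinate_noise, profile_contrast = profile_contrast,
      peptide_length = as.integer(peptide_length)
    ),
    class = "fixture_spec"
  )
}

stopifnot_spec <- function(ok, msg) if (!isTRUE(ok)) abort(paste0("Invalid fixture spec: ", msg, "."))

#' Generate a synthetic raw-profile registry with structures
#'
#' Draws `m` unique random pseudosequences of length `n` per requested
#' pocket, uniform profiles in \[-2, 2\] (TEPITOPE-style signed scores), and
#' coordinates built from a fixed helical template: entry `i` is the template
#' plus a Gaussian displacement rescaled to RMS magnitude
#' `i * coordinate_noise`. Against the unperturbed template the structural
#' distances therefore grow with entry index, which makes the expected
#' structural-similarity ordering part of the construction.
#'
#' @param spec A [fixture_spec()].
#' @param pockets Pockets to populate (default 4, 6, 7, 9).
#' @return A registry tibble with a `coords` list-column, plus the query
#'   template under `attr(, "template")`.
#' @export
generate_registry <- function(spec, pockets = SYNTH_POCKETS) {
  if (spec$m > 20^spec$n) {
    abort("Registry size exceeds the number of distinct pseudosequences.")
  }
  withr::with_seed(spec$seed, {
    template <- helix_template(spec$n)
    rows <- purrr::map(pockets, function(p) {
      ps <- unique_pseudoseqs(spec$m, spec$n)
      scores <- matrix(runif(spec$m * 20, -2, 2), nrow = spec$m,
                       dimnames = list(NULL, AA_ALPHABET))
      coords <- purrr::map(seq_len(spec$m), function(i) {
        perturb_template(template, i * spec$coordinate_noise)
      })
      dplyr::bind_cols(
        tibble::tibble(
          allele = sprintf("SYN-%d-%03d", p, seq_len(spec$m)),
          pocket = as.integer(p),
          pseudoseq = ps
        ),
        tibble::as_tibble(scores)
      ) |>
        dplyr::mutate(coords = coords)
    })
    out <- validate_registry(dplyr::bind_rows(rows))
    attr(out, "template") <- template
    out
  })
}

helix_template <- function(n) {
  t <- seq_len(n)
  cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * t)
}

perturb_template <- function(template, magnitude) {
  if (magnitude == 0) return(template)
  delta <- matrix(rnorm(length(template)), nrow = nrow(template))
  rms <- sqrt(sum(delta^2) / nrow(delta))
  template + delta / rms * magnitude
}

unique_pseudoseqs <- function(m, n) {
  out <- character(0)
  while (length(out) < m) {
    need <- m - length(out)
    new <- vapply(seq_len(need * 2), function(i) {
      paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, new))
  }
  out[seq_len(m)]
}

#' Generate a random profile set
#'
#' Uniform \[-2, 2\] scores for pockets 1, 4, 6, 7, 9; a quick source of
#' plausible profiles for planted-core fixtures.
#'
#' @param seed Integer seed.
#' @return A `dr_profile_set`-shaped named list of 20-score vectors.
#' @export
random_profile_set <- function(seed = 1L) {
  withr::with_seed(seed, {
    out <- purrr::map(ANCHOR_POCKETS, function(p) {
      setNames(runif(20, -2, 2), AA_ALPHABET)
    })
    names(out) <- as.character(ANCHOR_POCKETS)
    structure(out, class = "dr_profile_set")
  })
}

#' Plant a binding core in a synthetic peptide
#'
#' Builds a peptide whose designated 9-mer window is guaranteed to out-score
#' every other window by at least `profile_contrast` under [score_window()]
#' with the given profiles: scored anchor positions of the core take each
#' pocket profile's best residue, remaining core positions are random, and
#' flanking positions take the globally worst-scoring residue. The guarantee
#' is re-verified by exhaustive window scoring before returning; if the
#' profiles cannot support the requested contrast the generator errors rather
#' than emit a weak fixture.
#'
#' @param profiles A profile set covering the scored anchor pockets.
#' @param spec A [fixture_spec()]; `peptide_length` and `profile_contrast`
#'   are used.
#' @param offset Optional fixed 0-based core offset; random by default.
#' @inheritParams score_window
#' @return A list with `peptide`, `offset` (0-based), `core` and the realised
#'   `gap` to the runner-up window.
#' @export
plant_core_peptide <- function(profiles, spec, offset = NULL,
                               include_pocket1 = TRUE) {
  pockets <- scored_pockets(profiles, include_pocket1)
  len <- spec$peptide_length
  withr::with_seed(spec$seed + 104729L, {
    off <- offset %||% (sample.int(len - 8, 1) - 1L)
    if (off < 0 || off > len - 9) abort("Core offset outside the peptide.")

    best_res <- purrr::map_chr(pockets, function(p) {
      prof <- check_profile_vector(profiles[[as.character(p)]])
      names(prof)[which.max(prof)]
    })
    # residue with the lowest worst-case contribution across scored pockets
    pooled <- purrr::map(pockets, function(p) {
      check_profile_vector(profiles[[as.character(p)]])
    })
    worst_case <- purrr::reduce(pooled, pmax)
    flank_res <- names(worst_case)[which.min(worst_case)]

    core <- sample(AA_ALPHABET, 9, replace = TRUE)
    core[pockets] <- best_res
    pep <- rep(flank_res, len)
    pep[off + 1:9] <- core
    peptide <- paste(pep, collapse = "")

    pred <- predict_core(peptide, profiles, include_pocket1)
    scores <- pred$window_scores
    others <- scores[-(off + 1)]
    gap <- scores[off + 1] - if (length(others)) max(others) else -Inf
    if (length(others) > 0 && gap < spec$profile_contrast) {
      abort(paste0(
        "Requested contrast ", spec$profile_contrast,
        " unachievable with these profiles (best gap ", signif(gap, 4), ")."
      ))
    }
    list(peptide = peptide, offset = off,
         core = stringr::str_sub(peptide, off + 1, off + 9), gap = gap)
  })
}

#' Generate a fully synthetic evaluation benchmark
#'
#' End-to-end fixture: a registry (with structures), one query allele per
#' requested record whose pocket pseudosequences and coordinates coincide
#' with a chosen registry entry, profiles synthesized through the actual
#' pipeline, and a peptide with a core planted under those profiles. The
#' resulting records/queries pair can be fed straight to [evaluate_cores()]
#' or [alpha_sweep()].
#'
#' @param spec A [fixture_spec()].
#' @param n_records Number of synthetic complexes.
#' @param alpha,mode Synthesis parameters used when planting.
#' @return A list with `records` (tibble: pdb_id, allele, peptide, core),
#'   `registry`, `queries` (named list for [alpha_sweep()]),
#'   `pocket1_profile` and `profile_sets` (the planting profiles).
#' @export
generate_benchmark <- function(spec, n_records = 5, alpha = 3, mode = "K1") {
  registry <- generate_registry(spec)
  pocket1 <- random_profile_set(spec$seed + 7L)[["1"]]
  template <- attr(registry, "template")
  withr::with_seed(spec$seed + 524287L, {
    anchors <- sample.int(spec$m, n_records, replace = TRUE)
  })
  queries <- list()
  records <- list()
  sets <- list()
  for (r in seq_len(n_records)) {
    j <- anchors[r]
    allele <- sprintf("QRY-%03d", r)
    query <- list()
    for (p in SYNTH_POCKETS) {
      reg_p <- registry[registry$pocket == p, ]
      query[[as.character(p)]] <- list(
        pseudoseq = reg_p$pseudoseq[j],
        coords = reg_p$coords[[j]]
      )
    }
    queries[[allele]] <- query
    profs <- synthesize_allele(query, registry, pocket1_profile = pocket1,
                               mode = mode, alpha = alpha)
    sets[[allele]] <- profs
    rec_spec <- spec
    rec_spec$seed <- spec$seed + 1000L * r
    planted <- plant_core_peptide(profs, rec_spec)
    records[[r]] <- tibble::tibble(
      pdb_id = sprintf("SYN%03d", r), allele = allele,
      peptide = planted$peptide, core = planted$core
    )
  }
  list(
    records = dplyr::bind_rows(records),
    registry = registry,
    queries = queries,
    pocket1_profile = pocket1,
    profile_sets = sets
  )
}

# ---- bundled benchmark tables ------------------------------------------------

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "drpocket")
  if (!nzchar(path)) abort(paste0("Bundled data file missing: ", file))
  path
}

read_bundled_tsv <- function(file, col_types) {
  tbl <- readr::read_tsv(extdata_path(file), comment = "#",
                         col_types = col_types, progress = FALSE)
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) abort(paste0("Malformed bundled file: ", file))
  tbl
}

#' Load the bundled HLA-DR complex benchmark
#'
#' 39 HLA-DR/peptide complexes with annotated 9-mer binding cores: a
#' 30-complex test split and 9 additional held-out complexes. Loading
#' validates the structural invariants (9-residue cores contained in their
#' peptides).
#'
#' @param split `"all"` (default), `"test30"` or `"heldout9"`.
#' @return A tibble with columns `pdb_id`, `allele`, `peptide`, `core`,
#'   `split`.
#' @export
load_complexes <- function(split = c("all", "test30", "heldout9")) {
  split <- match.arg(split)
  tbl <- read_bundled_tsv("complexes.tsv", readr::cols(.default = "c"))
  need <- c("pdb_id", "allele", "peptide", "core", "split")
  if (!identical(names(tbl), need)) abort("complexes.tsv: unexpected schema.")
  if (any(nchar(tbl$core) != 9)) abort("complexes.tsv: non-9-mer core.")
  if (!all(stringr::str_detect(tbl$peptide, stringr::fixed(tbl$core)))) {
    abort("complexes.tsv: a core is not contained in its peptide.")
  }
  if (!all(tbl$split %in% c("test30", "heldout9"))) {
    abort("complexes.tsv: unknown split label.")
  }
  if (split != "all") tbl <- tbl[tbl$split == split, ]
  tbl
}

#' Load bundled reference predictions
#'
#' Per-complex binding cores as published: the `published` method is the
#' pocket-similarity synthesis approach this package reimplements; the other
#' methods are competitor tools, shipped as static reference rows only.
#'
#' @return A tibble with columns `pdb_id`, `method`, `predicted_core`.
#' @export
load_reference_predictions <- function() {
  tbl <- read_bundled_tsv("reference_predictions.tsv",
                          readr::cols(.default = "c"))
  if (!identical(names(tbl), c("pdb_id", "method", "predicted_core"))) {
    abort("reference_predictions.tsv: unexpected schema.")
  }
  if (any(nchar(tbl$predicted_core) != 9)) {
    abort("reference_predictions.tsv: non-9-mer prediction.")
  }
  tbl
}

#' Load observed per-complex pocket compositions
#'
#' The residues (beta-chain position + one-letter code) observed lining each
#' pocket in the solved test-set structures. Observational: the canonical
#' pocket definitions are [pocket_definitions()].
#'
#' @return A long tibble with columns `pdb_id`, `pocket`, `position`,
#'   `residue`.
#' @export
load_complex_pockets <- function() {
  tbl <- read_bundled_tsv("complex_pockets.tsv",
                          readr::cols(pdb_id = "c", pocket = "i", residues = "c"))
  tbl |>
    dplyr::mutate(token = stringr::str_split(.data$residues, "\\s+")) |>
    tidyr::unnest("token") |>
    dplyr::mutate(
      position = as.integer(stringr::str_extract(.data$token, "^\\d+")),
      residue = stringr::str_extract(.data$token, "[A-Z]$")
    ) |>
    dplyr::select("pdb_id", "pocket", "position", "residue")
}

#' Load the reference-allele registry skeleton
#'
#' The eleven reference HLA-DR alleles that anchor pan-specific synthesis.
#' Their quantitative pocket matrices are not redistributable, so the
#' skeleton ships with empty pseudosequence/profile slots; populate a working
#' registry via [read_profile_registry()].
#'
#' @return A tibble with column `allele` plus empty per-pocket
#'   pseudosequence slots.
#' @export
load_reference_alleles <- function() {
  read_bundled_tsv("alleles.tsv", readr::cols(.default = "c"))
}

#' Load every bundled benchmark table at once
#'
#' @return A named list: `complexes`, `pockets` (canonical definitions),
#'   `complex_pockets`, `reference_predictions`, `reference_alleles`.
#' @export
load_benchmark_tables <- function() {
  list(
    complexes = load_complexes(),
    pockets = pocket_definitions(),
    complex_pockets = load_complex_pockets(),
    reference_predictions = load_reference_predictions(),
    reference_alleles = load_reference_alleles()
  )
}
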