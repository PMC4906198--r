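#' Gaussian RBF sequence similarity between encoded pseudosequences
#'
#' Similarity is `exp(-d^2 / (2 * bandwidth^2))` where `d` is the Euclidean
#' distance between the two substitution-matrix encodings (see
#' [encode_pseudosequence()]). The value lies in (0, 1] and equals 1 exactly
#' when the encodings coincide.
#'
#' @param va,vi Numeric encoding vectors of equal length.
#' @param bandwidth Positive kernel bandwidth (same units as the encoding).
#' @return A similarity in (0, 1].
#' @examples
#' a <- encode_pseudosequence("NVGF")
#' b <- encode_pseudosequence("NVGY")
#' seq_similarity(a, b, bandwidth = 10)
#' @export
seq_similarity <- function(va, vi, bandwidth) {
  check_bandwidth(bandwidth)
  if (length(va) != length(vi)) {
    abort("Encoded pseudosequences must have equal dimension.")
  }
  rbf(sqrt(sum((va - vi)^2)), bandwidth)
}

rbf <- function(d, bandwidth) exp(-d^2 / (2 * bandwidth^2))

check_bandwidth <- function(bandwidth) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 ||
      !is.finite(bandwidth) || bandwidth <= 0) {
    abort("`bandwidth` must be a single positive number.")
  }
}

#' Raw alignment score between two pseudosequences
#'
#' The plain summed substitution score `sum_j M[a_j, b_j]` over aligned
#' positions; an alternative, unbounded sequence channel for users who prefer
#' classic alignment scores over the RBF encoding distance. Note that rank
#' orderings (and hence synthesized profiles) may differ from the RBF channel.
#'
#' @param a,b Pseudosequence strings of equal length.
#' @param matrix A substitution matrix.
#' @return A numeric score.
#' @export
alignment_score <- function(a, b, matrix = read_substitution_matrix()) {
  ra <- strsplit(toupper(a), "")[[1]]
  rb <- strsplit(toupper(b), "")[[1]]
  if (length(ra) != length(rb)) abort("Pseudosequences must have equal length.")
  bad <- setdiff(c(ra, rb), rownames(matrix))
  if (length(bad) > 0) {
    abort(paste0("Cannot score residue(s) ", paste(unique(bad), collapse = ", "), "."))
  }
  sum(matrix[cbind(ra, rb)])
}

#' Minimal RMSD under optimal rigid superposition
#'
#' Computes the least-squares rigid superposition (rotation + translation) of
#' point set `b` onto point set `a`, points in one-to-one correspondence by
#' order, and returns the residual root-mean-square deviation in Angstrom.
#' The optimal rotation is obtained from the SVD of the cross-covariance
#' matrix with the sign correction that forbids reflections (rotation
#' determinant +1), the standard practice for comparing protein substructures.
#'
#' @param a,b Pocket structures ([extract_pocket_coordinates()]), n x 3
#'   matrices, or data frames with `x`, `y`, `z` columns; at least 3 points,
#'   equal counts.
#' @return The minimal RMSD (Angstrom), a non-negative number.
#' @examples
#' a <- cbind(c(0, 1, 0, 2), c(0, 0, 1, 2), c(0, 0, 0, 1))
#' superpose_rmsd(a, a)
#' @export
superpose_rmsd <- function(a, b) {
  A <- coord_matrix(a)
  B <- coord_matrix(b)
  if (nrow(A) != nrow(B)) abort("Point sets must have equal counts.")
  if (nrow(A) < 3) abort("Superposition needs at least 3 points.")
  if (!all(is.finite(A)) || !all(is.finite(B))) abort("Coordinates must be finite.")
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  if (is_collinear(Ac) || is_collinear(Bc)) {
    abort("Degenerate point set: all points are collinear.")
  }
  M <- crossprod(Bc, Ac)  # 3x3 cross-covariance
  sv <- svd(M)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- Ac - Bc %*% t(R)
  sqrt(sum(diff^2) / nrow(A))
}

is_collinear <- function(centered, tol = 1e-9) {
  s <- svd(centered, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1e-300)
}

#' Structural similarity from a superposition RMSD
#'
#' Maps an RMSD (a distance) into a similarity in (0, 1] through the same
#' Gaussian RBF used for the sequence channel:
#' `exp(-rmsd^2 / (2 * bandwidth^2))`. Strictly decreasing in the RMSD and 1
#' exactly at RMSD 0.
#'
#' @param rmsd Non-negative RMSD in Angstrom.
#' @param bandwidth Positive kernel bandwidth in Angstrom.
#' @return A similarity in (0, 1].
#' @export
spa_similarity <- function(rmsd, bandwidth) {
  check_bandwidth(bandwidth)
  if (!is.numeric(rmsd) || anyNA(rmsd) || any(!is.finite(rmsd)) || any(rmsd < 0)) {
    abort("`rmsd` must be finite and non-negative.")
  }
  rbf(rmsd, bandwidth)
}

#' Combine sequence and structural similarity
#'
#' Three combination rules for a sequence similarity `kseq` and a structural
#' similarity `kspa`, both in \[0, 1\]:
#' * `K1`: quadratic mean, `sqrt((kseq^2 + kspa^2) / 2)`
#' * `K2`: arithmetic mean, `(kseq + kspa) / 2`
#' * `K3`: plain sum, `kseq + kspa`
#'
#' `K3 = 2 * K2`, so the two always rank candidates identically; they are kept
#' separate for completeness of the scoring-function comparison.
#'
#' @param kseq,kspa Similarities in \[0, 1\] (vectorized).
#' @param mode One of `"K1"`, `"K2"`, `"K3"`.
#' @return The combined score(s).
#' @examples
#' combine_similarity(1, 0, "K1")
#' @export
combine_similarity <- function(kseq, kspa, mode = c("K1", "K2", "K3")) {
  mode <- match.arg(mode)
  for (v in list(kseq, kspa)) {
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 1)) {
      abort("`kseq` and `kspa` must lie in [0, 1].")
    }
  }
  switch(mode,
    K1 = sqrt((kseq^2 + kspa^2) / 2),
    K2 = (kseq + kspa) / 2,
    K3 = kseq + kspa
  )
}

#' Similarity of a query pocket to every registry entry
#'
#' Computes, for one pocket, the sequence similarity (and, when coordinates
#' are available on both sides, the structural similarity) between a query
#' allele and each entry of a raw-profile registry, then combines the two
#' channels with the chosen rule. Entries lacking structural data -- or a
#' query without coordinates -- fall back to the sequence channel alone and
#' are flagged `sequence_only`.
#'
#' Bandwidths default to the median pairwise distance among the registry's
#' own entries (per channel), a scale-free choice that is deterministic given
#' the registry; a degenerate median of 0 falls back to 1.
#'
#' @param pseudoseq Query pocket pseudosequence (string).
#' @param registry A registry tibble for one pocket (see
#'   [read_profile_registry()]): columns `allele`, `pocket`, `pseudoseq`, the
#'   20 amino-acid score columns, optionally a `coords` list-column.
#' @param coords Optional query coordinates (n x 3 matrix or pocket
#'   structure).
#' @param mode Combination rule, `"K1"` (default), `"K2"` or `"K3"`.
#' @param matrix Substitution matrix for the sequence channel.
#' @param seq_bandwidth,spa_bandwidth Optional bandwidth overrides.
#'
#' @return A `dr_similarity` tibble with one row per registry entry: `entry`,
#'   `allele`, `kseq`, `rmsd`, `kspa`, `combined`, `sequence_only`, in
#'   registry order, with the scoring parameters stored as attributes.
#' @export
similarity_vector <- function(pseudoseq, registry, coords = NULL,
                              mode = c("K1", "K2", "K3"),
                              matrix = read_substitution_matrix(),
                              seq_bandwidth = NULL, spa_bandwidth = NULL) {
  mode <- match.arg(mode)
  registry <- validate_registry(registry)
  if (nrow(registry) == 0) abort("Registry is empty.")
  if (dplyr::n_distinct(registry$pocket) != 1) {
    abort("`registry` must contain a single pocket; filter first.")
  }

  enc_q <- encode_pseudosequence(pseudoseq, matrix)
  enc_r <- lapply(registry$pseudoseq, encode_pseudosequence, matrix = matrix)
  seq_bandwidth <- seq_bandwidth %||% median_pairwise(enc_r, dist_euclid)
  check_bandwidth(seq_bandwidth)
  kseq <- vapply(enc_r, seq_similarity, numeric(1), va = enc_q,
                 bandwidth = seq_bandwidth)

  reg_coords <- if ("coords" %in% names(registry)) registry$coords else
    vector("list", nrow(registry))
  have_struct <- !is.null(coords) & !vapply(reg_coords, is.null, logical(1))
  rmsd <- rep(NA_real_, nrow(registry))
  if (!is.null(coords) && any(have_struct)) {
    for (i in which(have_struct)) {
      rmsd[i] <- superpose_rmsd(coords, reg_coords[[i]])
    }
  }
  spa_bandwidth <- spa_bandwidth %||% {
    with_struct <- reg_coords[!vapply(reg_coords, is.null, logical(1))]
    if (length(with_struct) >= 2) {
      median_pairwise(with_struct, function(x, y) superpose_rmsd(x, y))
    } else 1
  }
  check_bandwidth(spa_bandwidth)

  kspa <- ifelse(is.na(rmsd), NA_real_, rbf(rmsd, spa_bandwidth))
  combined <- ifelse(
    is.na(kspa),
    kseq,  # sequence-only fallback
    combine_similarity(kseq, ifelse(is.na(kspa), 0, kspa), mode)
  )

  out <- tibble::tibble(
    entry = seq_len(nrow(registry)),
    allele = registry$allele,
    kseq = kseq, rmsd = rmsd, kspa = kspa,
    combined = combined,
    sequence_only = is.na(kspa)
  )
  structure(out,
    class = c("dr_similarity", class(out)),
    pocket = registry$pocket[1], mode = mode, ordering = "raw",
    seq_bandwidth = seq_bandwidth, spa_bandwidth = spa_bandwidth
  )
}

dist_euclid <- function(x, y) sqrt(sum((x - y)^2))

median_pairwise <- function(items, distfun) {
  m <- length(items)
  if (m < 2) return(1)
  d <- unlist(lapply(seq_len(m - 1), function(i) {
    vapply((i + 1):m, function(j) distfun(items[[i]], items[[j]]), numeric(1))
  }))
  md <- median(d)
  if (!is.finite(md) || md <= 0) 1 else md
}

#' Sort a similarity vector in descending order
#'
#' Stable descending sort by combined similarity: ties keep registry order.
#' Adds a `rank` column and flips the `ordering` attribute to `"descending"`.
#'
#' @param simvec A `dr_similarity` from [similarity_vector()].
#' @return The sorted `dr_similarity`.
#' @export
sort_similarity <- function(simvec) {
  if (!inherits(simvec, "dr_similarity")) abort("Expected a `dr_similarity`.")
  ord <- order(-simvec$combined, simvec$entry)  # stable: ties by registry order
  out <- restore_sim_attrs(simvec[ord, ], simvec)
  out$rank <- seq_len(nrow(out))
  attr(out, "ordering") <- "descending"
  out
}

# tibble subsetting drops custom attributes; copy them back
restore_sim_attrs <- function(new, old) {
  for (a in c("pocket", "mode", "ordering", "seq_bandwidth", "spa_bandwidth")) {
    attr(new, a) <- attr(old, a)
  }
  class(new) <- unique(c("dr_similarity", class(new)))
  new
}

#' @export
print.dr_similarity <- function(x, ...) {
  cat("<dr_similarity> pocket ", attr(x, "pocket"), ", mode ", attr(x, "mode"),
      ", ordering ", attr(x, "ordering"), "\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
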