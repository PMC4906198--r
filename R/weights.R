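#' Gamma-distribution rank weights
#'
#' Builds the weight vector used to average raw pocket profiles. The gamma
#' density `g(x; k, theta)` is discretized at the integer ranks
#' `i = 1, ..., m`, each mass is raised to the sharpening exponent `alpha`,
#' and the result is normalized to sum to one:
#' `w_i = G(i)^alpha / sum_j G(j)^alpha` with
#' `G(i) = i^(k-1) * exp(-i / theta) / (theta^k * Gamma(k))`.
#'
#' With the default shape `k = 1` the masses decay strictly with rank, so the
#' most similar registry entry always receives the largest weight; raising
#' `alpha` concentrates weight on the top ranks (as `alpha` grows the weight
#' vector approaches an indicator on rank 1). The `Gamma(k)`/`theta^k`
#' normalization cancels between numerator and denominator; it is kept for
#' fidelity to the gamma density but has no numerical effect. Computation is
#' carried out on log masses, so large `alpha` or `m` cannot underflow the
#' normalization.
#'
#' @param m Number of ranks (registry size), a positive integer.
#' @param shape,scale Gamma shape `k` and scale `theta`, positive; defaults
#'   `k = 1`, `theta = 1`.
#' @param alpha Positive sharpening exponent; default 3.
#'
#' @return A `dr_weights` object: the numeric weight vector (length `m`,
#'   summing to 1) with parameters and the raw discretized masses as
#'   attributes.
#' @examples
#' gamma_weights(3, shape = 1, scale = 1, alpha = 1)
#' @export
gamma_weights <- function(m, shape = 1, scale = 1, alpha = 3) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 1 || m != floor(m)) {
    abort("`m` must be a positive integer.")
  }
  for (p in c(shape = shape, scale = scale, alpha = alpha)) {
    if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0) {
      abort("`shape`, `scale` and `alpha` must be single positive numbers.")
    }
  }
  i <- seq_len(m)
  log_mass <- dgamma(i, shape = shape, scale = scale, log = TRUE)
  lw <- alpha * log_mass
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  structure(w,
    class = "dr_weights",
    m = as.integer(m), shape = shape, scale = scale, alpha = alpha,
    mass = exp(log_mass)
  )
}

#' @export
print.dr_weights <- function(x, ...) {
  cat(sprintf(
    "<dr_weights> m = %d, shape = %g, scale = %g, alpha = %g\n",
    attr(x, "m"), attr(x, "shape"), attr(x, "scale"), attr(x, "alpha")
  ))
  print(as.numeric(x), ...)
  invisible(x)
}

#' @describeIn gamma_weights One row per rank: the discretized gamma mass and
#'   the normalized weight.
#' @param x A `dr_weights` object.
#' @param ... Unused.
#' @export
tidy.dr_weights <- function(x, ...) {
  tibble::tibble(
    rank = seq_along(as.numeric(x)),
    mass = attr(x, "mass"),
    weight = as.numeric(x)
  )
}

#' @describeIn gamma_weights Bar chart of weight against rank.
#' @param object A `dr_weights` object.
#' @export
autoplot.dr_weights <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$rank, .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "similarity rank", y = "weight",
      title = sprintf("Gamma rank weights (k = %g, θ = %g, α = %g)",
                      attr(object, "shape"), attr(object, "scale"),
                      attr(object, "alpha"))
    )
}
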