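# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the RMSD oracle minimizes over an explicit grid of
# Euler-angle rotations, and the weight oracle evaluates the discretized gamma
# mass formula directly.

# Brute-force minimal RMSD: centroid alignment plus a ZYZ Euler-angle grid
# search, swept coarsely over all of SO(3) and refined down to 0.05-degree
# steps around the best cell. Only proper rotations are enumerated.
grid_rmsd <- function(A, B) {
  A <- unname(as.matrix(A)); B <- unname(as.matrix(B))
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  M <- crossprod(Bc, Ac)   # RMSD^2 = (|Ac|^2 + |Bc|^2 - 2 tr(R M)) / n
  sa <- sum(Ac^2); sb <- sum(Bc^2); n <- nrow(A)

  trace_for <- function(a, b, g) {
    ca <- cos(a); sa_ <- sin(a); cb <- cos(b); sb_ <- sin(b)
    cg <- cos(g); sg <- sin(g)
    # R = Rz(a) %*% Ry(b) %*% Rz(g), elementwise
    r11 <- ca * cb * cg - sa_ * sg; r12 <- -ca * cb * sg - sa_ * cg; r13 <- ca * sb_
    r21 <- sa_ * cb * cg + ca * sg; r22 <- -sa_ * cb * sg + ca * cg; r23 <- sa_ * sb_
    r31 <- -sb_ * cg;               r32 <- sb_ * sg;                 r33 <- cb
    r11 * M[1, 1] + r12 * M[2, 1] + r13 * M[3, 1] +
      r21 * M[1, 2] + r22 * M[2, 2] + r23 * M[3, 2] +
      r31 * M[1, 3] + r32 * M[2, 3] + r33 * M[3, 3]
  }
  search <- function(ctr, half, step) {
    g <- expand.grid(
      a = ctr[1] + seq(-half[1], half[1], by = step),
      b = ctr[2] + seq(-half[2], half[2], by = step),
      g = ctr[3] + seq(-half[3], half[3], by = step)
    )
    tr <- trace_for(g$a, g$b, g$g)
    best <- which.max(tr)
    list(ctr = c(g$a[best], g$b[best], g$g[best]), tr = tr[best])
  }
  deg <- pi / 180
  s1 <- search(c(pi, pi / 2, pi), c(pi, pi / 2, pi), 6 * deg)
  s2 <- search(s1$ctr, rep(6 * deg, 3), 1 * deg)
  s3 <- search(s2$ctr, rep(1 * deg, 3), 0.05 * deg)
  sqrt(max(0, sa + sb - 2 * s3$tr) / n)
}

# Random proper rotation (QR of a Gaussian matrix, determinant forced to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Direct evaluation of the discretized-gamma weight formula.
direct_gamma_weights <- function(m, k, theta, alpha) {
  i <- seq_len(m)
  G <- (1 / (theta^k * gamma(k))) * i^(k - 1) * exp(-i / theta)
  G^alpha / sum(G^alpha)
}

# Random non-degenerate point cloud for superposition tests.
random_points <- function(n, scale = 3) {
  repeat {
    P <- matrix(rnorm(3 * n, sd = scale), ncol = 3)
    s <- svd(sweep(P, 2, colMeans(P)))$d
    if (s[2] > 0.3) return(P)
  }
}

# Indicator profile set: every pocket scores `hit` for residue `res`, 0 else.
indicator_profiles <- function(res = "A", hit = 1) {
  prof <- stats::setNames(rep(0, 20), drpocket_alphabet())
  prof[res] <- hit
  out <- stats::setNames(rep(list(prof), 5), c("1", "4", "6", "7", "9"))
  structure(out, class = "dr_profile_set")
}

# Tiny registry with fixed distinct profiles for synthesis tests.
toy_registry <- function(pocket = 4, m = 3, seed = 11) {
  withr::with_seed(seed, {
    ps <- replicate(m, paste(sample(drpocket_alphabet(), 6, TRUE), collapse = ""))
    while (anyDuplicated(ps)) {
      ps[duplicated(ps)] <- replicate(sum(duplicated(ps)),
        paste(sample(drpocket_alphabet(), 6, TRUE), collapse = ""))
    }
    scores <- matrix(round(runif(m * 20, -2, 2), 3), nrow = m,
                     dimnames = list(NULL, drpocket_alphabet()))
    dplyr::bind_cols(
      tibble::tibble(allele = sprintf("TOY-%02d", seq_len(m)),
                     pocket = as.integer(pocket), pseudoseq = ps),
      tibble::as_tibble(scores)
    )
  })
}

# Hand-built dr_similarity with prescribed combined values (registry order).
manual_simvec <- function(registry, combined, mode = "K1") {
  out <- tibble::tibble(
    entry = seq_len(nrow(registry)),
    allele = registry$allele,
    kseq = combined, rmsd = NA_real_, kspa = NA_real_,
    combined = combined, sequence_only = TRUE
  )
  structure(out,
    class = c("dr_similarity", class(out)),
    pocket = registry$pocket[1], mode = mode, ordering = "raw",
    seq_bandwidth = 1, spa_bandwidth = 1
  )
}
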