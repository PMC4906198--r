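test_that("synthesis is the rank-weighted convex combination of raw profiles", {
  reg <- toy_registry(m = 3)
  profs <- as.matrix(reg[, drpocket_alphabet()])
  # similarity order: entry 3 > entry 1 > entry 2
  sv <- manual_simvec(reg, combined = c(0.6, 0.1, 0.9))
  w <- gamma_weights(3, 1, 1, 1)
  got <- synthesize_profile(sv, reg, w)
  wo <- direct_gamma_weights(3, 1, 1, 1)
  want <- wo[1] * profs[3, ] + wo[2] * profs[1, ] + wo[3] * profs[2, ]
  expect_equal(as.numeric(got), unname(want), tolerance = 1e-12)
  expect_equal(attr(got, "provenance")$entry, c(3L, 1L, 2L))
  # convexity: scores stay within raw per-residue bounds
  expect_true(all(as.numeric(got) <= apply(profs, 2, max) + 1e-12))
  expect_true(all(as.numeric(got) >= apply(profs, 2, min) - 1e-12))
})

test_that("degenerate weights and identical profiles behave as fixed points", {
  reg <- toy_registry(m = 2)
  sv <- manual_simvec(reg, c(0.2, 0.8))
  got <- synthesize_profile(sv, reg, c(1, 0))
  expect_equal(as.numeric(got),
               unname(as.numeric(reg[2, drpocket_alphabet()])))
  # all profiles identical: any weights return that profile
  reg_same <- reg
  reg_same[2, drpocket_alphabet()] <- reg[1, drpocket_alphabet()]
  got2 <- synthesize_profile(sv, reg_same, c(0.37, 0.63))
  expect_equal(as.numeric(got2),
               unname(as.numeric(reg[1, drpocket_alphabet()])))
  expect_error(synthesize_profile(sv, reg, c(1, 0, 0)), "length")
  expect_error(synthesize_profile(sv, reg, c(0.7, 0.7)), "sum to 1")
})

test_that("weights attach to ranks: monotone transforms change nothing", {
  reg <- toy_registry(m = 5, seed = 23)
  w <- gamma_weights(5, 1, 1, 3)
  sims <- c(0.31, 0.92, 0.44, 0.08, 0.77)
  base <- synthesize_profile(manual_simvec(reg, sims), reg, w)
  for (f in list(function(x) 2 * x, function(x) x^3, function(x) exp(x) / 10)) {
    tr <- synthesize_profile(manual_simvec(reg, f(sims)), reg, w)
    expect_equal(as.numeric(tr), as.numeric(base), tolerance = 1e-12)
  }
})

test_that("K2 and K3 always synthesize identical profiles", {
  spec <- fixture_spec(seed = 31, m = 6, n = 6, coordinate_noise = 0.3)
  reg <- generate_registry(spec)
  p1 <- random_profile_set(spec$seed)[["1"]]
  q <- list()
  for (p in c(4, 6, 7, 9)) {
    reg_p <- reg[reg$pocket == p, ]
    q[[as.character(p)]] <- list(pseudoseq = reg_p$pseudoseq[2],
                                 coords = attr(reg, "template"))
  }
  s2 <- synthesize_allele(q, reg, p1, mode = "K2", alpha = 2)
  s3 <- synthesize_allele(q, reg, p1, mode = "K3", alpha = 2)
  for (p in c("4", "6", "7", "9")) {
    expect_equal(as.numeric(s2[[p]]), as.numeric(s3[[p]]), tolerance = 1e-12)
  }
})

test_that("an exact registry match dominates at large alpha", {
  spec <- fixture_spec(seed = 41, m = 5, n = 6, coordinate_noise = 0.5)
  reg <- generate_registry(spec)
  p1 <- random_profile_set(spec$seed)[["1"]]
  j <- 4L
  q <- list()
  for (p in c(4, 6, 7, 9)) {
    reg_p <- reg[reg$pocket == p, ]
    q[[as.character(p)]] <- list(pseudoseq = reg_p$pseudoseq[j],
                                 coords = reg_p$coords[[j]])
  }
  out <- synthesize_allele(q, reg, p1, mode = "K1", alpha = 20)
  for (p in c(4, 6, 7, 9)) {
    reg_p <- reg[reg$pocket == p, ]
    expect_equal(as.numeric(out[[as.character(p)]]),
                 unname(as.numeric(reg_p[j, drpocket_alphabet()])),
                 tolerance = 1e-3)
  }
})

test_that("tiny alpha with scale m approaches the plain profile average", {
  reg <- toy_registry(m = 4, seed = 29)
  sv <- manual_simvec(reg, c(0.9, 0.1, 0.5, 0.3))
  w <- gamma_weights(4, shape = 1, scale = 4, alpha = 1e-6)
  got <- synthesize_profile(sv, reg, w)
  avg <- colMeans(as.matrix(reg[, drpocket_alphabet()]))
  expect_equal(as.numeric(got), unname(avg), tolerance = 1e-4)
})

test_that("identical queries yield identical profiles; pocket 1 is required", {
  spec <- fixture_spec(seed = 51)
  reg <- generate_registry(spec)
  p1 <- random_profile_set(1)[["1"]]
  q <- list()
  for (p in c(4, 6, 7, 9)) {
    reg_p <- reg[reg$pocket == p, ]
    q[[as.character(p)]] <- list(pseudoseq = reg_p$pseudoseq[1], coords = NULL)
  }
  a <- synthesize_allele(q, reg, p1)
  b <- synthesize_allele(q, reg, p1)
  for (p in names(a)) expect_equal(as.numeric(a[[p]]), as.numeric(b[[p]]))
  expect_equal(as.numeric(a[["1"]]), unname(p1))
  expect_error(synthesize_allele(q, reg, NULL), "pocket-1")
  expect_error(synthesize_allele(q[c("4", "6", "7")], reg, p1), "pocket 9")
})

test_that("registry TSV round-trips and is validated", {
  reg <- toy_registry(m = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_registry(reg, path)
  back <- read_profile_registry(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(reg))
  dup <- dplyr::bind_rows(reg, reg[1, ])
  expect_error(validate_registry(dup), "duplicated")
  short <- reg; short$pseudoseq[2] <- "AC"
  expect_error(validate_registry(short), "length")
  expect_error(validate_registry(reg[, -4]), "missing column")
})
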