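test_that("window scores sum anchor contributions with the X rule", {
  profs <- indicator_profiles("A", hit = 1)
  expect_equal(score_window("AAAAAAAAA", profs), 5)
  # position 2 is not an anchor, so replacing it changes nothing
  expect_equal(score_window("AXAAAAAAA", profs), 5)
  # X at anchor 1 contributes zero
  expect_equal(score_window("XAAAAAAAA", profs), 4)
  # pocket 1 can be excluded from scoring
  expect_equal(score_window("AAAAAAAAA", profs, include_pocket1 = FALSE), 4)
  expect_error(score_window("AAAA", profs), "9 residues")
  expect_error(score_window("AAAAAAAAA", profs[c("1", "4")]), "pocket")
})

test_that("core prediction scans every window and breaks ties leftward", {
  profs <- indicator_profiles("A")
  # single window: the peptide itself regardless of profiles
  p9 <- predict_core("WMNQRSTVC", profs)
  expect_equal(p9$core, "WMNQRSTVC")
  expect_equal(p9$offset, 0L)
  # 13-mer gives exactly 5 windows
  p13 <- predict_core("PKYVKQNTLKLAT", profs)
  expect_length(p13$window_scores, 5)
  expect_equal(tidy(p13)$offset, 0:4)
  # uniform scores tie: leftmost window wins
  flat <- predict_core(strrep("C", 12), profs)
  expect_equal(flat$offset, 0L)
  expect_error(predict_core("SHORT", profs), "at least 9")
  g <- glance(p13)
  expect_equal(g$n_windows, 5)
})

test_that("planted cores are recovered by exhaustive window scoring", {
  withr::with_seed(61, {
    for (i in 1:10) {
      profs <- random_profile_set(seed = 6000 + i)
      spec <- fixture_spec(seed = 6000 + i, peptide_length = 18)
      planted <- plant_core_peptide(profs, spec)
      pred <- predict_core(planted$peptide, profs)
      expect_identical(pred$offset, planted$offset)
      # oracle: exhaustive scoring inside the test
      scores <- vapply(seq_len(nchar(planted$peptide) - 8), function(s) {
        score_window(substr(planted$peptide, s, s + 8), profs)
      }, numeric(1))
      expect_equal(pred$window_scores, scores)
      expect_equal(which.max(scores) - 1L, planted$offset)
      expect_gte(planted$gap, spec$profile_contrast)
    }
  })
})

test_that("evaluation counts exact-string mismatches and survives bad alleles", {
  spec <- fixture_spec(seed = 71)
  bench <- generate_benchmark(spec, n_records = 6)
  # perfect oracle predictor: annotated cores come back, zero errors
  ev <- evaluate_cores(bench$records, bench$profile_sets)
  expect_s3_class(ev, "core_evaluation")
  expect_equal(attr(ev, "total_errors"), 0L)
  expect_true(all(ev$correct))
  expect_equal(glance(ev)$accuracy, 1)

  # corrupt one annotation: exactly that record flags as the single error
  records2 <- bench$records
  records2$core[3] <- strrep("W", 9)
  ev2 <- evaluate_cores(records2, bench$profile_sets)
  expect_equal(attr(ev2, "total_errors"), 1L)
  expect_equal(ev2$pdb_id[!ev2$correct], records2$pdb_id[3])

  # a predictor that always returns the first window errs everywhere the
  # annotated core is not at offset 0
  first_window <- function(allele) indicator_profiles("A", hit = 0)
  off0 <- vapply(seq_len(nrow(bench$records)), function(i) {
    startsWith(bench$records$peptide[i], bench$records$core[i])
  }, logical(1))
  ev3 <- evaluate_cores(bench$records, first_window)
  expect_equal(attr(ev3, "total_errors"), sum(!off0))

  # unresolvable alleles become per-record notes, not crashes
  sets <- bench$profile_sets
  sets[[bench$records$allele[2]]] <- NULL
  ev4 <- evaluate_cores(bench$records, sets)
  expect_equal(attr(ev4, "total_errors"), 1L)
  expect_false(is.na(ev4$note[2]))
  expect_true(is.na(ev4$predicted[2]))
})

test_that("evaluation totals are permutation-equivariant", {
  spec <- fixture_spec(seed = 81)
  bench <- generate_benchmark(spec, n_records = 5)
  records2 <- bench$records
  records2$core[c(1, 4)] <- strrep("W", 9)
  base <- evaluate_cores(records2, bench$profile_sets)
  withr::with_seed(9, perm <- sample(nrow(records2)))
  shuf <- evaluate_cores(records2[perm, ], bench$profile_sets)
  expect_equal(attr(shuf, "total_errors"), attr(base, "total_errors"))
  expect_equal(shuf$pdb_id, records2$pdb_id[perm])
})

test_that("alpha sweeps tabulate every cell and obey rank equivalence", {
  spec <- fixture_spec(seed = 91, m = 4, n = 5)
  bench <- generate_benchmark(spec, n_records = 4)
  sw <- alpha_sweep(bench$records, bench$registry, bench$queries,
                    bench$pocket1_profile, modes = c("K2", "K3"),
                    alphas = c(1, 3, 20))
  expect_equal(nrow(sw), 6)
  wide <- tidyr::pivot_wider(tibble::as_tibble(sw), names_from = "mode",
                             values_from = "errors", id_cols = "alpha")
  expect_equal(wide$K2, wide$K3)
  # degenerate sweep equals a single evaluation
  one <- alpha_sweep(bench$records, bench$registry, bench$queries,
                     bench$pocket1_profile, modes = "K1", alphas = 3)
  sets <- purrr::map(bench$queries, synthesize_allele, registry = bench$registry,
                     pocket1_profile = bench$pocket1_profile, mode = "K1",
                     alpha = 3)
  ev <- evaluate_cores(bench$records, sets)
  expect_equal(one$errors, attr(ev, "total_errors"))
  expect_error(alpha_sweep(bench$records, bench$registry, bench$queries,
                           bench$pocket1_profile, alphas = numeric(0)),
               "non-empty")
})

test_that("errors do not increase with alpha when rank 1 is the true donor", {
  # queries coincide with registry entries and cores are planted under the
  # registry entry's own raw profile, so concentrating weight on rank 1 can
  # only help
  spec <- fixture_spec(seed = 105, m = 5, n = 6, coordinate_noise = 0.4)
  reg <- generate_registry(spec)
  p1 <- random_profile_set(spec$seed + 7L)[["1"]]
  queries <- list(); records <- list()
  for (r in 1:6) {
    j <- ((r - 1) %% spec$m) + 1
    allele <- sprintf("Q%02d", r)
    q <- list()
    raw <- list("1" = p1)
    for (p in c(4, 6, 7, 9)) {
      reg_p <- reg[reg$pocket == p, ]
      q[[as.character(p)]] <- list(pseudoseq = reg_p$pseudoseq[j],
                                   coords = reg_p$coords[[j]])
      raw[[as.character(p)]] <- stats::setNames(
        as.numeric(reg_p[j, drpocket_alphabet()]), drpocket_alphabet())
    }
    queries[[allele]] <- q
    rs <- spec; rs$seed <- spec$seed + 13L * r
    planted <- plant_core_peptide(raw, rs)
    records[[r]] <- tibble::tibble(pdb_id = sprintf("S%03d", r), allele = allele,
                                   peptide = planted$peptide, core = planted$core)
  }
  sw <- alpha_sweep(dplyr::bind_rows(records), reg, queries, p1,
                    modes = "K1", alphas = c(1, 3, 20))
  expect_true(all(diff(sw$errors) <= 0))
})
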