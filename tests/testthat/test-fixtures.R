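test_that("generation is seed-deterministic", {
  spec <- fixture_spec(seed = 7)
  r1 <- generate_registry(spec)
  r2 <- generate_registry(spec)
  expect_identical(r1, r2)
  b1 <- generate_benchmark(spec, n_records = 3)
  b2 <- generate_benchmark(spec, n_records = 3)
  expect_identical(b1$records, b2$records)
  expect_identical(b1$pocket1_profile, b2$pocket1_profile)
  # a different seed changes the draw
  expect_false(identical(r1$pseudoseq,
                         generate_registry(fixture_spec(seed = 8))$pseudoseq))
})

test_that("registry construction honors its own spec", {
  spec <- fixture_spec(seed = 3, m = 7, n = 5, coordinate_noise = 0.25)
  reg <- generate_registry(spec)
  expect_equal(nrow(reg), 7 * 4)
  expect_true(all(nchar(reg$pseudoseq) == 5))
  for (p in unique(reg$pocket)) {
    expect_equal(anyDuplicated(reg$pseudoseq[reg$pocket == p]), 0L)
  }
  expect_true(all(purrr::map_lgl(reg$coords, \(m) all(dim(m) == c(5, 3)))))
  # zero coordinate noise: all structures identical to the template
  reg0 <- generate_registry(fixture_spec(seed = 3, coordinate_noise = 0))
  rmsds <- purrr::map_dbl(reg0$coords, superpose_rmsd,
                          b = attr(reg0, "template"))
  expect_true(all(rmsds < 1e-9))
  # impossible uniqueness requests fail
  expect_error(generate_registry(fixture_spec(m = 500, n = 1)), "distinct")
})

test_that("fixture specs validate their fields", {
  expect_error(fixture_spec(m = 0), "m")
  expect_error(fixture_spec(peptide_length = 8), "peptide_length")
  expect_error(fixture_spec(profile_contrast = 0), "profile_contrast")
  expect_error(fixture_spec(coordinate_noise = -1), "coordinate_noise")
})

test_that("planted peptides carry their guarantee and reject impossible asks", {
  profs <- random_profile_set(seed = 77)
  spec <- fixture_spec(seed = 77, peptide_length = 9)
  # single window: trivially recovered
  planted <- plant_core_peptide(profs, spec)
  expect_equal(planted$offset, 0L)
  expect_equal(planted$core, planted$peptide)
  # fixed offsets are honored
  spec15 <- fixture_spec(seed = 77, peptide_length = 15)
  p2 <- plant_core_peptide(profs, spec15, offset = 4)
  expect_equal(p2$offset, 4L)
  expect_equal(substr(p2$peptide, 5, 13), p2$core)
  # a zero contrast is rejected at spec construction
  expect_error(fixture_spec(profile_contrast = 0), "contrast")
  # absurd contrast demands error instead of silently weak fixtures
  flat <- indicator_profiles("A", hit = 0)
  spec_hi <- fixture_spec(seed = 1, peptide_length = 15, profile_contrast = 100)
  expect_error(plant_core_peptide(flat, spec_hi), "unachievable")
})

test_that("bundled complex benchmark obeys its documented contracts", {
  cx <- load_complexes()
  expect_equal(names(cx), c("pdb_id", "allele", "peptide", "core", "split"))
  expect_true(all(nchar(cx$core) == 9))
  expect_true(all(stringr::str_detect(cx$peptide, stringr::fixed(cx$core))))
  expect_true(all(nchar(cx$peptide) >= 9))
  expect_equal(nrow(load_complexes("test30")) + nrow(load_complexes("heldout9")),
               nrow(cx))
  # every reference prediction points at a benchmark complex
  rp <- load_reference_predictions()
  expect_true(all(rp$pdb_id %in% cx$pdb_id))
  expect_true(all(nchar(rp$predicted_core) == 9))
  # predicted cores are windows of their peptides
  joined <- dplyr::inner_join(rp, cx[, c("pdb_id", "peptide")], by = "pdb_id")
  expect_true(all(stringr::str_detect(joined$peptide,
                                      stringr::fixed(joined$predicted_core))))
  tables <- load_benchmark_tables()
  expect_named(tables, c("complexes", "pockets", "complex_pockets",
                         "reference_predictions", "reference_alleles"))
})

test_that("observed pocket positions stay within the canonical pocket sets", {
  cp <- load_complex_pockets()
  defs <- pocket_definitions()
  joined <- dplyr::left_join(cp, defs, by = "pocket")
  inside <- purrr::map2_lgl(joined$position, joined$positions, `%in%`)
  # observational cells occasionally record extra contacts; the overwhelming
  # majority must match the canonical definitions
  expect_gt(mean(inside), 0.95)
})
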