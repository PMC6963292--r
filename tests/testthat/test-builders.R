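test_that("toy designs enumerate the expected free parameters", {
  toy <- study_design(2, 2, 1, 3)
  # 2 loadings + 4 thresholds + 2 variances + 1 covariance
  expect_length(spec_free_labels(ability_cfa(toy, "configural")), 9)
  expect_error(ability_cfa(toy, "nonsense"), class = "latsem_spec_error")
  expect_error(sta_cfa(toy, "configural"), class = "latsem_design_error")
})

test_that("invariance levels form a strict nesting chain", {
  d <- study_design(4, 3, 3, 5)
  ab <- lapply(c("configural", "weak", "strong"), ability_cfa, design = d)
  expect_true(latsem:::nesting_positions_ok(ab[[1]], ab[[2]]))
  expect_lt(count_df(ab[[1]]), count_df(ab[[2]]))
  expect_lt(count_df(ab[[2]]), count_df(ab[[3]]))
  st <- lapply(c("configural", "weak"), sta_cfa, design = d)
  expect_true(latsem:::nesting_positions_ok(st[[1]], st[[2]]))
  full <- full_interference_model(d)
  r <- restrict_interference(full, 4)
  expect_true(latsem:::nesting_positions_ok(full, r))
})

test_that("the 3-wave full interference model has the documented structure", {
  d <- study_design(3, 4, 2, 5)
  spec <- full_interference_model(d)
  expect_setequal(spec$latents,
                  c("eta1", "d2", "d3", "eta2", "eta3",
                    "xi1", "xi2", "xi3", "ze1", "ze2"))
  # every equation symbol is representable: difference means, state
  # correlations, interference loadings, deficit correlation
  labs <- spec_free_labels(spec)
  expect_true(all(c("m.d2", "m.d3", "c.d2.eta1", "c.xi1.eta1",
                    "b1.w1", "b4.w3", "c.xi2.xi1") %in% labs))
  # all unit variances under the default identification
  expect_equal(diag(spec$psi_fixed), rep(1, spec$n_exo))
  # interference = none equals the union of the CFAs plus cross correlations
  none <- full_interference_model(d, interference = "none",
                                  anxiety_ability_corr = "wave1")
  expect_equal(sum(grepl("^b", spec_free_labels(none))), 0)
  expect_setequal(setdiff(spec_free_labels(spec), spec_free_labels(none)),
                  grep("^b", spec_free_labels(spec), value = TRUE))
})

test_that("identification rules reject rotationally indeterminate models", {
  d <- study_design(3, 4, 2, 5)
  expect_error(lat_model(d, ability_invariance = "configural",
                         interference = "free"),
               class = "latsem_identification_error")
  # the conservative equal-within-wave strategy is accepted on a
  # configural base
  spec <- lat_model(d, ability_invariance = "configural",
                    interference = "equal-within-wave")
  expect_true(all(paste0("b.w", 1:3) %in% spec_free_labels(spec)))
  # the full model refuses anything below strong ability invariance
  expect_error(full_interference_model(d, ability_invariance = "weak"),
               class = "latsem_spec_error")
  expect_error(ability_cfa(d, "weak", neighbor_change = TRUE),
               class = "latsem_spec_error")
})

test_that("restrict_interference zeroes waves, warns on no-ops, idempotent", {
  d <- study_design(3, 4, 2, 5)
  full <- full_interference_model(d)
  r3 <- restrict_interference(full, 3)
  expect_equal(count_df(r3) - count_df(full), 4)
  expect_warning(restrict_interference(r3, 3), class = "latsem_noop")
  r3b <- suppressWarnings(restrict_interference(r3, 3))
  expect_identical(r3b$lambda_fixed, r3$lambda_fixed)
  expect_identical(spec_free_labels(r3b), spec_free_labels(r3))
  rall <- restrict_interference(full, 1:3)
  expect_equal(count_df(rall) - count_df(full), 12)
  expect_null(rall$meta$interference_table)
})

test_that("strong CFA and its neighbor-change form are df-identical", {
  for (d in list(study_design(3, 3, 0), study_design(7, 13, 0))) {
    expect_equal(count_df(ability_cfa(d, "strong")),
                 count_df(ability_cfa(d, "strong", neighbor_change = TRUE)))
  }
})

test_that("specs round-trip through the YAML config format", {
  d <- study_design(3, 3, 2, 4)
  for (spec in list(ability_cfa(d, "weak"), sta_cfa(d, "weak"),
                    full_interference_model(d))) {
    path <- tempfile(fileext = ".yaml")
    write_spec(spec, path)
    back <- read_spec(path)
    expect_identical(back$manifest, spec$manifest)
    expect_identical(spec_free_labels(back), spec_free_labels(spec))
    expect_equal(count_df(back), count_df(spec))
    labs <- spec_free_labels(spec)
    th <- setNames(seq(0.1, 0.3, length.out = length(labs)), labs)
    expect_equal(implied_moments(back, th)$moments,
                 implied_moments(spec, th)$moments, tolerance = 1e-12)
  }
})
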