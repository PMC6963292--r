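test_that("invariance ladders fit, compare, and report in order", {
  # 3 anxiety items so that even the configural rung has positive df
  d <- study_design(3, 3, 3, 5)
  Ra <- diag(1, 3); Ra[1, 2:3] <- Ra[2:3, 1] <- -0.3
  Rx <- matrix(0.8, 3, 3); diag(Rx) <- 1
  sc <- sim_scenario(d, n = 400,
                     ability_loadings = c(0.65, 0.55, 0.45),
                     ability_thresholds = c(-0.5, 0, 0.5),
                     delta_means = c(0.5, 0.2),
                     ability_side_corr = Ra,
                     anxiety_loadings = c(0.8, 0.75, 0.7),
                     anxiety_thresholds = rbind(qnorm(c(.2, .4, .6, .8)),
                                                qnorm(c(.25, .45, .65, .85)),
                                                qnorm(c(.15, .4, .62, .8))),
                     anxiety_corr = Rx,
                     zeta_variances = c(0.09, 0.09, 0.09),
                     cross_corr = matrix(0, 3, 3),
                     interference = matrix(0, 3, 3),
                     seed = 31)
  dat <- generate(sc)
  lad <- invariance_ladder(dat, "ability")
  expect_equal(lad$table$model, c("configural", "weak", "strong"))
  # weak adds (J-1)(T-1) loading constraints, strong nets thresholds-means
  expect_equal(lad$table$delta_df[2], 2 * 2)
  expect_true(all(diff(lad$table$df) > 0))
  expect_true(all(is.finite(lad$table$cfi)))
  # generating model is weak+strong invariant: no substantial CFI decline
  expect_true(all(!lad$substantial_decline[-1]))

  anx <- invariance_ladder(dat, "anxiety")
  expect_equal(anx$table$model, c("configural", "weak"))
  expect_equal(anx$table$delta_df[2], (3 - 1) * (3 - 1))
  expect_true(all(is.finite(anx$table$rmsea)))
})

test_that("interference reduction produces the full nested sequence", {
  sc <- small_mixed_scenario(n = 500, seed = 41)
  dat <- generate(sc)
  red <- interference_reduction(dat)
  expect_equal(nrow(red$table), 4)          # waves + 1 rows
  expect_equal(red$table$model, c("1 to 3", "1 to 2", "1", "none"))
  expect_equal(red$table$delta_df[-1], rep(4, 3))
  expect_true(all(diff(red$table$df) == 4))
  # interference is simulated at wave 1 (strongly) - the last step should
  # reveal it while the early steps stay quiet
  expect_true(is.na(red$last_interference_wave) ||
                red$last_interference_wave <= 3)
})

test_that("retest effects satisfy the difference-variable identities", {
  sc <- tiny_ability_scenario(n = 500, seed = 51)
  dat <- generate(sc)
  mom <- estimate_moments(dat, variables = colnames(dat$ability))
  f <- fit_quiet(ability_cfa(study_design(3, 3, 0), "strong",
                             identification = "unit",
                             neighbor_change = TRUE), moments = mom)
  re <- retest_effects(f)
  # d equals the implied mean difference of successive states exactly
  expect_equal(re$effects$d, re$implied_mean_diff, tolerance = 1e-12)
  # telescoping: sum of effects equals the last state's implied mean
  eta3_mean <- f$implied$latent_mean[match("eta3", f$spec$latents)]
  expect_equal(sum(re$effects$d), eta3_mean, tolerance = 1e-12)
  # unit-variance identification: d is the raw mean estimate
  expect_equal(re$effects$d, unname(f$estimates[c("m.d2", "m.d3")]),
               tolerance = 1e-12)
  expect_equal(nrow(re$successive_diffs), 1)
  # a fit without difference variables is refused
  f2 <- fit_quiet(ability_cfa(study_design(3, 3, 0), "weak"), moments = mom)
  expect_error(retest_effects(f2), class = "latsem_spec_error")
})

test_that("retest effects are substantively stable across nested builds", {
  sc <- small_mixed_scenario(n = 800, seed = 61)
  dat <- generate(sc)
  mom <- estimate_moments(dat)
  d <- study_design(3, 4, 2, 5)
  full <- full_interference_model(d)
  f_full <- fit_quiet(full, moments = mom, options = list(ss = FALSE))
  f_r <- fit_quiet(restrict_interference(full, 2:3), moments = mom,
                   options = list(ss = FALSE))
  d1 <- retest_effects(f_full)$effects$d
  d2 <- retest_effects(f_r)$effects$d
  expect_lt(max(abs(d1 - d2)), 0.05)
})

test_that("interference reports have the documented shape", {
  sc <- small_mixed_scenario(n = 600, seed = 71)
  dat <- generate(sc)
  mom <- estimate_moments(dat)
  d <- study_design(3, 4, 2, 5)
  f <- fit_quiet(full_interference_model(d), moments = mom,
                 options = list(ss = FALSE))
  rep_ <- interference_report(f)
  expect_equal(nrow(rep_$interference), 12)   # item x wave
  expect_equal(nrow(rep_$deficit), 3)
  expect_equal(nrow(rep_$thresholds), 4)
  expect_true(all(abs(rep_$deficit$r) <= 1))
  # interference = none: only deficit columns remain
  f0 <- fit_quiet(full_interference_model(d, interference = "none"),
                  moments = mom, options = list(ss = FALSE))
  rep0 <- interference_report(f0)
  expect_null(rep0$interference)
  expect_equal(nrow(rep0$deficit), 3)
})
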