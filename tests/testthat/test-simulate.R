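test_that("generation is deterministic and seed-sensitive", {
  sc <- small_mixed_scenario(n = 100, seed = 5)
  d1 <- generate(sc)
  d2 <- generate(sc)
  expect_identical(d1$ability, d2$ability)
  expect_identical(d1$anxiety, d2$anxiety)
  d3 <- generate(sc, seed = 6)
  expect_false(identical(d1$ability, d3$ability))
})

test_that("marginal success probabilities follow the threshold model", {
  # beta = 0, no cross-correlation, thresholds 0: success proportion 1/2
  d <- study_design(2, 3, 0)
  sc <- sim_scenario(d, n = 10000,
                     ability_loadings = c(0.6, 0.5, 0.4),
                     ability_thresholds = c(0, 0, 0),
                     delta_means = 0,
                     ability_side_corr = matrix(c(1, -0.2, -0.2, 1), 2),
                     anxiety_loadings = numeric(0),
                     anxiety_thresholds = matrix(0, 0, 6),
                     anxiety_corr = diag(1, 2),
                     zeta_variances = numeric(0),
                     cross_corr = matrix(0, 2, 2),
                     interference = matrix(0, 3, 2),
                     seed = 9)
  dat <- generate(sc)
  p_hat <- colMeans(dat$ability)
  se <- sqrt(0.25 / 10000)
  expect_true(all(abs(p_hat - 0.5) < 3 * se))
  # zero difference means: wave sum-score means equal within noise
  ws <- rowSums(dat$ability[, 1:3])
  ws2 <- rowSums(dat$ability[, 4:6])
  expect_lt(abs(mean(ws) - mean(ws2)), 3 * sd(ws - ws2) / sqrt(10000))
})

test_that("marginal success probability matches Phi(-tau) under no bias", {
  sc <- tiny_ability_scenario(n = 20000, seed = 13)
  dat <- generate(sc)
  # wave 1: latent mean 0, so P(success) = Phi(-tau_j)
  for (j in 1:3) {
    expect_equal(mean(dat$ability[, j]),
                 pnorm(-sc$ability_thresholds[j]),
                 tolerance = 0.02)
  }
})

test_that("scenario invariants reject impossible configurations", {
  sc <- study_like_scenario()
  expect_s3_class(sc, "latsem_scenario")
  v <- latsem:::scenario_internals(sc)
  expect_true(all(v$resid_a > 0))
  expect_true(all(eigen(v$R, only.values = TRUE)$values > 0))
  # oversized loadings make a unit-variance latent response impossible
  expect_error(
    sim_scenario(study_design(2, 2, 0), n = 10,
                 ability_loadings = c(0.9, 0.9),
                 ability_thresholds = c(0, 0),
                 delta_means = 0.2,
                 ability_side_corr = diag(1, 2),
                 anxiety_loadings = numeric(0),
                 anxiety_thresholds = matrix(0, 0, 6),
                 anxiety_corr = diag(1, 2),
                 zeta_variances = numeric(0),
                 cross_corr = matrix(0, 2, 2),
                 interference = matrix(0, 2, 2), seed = 1),
    class = "latsem_scenario_error")
  # non-monotone Likert thresholds are rejected
  bad_thr <- rbind(c(0.5, 0.2, 0.8, 1.2), qnorm(c(.2, .4, .6, .8)))
  expect_error(
    sim_scenario(study_design(2, 2, 2, 5), n = 10,
                 ability_loadings = c(0.6, 0.5),
                 ability_thresholds = c(0, 0),
                 delta_means = 0.2,
                 ability_side_corr = diag(1, 2),
                 anxiety_loadings = c(0.8, 0.7),
                 anxiety_thresholds = bad_thr,
                 anxiety_corr = diag(1, 2),
                 zeta_variances = c(0.1, 0.1),
                 cross_corr = matrix(0, 2, 2),
                 interference = matrix(0, 2, 2), seed = 1),
    class = "latsem_scenario_error")
})

test_that("the study-like scenario runs the full pipeline end to end", {
  sc <- study_like_scenario(n = 225, seed = 1)
  dat <- generate(sc)
  expect_equal(nrow(dat$ability), 225)
  expect_equal(ncol(dat$ability), 91)
  expect_equal(ncol(dat$anxiety), 35)
  flt <- ceiling_filter(dat)
  # the easy test plus large early gains produce a sizable ceiling group;
  # the filter must leave a clear majority for analysis
  expect_lt(nrow(flt$excluded), 113)
  expect_gt(nrow(flt$data$ability), 112)
  de <- descriptives(flt$data)
  expect_true(all(de$summary$consistency > 0.3, na.rm = TRUE))
  # truth vector covers every free label of the matching model
  spec <- full_interference_model(sc$design)
  expect_true(all(spec_free_labels(spec) %in% names(scenario_truth(sc))))
})
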