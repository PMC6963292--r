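# one-factor ordinal spec built by hand: 3 binary markers with fixed
# loadings, unit latent variance
one_factor_spec <- function(loadings = c(NA, NA, NA),
                            labels = c("l1", "l2", "l3")) {
  lam_f <- matrix(loadings, 3, 1)
  lam_l <- matrix(ifelse(is.na(loadings), labels, NA_character_), 3, 1)
  model_spec(manifest = c("y1", "y2", "y3"), n_cat = rep(2L, 3),
             latents = "f", n_exo = 1L, defn = matrix(1, 1, 1),
             lambda_fixed = lam_f, lambda_label = lam_l,
             psi_fixed = matrix(1, 1, 1),
             psi_label = matrix(NA_character_, 1, 1),
             kappa_fixed = 0, kappa_label = NA_character_,
             tau_fixed = rep(NA_real_, 3),
             tau_label = paste0("t", 1:3))
}

test_that("implied correlations are products of standardized loadings", {
  spec <- one_factor_spec(loadings = c(1, 0.8, 0.5))
  imp <- implied_moments(spec, c(t1 = 0, t2 = 0, t3 = 0))
  # pairs (2,1), (3,1), (3,2) in column-major strict lower order
  expect_equal(unname(imp$moments[4:6]), c(0.8, 0.5, 0.4))
  expect_equal(diag(imp$cov), rep(1, 3), ignore_attr = TRUE)
})

test_that("zero latent-difference means give equal implied wave means", {
  spec <- full_interference_model(study_design(3, 4, 2, 5))
  th <- setNames(rep(0.1, length(spec_free_labels(spec))),
                 spec_free_labels(spec))
  th[spec$meta$delta_mean_labels] <- 0
  imp <- implied_moments(spec, th)
  eta_means <- imp$latent_mean[match(paste0("eta", 1:3), spec$latents)]
  expect_equal(eta_means, rep(0, 3), ignore_attr = TRUE)
})

test_that("neighbor-change expansion matches explicit 3-wave matrix algebra", {
  d <- study_design(3, 2, 0)
  spec <- ability_cfa(d, "strong", identification = "unit",
                      neighbor_change = TRUE)
  labs <- spec_free_labels(spec)
  set.seed(8)
  th <- setNames(runif(length(labs), 0.1, 0.4), labs)
  imp <- implied_moments(spec, th)
  # oracle: explicit covariance of eta_3 = eta1 + d2 + d3
  P <- diag(1, 3)
  P[2, 1] <- P[1, 2] <- th["c.d2.eta1"]
  P[3, 1] <- P[1, 3] <- th["c.d3.eta1"]
  P[3, 2] <- P[2, 3] <- th["c.d3.d2"]
  a2 <- c(1, 1, 0); a3 <- c(1, 1, 1)
  lam <- c(th["la1"], th["la2"])
  # covariance of wave-3 items with wave-2 items
  expect_equal(imp$cov[5, 3], unname(lam[1] * lam[1] * (a3 %*% P %*% a2)[1]),
               tolerance = 1e-12)
  expect_equal(imp$cov[6, 4], unname(lam[2] * lam[2] * (a3 %*% P %*% a2)[1]),
               tolerance = 1e-12)
  # implied mean of eta3 telescopes the difference means
  expect_equal(imp$latent_mean[match("eta3", spec$latents)],
               unname(th["m.d2"] + th["m.d3"]))
})

test_that("df accounting: saturation, additivity under label fixing", {
  sat <- saturated_spec(paste0("y", 1:4), n_cat = rep(2L, 4))
  expect_equal(count_df(sat), 0)
  satm <- saturated_spec(paste0("y", 1:4), moment_mode = "ml")
  expect_equal(count_df(satm), 0)
  full <- full_interference_model(study_design(4, 3, 2, 4))
  r1 <- restrict_interference(full, 4)
  expect_equal(count_df(r1) - count_df(full), 3)
  r2 <- restrict_interference(full, 3:4)
  expect_equal(count_df(r2) - count_df(full), 6)
})

test_that("analytic Jacobian matches numeric differentiation", {
  spec <- full_interference_model(study_design(3, 3, 2, 4))
  labs <- spec_free_labels(spec)
  for (seed in 1:3) {
    set.seed(seed)
    th <- setNames(runif(length(labs), -0.3, 0.5), labs)
    th[grep("^c\\.", labs)] <- runif(length(grep("^c\\.", labs)), -0.2, 0.2)
    J <- latsem:::spec_jacobian(spec, th, NULL,
                                latsem:::spec_param_map(spec))
    h <- 1e-6
    for (lab in sample(labs, 8)) {
      tp <- th; tp[lab] <- tp[lab] + h
      tm <- th; tm[lab] <- tm[lab] - h
      num <- (implied_moments(spec, tp)$moments -
                implied_moments(spec, tm)$moments) / (2 * h)
      expect_equal(J[, lab], num, tolerance = 1e-5, ignore_attr = TRUE)
    }
  }
})

test_that("saturated fits are exact; estimation is deterministic", {
  sc <- tiny_ability_scenario(n = 300, seed = 4)
  dat <- generate(sc)
  mom <- estimate_moments(dat, variables = colnames(dat$ability))
  sat <- saturated_spec(colnames(dat$ability), n_cat = rep(2L, 9))
  fs <- fit_quiet(sat, moments = mom)
  expect_equal(fs$discrepancy, 0, tolerance = 1e-12)
  expect_equal(fs$T_raw, 0, tolerance = 1e-9)
  expect_equal(fs$df, 0)

  spec <- ability_cfa(study_design(3, 3, 0), "weak")
  f1 <- fit_quiet(spec, moments = mom)
  f2 <- fit_quiet(spec, moments = mom)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$T_scaled, f2$T_scaled)
})

test_that("DWLS recovers one-factor loadings within 3 SE at large n", {
  set.seed(99)
  n <- 20000
  lam <- c(0.7, 0.6, 0.5, 0.4)
  f <- rnorm(n)
  y <- sapply(1:4, function(j)
    as.integer(lam[j] * f + rnorm(n, sd = sqrt(1 - lam[j]^2)) > 0))
  colnames(y) <- paste0("y", 1:4)
  mom <- estimate_moments(y)
  lam_f <- matrix(NA_real_, 4, 1)
  lam_l <- matrix(paste0("l", 1:4), 4, 1)
  spec <- model_spec(manifest = colnames(y), n_cat = rep(2L, 4),
                     latents = "f", n_exo = 1L, defn = matrix(1, 1, 1),
                     lambda_fixed = lam_f, lambda_label = lam_l,
                     psi_fixed = matrix(1, 1, 1),
                     psi_label = matrix(NA_character_, 1, 1),
                     kappa_fixed = 0, kappa_label = NA_character_,
                     tau_fixed = rep(NA_real_, 4),
                     tau_label = paste0("t", 1:4))
  f1 <- fit_quiet(spec, moments = mom)
  expect_true(f1$converged)
  for (j in 1:4)
    expect_lt(abs(f1$estimates[paste0("l", j)] - lam[j]),
              3 * f1$std_errors[paste0("l", j)])
})

test_that("ML mode reproduces closed-form saturated statistics", {
  sc <- small_mixed_scenario(n = 250, seed = 21)
  dat <- generate(sc)
  x <- dat$anxiety
  sat <- saturated_spec(colnames(x), moment_mode = "ml")
  f <- fit_quiet(sat, data = x)
  expect_equal(f$discrepancy, 0, tolerance = 1e-10)
  n <- nrow(x)
  expect_equal(f$implied$mean, colMeans(x), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(f$implied$cov, crossprod(sweep(x, 2, colMeans(x))) / n,
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("standardize follows the latent scale algebra", {
  sc <- tiny_ability_scenario(n = 400, seed = 6)
  dat <- generate(sc)
  mom <- estimate_moments(dat, variables = colnames(dat$ability))
  fm <- fit_quiet(ability_cfa(study_design(3, 3, 0), "configural", "marker"),
                  moments = mom)
  std <- standardize(fm)
  v1 <- fm$estimates["v.eta1"]
  # marker loading (fixed 1) standardizes to sqrt of the latent variance
  expect_equal(unname(std$loadings[1, 1]), unname(sqrt(v1)),
               tolerance = 1e-10)
  expect_equal(unname(std$loadings[2, 1]),
               unname(fm$estimates["la2.w1"] * sqrt(v1)), tolerance = 1e-10)
  expect_equal(diag(std$latent_cor), rep(1, 3), ignore_attr = TRUE)
  # unit-variance identification: standardize is the identity on latents
  fu <- fit_quiet(ability_cfa(study_design(3, 3, 0), "configural", "unit"),
                  moments = mom)
  stdu <- standardize(fu)
  expect_equal(unname(stdu$loadings[2, 1]),
               unname(fu$estimates["la2.w1"]), tolerance = 1e-10)
})
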