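test_that("threshold estimation matches inverse-normal oracles", {
  expect_equal(estimate_thresholds(c(50, 50)), 0)
  expect_equal(estimate_thresholds(c(16, 84)), qnorm(0.16), tolerance = 1e-12)
  expect_equal(estimate_thresholds(c(16, 84)), -0.9944579, tolerance = 1e-6)
  expect_equal(estimate_thresholds(c(25, 50, 25)), qnorm(c(0.25, 0.75)),
               tolerance = 1e-12)
  # empty boundary categories collapse, interior too
  expect_equal(estimate_thresholds(c(0, 30, 0, 70, 0)), qnorm(0.3))
  expect_error(estimate_thresholds(c(0, 10, 0)),
               class = "latsem_degenerate_error")
})

test_that("polychoric matches the independence and clipping contracts", {
  expect_equal(polychoric(matrix(c(25, 25, 25, 25), 2))$rho, 0,
               tolerance = 1e-6)
  pc <- polychoric(matrix(c(50, 0, 0, 50), 2))
  expect_equal(pc$rho, 0.999)
  expect_true(pc$boundary)
  pcn <- polychoric(matrix(c(0, 50, 50, 0), 2))
  expect_equal(pcn$rho, -0.999)
  expect_true(pcn$boundary)
})

test_that("polychoric agrees with the brute-force grid oracle", {
  tables <- list(
    matrix(c(40, 10, 10, 40), 2),
    matrix(c(70, 20, 15, 80), 2),
    matrix(c(10, 35, 55, 25), 2),
    matrix(c(90, 30, 10, 60), 2),
    matrix(c(30, 10, 5, 12, 40, 12, 6, 10, 25), 3),
    matrix(c(50, 20, 5, 18, 30, 14, 4, 15, 45), 3))
  for (tab in tables) {
    expect_lt(abs(polychoric(tab)$rho - oracle_polychoric(tab)), 1.5e-3)
  }
})

test_that("polychoric is symmetric and sign-equivariant", {
  tab <- matrix(c(40, 12, 8, 30, 22, 9, 6, 14, 35), 3)
  r1 <- polychoric(tab)$rho
  expect_equal(polychoric(t(tab))$rho, r1, tolerance = 1e-6)
  # reversing one margin's category order negates the correlation
  expect_equal(polychoric(tab[3:1, ])$rho, -r1, tolerance = 1e-6)
  expect_equal(polychoric(tab[, 3:1])$rho, -r1, tolerance = 1e-6)
})

test_that("bivariate normal CDF is accurate against quadrature", {
  grid <- expand.grid(h = c(-1.5, 0, 0.8), k = c(-0.6, 0.3, 2),
                      r = c(-0.95, -0.5, 0, 0.6, 0.95))
  for (i in seq_len(nrow(grid))) {
    h <- grid$h[i]; k <- grid$k[i]; r <- grid$r[i]
    ref <- integrate(function(x) dnorm(x) *
                       pnorm((k - r * x) / sqrt(1 - r^2)),
                     -Inf, h, rel.tol = 1e-12)$value
    expect_equal(latsem:::cpp_pbvn(h, k, r), ref, tolerance = 1e-10)
  }
})

test_that("estimate_moments stacks the right dimensions and flags errors", {
  sc <- small_mixed_scenario(n = 200, seed = 3)
  dat <- generate(sc)
  mom <- estimate_moments(dat)
  p <- 3 * 4 + 3 * 2
  n_thr <- 3 * 4 * 1 + 3 * 2 * 4   # binary: 1 threshold; 5-point: 4
  expect_length(mom$moments, n_thr + p * (p - 1) / 2)
  expect_equal(dim(mom$scores), c(200, length(mom$moments)))
  expect_true(all(abs(mom$rho[lower.tri(mom$rho)]) <= 0.999))
  # thresholds strictly increasing within each Likert variable
  expect_true(all(vapply(mom$thresholds, function(x)
    length(x) < 2 || all(diff(x) > 0), logical(1))))
  # degenerate variable is named
  bad <- dat
  bad$ability[, 1] <- 1L
  expect_error(estimate_moments(bad), class = "latsem_degenerate_error")
  expect_error(estimate_moments(bad), "w1_a1")
})

test_that("moment sampling theory: nulls, recovery, and acov consistency", {
  # four independent binary variables: all polychorics within 3 SE of zero
  set.seed(42)
  y <- matrix(rbinom(5000 * 4, 1, rep(c(0.3, 0.5, 0.6, 0.7), each = 5000)),
              5000, 4)
  colnames(y) <- paste0("v", 1:4)
  mom <- estimate_moments(y)
  lt <- lower.tri(mom$rho)
  expect_true(all(abs(mom$rho[lt]) <= 3 * mom$se_rho[lt]))

  # latent correlation 0.5 recovered within 3 SE
  set.seed(43)
  n <- 20000
  z <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, .5, .5, 1), 2))
  yb <- cbind(a = as.integer(z[, 1] > 0), b = as.integer(z[, 2] > 0))
  m2 <- estimate_moments(yb)
  expect_lt(abs(m2$rho[2, 1] - 0.5), 3 * m2$se_rho[2, 1])

  # acov: symmetric, diagonal matches per-moment squared SEs
  ac <- moment_acov(m2)
  expect_equal(ac, t(ac))
  expect_equal(sqrt(diag(ac) / m2$n), m2$se, tolerance = 1e-12,
               ignore_attr = TRUE)
  # sandwich SE close to the observed-information SE for the correlation
  expect_equal(m2$se[length(m2$se)], m2$se_rho[2, 1], tolerance = 0.15,
               ignore_attr = TRUE)
})

test_that("moment estimates converge to generator truth as n grows", {
  sc_small <- tiny_ability_scenario(n = 500, seed = 10)
  sc_big <- tiny_ability_scenario(n = 8000, seed = 10)
  spec <- ability_cfa(study_design(3, 3, 0), "strong",
                      identification = "unit", neighbor_change = TRUE)
  tr <- scenario_truth(sc_small)
  err <- sapply(list(sc_small, sc_big), function(sc) {
    dat <- generate(sc)
    mom <- estimate_moments(dat, variables = colnames(dat$ability))
    imp <- implied_moments(spec, tr[spec_free_labels(spec)])
    mean(abs(mom$moments - imp$moments))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.03)
})

test_that("moment sets serialize to readable CSV pairs", {
  sc <- small_mixed_scenario(n = 150, seed = 5)
  mom <- estimate_moments(generate(sc))
  stem <- tempfile()
  write_moments(mom, stem)
  thr <- read.csv(paste0(stem, "_thresholds.csv"))
  cors <- read.csv(paste0(stem, "_correlations.csv"))
  expect_equal(nrow(thr), sum(mom$n_cat - 1))
  expect_equal(nrow(cors), length(mom$variables) * (length(mom$variables) - 1) / 2)
  expect_equal(cors$rho[1], mom$rho[2, 1], tolerance = 1e-12)
})
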