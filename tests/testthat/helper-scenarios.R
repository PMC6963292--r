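# Shared fixture builders: every data set used by the suite is generated in
# code from a scenario with a fixed seed.

# 3 waves x 3 binary items, no anxiety side
tiny_ability_scenario <- function(n = 400, seed = 2) {
  d <- study_design(3, 3, 0)
  Ra <- diag(1, 3); Ra[1, 2:3] <- Ra[2:3, 1] <- -0.3
  sim_scenario(d, n = n,
               ability_loadings = c(0.65, 0.55, 0.45),
               ability_thresholds = c(-0.5, 0, 0.5),
               delta_means = c(0.5, 0.2),
               ability_side_corr = Ra,
               anxiety_loadings = numeric(0),
               anxiety_thresholds = matrix(0, 0, 6),
               anxiety_corr = diag(1, 3),
               zeta_variances = numeric(0),
               cross_corr = matrix(0, 3, 3),
               interference = matrix(0, 3, 3),
               seed = seed)
}

# 3 waves x (4 binary + 2 Likert-5) with decaying interference
small_mixed_scenario <- function(n = 800, seed = 7,
                                 interference = NULL) {
  d <- study_design(3, 4, 2, 5)
  Ra <- diag(1, 3); Ra[1, 2:3] <- Ra[2:3, 1] <- -0.3
  Rx <- matrix(0.8, 3, 3); diag(Rx) <- 1
  if (is.null(interference)) {
    interference <- matrix(0, 4, 3)
    interference[c(1, 3), 1] <- c(-0.3, -0.25)
  }
  cross <- matrix(0, 3, 3); cross[, 1] <- -0.15
  sim_scenario(d, n = n,
               ability_loadings = c(0.6, 0.55, 0.5, 0.45),
               ability_thresholds = c(-0.5, -0.2, 0.1, 0.4),
               delta_means = c(0.5, 0.2),
               ability_side_corr = Ra,
               anxiety_loadings = c(0.8, 0.75),
               anxiety_thresholds = rbind(qnorm(c(.2, .4, .6, .8)),
                                          qnorm(c(.25, .45, .65, .85))),
               anxiety_corr = Rx,
               zeta_variances = c(0.09, 0.09),
               cross_corr = cross,
               interference = interference,
               seed = seed)
}

# 2 waves x 4 binary items, weak invariance true (used for difference-test
# calibration)
two_wave_scenario <- function(n = 500, seed = 1) {
  d <- study_design(2, 4, 0)
  sim_scenario(d, n = n,
               ability_loadings = c(0.7, 0.6, 0.5, 0.4),
               ability_thresholds = c(-0.8, -0.3, 0.2, 0.7),
               delta_means = 0.4,
               ability_side_corr = matrix(c(1, -0.3, -0.3, 1), 2),
               anxiety_loadings = numeric(0),
               anxiety_thresholds = matrix(0, 0, 6),
               anxiety_corr = diag(1, 2),
               zeta_variances = numeric(0),
               cross_corr = matrix(0, 2, 2),
               interference = matrix(0, 4, 2),
               seed = seed)
}

fit_quiet <- function(...) suppressWarnings(fit_sem(...))

# bivariate-normal rectangle probabilities by one-dimensional quadrature --
# independent of the package's own algorithm (oracle for polychoric tests)
oracle_cellprobs <- function(tau1, tau2, rho) {
  a <- c(-Inf, tau1, Inf); b <- c(-Inf, tau2, Inf)
  s <- sqrt(1 - rho^2)
  P <- matrix(0, length(tau1) + 1, length(tau2) + 1)
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    f <- function(x) dnorm(x) * (pnorm((b[j + 1] - rho * x) / s) -
                                   pnorm((b[j] - rho * x) / s))
    P[i, j] <- integrate(f, a[i], a[i + 1], rel.tol = 1e-10)$value
  }
  P
}

# two-stage grid-search oracle for the polychoric correlation
oracle_polychoric <- function(tab) {
  tau1 <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  tau2 <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  ll <- function(r) sum(tab * log(pmax(oracle_cellprobs(tau1, tau2, r),
                                       1e-300)))
  coarse <- seq(-0.99, 0.99, by = 0.01)
  r0 <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(max(-0.999, r0 - 0.02), min(0.999, r0 + 0.02), by = 0.001)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# hand-rolled KR-20 transcription (oracle for descriptives)
oracle_kr20 <- function(items) {
  k <- ncol(items); n <- nrow(items)
  p <- colMeans(items)
  s2 <- var(rowSums(items)) * (n - 1) / n
  (k / (k - 1)) * (1 - sum(p * (1 - p)) / s2)
}
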