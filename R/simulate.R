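# Synthetic-data generator: the generative mirror of the full interference
# model.  Per person a joint latent vector (eta1, deltas, xis, zetas) is
# drawn from a multivariate normal; later ability states are exact
# unit-weight sums (the neighbor-change curve); item latent responses add
# measurement residuals whose variances are derived - never specified - so
# every latent response has unit variance (delta-parameterization
# consistency with the estimator); codes arise by thresholding.

#' Simulation scenario for the full interference model
#'
#' All latent variances are fixed at 1 (matching the estimator's
#' unit-variance identification), so `delta_means` are standardized retest
#' effects, `interference` entries are standardized interference loadings,
#' and all correlation matrices are on the correlation metric.
#'
#' @param design A [study_design()].
#' @param n Number of persons.
#' @param ability_loadings Vector (per ability item) of loadings on the
#'   ability state, constant across waves (strong invariance holds in
#'   truth).
#' @param ability_thresholds Vector (per ability item) of thresholds,
#'   constant across waves.
#' @param delta_means Length `n_waves - 1`: standardized mean latent change
#'   between successive waves (retest effect sizes).
#' @param ability_side_corr Correlation matrix over (eta1, delta_2, ...,
#'   delta_T).
#' @param anxiety_loadings Vector (per anxiety item) of loadings on the
#'   anxiety state.
#' @param anxiety_thresholds Matrix (item x categories-1) of increasing
#'   thresholds.
#' @param anxiety_corr Correlation matrix over the anxiety states.
#' @param zeta_variances Vector (per anxiety item): variance share of the
#'   indicator-specific factor.
#' @param cross_corr Matrix (anxiety states x ability-side latents) of
#'   correlations between the anxiety states and (eta1, deltas).
#' @param interference Matrix (ability item x wave) of interference
#'   loadings.
#' @param seed Integer RNG seed; the scenario plus the seed fully determine
#'   the generated data.
#' @return An object of class `latsem_scenario`.
#' @export
sim_scenario <- function(design, n, ability_loadings, ability_thresholds,
                         delta_means, ability_side_corr, anxiety_loadings,
                         anxiety_thresholds, anxiety_corr, zeta_variances,
                         cross_corr, interference, seed = 1L) {
  stopifnot(inherits(design, "latsem_design"))
  Tn <- design$n_waves; J <- design$n_ability_items
  K <- design$n_anxiety_items; C <- design$anxiety_categories
  anxiety_thresholds <- as.matrix(anxiety_thresholds)
  interference <- as.matrix(interference)
  stopifnot(length(ability_loadings) == J, length(ability_thresholds) == J,
            length(delta_means) == Tn - 1,
            all(dim(ability_side_corr) == Tn),
            length(anxiety_loadings) == K,
            all(dim(anxiety_thresholds) == c(K, C - 1)),
            all(dim(anxiety_corr) == Tn), length(zeta_variances) == K,
            all(dim(cross_corr) == c(Tn, Tn)),
            all(dim(interference) == c(J, Tn)))
  if (any(apply(anxiety_thresholds, 1, function(x) any(diff(x) <= 0))))
    ls_stop("anxiety thresholds must be strictly increasing per item",
            "latsem_scenario_error")
  sc <- structure(list(design = design, n = as.integer(n),
                       ability_loadings = ability_loadings,
                       ability_thresholds = ability_thresholds,
                       delta_means = delta_means,
                       ability_side_corr = ability_side_corr,
                       anxiety_loadings = anxiety_loadings,
                       anxiety_thresholds = anxiety_thresholds,
                       anxiety_corr = anxiety_corr,
                       zeta_variances = zeta_variances,
                       cross_corr = cross_corr,
                       interference = interference,
                       seed = as.integer(seed)),
                  class = "latsem_scenario")
  v <- scenario_internals(sc)   # validates PD + residual positivity
  sc
}

# joint latent correlation matrix, per-wave ability-state variances and
# residual variances; rejects invalid scenarios
scenario_internals <- function(sc) {
  d <- sc$design
  Tn <- d$n_waves; J <- d$n_ability_items; K <- d$n_anxiety_items
  L <- 2 * Tn + K
  R <- diag(1, L)
  ia <- seq_len(Tn)                 # eta1, d2..dT
  ix <- Tn + seq_len(Tn)            # xi1..xiT
  iz <- 2 * Tn + seq_len(K)         # ze1..zeK
  R[ia, ia] <- sc$ability_side_corr
  R[ix, ix] <- sc$anxiety_corr
  R[ix, ia] <- sc$cross_corr
  R[ia, ix] <- t(sc$cross_corr)
  if (max(abs(R - t(R))) > 1e-10)
    ls_stop("assembled latent correlation matrix is not symmetric",
            "latsem_scenario_error")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8)
    ls_stop("assembled latent correlation matrix is not positive definite",
            "latsem_scenario_error")
  # wave expansion vectors a_t over (eta1, deltas)
  A <- t(vapply(seq_len(Tn), function(t) as.numeric(seq_len(Tn) <= t),
                numeric(Tn)))
  var_eta <- diag(A %*% sc$ability_side_corr %*% t(A))
  cov_eta_xi <- A %*% t(sc$cross_corr)   # Tn x Tn: cov(eta_t, xi_s)
  resid_a <- matrix(NA_real_, J, Tn)
  for (t in seq_len(Tn)) for (j in seq_len(J)) {
    lam <- sc$ability_loadings[j]; b <- sc$interference[j, t]
    comm <- lam^2 * var_eta[t] + b^2 + 2 * lam * b * cov_eta_xi[t, t]
    resid_a[j, t] <- 1 - comm
  }
  resid_f <- 1 - sc$anxiety_loadings^2 - sc$zeta_variances
  if (any(resid_a <= 0) || any(resid_f <= 0))
    ls_stop("scenario implies non-positive residual variance (loadings/interference too large for unit latent-response variance)",
            "latsem_scenario_error")
  list(R = R, A = A, var_eta = var_eta, cov_eta_xi = cov_eta_xi,
       resid_a = resid_a, resid_f = resid_f, ia = ia, ix = ix, iz = iz)
}

#' @export
print.latsem_scenario <- function(x, ...) {
  cat(sprintf("latsem_scenario: n = %d, seed = %d, retest effects (%s)\n",
              x$n, x$seed, paste(format(x$delta_means), collapse = ", ")))
  invisible(x)
}

#' The reference scenario patterned on the empirical study
#'
#' Seven waves of 13 binary matrices items and 5 seven-point Likert anxiety
#' items, N = 225: item difficulties roughly increasing with presentation
#' position on an easy test (success rates about 0.49-0.85 at the first
#' wave), standardized retest effects (0.7, 0.3, 0.2, -0.1, 0, 0) that
#' plateau after the fourth session, negative interference loadings on a
#' subset of items that decay across waves (six affected items at wave 1,
#' four at wave 2, two at wave 3, none later), highly stable anxiety states
#' (latent correlations 0.85), mildly negative correlations between initial
#' ability and both the latent changes and the anxiety states, and
#' magnitudes patterned on - not equal to - the empirical estimates.
#'
#' @param n Persons (default 225).
#' @param seed RNG seed (default 1).
#' @return A `latsem_scenario`.
#' @export
study_like_scenario <- function(n = 225, seed = 1L) {
  design <- study_design()
  Tn <- 7; J <- 13; K <- 5
  abil_load <- seq(0.38, 0.50, length.out = J)
  abil_thr <- c(-1.019, -0.933, -1.062, -0.702, -0.760, -0.821, -0.536,
                -0.493, -0.549, -0.447, -0.248, 0.059, 0.025)
  delta_means <- c(0.7, 0.3, 0.2, -0.1, 0, 0)
  Ra <- diag(1, Tn)
  Ra[1, 2:Tn] <- Ra[2:Tn, 1] <- -0.3   # larger gains for lower starters
  interference <- matrix(0, J, Tn)
  interference[c(1, 3, 6, 7, 8, 10), 1] <- c(-0.30, -0.27, -0.38, -0.35,
                                             -0.34, -0.40)
  interference[c(3, 9, 10, 13), 2] <- c(-0.30, -0.25, -0.24, -0.23)
  interference[c(3, 7), 3] <- c(-0.27, -0.29)
  anx_load <- c(0.80, 0.85, 0.82, 0.78, 0.84)
  base_cut <- qnorm(c(0.15, 0.35, 0.55, 0.72, 0.85, 0.94))
  anx_thr <- t(vapply(seq_len(K), function(j) base_cut + 0.1 * (j - 3),
                      numeric(6)))
  Rx <- matrix(0.85, Tn, Tn); diag(Rx) <- 1
  zeta_var <- rep(0.09, K)
  cross <- matrix(0, Tn, Tn)
  cross[, 1] <- -0.15                   # xi_s with eta1
  sim_scenario(design, n = n, ability_loadings = abil_load,
               ability_thresholds = abil_thr, delta_means = delta_means,
               ability_side_corr = Ra, anxiety_loadings = anx_load,
               anxiety_thresholds = anx_thr, anxiety_corr = Rx,
               zeta_variances = zeta_var, cross_corr = cross,
               interference = interference, seed = seed)
}

#' Generate an item-response matrix from a scenario
#'
#' Deterministic given the scenario and its seed: the same scenario and seed
#' always yield the identical matrix.
#'
#' @param scenario A `latsem_scenario`.
#' @param seed Optional seed override.
#' @return A `latsem_data` object.
#' @export
generate <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "latsem_scenario"))
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  v <- scenario_internals(scenario)
  d <- scenario$design
  Tn <- d$n_waves; J <- d$n_ability_items; K <- d$n_anxiety_items
  n <- scenario$n
  set.seed(scenario$seed)
  L <- 2 * Tn + K
  mu <- c(0, scenario$delta_means, rep(0, Tn + K))
  Z <- matrix(rnorm(n * L), n, L) %*% chol(v$R)
  Z <- sweep(Z, 2, mu, "+")
  eta <- t(apply(Z[, v$ia, drop = FALSE], 1, cumsum))  # eta_t = eta1 + sum d
  xis <- Z[, v$ix, drop = FALSE]
  zes <- Z[, v$iz, drop = FALSE]
  ability <- matrix(0L, n, Tn * J)
  for (t in seq_len(Tn)) for (j in seq_len(J)) {
    ystar <- scenario$ability_loadings[j] * eta[, t] +
      scenario$interference[j, t] * xis[, t] +
      rnorm(n, sd = sqrt(v$resid_a[j, t]))
    ability[, (t - 1) * J + j] <- as.integer(ystar >
                                               scenario$ability_thresholds[j])
  }
  anxiety <- NULL
  if (K > 0) {
    anxiety <- matrix(0L, n, Tn * K)
    for (t in seq_len(Tn)) for (j in seq_len(K)) {
      ystar <- scenario$anxiety_loadings[j] * xis[, t] +
        sqrt(scenario$zeta_variances[j]) * zes[, j] +
        rnorm(n, sd = sqrt(v$resid_f[j]))
      anxiety[, (t - 1) * K + j] <-
        findInterval(ystar, scenario$anxiety_thresholds[j, ]) + 1L
    }
  }
  response_matrix(d, ability, anxiety)
}

#' True parameter values of a scenario under the full-interference labels
#'
#' @param scenario A `latsem_scenario`.
#' @return Named numeric vector over the free labels of
#'   `full_interference_model(scenario$design)` (the generating truth).
#' @export
scenario_truth <- function(scenario) {
  d <- scenario$design
  Tn <- d$n_waves; J <- d$n_ability_items; K <- d$n_anxiety_items
  out <- c()
  out[sprintf("la%d", seq_len(J))] <- scenario$ability_loadings
  out[sprintf("ta%d", seq_len(J))] <- scenario$ability_thresholds
  out[sprintf("m.d%d", 2:Tn)] <- scenario$delta_means
  abil <- c("eta1", sprintf("d%d", 2:Tn))
  for (l2 in seq_len(Tn - 1)) for (l1 in (l2 + 1):Tn)
    out[sprintf("c.%s.%s", abil[l1], abil[l2])] <-
      scenario$ability_side_corr[l1, l2]
  out[sprintf("lf%d", seq_len(K))] <- scenario$anxiety_loadings
  for (t in seq_len(Tn)) for (j in seq_len(K))
    if (t > 1)
      out[sprintf("lz%d.w%d", j, t)] <- sqrt(scenario$zeta_variances[j])
  out[sprintf("lz%d.w%d", seq_len(K), 1)] <- sqrt(scenario$zeta_variances)
  for (t2 in seq_len(Tn - 1)) for (t1 in (t2 + 1):Tn)
    out[sprintf("c.xi%d.xi%d", t1, t2)] <- scenario$anxiety_corr[t1, t2]
  for (s in seq_len(Tn)) for (a in seq_len(Tn))
    out[sprintf("c.xi%d.%s", s, abil[a])] <- scenario$cross_corr[s, a]
  for (t in seq_len(Tn)) for (j in seq_len(J))
    out[sprintf("b%d.w%d", j, t)] <- scenario$interference[j, t]
  for (t in seq_len(Tn)) for (j in seq_len(K))
    out[sprintf("tf%d.c%d.w%d", j, seq_len(ncol(scenario$anxiety_thresholds)), t)] <-
      scenario$anxiety_thresholds[j, ]
  out
}

#' Monte-Carlo parameter recovery and calibration experiment
#'
#' Generates `reps` replicate data sets from a scenario (replicate r uses
#' seed `base_seed + r`), fits the matching full interference model to each,
#' and aggregates truth-versus-estimate discrepancies: per-parameter mean
#' bias, RMSE, and empirical coverage of nominal 95\% Wald intervals.
#' Optionally performs, per replicate, the scaled difference test obtained
#' by zeroing the interference loadings of the given waves, recording the
#' rejection rate (type-I error when the restriction is true in the
#' scenario, power otherwise).  Replicates with non-converged fits are
#' excluded and counted; more than 20\% exclusions aborts the run.
#'
#' @param scenario A `latsem_scenario`.
#' @param reps Number of replicates (>= 2).
#' @param base_seed Base RNG seed (default: the scenario's seed).
#' @param params Labels to aggregate (default: the latent-difference means
#'   and all interference loadings).
#' @param reduction_waves Optional integer vector: waves whose interference
#'   loadings are zeroed for the per-replicate difference test.
#' @param alpha Test level for rejection rates (default 0.05).
#' @param options Fit options for [fit_sem()].
#' @return An object of class `latsem_recovery`: `table` (per-parameter
#'   bias/RMSE/coverage), `rejection_rate`, `n_excluded`, `reps_used`.
#' @export
recovery_experiment <- function(scenario, reps, base_seed = NULL,
                                params = NULL, reduction_waves = NULL,
                                alpha = 0.05, options = list(ss = FALSE)) {
  stopifnot(inherits(scenario, "latsem_scenario"), reps >= 2)
  if (is.null(base_seed)) base_seed <- scenario$seed
  spec <- full_interference_model(scenario$design)
  truth <- scenario_truth(scenario)
  if (is.null(params))
    params <- c(spec$meta$delta_mean_labels,
                unique(spec$meta$interference_table$label))
  params <- intersect(params, spec_free_labels(spec))
  rspec <- if (!is.null(reduction_waves))
    restrict_interference(spec, reduction_waves) else NULL
  est <- se <- matrix(NA_real_, reps, length(params),
                      dimnames = list(NULL, params))
  pvals <- rep(NA_real_, reps)
  ok <- logical(reps)
  for (r in seq_len(reps)) {
    dat <- generate(scenario, seed = base_seed + r)
    mom <- tryCatch(estimate_moments(dat), latsem_error = function(e) NULL)
    if (is.null(mom)) next
    f <- tryCatch(withCallingHandlers(
      fit_sem(spec, moments = mom, options = options),
      latsem_warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    ok[r] <- TRUE
    est[r, ] <- f$estimates[params]
    se[r, ] <- f$std_errors[params]
    if (!is.null(rspec)) {
      fr <- tryCatch(withCallingHandlers(
        fit_sem(rspec, moments = mom, options = options),
        latsem_warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
      if (!is.null(fr) && fr$converged)
        pvals[r] <- scaled_difference_test(f, fr)$p
    }
  }
  n_excl <- sum(!ok)
  if (n_excl > 0.2 * reps)
    ls_stop(sprintf("%d of %d replicates excluded (non-convergence); run failed",
                    n_excl, reps), "latsem_recovery_error")
  est <- est[ok, , drop = FALSE]; se <- se[ok, , drop = FALSE]
  tr <- truth[params]
  bias <- colMeans(est) - tr
  rmse <- sqrt(colMeans(sweep(est, 2, tr)^2))
  zc <- qnorm(0.975)
  cover <- colMeans(abs(sweep(est, 2, tr)) <= zc * se)
  tab <- data.frame(label = params, truth = unname(tr),
                    mean_est = unname(colMeans(est)), bias = unname(bias),
                    rmse = unname(rmse), coverage = unname(cover),
                    stringsAsFactors = FALSE)
  rej <- if (!is.null(rspec)) mean(pvals[ok] < alpha, na.rm = TRUE)
         else NA_real_
  structure(list(table = tab, rejection_rate = rej, n_excluded = n_excl,
                 reps_used = sum(ok), alpha = alpha,
                 reduction_waves = reduction_waves),
            class = "latsem_recovery")
}

#' @export
print.latsem_recovery <- function(x, digits = 3, ...) {
  cat(sprintf("Recovery experiment: %d replicates used, %d excluded\n",
              x$reps_used, x$n_excluded))
  print(format(head(x$table, 12), digits = digits), row.names = FALSE)
  if (nrow(x$table) > 12) cat(sprintf("  ... %d more rows\n",
                                      nrow(x$table) - 12))
  if (is.finite(x$rejection_rate))
    cat(sprintf("Rejection rate of the difference test (waves %s zeroed): %.3f\n",
                paste(x$reduction_waves, collapse = ","), x$rejection_rate))
  invisible(x)
}
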