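#' Independence baseline specification
#'
#' The conventional null model for incremental fit indices: all correlations
#' fixed to zero with free thresholds (ordinal mode), or a diagonal
#' covariance matrix with free means and variances (ML mode).
#'
#' @param spec A `latsem_spec` whose manifest variables and mode to match.
#' @return A `latsem_spec` for the baseline model.
#' @export
baseline_spec <- function(spec) {
  p <- length(spec$manifest)
  ordinal <- spec$moment_mode == "ordinal"
  lam_f <- matrix(1, p, 1)
  lam_l <- matrix(NA_character_, p, 1)
  psi_f <- matrix(0, 1, 1); psi_l <- matrix(NA_character_, 1, 1)
  model_spec(
    manifest = spec$manifest, n_cat = spec$n_cat,
    latents = "null_", n_exo = 1L, defn = matrix(1, 1, 1),
    lambda_fixed = lam_f, lambda_label = lam_l,
    psi_fixed = psi_f, psi_label = psi_l,
    kappa_fixed = 0, kappa_label = NA_character_,
    tau_fixed = if (ordinal) rep(NA_real_, sum(spec$n_cat - 1)) else NULL,
    tau_label = if (ordinal)
      sprintf("tau_%s", moment_names(spec$manifest, spec$n_cat)[seq_len(sum(spec$n_cat - 1))])
    else NULL,
    moment_mode = spec$moment_mode,
    meta = list(baseline = TRUE))
}

#' Chi-square based fit indices
#'
#' Computes the chi-square test (scaled statistic), chi-square/df ratio,
#' RMSEA with a 90\% confidence interval from inverting the noncentral
#' chi-square distribution, and the incremental CFI and TLI against an
#' independence baseline.  CFI is capped at 1; a TLI above 1 is capped and
#' flagged.
#'
#' @param fit A converged `latsem_fit`.
#' @param baseline A `latsem_fit` of the independence baseline on the same
#'   data (fitted automatically when omitted).
#' @return An object of class `latsem_indices`: fields `chi2`, `df`, `p`,
#'   `chi2_df`, `rmsea`, `rmsea_ci` (length 2), `cfi`, `tli`, `tli_capped`.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "latsem_fit"))
  if (!fit$converged)
    ls_stop("fit_indices refuses a non-converged fit", "latsem_fit_error")
  if (is.null(baseline)) {
    bs <- baseline_spec(fit$spec)
    baseline <- if (fit$spec$moment_mode == "ordinal")
      fit_sem(bs, moments = fit$moments)
    else fit_sem_ml_refit(bs, fit)
  }
  chi2 <- fit$T_scaled; df <- fit$df
  chi2_b <- baseline$T_scaled; df_b <- baseline$df
  n <- fit$n
  if (df == 0)
    return(structure(list(chi2 = chi2, df = 0L, p = NA_real_,
                          chi2_df = NA_real_, rmsea = NA_real_,
                          rmsea_ci = c(NA_real_, NA_real_), cfi = NA_real_,
                          tli = NA_real_, tli_capped = FALSE, n = n),
                     class = "latsem_indices"))
  p_val <- pchisq(chi2, df, lower.tail = FALSE)
  rmsea <- sqrt(max(0, (chi2 - df) / (df * (n - 1))))
  ci <- rmsea_ci(chi2, df, n)
  cfi <- 1 - max(0, chi2 - df) / max(0, chi2_b - df_b, chi2 - df)
  tli_raw <- if (df_b > 0 && (chi2_b / df_b) > 1)
    ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
  else NA_real_
  tli_capped <- is.finite(tli_raw) && tli_raw > 1
  tli <- if (is.finite(tli_raw)) min(tli_raw, 1) else tli_raw
  structure(list(chi2 = chi2, df = df, p = p_val, chi2_df = chi2 / df,
                 rmsea = rmsea, rmsea_ci = ci, cfi = cfi, tli = tli,
                 tli_capped = tli_capped, n = n,
                 baseline = list(chi2 = chi2_b, df = df_b)),
            class = "latsem_indices")
}

# refit helper for ML baselines: reuse the sample statistics cached on the
# original fit so baselines never need the raw data again
fit_sem_ml_refit <- function(bspec, fit) {
  fit_sem(bspec, options = list(ml_stats = fit$ml_stats))
}

rmsea_ci <- function(chi2, df, n, level = 0.90) {
  alpha <- (1 - level) / 2
  ncp_for <- function(target_p) {
    # largest lambda with P(chisq_df(lambda) <= chi2) = target_p
    if (pchisq(chi2, df) < target_p) return(0)
    hi <- max(chi2 * 2, df * 2, 10)
    while (pchisq(chi2, df, ncp = hi) > target_p && hi < 1e8) hi <- hi * 2
    uniroot(function(l) pchisq(chi2, df, ncp = l) - target_p,
            c(0, hi), tol = 1e-8)$root
  }
  lo <- ncp_for(1 - alpha)   # P = 0.95
  hi <- ncp_for(alpha)       # P = 0.05
  c(sqrt(lo / (df * (n - 1))), sqrt(hi / (df * (n - 1))))
}

#' @export
print.latsem_indices <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, p = %.3g, chi2/df = %.3f\nRMSEA = %.3f [%.3f, %.3f], CFI = %.3f, TLI = %.3f\n",
              x$df, x$chi2, x$p, x$chi2_df, x$rmsea, x$rmsea_ci[1],
              x$rmsea_ci[2], x$cfi, x$tli))
  invisible(x)
}

# positional nesting heuristic: every free position of the restricted spec
# is free in the full spec, matrix by matrix, and entries fixed in both have
# equal values where the full one is fixed
nesting_positions_ok <- function(full, restricted) {
  fams <- c("lambda", "psi", "kappa", "tau", "nu", "theta")
  for (f in fams) {
    fl <- full[[paste0(f, "_label")]]; rl <- restricted[[paste0(f, "_label")]]
    ff <- full[[paste0(f, "_fixed")]]; rf <- restricted[[paste0(f, "_fixed")]]
    if (length(fl) != length(rl)) return(FALSE)
    free_r <- !is.na(rl); free_f <- !is.na(fl)
    if (any(free_r & !free_f)) return(FALSE)
    both_fixed <- !free_r & !free_f
    if (any(both_fixed) &&
        !isTRUE(all.equal(ff[both_fixed], rf[both_fixed]))) return(FALSE)
  }
  TRUE
}

#' Scaled chi-square difference test for nested fits
#'
#' Satorra-Bentler style construction from the two fits' mean-scaling
#' factors: with raw statistics T and scaling factors c = tr(U Gamma)/df,
#' the difference scaling is `c_d = (df_r c_r - df_f c_f) / (df_r - df_f)`
#' and the scaled difference `(T_r - T_f) / c_d` is referred to a chi-square
#' with `df_r - df_f` degrees of freedom.  When `c_d <= 0` the unscaled
#' difference is used and flagged.  A CFI difference is included when a
#' baseline fit is supplied.
#'
#' @param fit_full The less restricted fit.
#' @param fit_restricted The nested (more restricted) fit on the same data.
#' @param baseline Optional baseline `latsem_fit` for the CFI difference.
#' @return An object of class `latsem_lrt`: `delta_chi2`, `delta_df`, `p`,
#'   `delta_cfi` (NA without baseline), `scaling_fallback`,
#'   `nesting_verified`.
#' @export
scaled_difference_test <- function(fit_full, fit_restricted, baseline = NULL) {
  stopifnot(inherits(fit_full, "latsem_fit"),
            inherits(fit_restricted, "latsem_fit"))
  if (!fit_full$converged || !fit_restricted$converged)
    ls_stop("difference test refuses non-converged fits", "latsem_fit_error")
  if (!isTRUE(all.equal(fit_full$data_fingerprint,
                        fit_restricted$data_fingerprint)))
    ls_stop("fits are based on different data", "latsem_data_error")
  ddf <- fit_restricted$df - fit_full$df
  if (ddf <= 0)
    ls_stop("restricted model must have strictly more degrees of freedom",
            "latsem_nesting_error")
  nesting_verified <- nesting_positions_ok(fit_full$spec, fit_restricted$spec)
  c_f <- fit_full$scaling$c_mean %||% 1
  c_r <- fit_restricted$scaling$c_mean %||% 1
  if (!is.finite(c_f)) c_f <- 1
  if (!is.finite(c_r)) c_r <- 1
  c_d <- (fit_restricted$df * c_r - fit_full$df * c_f) / ddf
  raw_diff <- fit_restricted$T_raw - fit_full$T_raw
  fallback <- !is.finite(c_d) || c_d <= 0
  delta <- if (fallback) raw_diff else raw_diff / c_d
  delta <- max(delta, 0)
  dcfi <- NA_real_
  if (!is.null(baseline)) {
    dcfi <- fit_indices(fit_full, baseline)$cfi -
      fit_indices(fit_restricted, baseline)$cfi
  }
  structure(list(delta_chi2 = delta, delta_df = ddf,
                 p = pchisq(delta, ddf, lower.tail = FALSE),
                 delta_cfi = dcfi, scaling = c_d,
                 scaling_fallback = fallback,
                 raw_difference = raw_diff,
                 nesting_verified = nesting_verified),
            class = "latsem_lrt")
}

#' @export
print.latsem_lrt <- function(x, ...) {
  cat(sprintf("scaled delta-chi2(%d) = %.3f, p = %.4g%s\n", x$delta_df,
              x$delta_chi2, x$p,
              if (x$scaling_fallback) " [unscaled fallback]" else ""))
  if (is.finite(x$delta_cfi)) cat(sprintf("delta CFI = %.4f\n", x$delta_cfi))
  invisible(x)
}

#' Export a fit-index report row in the conventional table layout
#'
#' @param indices A `latsem_indices`.
#' @param comparison Optional `latsem_lrt` against the previous model.
#' @param label Row label.
#' @return One-row data frame with columns matching the usual invariance /
#'   reduction tables.
#' @export
index_row <- function(indices, comparison = NULL, label = "") {
  data.frame(
    model = label,
    delta_chi2 = if (is.null(comparison)) NA_real_ else comparison$delta_chi2,
    delta_df = if (is.null(comparison)) NA_integer_ else comparison$delta_df,
    delta_p = if (is.null(comparison)) NA_real_ else comparison$p,
    chi2 = indices$chi2, df = indices$df, p = indices$p,
    chi2_df = indices$chi2_df, rmsea = indices$rmsea,
    rmsea_lo = indices$rmsea_ci[1], rmsea_hi = indices$rmsea_ci[2],
    cfi = indices$cfi, tli = indices$tli,
    delta_cfi = if (is.null(comparison)) NA_real_ else comparison$delta_cfi,
    stringsAsFactors = FALSE)
}
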