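#' Measurement-invariance ladder
#'
#' Fits the longitudinal CFA at increasing invariance levels - configural,
#' weak and (for the ability scale) strong - and compares successive rungs
#' with scaled chi-square difference tests and the CFI-difference rule (a
#' CFI drop larger than 0.01 counts as a substantial decline in fit).
#' Ability models are estimated by DWLS on ordinal moments; the anxiety
#' (fear-of-failure) models by robust ML on raw scores.
#'
#' @param data A `latsem_data` object.
#' @param which `"ability"` or `"anxiety"`.
#' @param moments Optional precomputed `latsem_moments` for the ability
#'   items (estimated when missing).
#' @param options Fit options passed to [fit_sem()].
#' @param delta_cfi_cut CFI-difference cutoff (default 0.01).
#' @return An object of class `latsem_ladder`: `table` (one row per rung in
#'   the conventional layout), `fits`, `comparisons`, `verdicts`.
#' @export
invariance_ladder <- function(data, which = c("ability", "anxiety"),
                              moments = NULL, options = list(),
                              delta_cfi_cut = 0.01) {
  stopifnot(inherits(data, "latsem_data"))
  which <- match.arg(which)
  design <- data$design
  if (which == "ability") {
    levels_ <- c("configural", "weak", "strong")
    specs <- lapply(levels_, function(v) ability_cfa(design, v))
    if (is.null(moments))
      moments <- estimate_moments(data, variables = ability_colnames(design))
    fits <- lapply(specs, function(sp) fit_sem(sp, moments = moments,
                                               options = options))
    baseline <- fit_sem(baseline_spec(specs[[1]]), moments = moments,
                        options = options)
  } else {
    levels_ <- c("configural", "weak")
    specs <- lapply(levels_, function(v) sta_cfa(design, v))
    fits <- lapply(specs, function(sp) fit_sem(sp, data = data,
                                               options = options))
    baseline <- fit_sem_ml_refit(baseline_spec(specs[[1]]), fits[[1]])
  }
  bad <- !vapply(fits, `[[`, logical(1), "converged")
  if (any(bad))
    ls_stop(sprintf("non-converged rung(s): %s (gradient norms %s)",
                    paste(levels_[bad], collapse = ", "),
                    paste(signif(vapply(fits[bad], `[[`, numeric(1),
                                        "grad_norm"), 3), collapse = ", ")),
            "latsem_fit_error")
  comparisons <- vector("list", length(fits))
  rows <- list()
  for (i in seq_along(fits)) {
    cmp <- if (i > 1)
      scaled_difference_test(fits[[i - 1]], fits[[i]], baseline = baseline)
    else NULL
    comparisons[[i]] <- cmp
    rows[[i]] <- index_row(fit_indices(fits[[i]], baseline), cmp, levels_[i])
  }
  verdicts <- vapply(comparisons, function(cmp)
    if (is.null(cmp)) NA else is.finite(cmp$delta_cfi) &&
      cmp$delta_cfi > delta_cfi_cut, logical(1))
  structure(list(table = do.call(rbind, rows), fits = setNames(fits, levels_),
                 comparisons = comparisons, substantial_decline = verdicts,
                 which = which, baseline = baseline),
            class = "latsem_ladder")
}

#' @export
print.latsem_ladder <- function(x, digits = 3, ...) {
  cat(sprintf("Measurement-invariance ladder (%s scale)\n", x$which))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Sequential interference-reduction testing
#'
#' Starting from the full interference model (interference loadings at every
#' wave), the loadings of the last wave are fixed to zero and the restricted
#' model is compared with its predecessor by a scaled chi-square difference
#' test; the procedure continues wave by wave until no interference remains.
#' Because each step releases the same number of loadings, the difference
#' statistics are directly comparable in size across steps.  The first step
#' (counting from the last wave backwards) with p below `alpha` marks the
#' last wave with detectable anxiety interference; the sequence is always
#' run to completion, as all rows are informative.
#'
#' @param data A `latsem_data` object.
#' @param moments Optional precomputed `latsem_moments` over all columns.
#' @param alpha Significance level for the per-step flag (default 0.05;
#'   two-sided chi-square upper tail, no multiplicity correction).
#' @param options Fit options for [fit_sem()].
#' @param indices Compute fit indices per step (needs the variance
#'   adjustment; default TRUE).
#' @return An object of class `latsem_reduction`: `table` (one row per
#'   step), `fits`, `comparisons`, `last_interference_wave` (NA when no step
#'   is significant).
#' @export
interference_reduction <- function(data, moments = NULL, alpha = 0.05,
                                   options = list(), indices = TRUE) {
  stopifnot(inherits(data, "latsem_data"))
  design <- data$design
  Tn <- design$n_waves
  if (is.null(moments)) moments <- estimate_moments(data)
  full <- full_interference_model(design)
  options$ss <- indices
  fits <- list(); specs <- list()
  specs[[1]] <- full
  labels <- c(if (Tn > 1) sprintf("1 to %d", Tn:2), "1", "none")
  for (k in seq_len(Tn)) {
    specs[[k + 1]] <- restrict_interference(full, (Tn - k + 1):Tn)
  }
  baseline <- NULL
  rows <- list(); comparisons <- vector("list", Tn + 1)
  for (i in seq_len(Tn + 1)) {
    fits[[i]] <- fit_sem(specs[[i]], moments = moments, options = options)
    if (!fits[[i]]$converged)
      ls_stop(sprintf("reduction step %d did not converge (gradient norm %.2e)",
                      i, fits[[i]]$grad_norm), "latsem_fit_error")
    if (indices && is.null(baseline))
      baseline <- fit_sem(baseline_spec(full), moments = moments,
                          options = options)
    cmp <- if (i > 1)
      scaled_difference_test(fits[[i - 1]], fits[[i]],
                             baseline = if (indices) baseline)
    else NULL
    comparisons[[i]] <- cmp
    rows[[i]] <- if (indices)
      index_row(fit_indices(fits[[i]], baseline), cmp, labels[i])
    else data.frame(model = labels[i],
                    delta_chi2 = if (is.null(cmp)) NA_real_ else cmp$delta_chi2,
                    delta_df = if (is.null(cmp)) NA_integer_ else cmp$delta_df,
                    delta_p = if (is.null(cmp)) NA_real_ else cmp$p,
                    chi2 = fits[[i]]$T_scaled, df = fits[[i]]$df,
                    stringsAsFactors = FALSE)
  }
  pvals <- vapply(comparisons[-1], `[[`, numeric(1), "p")
  sig <- which(pvals < alpha)
  last_wave <- if (length(sig)) Tn - min(sig) + 1L else NA_integer_
  structure(list(table = do.call(rbind, rows), fits = fits,
                 comparisons = comparisons,
                 last_interference_wave = last_wave, alpha = alpha),
            class = "latsem_reduction")
}

#' @export
print.latsem_reduction <- function(x, digits = 3, ...) {
  cat("Interference-reduction sequence\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  if (is.na(x$last_interference_wave))
    cat(sprintf("No step significant at alpha = %g\n", x$alpha))
  else
    cat(sprintf("Last wave with detectable interference: %d (alpha = %g)\n",
                x$last_interference_wave, x$alpha))
  invisible(x)
}

#' Retest effects from a fitted neighbor-change model
#'
#' Extracts the estimated means of the latent difference variables - the
#' mean ability changes between successive waves.  Under unit-variance
#' identification these are standardized mean differences (Cohen's d).
#' Includes Wald tests against zero, 95\% confidence intervals, and tests of
#' the differences between successive retest effects via the joint parameter
#' covariance.
#'
#' @param fit A converged `latsem_fit` of a neighbor-change model
#'   ([full_interference_model()] or [ability_cfa()] with
#'   `neighbor_change = TRUE`).
#' @return An object of class `latsem_retest`: `effects` (data frame with
#'   d, se, ci, p per wave pair), `successive_diffs` (data frame), and
#'   `implied_mean_diff` (the implied mean differences of successive ability
#'   states, equal to d by construction).
#' @export
retest_effects <- function(fit) {
  stopifnot(inherits(fit, "latsem_fit"))
  if (!fit$converged)
    ls_stop("retest_effects refuses a non-converged fit", "latsem_fit_error")
  labs <- fit$spec$meta$delta_mean_labels
  if (is.null(labs))
    ls_stop("fit has no latent difference variables (not a neighbor-change model)",
            "latsem_spec_error")
  Tn <- length(labs) + 1L
  unit <- identical(fit$spec$meta$identification, "unit")
  if (unit) {
    d <- fit$estimates[labs]
    se <- fit$std_errors[labs]
    V <- fit$vcov[labs, labs]
  } else {
    # marker identification: standardize the difference means by the
    # latent-difference SDs, delta method over the involved parameters
    spec <- fit$spec
    th <- fit$estimates
    d_fun <- function(theta) {
      imp <- implied_moments(spec, theta)
      sdl <- sqrt(diag(imp$latent_cov))
      dl <- match(sprintf("d%d", 2:Tn), spec$latents)
      imp$latent_mean[dl] / sdl[dl]
    }
    d <- d_fun(th)
    rel <- unique(c(labs, na.omit(as.vector(spec$psi_label))))
    G <- matrix(0, Tn - 1, length(th)); colnames(G) <- names(th)
    h <- 1e-6
    for (lab in rel) {
      tp <- th; tp[lab] <- tp[lab] + h
      tm <- th; tm[lab] <- tm[lab] - h
      G[, lab] <- (d_fun(tp) - d_fun(tm)) / (2 * h)
    }
    V <- G %*% fit$vcov %*% t(G)
    se <- sqrt(pmax(diag(V), 0))
    names(d) <- names(se) <- labs
  }
  z <- d / se
  eff <- data.frame(
    pair = sprintf("%d,%d", 2:Tn, 1:(Tn - 1)),
    d = unname(d), se = unname(se),
    ci_lo = unname(d - qnorm(0.975) * se),
    ci_hi = unname(d + qnorm(0.975) * se),
    p = unname(2 * pnorm(-abs(z))), stringsAsFactors = FALSE)
  sd_diff <- NULL
  if (Tn > 2) {
    est <- diff(unname(d))
    sev <- vapply(seq_len(Tn - 2), function(k)
      sqrt(V[k, k] + V[k + 1, k + 1] - 2 * V[k, k + 1]), numeric(1))
    sd_diff <- data.frame(
      contrast = sprintf("d%d,%d - d%d,%d", 3:Tn, 2:(Tn - 1), 2:(Tn - 1),
                         1:(Tn - 2)),
      estimate = est, se = sev, p = 2 * pnorm(-abs(est / sev)),
      stringsAsFactors = FALSE)
  }
  lm_all <- fit$implied$latent_mean
  names(lm_all) <- fit$spec$latents
  eta_means <- lm_all[sprintf("eta%d", seq_len(Tn))]
  # implied successive mean differences on the same (standardized) scale as
  # d: identical to d by construction of the difference variables
  mdiff <- unname(diff(eta_means))
  if (!unit) {
    dl <- match(sprintf("d%d", 2:Tn), fit$spec$latents)
    mdiff <- mdiff / sqrt(diag(fit$implied$latent_cov)[dl])
  }
  structure(list(effects = eff, successive_diffs = sd_diff,
                 implied_mean_diff = mdiff,
                 identification = fit$spec$meta$identification),
            class = "latsem_retest")
}

#' @export
print.latsem_retest <- function(x, digits = 3, ...) {
  cat("Retest effects (standardized latent difference means)\n")
  print(format(x$effects, digits = digits), row.names = FALSE)
  if (!is.null(x$successive_diffs)) {
    cat("Differences between successive retest effects\n")
    print(format(x$successive_diffs, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.latsem_retest <- function(x, ...) {
  eff <- x$effects
  k <- nrow(eff)
  graphics::plot(seq_len(k), eff$d, ylim = range(c(eff$ci_lo, eff$ci_hi, 0)),
                 xaxt = "n", xlab = "wave pair", ylab = "retest effect d",
                 pch = 19, ...)
  graphics::axis(1, at = seq_len(k), labels = eff$pair)
  graphics::arrows(seq_len(k), eff$ci_lo, seq_len(k), eff$ci_hi,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Standardized interference effects and deficit correlations
#'
#' Tabulates the standardized interference loadings per item and wave with
#' Wald p-values, the (shared) ability item thresholds, and the per-wave
#' correlation between latent ability and latent anxiety (the deficit
#' effects).  For waves after the first under the neighbor-change
#' parameterization the state-anxiety correlation is a derived quantity
#' (the ability state is a sum of exogenous latents); its standard error
#' uses the delta method on the latent covariance parameters.
#'
#' @param fit A converged `latsem_fit` from [lat_model()] or
#'   [full_interference_model()].
#' @return An object of class `latsem_interference`: `interference` (data
#'   frame wave x item), `deficit` (per-wave correlation, se, p),
#'   `thresholds` (per item).
#' @export
interference_report <- function(fit) {
  stopifnot(inherits(fit, "latsem_fit"))
  if (!fit$converged)
    ls_stop("interference_report refuses a non-converged fit",
            "latsem_fit_error")
  spec <- fit$spec
  design <- spec$meta$design
  Tn <- design$n_waves; J <- design$n_ability_items
  std <- standardize(fit)
  tab <- spec$meta$interference_table
  inter <- NULL
  if (!is.null(tab)) {
    b_std <- std$loadings[cbind(tab$row, tab$col)]
    b_raw <- fit$estimates[tab$label]
    b_se <- fit$std_errors[tab$label]
    inter <- data.frame(wave = tab$wave, item = tab$item,
                        beta_std = b_std, beta = unname(b_raw),
                        se = unname(b_se),
                        p = unname(2 * pnorm(-abs(b_raw / b_se))),
                        stringsAsFactors = FALSE)
  }
  # deficit correlations r(eta_t, xi_t), delta method over the free
  # parameters the latent covariance depends on
  lat <- spec$latents
  r_fun <- function(theta) {
    imp <- implied_moments(spec, theta)
    lc <- imp$latent_cov
    dimnames(lc) <- list(lat, lat)
    vapply(seq_len(Tn), function(t) {
      e <- sprintf("eta%d", t); x <- sprintf("xi%d", t)
      lc[e, x] / sqrt(lc[e, e] * lc[x, x])
    }, numeric(1))
  }
  th <- fit$estimates
  r0 <- r_fun(th)
  psi_labels <- unique(na.omit(as.vector(spec$psi_label)))
  Gr <- matrix(0, Tn, length(th))
  colnames(Gr) <- names(th)
  h <- 1e-6
  for (lab in psi_labels) {
    tp <- th; tp[lab] <- tp[lab] + h
    tm <- th; tm[lab] <- tm[lab] - h
    Gr[, lab] <- (r_fun(tp) - r_fun(tm)) / (2 * h)
  }
  Vr <- Gr %*% fit$vcov %*% t(Gr)
  r_se <- sqrt(pmax(diag(Vr), 0))
  deficit <- data.frame(wave = seq_len(Tn), r = r0, se = r_se,
                        p = 2 * pnorm(-abs(r0 / r_se)),
                        stringsAsFactors = FALSE)
  thr_labs <- sprintf("ta%d", seq_len(J))
  thresholds <- if (all(thr_labs %in% names(th)))
    data.frame(item = seq_len(J), threshold = unname(th[thr_labs]),
               stringsAsFactors = FALSE)
  else NULL
  structure(list(interference = inter, deficit = deficit,
                 thresholds = thresholds),
            class = "latsem_interference")
}

#' @export
print.latsem_interference <- function(x, digits = 3, ...) {
  if (!is.null(x$interference)) {
    cat("Standardized interference effects (beta_std, * p < .05)\n")
    m <- matrix(NA_real_, max(x$interference$wave), max(x$interference$item))
    m[cbind(x$interference$wave, x$interference$item)] <-
      x$interference$beta_std
    s <- matrix("", nrow(m), ncol(m))
    s[cbind(x$interference$wave, x$interference$item)] <-
      ifelse(x$interference$p < 0.05, "*", "")
    disp <- matrix(paste0(format(round(m, digits)), s), nrow(m))
    dimnames(disp) <- list(paste("wave", seq_len(nrow(m))),
                           paste0("i", seq_len(ncol(m))))
    print(disp, quote = FALSE)
  } else cat("No interference loadings in this model.\n")
  cat("Deficit correlations r(ability, anxiety) per wave\n")
  print(format(x$deficit, digits = digits), row.names = FALSE)
  invisible(x)
}
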