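# Config-file serialization: specs round-trip through a YAML schema with
# blocks latents / loadings / constraints; pattern entries are strings,
# either a number (fixed value) or a label (free parameter).

pattern_to_strings <- function(fixed, label) {
  out <- ifelse(is.na(label), as.character(fixed), label)
  if (is.matrix(fixed)) matrix(out, nrow(fixed), ncol(fixed)) else out
}

strings_to_pattern <- function(s) {
  num <- suppressWarnings(as.numeric(s))
  fixed <- ifelse(is.na(num), NA_real_, num)
  label <- ifelse(is.na(num), as.character(s), NA_character_)
  if (is.matrix(s)) {
    fixed <- matrix(fixed, nrow(s), ncol(s))
    label <- matrix(label, nrow(s), ncol(s))
  }
  list(fixed = fixed, label = label)
}

#' Write a model specification to a YAML config file
#'
#' @param spec A `latsem_spec`.
#' @param path Output file path.
#' @export
write_spec <- function(spec, path) {
  mat2list <- function(m) apply(m, 1, function(r) unname(as.list(r)),
                                simplify = FALSE)
  obj <- list(
    moment_mode = spec$moment_mode,
    manifest = as.list(spec$manifest),
    n_cat = as.list(spec$n_cat),
    latents = as.list(spec$latents),
    n_exo = spec$n_exo,
    defn = mat2list(spec$defn),
    loadings = mat2list(pattern_to_strings(spec$lambda_fixed,
                                           spec$lambda_label)),
    latent_cov = mat2list(pattern_to_strings(spec$psi_fixed,
                                             spec$psi_label)),
    latent_means = as.list(pattern_to_strings(spec$kappa_fixed,
                                              spec$kappa_label)),
    thresholds = as.list(pattern_to_strings(spec$tau_fixed, spec$tau_label)),
    intercepts = as.list(pattern_to_strings(spec$nu_fixed, spec$nu_label)),
    residuals = as.list(pattern_to_strings(spec$theta_fixed,
                                           spec$theta_label)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a model specification from a YAML config file
#'
#' @param path File written by [write_spec()].
#' @return A `latsem_spec`.
#' @export
read_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  list2mat <- function(l) do.call(rbind, lapply(l, function(r)
    unlist(r, use.names = FALSE)))
  lam <- strings_to_pattern(list2mat(obj$loadings))
  psi <- strings_to_pattern(list2mat(obj$latent_cov))
  kap <- strings_to_pattern(unlist(obj$latent_means))
  tau <- strings_to_pattern(unlist(obj$thresholds))
  nu <- strings_to_pattern(unlist(obj$intercepts))
  th <- strings_to_pattern(unlist(obj$residuals))
  ordinal <- obj$moment_mode == "ordinal"
  model_spec(manifest = unlist(obj$manifest), n_cat = unlist(obj$n_cat),
             latents = unlist(obj$latents), n_exo = obj$n_exo,
             defn = list2mat(obj$defn),
             lambda_fixed = lam$fixed, lambda_label = lam$label,
             psi_fixed = psi$fixed, psi_label = psi$label,
             kappa_fixed = kap$fixed, kappa_label = kap$label,
             tau_fixed = if (ordinal) tau$fixed else NULL,
             tau_label = if (ordinal) tau$label else NULL,
             nu_fixed = if (!ordinal) nu$fixed else NULL,
             nu_label = if (!ordinal) nu$label else NULL,
             theta_fixed = if (!ordinal) th$fixed else NULL,
             theta_label = if (!ordinal) th$label else NULL,
             moment_mode = obj$moment_mode)
}

#' Export a fitted model as a parameter CSV plus JSON fit summary
#'
#' @param fit A `latsem_fit`.
#' @param stem Output path stem (writes `<stem>_parameters.csv` and
#'   `<stem>_fit.json`).
#' @export
write_fit <- function(fit, stem) {
  pars <- data.frame(label = names(fit$estimates),
                     estimate = unname(fit$estimates),
                     se = unname(fit$std_errors),
                     z = unname(fit$estimates / fit$std_errors),
                     p = unname(2 * pnorm(-abs(fit$estimates /
                                                 fit$std_errors))),
                     stringsAsFactors = FALSE)
  write.csv(format(pars, digits = 6), paste0(stem, "_parameters.csv"),
            row.names = FALSE, quote = FALSE)
  summ <- list(mode = fit$spec$moment_mode, n = fit$n, df = fit$df,
               chi2_raw = fit$T_raw, chi2_scaled = fit$T_scaled,
               p = fit$p_value, scaling = fit$scaling,
               converged = fit$converged, iterations = fit$iterations,
               grad_norm = fit$grad_norm, heywood = fit$heywood)
  jsonlite::write_json(summ, paste0(stem, "_fit.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}
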