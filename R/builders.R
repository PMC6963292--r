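# Builders for every model family in the longitudinal anxiety-test (LAT)
# framework.  Label conventions (1-based wave t, item j):
#   la{j}[.w{t}]   ability loadings          ta{j}[.w{t}]  ability thresholds
#   lf{j}[.w{t}]   anxiety loadings          tf{j}.c{c}.w{t} anxiety thresholds
#   lz{j}.w{t}     indicator-specific (zeta) loadings
#   b{j}.w{t} / b.w{t}  interference loadings (free / equal within wave)
#   v.<latent>     latent variance            c.<l1>.<l2>   latent covariance
#   m.<latent>     latent mean (m.d{t} are the retest-effect means)
# Latents: eta{t} ability states, d{t} latent differences (eta_t - eta_{t-1}),
# xi{t} anxiety states, ze{j} indicator-specific factors.

new_pattern <- function(nr, nc = NULL) {
  if (is.null(nc)) list(fixed = rep(0, nr), label = rep(NA_character_, nr))
  else list(fixed = matrix(0, nr, nc), label = matrix(NA_character_, nr, nc))
}

set_free <- function(pat, i, j = NULL, label) {
  if (is.null(j)) { pat$fixed[i] <- NA; pat$label[i] <- label }
  else { pat$fixed[i, j] <- NA; pat$label[i, j] <- label }
  pat
}

set_fixed <- function(pat, i, j = NULL, value) {
  if (is.null(j)) { pat$fixed[i] <- value; pat$label[i] <- NA }
  else { pat$fixed[i, j] <- value; pat$label[i, j] <- NA }
  pat
}

sym_set_free <- function(pat, i, j, label) {
  pat <- set_free(pat, i, j, label)
  set_free(pat, j, i, label)
}

check_token <- function(x, allowed, what) {
  if (!is.character(x) || length(x) != 1 || !(x %in% allowed))
    ls_stop(sprintf("invalid %s '%s'; allowed: %s", what, paste(x)[1],
                    paste(allowed, collapse = ", ")),
            "latsem_spec_error")
  x
}

#' Longitudinal ability CFA
#'
#' One correlated latent ability state per wave measured by the binary
#' ability items, at a chosen level of longitudinal measurement invariance:
#' configural (free loadings and thresholds per wave, latent means fixed 0),
#' weak (loadings equality-constrained across waves), strong (thresholds
#' additionally equality-constrained, latent means free from wave 2 on).
#' With `neighbor_change = TRUE` (strong invariance only) the cross-wave
#' ability covariances are re-parameterized as a latent neighbor-change
#' growth curve: exogenous latents are the first-wave state and the
#' successive latent difference variables, later states being their
#' residual-free unit-weight sums, so the difference-variable means are the
#' retest effects.  The re-parameterization has identical degrees of freedom
#' and fit to the strong-invariant CFA.
#'
#' @param design A [study_design()] with `n_waves >= 2`.
#' @param invariance `"configural"`, `"weak"` or `"strong"`.
#' @param identification `"marker"` (first item's loading fixed to 1 per
#'   wave) or `"unit"` (latent variances fixed to 1).
#' @param neighbor_change Replace cross-wave correlations by the latent
#'   difference growth curve (requires strong invariance).
#' @return A `latsem_spec` in ordinal mode.
#' @export
ability_cfa <- function(design, invariance = c("configural", "weak", "strong"),
                        identification = c("marker", "unit"),
                        neighbor_change = FALSE) {
  stopifnot(inherits(design, "latsem_design"))
  if (length(invariance) > 1) invariance <- invariance[1]
  invariance <- check_token(invariance, c("configural", "weak", "strong"),
                            "invariance")
  identification <- match.arg(identification)
  Tn <- design$n_waves; J <- design$n_ability_items
  if (Tn < 2) ls_stop("ability_cfa needs >= 2 waves", "latsem_design_error")
  if (neighbor_change && invariance != "strong")
    ls_stop("the neighbor-change growth curve requires strong invariance: latent difference means are meaningless unless thresholds are constant across waves",
            "latsem_spec_error")
  manifest <- ability_colnames(design)
  p <- Tn * J
  if (neighbor_change) {
    exo <- c("eta1", sprintf("d%d", 2:Tn))
    latents <- c(exo, sprintf("eta%d", 2:Tn))
    defn <- rbind(diag(1, Tn),
                  t(vapply(2:Tn, function(k) c(1, as.numeric(2:Tn <= k)),
                           numeric(Tn))))
  } else {
    exo <- latents <- sprintf("eta%d", seq_len(Tn))
    defn <- diag(1, Tn)
  }
  lam <- new_pattern(p, length(latents))
  tau <- new_pattern(p)
  for (t in seq_len(Tn)) {
    lat <- match(sprintf("eta%d", t), latents)
    for (j in seq_len(J)) {
      row <- (t - 1) * J + j
      lab_l <- if (invariance == "configural") sprintf("la%d.w%d", j, t)
               else sprintf("la%d", j)
      if (identification == "marker" && j == 1)
        lam <- set_fixed(lam, row, lat, 1)
      else lam <- set_free(lam, row, lat, lab_l)
      lab_t <- if (invariance == "strong") sprintf("ta%d", j)
               else sprintf("ta%d.w%d", j, t)
      tau <- set_free(tau, row, NULL, lab_t)
    }
  }
  ne <- length(exo)
  psi <- new_pattern(ne, ne)
  for (l in seq_len(ne)) {
    psi <- if (identification == "unit") set_fixed(psi, l, l, 1)
           else set_free(psi, l, l, sprintf("v.%s", exo[l]))
  }
  for (l2 in seq_len(ne - 1)) for (l1 in (l2 + 1):ne)
    psi <- sym_set_free(psi, l1, l2, sprintf("c.%s.%s", exo[l1], exo[l2]))
  kap <- new_pattern(ne)
  if (invariance == "strong") {
    for (l in 2:ne)
      kap <- set_free(kap, l, NULL, sprintf("m.%s", exo[l]))
  }
  model_spec(manifest = manifest, n_cat = rep(2L, p),
             latents = latents, n_exo = ne, defn = defn,
             lambda_fixed = lam$fixed, lambda_label = lam$label,
             psi_fixed = psi$fixed, psi_label = psi$label,
             kappa_fixed = kap$fixed, kappa_label = kap$label,
             tau_fixed = tau$fixed, tau_label = tau$label,
             moment_mode = "ordinal",
             meta = list(model = "ability_cfa", design = design,
                         invariance = invariance,
                         identification = identification,
                         neighbor_change = neighbor_change,
                         delta_mean_labels = if (neighbor_change)
                           sprintf("m.d%d", 2:Tn) else NULL,
                         wave_of_manifest = rep(seq_len(Tn), each = J)))
}

#' Longitudinal situational-test-anxiety CFA with indicator-specific factors
#'
#' One anxiety state per wave measured by the Likert items, plus one
#' indicator-specific factor per item loading on that item at every wave to
#' absorb the covariance of identical questionnaire items across sessions.
#' Indicator-specific factors are mutually uncorrelated and uncorrelated
#' with the anxiety states.  The standalone model is estimated by robust ML
#' on means and covariances (`moment_mode = "ml"`); an ordinal variant is
#' available for use inside combined models.
#'
#' @param design A [study_design()] with `n_waves >= 2` and
#'   `n_anxiety_items >= 2`.
#' @param invariance `"configural"` or `"weak"` (loadings equal across
#'   waves; indicator-specific loadings stay free).
#' @param moment_mode `"ml"` (default) or `"ordinal"`.
#' @param identification `"marker"` or `"unit"`.
#' @return A `latsem_spec`.
#' @export
sta_cfa <- function(design, invariance = c("configural", "weak"),
                    moment_mode = c("ml", "ordinal"),
                    identification = c("marker", "unit")) {
  stopifnot(inherits(design, "latsem_design"))
  if (length(invariance) > 1) invariance <- invariance[1]
  invariance <- check_token(invariance, c("configural", "weak"), "invariance")
  moment_mode <- match.arg(moment_mode)
  identification <- match.arg(identification)
  Tn <- design$n_waves; K <- design$n_anxiety_items
  if (Tn < 2 || K < 2)
    ls_stop("sta_cfa needs >= 2 waves and >= 2 anxiety items",
            "latsem_design_error")
  manifest <- anxiety_colnames(design)
  p <- Tn * K
  latents <- c(sprintf("xi%d", seq_len(Tn)), sprintf("ze%d", seq_len(K)))
  ne <- length(latents)
  lam <- new_pattern(p, ne)
  ncat <- rep(design$anxiety_categories, p)
  tau <- if (moment_mode == "ordinal")
    new_pattern(sum(ncat - 1)) else NULL
  thr_off <- 0L
  for (t in seq_len(Tn)) for (j in seq_len(K)) {
    row <- (t - 1) * K + j
    # anxiety-state loading
    lab <- if (invariance == "configural") sprintf("lf%d.w%d", j, t)
           else sprintf("lf%d", j)
    if (identification == "marker" && j == 1)
      lam <- set_fixed(lam, row, t, 1)
    else lam <- set_free(lam, row, t, lab)
    # indicator-specific loading
    zcol <- Tn + j
    if (identification == "marker" && t == 1)
      lam <- set_fixed(lam, row, zcol, 1)
    else lam <- set_free(lam, row, zcol, sprintf("lz%d.w%d", j, t))
    if (moment_mode == "ordinal") {
      for (cc in seq_len(ncat[row] - 1))
        tau <- set_free(tau, thr_off + cc, NULL,
                        sprintf("tf%d.c%d.w%d", j, cc, t))
      thr_off <- thr_off + ncat[row] - 1L
    }
  }
  psi <- new_pattern(ne, ne)
  for (t in seq_len(Tn))
    psi <- if (identification == "unit") set_fixed(psi, t, t, 1)
           else set_free(psi, t, t, sprintf("v.xi%d", t))
  for (j in seq_len(K)) {
    z <- Tn + j
    psi <- if (identification == "unit") set_fixed(psi, z, z, 1)
           else set_free(psi, z, z, sprintf("v.ze%d", j))
  }
  for (t2 in seq_len(Tn - 1)) for (t1 in (t2 + 1):Tn)
    psi <- sym_set_free(psi, t1, t2, sprintf("c.xi%d.xi%d", t1, t2))
  kap <- new_pattern(ne)
  model_spec(manifest = manifest, n_cat = ncat,
             latents = latents, n_exo = ne, defn = diag(1, ne),
             lambda_fixed = lam$fixed, lambda_label = lam$label,
             psi_fixed = psi$fixed, psi_label = psi$label,
             kappa_fixed = kap$fixed, kappa_label = kap$label,
             tau_fixed = if (moment_mode == "ordinal") tau$fixed else NULL,
             tau_label = if (moment_mode == "ordinal") tau$label else NULL,
             moment_mode = moment_mode,
             meta = list(model = "sta_cfa", design = design,
                         invariance = invariance,
                         identification = identification,
                         wave_of_manifest = rep(seq_len(Tn), each = K)))
}

# merge two specs over disjoint manifests/latents into one block spec
merge_specs <- function(s1, s2, mode) {
  p1 <- length(s1$manifest); p2 <- length(s2$manifest)
  L1 <- length(s1$latents); L2 <- length(s2$latents)
  ne1 <- s1$n_exo; ne2 <- s2$n_exo
  blk <- function(a, b, fill) {
    out <- matrix(fill, nrow(a) + nrow(b), ncol(a) + ncol(b))
    out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
    out[nrow(a) + seq_len(nrow(b)), ncol(a) + seq_len(ncol(b))] <- b
    out
  }
  # exogenous latents must come first: reorder latents as
  # (exo1, exo2, defined1, defined2)
  ord1 <- c(seq_len(ne1), if (L1 > ne1) (ne1 + 1):L1)
  lam_f <- cbind(blk(s1$lambda_fixed[, seq_len(ne1), drop = FALSE],
                     s2$lambda_fixed[, seq_len(ne2), drop = FALSE], 0),
                 blk(s1$lambda_fixed[, -seq_len(ne1), drop = FALSE],
                     s2$lambda_fixed[, -seq_len(ne2), drop = FALSE], 0))
  lam_l <- cbind(blk(s1$lambda_label[, seq_len(ne1), drop = FALSE],
                     s2$lambda_label[, seq_len(ne2), drop = FALSE],
                     NA_character_),
                 blk(s1$lambda_label[, -seq_len(ne1), drop = FALSE],
                     s2$lambda_label[, -seq_len(ne2), drop = FALSE],
                     NA_character_))
  defn <- blk(s1$defn[seq_len(ne1), , drop = FALSE],
              s2$defn[seq_len(ne2), , drop = FALSE], 0)
  if (L1 > ne1 || L2 > ne2)
    defn <- rbind(defn,
                  blk(s1$defn[-seq_len(ne1), , drop = FALSE],
                      s2$defn[-seq_len(ne2), , drop = FALSE], 0))
  psi_f <- blk(s1$psi_fixed, s2$psi_fixed, 0)
  psi_l <- blk(s1$psi_label, s2$psi_label, NA_character_)
  list(manifest = c(s1$manifest, s2$manifest),
       n_cat = c(s1$n_cat, s2$n_cat),
       latents = c(s1$latents[seq_len(ne1)], s2$latents[seq_len(ne2)],
                   if (L1 > ne1) s1$latents[(ne1 + 1):L1],
                   if (L2 > ne2) s2$latents[(ne2 + 1):L2]),
       n_exo = ne1 + ne2, defn = defn,
       lambda_fixed = lam_f, lambda_label = lam_l,
       psi_fixed = psi_f, psi_label = psi_l,
       kappa_fixed = c(s1$kappa_fixed, s2$kappa_fixed),
       kappa_label = c(s1$kappa_label, s2$kappa_label),
       tau_fixed = c(s1$tau_fixed, s2$tau_fixed),
       tau_label = c(s1$tau_label, s2$tau_label))
}

#' Longitudinal anxiety-test (LAT) model
#'
#' Merges the ability and anxiety measurement models, lets ability and
#' anxiety states correlate freely within and across waves, and adds
#' interference loadings: regressions of every ability item of wave t on the
#' anxiety state of wave t.  A negative interference loading represents
#' anxiety-induced measurement bias; the latent ability-anxiety correlations
#' represent deficit effects.  Estimating all interference loadings freely
#' together with free deficit correlations creates rotational indeterminacy
#' unless loading equality constraints anchor the solution: with a fully
#' configural ability model, `interference = "free"` is rejected, while
#' `"equal-within-wave"` (all interference loadings of a wave share one
#' value) is the conservative identification strategy that works on a
#' configural base.
#'
#' @param design A [study_design()].
#' @param ability_invariance,anxiety_invariance Invariance tokens for the
#'   two measurement models.
#' @param interference `"free"`, `"equal-within-wave"`, or `"none"`.
#' @param identification `"marker"` or `"unit"`.
#' @param anxiety_ability_corr `"all"` (default: anxiety states correlate
#'   freely with every ability state) or `"wave1"`.
#' @return A `latsem_spec` in ordinal mode (both scales treated as ordinal).
#' @export
lat_model <- function(design,
                      ability_invariance = c("strong", "configural", "weak"),
                      anxiety_invariance = c("weak", "configural"),
                      interference = c("free", "equal-within-wave", "none"),
                      identification = c("unit", "marker"),
                      anxiety_ability_corr = c("all", "wave1")) {
  anxiety_ability_corr <- match.arg(anxiety_ability_corr)
  ability_invariance <- match.arg(ability_invariance)
  anxiety_invariance <- match.arg(anxiety_invariance)
  interference <- check_token(match.arg(interference),
                              c("free", "equal-within-wave", "none"),
                              "interference option")
  identification <- match.arg(identification)
  if (interference == "free" && ability_invariance == "configural")
    ls_stop("free interference loadings on a configural ability model are not identified: simultaneous free double loadings and free latent correlations create rotational indeterminacy; use equality constraints (interference = 'equal-within-wave') or loading invariance",
            "latsem_identification_error")
  build_lat(design, ability_invariance, anxiety_invariance, interference,
            identification, neighbor_change = FALSE,
            anxiety_ability_corr = anxiety_ability_corr)
}

build_lat <- function(design, ability_invariance, anxiety_invariance,
                      interference, identification, neighbor_change,
                      anxiety_ability_corr = if (neighbor_change &&
                                                 interference == "free")
                        "wave1" else "all") {
  sa <- ability_cfa(design, ability_invariance, identification,
                    neighbor_change = neighbor_change)
  sf <- sta_cfa(design, anxiety_invariance, moment_mode = "ordinal",
                identification = identification)
  m <- merge_specs(sa, sf, "ordinal")
  Tn <- design$n_waves; J <- design$n_ability_items
  ne <- m$n_exo
  # free cross-construct covariances: xi_s with the ability-side exogenous
  # latents.  With free per-item interference loadings, free correlations
  # between the anxiety states and the latent difference variables are not
  # identified (a uniform shift in the xi-delta correlations of a wave can
  # be absorbed exactly by that wave's interference loadings - the
  # longitudinal analogue of the rotational indeterminacy of the
  # cross-sectional model), so the default frees only the correlations with
  # the first-wave ability state; later-wave deficit correlations are
  # derived quantities.
  abil_exo <- if (identical(anxiety_ability_corr, "wave1")) 1L
              else seq_len(sa$n_exo)
  xi_idx <- sa$n_exo + seq_len(Tn)
  psi <- list(fixed = m$psi_fixed, label = m$psi_label)
  for (x in xi_idx) for (a in abil_exo)
    psi <- sym_set_free(psi, x, a,
                        sprintf("c.%s.%s", m$latents[x], m$latents[a]))
  # interference loadings
  lam <- list(fixed = m$lambda_fixed, label = m$lambda_label)
  interference_tab <- NULL
  if (interference != "none") {
    rows <- list()
    for (t in seq_len(Tn)) {
      xcol <- match(sprintf("xi%d", t), m$latents)
      for (j in seq_len(J)) {
        rr <- (t - 1) * J + j
        lab <- if (interference == "free") sprintf("b%d.w%d", j, t)
               else sprintf("b.w%d", t)
        lam <- set_free(lam, rr, xcol, lab)
        rows[[length(rows) + 1L]] <-
          data.frame(label = lab, wave = t, item = j,
                     manifest = m$manifest[rr], row = rr, col = xcol,
                     stringsAsFactors = FALSE)
      }
    }
    interference_tab <- do.call(rbind, rows)
  }
  start <- NULL
  if (!is.null(interference_tab))
    start <- setNames(rep(0, length(unique(interference_tab$label))),
                      unique(interference_tab$label))
  model_spec(manifest = m$manifest, n_cat = m$n_cat, latents = m$latents,
             n_exo = ne, defn = m$defn,
             lambda_fixed = lam$fixed, lambda_label = lam$label,
             psi_fixed = psi$fixed, psi_label = psi$label,
             kappa_fixed = m$kappa_fixed, kappa_label = m$kappa_label,
             tau_fixed = m$tau_fixed, tau_label = m$tau_label,
             moment_mode = "ordinal",
             meta = list(model = if (neighbor_change) "full_interference"
                         else "lat", design = design,
                         ability_invariance = ability_invariance,
                         anxiety_invariance = anxiety_invariance,
                         interference = interference,
                         identification = identification,
                         neighbor_change = neighbor_change,
                         interference_table = interference_tab,
                         delta_mean_labels = sa$meta$delta_mean_labels,
                         start = start))
}

#' Full interference model
#'
#' The LAT model with the cross-wave ability correlations replaced by the
#' latent neighbor-change growth curve: exogenous latents are the first-wave
#' ability state and one latent difference variable per successive wave
#' pair, all freely intercorrelated, with later ability states defined as
#' residual-free unit-weight sums.  The difference-variable means are free
#' (the retest effects; the first-wave mean is fixed 0) and interference
#' loadings are estimated for every ability item at every wave.  Requires
#' strong ability invariance (difference means are only interpretable with
#' constant thresholds) and weak anxiety invariance; under the default
#' unit-variance identification the difference means are standardized mean
#' changes (Cohen's d).
#'
#' @param design A [study_design()].
#' @param interference `"free"` (default), `"equal-within-wave"`, `"none"`.
#' @param ability_invariance Must be `"strong"`; any other value is an
#'   error, kept as an argument so the precondition is explicit.
#' @param anxiety_invariance `"weak"` (default) or `"configural"`.
#' @param identification `"unit"` (default; Cohen's d metric) or `"marker"`.
#' @param anxiety_ability_corr `"wave1"` (default with free interference:
#'   anxiety states correlate with the first-wave ability state only, the
#'   identified pattern) or `"all"` (free correlations with the latent
#'   differences too; only identified together with equality-constrained
#'   interference).
#' @return A `latsem_spec` in ordinal mode.
#' @export
full_interference_model <- function(design,
                                    interference = c("free", "equal-within-wave", "none"),
                                    ability_invariance = "strong",
                                    anxiety_invariance = c("weak", "configural"),
                                    identification = c("unit", "marker"),
                                    anxiety_ability_corr = NULL) {
  interference <- match.arg(interference)
  anxiety_invariance <- match.arg(anxiety_invariance)
  identification <- match.arg(identification)
  if (!identical(ability_invariance, "strong"))
    ls_stop("the full interference model requires strong longitudinal measurement invariance of the ability test: latent difference means cannot be estimated unless thresholds are constant across test sessions",
            "latsem_spec_error")
  if (is.null(anxiety_ability_corr))
    anxiety_ability_corr <- if (interference == "free") "wave1" else "all"
  build_lat(design, "strong", anxiety_invariance, interference,
            identification, neighbor_change = TRUE,
            anxiety_ability_corr = anxiety_ability_corr)
}

#' Fix interference loadings of selected waves to zero
#'
#' The elementary restriction step of the interference-reduction approach:
#' all interference loadings at the named waves are fixed to 0, leaving
#' everything else untouched, so the result nests the input spec.  Zeroing a
#' wave without interference loadings is a warning no-op.
#'
#' @param spec A `latsem_spec` with interference loadings (from
#'   [lat_model()] or [full_interference_model()]).
#' @param waves_to_zero Integer vector of wave indices.
#' @return The restricted `latsem_spec`.
#' @export
restrict_interference <- function(spec, waves_to_zero) {
  stopifnot(inherits(spec, "latsem_spec"))
  tab <- spec$meta$interference_table
  waves_to_zero <- unique(as.integer(waves_to_zero))
  for (w in waves_to_zero) {
    sel <- !is.null(tab) && any(tab$wave == w)
    if (!sel) {
      ls_warn(sprintf("wave %d has no interference loadings; nothing to restrict", w),
              "latsem_noop")
      next
    }
    rows <- tab[tab$wave == w, ]
    for (i in seq_len(nrow(rows))) {
      spec$lambda_fixed[rows$row[i], rows$col[i]] <- 0
      spec$lambda_label[rows$row[i], rows$col[i]] <- NA_character_
    }
    tab <- tab[tab$wave != w, ]
  }
  spec$meta$interference_table <- if (!is.null(tab) && nrow(tab)) tab else NULL
  spec$meta$zeroed_waves <- sort(unique(c(spec$meta$zeroed_waves,
                                          waves_to_zero)))
  spec$meta$start <- spec$meta$start[names(spec$meta$start) %in%
                                       unlist(spec$lambda_label)]
  spec
}

#' Saturated specification
#'
#' All moments free: zero degrees of freedom and, by construction, zero
#' fitted discrepancy.  Mostly useful for testing and as a reference point.
#'
#' @param manifest Manifest variable names.
#' @param n_cat Categories per variable (ordinal mode).
#' @param moment_mode `"ordinal"` or `"ml"`.
#' @return A `latsem_spec`.
#' @export
saturated_spec <- function(manifest, n_cat = NULL,
                           moment_mode = c("ordinal", "ml")) {
  moment_mode <- match.arg(moment_mode)
  p <- length(manifest)
  latents <- paste0("s.", manifest)
  lam_f <- diag(1, p); lam_l <- matrix(NA_character_, p, p)
  psi <- new_pattern(p, p)
  for (j in seq_len(p))
    psi <- if (moment_mode == "ordinal") set_fixed(psi, j, j, 1)
           else set_free(psi, j, j, sprintf("v.%s", manifest[j]))
  for (b in seq_len(p - 1)) for (a in (b + 1):p)
    psi <- sym_set_free(psi, a, b, sprintf("c.%s.%s", manifest[a], manifest[b]))
  kap <- new_pattern(p)
  if (moment_mode == "ordinal") {
    tau <- new_pattern(sum(n_cat - 1))
    k <- 0L
    for (j in seq_len(p)) for (cc in seq_len(n_cat[j] - 1)) {
      k <- k + 1L
      tau <- set_free(tau, k, NULL, sprintf("t.%s.c%d", manifest[j], cc))
    }
  }
  model_spec(manifest = manifest,
             n_cat = if (moment_mode == "ordinal") n_cat else rep(0L, p),
             latents = latents, n_exo = p, defn = diag(1, p),
             lambda_fixed = lam_f, lambda_label = lam_l,
             psi_fixed = psi$fixed, psi_label = psi$label,
             kappa_fixed = kap$fixed, kappa_label = kap$label,
             tau_fixed = if (moment_mode == "ordinal") tau$fixed else NULL,
             tau_label = if (moment_mode == "ordinal") tau$label else NULL,
             theta_fixed = if (moment_mode == "ml") rep(0, p) else NULL,
             theta_label = if (moment_mode == "ml") rep(NA_character_, p) else NULL,
             moment_mode = moment_mode,
             meta = list(model = "saturated"))
}
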