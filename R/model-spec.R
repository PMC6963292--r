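# ModelSpec: a symbolic latent-variable model.
#
# Pattern matrices come in pairs: *_fixed holds numeric values with NA where
# the entry is a free parameter, *_label holds the parameter label (shared
# labels force equality) with NA where the entry is fixed.  Latents are split
# into exogenous ones (free means/covariances) and defined ones, which are
# residual-free unit-weight combinations of exogenous latents (the
# neighbor-change growth curve: eta_k = eta_1 + sum of the preceding latent
# difference variables).  `defn` maps every latent to its exogenous
# expansion; exogenous latents occupy its leading identity block.

#' Construct a latent-variable model specification
#'
#' Low-level constructor; the model builders ([ability_cfa()],
#' [sta_cfa()], [lat_model()], [full_interference_model()]) are the intended
#' way to produce specs.
#'
#' @param manifest Character vector of manifest variable names.
#' @param n_cat Integer vector: response categories per manifest variable
#'   (ordinal mode); ignored in `"ml"` mode.
#' @param latents Character vector of latent names, exogenous first.
#' @param n_exo Number of exogenous latents.
#' @param defn Numeric matrix (latents x exogenous) of fixed unit/zero
#'   weights defining every latent from the exogenous set; leading block must
#'   be the identity.
#' @param lambda_fixed,lambda_label Loading pattern (manifest x latents).
#' @param psi_fixed,psi_label Exogenous latent covariance pattern (symmetric).
#' @param kappa_fixed,kappa_label Exogenous latent mean pattern.
#' @param tau_fixed,tau_label Threshold pattern, stacked per variable
#'   (`sum(n_cat - 1)` entries, ordinal mode only).
#' @param nu_fixed,nu_label Manifest intercepts (`"ml"` mode; fixed 0 in
#'   ordinal mode).
#' @param theta_fixed,theta_label Residual variances (`"ml"` mode; derived as
#'   unit-variance remainders in ordinal mode).
#' @param moment_mode `"ordinal"` (DWLS on thresholds + polychorics) or
#'   `"ml"` (normal-theory ML on means + covariances).
#' @param meta Free-form list the builders use to record wave/item structure.
#' @return An object of class `latsem_spec`.
#' @export
model_spec <- function(manifest, n_cat, latents, n_exo, defn,
                       lambda_fixed, lambda_label,
                       psi_fixed, psi_label,
                       kappa_fixed, kappa_label,
                       tau_fixed = NULL, tau_label = NULL,
                       nu_fixed = NULL, nu_label = NULL,
                       theta_fixed = NULL, theta_label = NULL,
                       moment_mode = c("ordinal", "ml"),
                       meta = list()) {
  moment_mode <- match.arg(moment_mode)
  p <- length(manifest); L <- length(latents)
  stopifnot(nrow(lambda_fixed) == p, ncol(lambda_fixed) == L,
            nrow(defn) == L, ncol(defn) == n_exo,
            nrow(psi_fixed) == n_exo, length(kappa_fixed) == n_exo)
  if (!isTRUE(all.equal(defn[seq_len(n_exo), , drop = FALSE],
                        diag(1, n_exo), check.attributes = FALSE)))
    ls_stop("defn must start with the identity block over exogenous latents",
            "latsem_spec_error")
  free_but_labeled <- function(f, l)
    all(is.na(f) == !is.na(l))
  if (!free_but_labeled(lambda_fixed, lambda_label) ||
      !free_but_labeled(psi_fixed, psi_label) ||
      !free_but_labeled(kappa_fixed, kappa_label))
    ls_stop("each pattern entry must be either fixed or labeled",
            "latsem_spec_error")
  if (moment_mode == "ordinal") {
    if (is.null(tau_fixed))
      ls_stop("ordinal mode requires a threshold pattern", "latsem_spec_error")
    stopifnot(length(tau_fixed) == sum(n_cat - 1))
    nu_fixed <- rep(0, p); nu_label <- rep(NA_character_, p)
    theta_fixed <- rep(NA_real_, p); theta_label <- rep(NA_character_, p)
  } else {
    if (is.null(nu_fixed)) { nu_fixed <- rep(NA_real_, p)
                             nu_label <- paste0("nu_", manifest) }
    if (is.null(theta_fixed)) { theta_fixed <- rep(NA_real_, p)
                                theta_label <- paste0("theta_", manifest) }
    tau_fixed <- numeric(0); tau_label <- character(0)
    n_cat <- rep(0L, p)
  }
  # every manifest loads somewhere
  loads <- rowSums(!is.na(lambda_label) |
                   (!is.na(lambda_fixed) & lambda_fixed != 0)) > 0
  if (!all(loads))
    ls_stop(sprintf("manifest variable(s) load on no latent: %s",
                    paste(manifest[!loads], collapse = ", ")),
            "latsem_spec_error")
  # scale must be set: a latent cannot have a free variance and all-free
  # loadings unless the variance is fixed elsewhere in its column
  for (l in seq_len(n_exo)) {
    own <- which(defn[, l] != 0)
    lam_cols <- lambda_label[, own, drop = FALSE]
    fix_cols <- lambda_fixed[, own, drop = FALSE]
    any_fixed_load <- any(!is.na(fix_cols) & fix_cols != 0)
    if (is.na(psi_fixed[l, l]) && !any_fixed_load) {
      used <- any(!is.na(lam_cols))
      if (used)
        ls_stop(sprintf(
          "latent '%s' has a free variance and no fixed loading: scale not set",
          latents[l]), "latsem_spec_error")
    }
  }
  structure(list(manifest = manifest, n_cat = as.integer(n_cat),
                 latents = latents, n_exo = as.integer(n_exo), defn = defn,
                 lambda_fixed = lambda_fixed, lambda_label = lambda_label,
                 psi_fixed = psi_fixed, psi_label = psi_label,
                 kappa_fixed = kappa_fixed, kappa_label = kappa_label,
                 tau_fixed = tau_fixed, tau_label = tau_label,
                 nu_fixed = nu_fixed, nu_label = nu_label,
                 theta_fixed = theta_fixed, theta_label = theta_label,
                 moment_mode = moment_mode, meta = meta),
            class = "latsem_spec")
}

#' @export
print.latsem_spec <- function(x, ...) {
  cat(sprintf("latsem_spec (%s): %d manifest, %d latents (%d exogenous), %d free parameters, df = %d\n",
              x$moment_mode, length(x$manifest), length(x$latents),
              x$n_exo, length(spec_free_labels(x)), count_df(x)))
  invisible(x)
}

#' Distinct free parameter labels of a specification
#'
#' @param spec A `latsem_spec`.
#' @return Character vector in canonical (first appearance) order.
#' @export
spec_free_labels <- function(spec) {
  unique(na.omit(c(spec$lambda_label, spec$psi_label[lower.tri(spec$psi_label, diag = TRUE)],
                   spec$kappa_label, spec$tau_label, spec$nu_label,
                   spec$theta_label)))
}

#' Model degrees of freedom
#'
#' Ordinal mode: (number of thresholds + p(p-1)/2 correlations) minus the
#' number of distinct free labels.  ML mode: (p means + p(p+1)/2 covariance
#' moments) minus the number of distinct free labels.
#'
#' @param spec A `latsem_spec`.
#' @return Integer degrees of freedom.
#' @export
count_df <- function(spec) {
  p <- length(spec$manifest)
  n_mom <- if (spec$moment_mode == "ordinal")
    sum(spec$n_cat - 1) + p * (p - 1) / 2
  else
    p + p * (p + 1) / 2
  as.integer(n_mom - length(spec_free_labels(spec)))
}

# Positions of each free label inside each pattern matrix; computed once per
# fit.  For psi only the lower triangle (incl. diagonal) is enumerated; the
# realization step symmetrizes.
spec_param_map <- function(spec) {
  labels <- spec_free_labels(spec)
  idx <- function(lab_obj) {
    w <- which(!is.na(lab_obj))
    split(w, factor(lab_obj[w], levels = labels))
  }
  psi_l <- spec$psi_label
  psi_l[upper.tri(psi_l)] <- NA
  list(labels = labels,
       lambda = idx(spec$lambda_label), psi = idx(psi_l),
       kappa = idx(spec$kappa_label), tau = idx(spec$tau_label),
       nu = idx(spec$nu_label), theta = idx(spec$theta_label))
}

# realize pattern matrices at a parameter vector theta (named by label)
spec_realize <- function(spec, theta, map = spec_param_map(spec)) {
  fill <- function(fixed, positions) {
    out <- fixed
    for (lab in names(positions))
      if (length(positions[[lab]])) out[positions[[lab]]] <- theta[[lab]]
    out
  }
  Lam <- fill(spec$lambda_fixed, map$lambda)
  Psi <- fill(spec$psi_fixed, map$psi)
  Psi[upper.tri(Psi)] <- t(Psi)[upper.tri(Psi)]
  list(lambda = Lam, psi = Psi,
       kappa = fill(spec$kappa_fixed, map$kappa),
       tau = fill(spec$tau_fixed, map$tau),
       nu = fill(spec$nu_fixed, map$nu),
       theta = fill(spec$theta_fixed, map$theta))
}

#' Model-implied moments
#'
#' Substitutes the structural definitions (defined latents are eliminated
#' exactly through their unit-weight expansions), giving the implied moment
#' vector as a deterministic function of the exogenous latent moments.  In
#' ordinal mode the implied latent-response covariance has a unit diagonal
#' (delta parameterization): residual variances are remainders, and the
#' implied moments are the thresholds (shifted by the implied latent-response
#' means) plus the strict lower triangle of the correlation matrix.  In ML
#' mode the implied moments are means plus the full lower triangle of the
#' covariance matrix.
#'
#' @param spec A `latsem_spec`.
#' @param theta Named numeric vector over `spec_free_labels(spec)`.
#' @return List with `moments` (stacked vector), `cov` (implied
#'   covariance/correlation matrix), `mean` (implied manifest means),
#'   `latent_cov` (over all latents), `latent_mean`, and `heywood` (logical:
#'   any communality above 1 in ordinal mode / negative residual in ML mode).
#' @export
implied_moments <- function(spec, theta) {
  map <- spec_param_map(spec)
  if (!all(map$labels %in% names(theta)))
    ls_stop("theta does not cover all free labels", "latsem_dim_error")
  mats <- spec_realize(spec, theta, map)
  B <- mats$lambda %*% spec$defn            # manifest x exo
  Phi_all <- spec$defn %*% mats$psi %*% t(spec$defn)
  Mu_all <- as.vector(spec$defn %*% mats$kappa)
  Sig <- B %*% mats$psi %*% t(B)
  mu_star <- as.vector(mats$lambda %*% Mu_all)
  if (spec$moment_mode == "ordinal") {
    heywood <- any(diag(Sig) > 1 + 1e-10)
    diag(Sig) <- 1
    thr_rep <- rep(seq_along(spec$manifest), spec$n_cat - 1)
    mom <- c(mats$tau - mu_star[thr_rep], Sig[lower.tri(Sig)])
    mu <- mu_star
  } else {
    theta_res <- mats$theta
    heywood <- any(theta_res < 0)
    diag(Sig) <- diag(Sig) + theta_res
    mu <- mats$nu + mu_star
    mom <- c(mu, Sig[lower.tri(Sig, diag = TRUE)])
  }
  list(moments = mom, cov = Sig, mean = mu, latent_cov = Phi_all,
       latent_mean = Mu_all, heywood = heywood, mats = mats)
}

# Analytic Jacobian d sigma / d theta, n_moments x n_free, same moment order
# as implied_moments.  Derivatives per pattern family:
#   lambda[j,l]: dSigma = E_jl Phi_all Lambda' + sym; d mu = Mu_all[l] e_j
#   psi[a,b]   : dSigma = u v' + v u' (u = B[,a], v = B[,b]); a==b: u u'
#   kappa[a]   : d mu = (Lambda defn[,a])
#   tau[t]     : d threshold_t = 1
#   nu[j], theta[j]: identity entries (ML mode)
# Ordinal mode drops the diagonal (it is identically 1) and propagates mean
# effects into the threshold block with a minus sign.
spec_jacobian <- function(spec, theta, imp = NULL, map = spec_param_map(spec)) {
  p <- length(spec$manifest)
  L <- length(spec$latents)
  if (is.null(imp)) imp <- implied_moments(spec, theta)
  mats <- imp$mats
  B <- mats$lambda %*% spec$defn
  Phi_all <- imp$latent_cov
  Mu_all <- imp$latent_mean
  LamPhi <- mats$lambda %*% Phi_all      # p x L ; = Lambda Phi_all
  Bexo <- B                              # p x n_exo
  ordinal <- spec$moment_mode == "ordinal"
  lt <- lower.tri(diag(p))
  lt_d <- lower.tri(diag(p), diag = TRUE)
  n_thr <- if (ordinal) sum(spec$n_cat - 1) else 0L
  thr_rep <- if (ordinal) rep(seq_len(p), spec$n_cat - 1) else integer(0)
  n_mean <- if (ordinal) n_thr else p
  n_cov <- if (ordinal) sum(lt) else sum(lt_d)
  q <- length(map$labels)
  J <- matrix(0, n_mean + n_cov, q)

  cov_block <- function(dS) if (ordinal) dS[lt] else dS[lt_d]

  for (qi in seq_len(q)) {
    lab <- map$labels[qi]
    dS <- NULL; dmu <- NULL
    pos <- map$lambda[[lab]]
    if (length(pos)) {
      dS <- matrix(0, p, p); dmu <- numeric(p)
      for (w in pos) {
        j <- (w - 1) %% p + 1
        l <- (w - 1) %/% p + 1
        dS[j, ] <- dS[j, ] + LamPhi[, l]
        dS[, j] <- dS[, j] + LamPhi[, l]
        dmu[j] <- dmu[j] + Mu_all[l]
      }
    }
    pos <- map$psi[[lab]]
    if (length(pos)) {
      if (is.null(dS)) { dS <- matrix(0, p, p); dmu <- numeric(p) }
      ne <- spec$n_exo
      for (w in pos) {
        b <- (w - 1) %/% ne + 1
        a <- (w - 1) %% ne + 1
        u <- Bexo[, a]; v <- Bexo[, b]
        if (a == b) dS <- dS + tcrossprod(u)
        else dS <- dS + tcrossprod(u, v) + tcrossprod(v, u)
      }
    }
    pos <- map$kappa[[lab]]
    if (length(pos)) {
      if (is.null(dmu)) dmu <- numeric(p)
      for (a in pos) dmu <- dmu + Bexo[, a]
    }
    pos <- map$theta[[lab]]
    if (length(pos) && !ordinal) {
      if (is.null(dS)) dS <- matrix(0, p, p)
      for (j in pos) dS[j, j] <- dS[j, j] + 1
    }
    # assemble
    if (!is.null(dS)) {
      if (ordinal) diag(dS) <- 0
      J[(n_mean + 1):(n_mean + n_cov), qi] <- cov_block(dS)
    }
    if (!is.null(dmu)) {
      if (ordinal) {
        J[seq_len(n_thr), qi] <- J[seq_len(n_thr), qi] - dmu[thr_rep]
      } else {
        J[seq_len(p), qi] <- J[seq_len(p), qi] + dmu
      }
    }
    pos <- map$tau[[lab]]
    if (length(pos)) J[pos, qi] <- J[pos, qi] + 1
    pos <- map$nu[[lab]]
    if (length(pos) && !ordinal) J[pos, qi] <- J[pos, qi] + 1
  }
  colnames(J) <- map$labels
  J
}
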