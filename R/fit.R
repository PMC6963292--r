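# DWLS / ML estimation of a latsem_spec.
#
# Both modes minimize a moment discrepancy by Gauss-Newton (Fisher scoring)
# with step halving on the exact objective and an analytic moment Jacobian;
# variance-type parameters (exogenous latent variances, ML residual
# variances) are optimized on the log scale to keep them positive.  There is
# no randomness anywhere in estimation: identical inputs give identical
# estimates.

# label classification: variance-type iff every position sits on the psi
# diagonal or in theta (ML residuals)
variance_labels <- function(spec, map) {
  ne <- spec$n_exo
  diag_pos <- (seq_len(ne) - 1) * ne + seq_len(ne)
  vapply(map$labels, function(lab) {
    pp <- map$psi[[lab]]; tp <- map$theta[[lab]]
    other <- length(map$lambda[[lab]]) + length(map$kappa[[lab]]) +
      length(map$tau[[lab]]) + length(map$nu[[lab]])
    has <- length(pp) + length(tp) > 0
    has && other == 0 && all(pp %in% diag_pos)
  }, logical(1))
}

start_values <- function(spec, map, sample_mom, ml_stats = NULL) {
  th <- setNames(numeric(length(map$labels)), map$labels)
  p <- length(spec$manifest)
  for (lab in map$labels) {
    val <- NULL
    if (length(map$tau[[lab]]))
      val <- mean(sample_mom[map$tau[[lab]]])
    else if (length(map$nu[[lab]]) && !is.null(ml_stats))
      val <- mean(ml_stats$mean[map$nu[[lab]]])
    else if (length(map$theta[[lab]]) && !is.null(ml_stats))
      val <- mean(diag(ml_stats$cov)[map$theta[[lab]]]) / 2
    else if (length(map$psi[[lab]])) {
      ne <- spec$n_exo
      on_diag <- all(map$psi[[lab]] %in% ((seq_len(ne) - 1) * ne + seq_len(ne)))
      val <- if (on_diag) 1 else 0.2
      if (on_diag && !is.null(ml_stats)) val <- mean(diag(ml_stats$cov)) / 2
    }
    else if (length(map$lambda[[lab]]))
      val <- if (spec$moment_mode == "ordinal") 0.5 else 1
    else if (length(map$kappa[[lab]])) val <- 0
    th[lab] <- if (is.null(val)) 0 else val
  }
  # builder-provided hints (e.g. interference coefficients start at 0)
  hint <- spec$meta$start
  if (!is.null(hint)) th[intersect(names(hint), names(th))] <-
      hint[intersect(names(hint), names(th))]
  th
}

# normal-theory weight matrix for the ML moment vector (means, then lower
# triangle incl. diagonal of the covariance): V_mean = Sigma^-1 and
# V_cov[P,Q] = m_P m_Q (K_ac K_bd + K_ad K_bc)/4 with K = Sigma^-1 and
# m = 2 - delta_ab, so that (s - sigma)' V (s - sigma) matches the
# second-order expansion of the ML discrepancy.
ml_weight <- function(Sigma) {
  p <- nrow(Sigma)
  K <- solve(Sigma)
  lt <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  a <- lt[, 1]; b <- lt[, 2]
  m <- ifelse(a == b, 1, 2)
  Vc <- (K[a, a] * K[b, b] + K[a, b] * K[b, a]) * tcrossprod(m) / 4
  nm <- nrow(lt)
  V <- matrix(0, p + nm, p + nm)
  V[seq_len(p), seq_len(p)] <- K
  V[p + seq_len(nm), p + seq_len(nm)] <- Vc
  V
}

ml_sample_stats <- function(x) {
  n <- nrow(x); p <- ncol(x)
  m <- colMeans(x)
  xc <- sweep(x, 2, m)
  S <- crossprod(xc) / n
  lt_d <- lower.tri(diag(p), diag = TRUE)
  # per-person moment deviations for the sandwich Gamma
  ia <- row(diag(p))[lt_d]; ib <- col(diag(p))[lt_d]
  Z <- cbind(xc, xc[, ia] * xc[, ib] - rep(1, n) %o% S[lt_d])
  s <- c(m, S[lt_d])
  list(mean = m, cov = S, s = s, gamma = crossprod(Z) / n, n = n,
       logdetS = determinant(S)$modulus[1])
}

ml_discrepancy <- function(imp, st) {
  p <- length(st$mean)
  ch <- tryCatch(chol(imp$cov), error = function(e) NULL)
  if (is.null(ch)) return(list(F = Inf))
  d <- st$mean - imp$mean
  Sinv_ <- chol2inv(ch)
  Tm <- st$cov + tcrossprod(d)
  F <- 2 * sum(log(diag(ch))) + sum(Tm * Sinv_) - st$logdetS - p
  G <- Sinv_ %*% (imp$cov - Tm) %*% Sinv_
  lt_d <- lower.tri(diag(p), diag = TRUE)
  mfac <- ifelse(row(diag(p)) == col(diag(p)), 1, 2)[lt_d]
  grad_mom <- c(-2 * as.vector(Sinv_ %*% d), mfac * G[lt_d])
  list(F = F, grad_mom = grad_mom, Sinv = Sinv_)
}

#' Fit a model specification
#'
#' Ordinal mode minimizes the diagonally weighted least squares discrepancy
#' `(s - sigma(theta))' W (s - sigma(theta))` with `W` the inverse diagonal
#' of the moment asymptotic covariance; standard errors and the
#' mean-and-variance adjusted (scaled-and-shifted) test statistic use the
#' full sandwich covariance through score-matrix products (the WLSMV
#' construction).  ML mode minimizes the normal-theory discrepancy on means
#' and covariances with a Satorra-Bentler mean-scaled statistic and sandwich
#' standard errors (robust ML).
#'
#' @param spec A `latsem_spec`.
#' @param data A `latsem_data` object or numeric matrix (required for ML
#'   mode; used to estimate moments in ordinal mode when `moments` is
#'   missing).
#' @param moments A `latsem_moments` object (ordinal mode).
#' @param options List: `tol` (gradient-norm convergence, default 1e-8),
#'   `maxit` (default 1000), `ss` (compute the variance-adjustment trace for
#'   the scaled-shifted statistic, default TRUE), `start` (named overrides).
#' @return An object of class `latsem_fit`.
#' @export
fit_sem <- function(spec, data = NULL, moments = NULL, options = list()) {
  stopifnot(inherits(spec, "latsem_spec"))
  tol <- options$tol %||% 1e-8
  maxit <- options$maxit %||% 1000L
  map <- spec_param_map(spec)
  q <- length(map$labels)

  if (spec$moment_mode == "ordinal") {
    if (is.null(moments)) {
      if (is.null(data))
        ls_stop("ordinal mode needs data or moments", "latsem_dim_error")
      moments <- estimate_moments(data, variables = spec$manifest)
    }
    if (!identical(moments$variables, spec$manifest))
      ls_stop("moment variables do not match the spec's manifest variables",
              "latsem_dim_error")
    if (!identical(as.integer(moments$n_cat), spec$n_cat))
      ls_stop("moment category counts do not match the spec", "latsem_dim_error")
    s <- unname(moments$moments)
    w <- 1 / pmax(moments$gamma_diag, 1e-6)
    n <- moments$n
    obj <- function(imp) {
      r <- s - imp$moments
      list(F = sum(w * r^2), r = r)
    }
    grad_fun <- function(imp, J) -2 * crossprod(J, w * (s - imp$moments))
    gn_dir <- function(imp, J) {
      r <- s - imp$moments
      K <- J * w
      A <- crossprod(J, K)
      list(A = A, g = crossprod(K, r))
    }
    st <- NULL
  } else {
    if (!is.null(options$ml_stats)) {
      st <- options$ml_stats
    } else {
      if (is.null(data)) ls_stop("ML mode needs raw data", "latsem_dim_error")
      x <- if (inherits(data, "latsem_data"))
        cbind(data$ability, if (ncol(data$anxiety)) data$anxiety else NULL)
      else as.matrix(data)
      x <- x[, spec$manifest, drop = FALSE]
      st <- ml_sample_stats(x)
    }
    s <- st$s
    n <- st$n
    obj <- function(imp) ml_discrepancy(imp, st)
    grad_fun <- function(imp, J, ml = NULL) {
      if (is.null(ml)) ml <- ml_discrepancy(imp, st)
      crossprod(J, ml$grad_mom)
    }
    gn_dir <- function(imp, J) {
      V <- ml_weight(imp$cov)
      K <- V %*% J
      list(A = crossprod(J, K), g = crossprod(K, s - imp$moments))
    }
  }

  theta <- start_values(spec, map, s, st)
  if (!is.null(options$start)) {
    ov <- options$start
    theta[intersect(names(ov), names(theta))] <-
      ov[intersect(names(ov), names(theta))]
  }
  is_var <- variance_labels(spec, map)
  theta[is_var] <- pmax(theta[is_var], 1e-4)

  to_phi <- function(th) { th[is_var] <- log(th[is_var]); th }
  to_theta <- function(ph) { ph[is_var] <- exp(ph[is_var]); ph }

  eval_F <- function(th) {
    imp <- implied_moments(spec, th)
    o <- obj(imp)
    list(imp = imp, F = o$F, o = o)
  }

  phi <- to_phi(theta)
  cur <- eval_F(to_theta(phi))
  iter <- 0L; grad_norm <- Inf; converged <- FALSE
  lm_ridge <- 1e-6   # Levenberg-Marquardt damping, adapted per iteration
  while (iter < maxit) {
    iter <- iter + 1L
    th <- to_theta(phi)
    J <- spec_jacobian(spec, th, cur$imp, map)
    chain <- ifelse(is_var, th, 1)
    Jt <- sweep(J, 2, chain, "*")
    g_exact <- if (spec$moment_mode == "ordinal")
      grad_fun(cur$imp, Jt)
    else crossprod(Jt, cur$o$grad_mom)
    grad_norm <- max(abs(g_exact))
    if (grad_norm < tol) { converged <- TRUE; break }
    d <- gn_dir(cur$imp, Jt)
    dA <- pmax(diag(d$A), 1e-8 * (mean(abs(diag(d$A))) + 1))
    improved <- FALSE
    for (h in 1:40) {
      step <- tryCatch(solve(d$A + diag(lm_ridge * dA, q), d$g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand_phi <- phi + as.vector(step)
        cand <- eval_F(to_theta(cand_phi))
        if (is.finite(cand$F) && cand$F < cur$F - 1e-15) {
          phi <- cand_phi; cur <- cand; improved <- TRUE
          lm_ridge <- max(lm_ridge / 3, 1e-10)
          break
        }
      }
      lm_ridge <- lm_ridge * 8
      if (lm_ridge > 1e12) break
    }
    if (!improved) break  # stalled: grad_norm records how close we got
  }
  # the objective is flat to double precision before the gradient reaches
  # tol on some problems; a stall with a gradient at the numerical floor is
  # a converged solution (grad_norm reports the attained value)
  if (!converged && grad_norm < 1e-6 * (1 + abs(cur$F)))
    converged <- TRUE
  theta <- to_theta(phi)
  names(theta) <- map$labels
  imp <- cur$imp
  F_val <- cur$F
  df <- count_df(spec)
  T_raw <- n * F_val

  res <- robust_stats(spec, theta, imp, map, n,
                      moments = moments, ml_stats = st,
                      ss = options$ss %||% TRUE, df = df)

  fit <- structure(list(
    spec = spec, estimates = theta, std_errors = res$se, vcov = res$vcov,
    discrepancy = F_val, T_raw = T_raw, T_scaled = res$T_scaled, df = df,
    scaling = res$scaling, p_value = res$p_value,
    implied = imp, n = n,
    converged = converged, iterations = iter, grad_norm = grad_norm,
    heywood = imp$heywood,
    moments = moments, ml_stats = st,
    data_fingerprint = signif(sum(s) + n, 12)),
    class = "latsem_fit")
  if (!converged)
    ls_warn(sprintf("fit did not reach gradient tolerance (norm %.2e after %d iterations)",
                    grad_norm, iter), "latsem_nonconvergence")
  if (imp$heywood)
    ls_warn("Heywood case: an implied residual variance is negative",
            "latsem_heywood")
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Robust (sandwich) quantities.  DWLS: everything is computed from products
# with the n x n_mom score matrix, never materializing the full moment
# covariance:
#   A  = J' W J,   C = J' W Gamma W J = crossprod(S W J)/n
#   tr(U Gamma)   = tr(W Gamma) - tr(A^-1 C)
#   tr((U Gamma)^2) = tr((W Gamma)^2) - 2 tr(A^-1 J'W Gamma W Gamma W J)
#                     + tr((A^-1 C)^2)
# with tr((W Gamma)^2) = ||C_s C_s'||_F^2 / n^2 for C_s = S sqrt(W).
# The reported statistic is the scaled-and-shifted form a*T + b with
# a = sqrt(df / tr((U Gamma)^2)), b = df - a tr(U Gamma) (mean and variance
# matched to the reference chi-square), the WLSMV convention.
robust_stats <- function(spec, theta, imp, map, n, moments = NULL,
                         ml_stats = NULL, ss = TRUE, df = NULL) {
  J <- spec_jacobian(spec, theta, imp, map)
  q <- ncol(J)
  if (spec$moment_mode == "ordinal") {
    w <- 1 / pmax(moments$gamma_diag, 1e-6)
    S <- moments$scores
    K <- J * w
    A <- crossprod(J, K)
    Ainv <- tryCatch(solve(A), error = function(e)
      solve(A + diag(1e-8 * (mean(diag(A)) + 1), q)))
    SK <- S %*% K
    C <- crossprod(SK) / n
    vcov <- Ainv %*% C %*% Ainv / n
    trWG <- sum(w * moments$gamma_diag)
    AC <- Ainv %*% C
    trUG <- trWG - sum(diag(AC))
    trUG2 <- NA_real_
    if (ss && df > 0) {
      # tr((W Gamma)^2) = ||Cs' Cs||_F^2 / n^2 = ||Cs Cs'||_F^2 / n^2;
      # form whichever Gram matrix is smaller
      Cs <- S * rep(sqrt(w), each = nrow(S))
      trWGWG <- if (nrow(Cs) <= ncol(Cs)) sum(tcrossprod(Cs)^2) / n^2
                else sum(crossprod(Cs)^2) / n^2
      GK <- crossprod(S, SK) / n              # Gamma W J
      t2 <- sum(diag(Ainv %*% crossprod(GK, GK * w)))
      t3 <- sum(AC * t(AC))
      trUG2 <- trWGWG - 2 * t2 + t3
    }
  } else {
    V <- ml_weight(imp$cov)
    K <- V %*% J
    A <- crossprod(J, K)
    Ainv <- tryCatch(solve(A), error = function(e)
      solve(A + diag(1e-8 * (mean(diag(A)) + 1), q)))
    G <- ml_stats$gamma
    C <- crossprod(K, G %*% K)
    vcov <- Ainv %*% C %*% Ainv / n
    UG <- (V - K %*% tcrossprod(Ainv, K)) %*% G
    trUG <- sum(diag(UG))
    trUG2 <- if (ss && df > 0) sum(UG * t(UG)) else NA_real_
  }
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- map$labels
  dimnames(vcov) <- list(map$labels, map$labels)
  T_raw <- n * if (spec$moment_mode == "ordinal")
    sum((1 / pmax(moments$gamma_diag, 1e-6)) *
          (unname(moments$moments) - imp$moments)^2)
  else ml_discrepancy(imp, ml_stats)$F
  c_mean <- if (df > 0) trUG / df else NA_real_
  if (df == 0) {
    T_scaled <- 0; a <- 1; b <- 0
  } else if (spec$moment_mode == "ordinal" && ss && is.finite(trUG2) &&
             trUG2 > 0) {
    a <- sqrt(df / trUG2); b <- df - a * trUG
    T_scaled <- a * T_raw + b
  } else if (is.finite(c_mean) && c_mean > 0) {
    a <- 1 / c_mean; b <- 0
    T_scaled <- T_raw / c_mean
  } else {
    a <- 1; b <- 0; T_scaled <- T_raw
  }
  p_value <- if (df > 0) pchisq(T_scaled, df, lower.tail = FALSE) else NA_real_
  list(se = se, vcov = vcov,
       scaling = list(c_mean = c_mean, a = a, b = b,
                      trUG = trUG, trUG2 = trUG2),
       T_scaled = T_scaled, p_value = p_value)
}

#' @export
print.latsem_fit <- function(x, ...) {
  cat(sprintf("latsem_fit (%s): chi2(%d) = %.3f (scaled %.3f), n = %d, %sconverged in %d iterations\n",
              x$spec$moment_mode, x$df, x$T_raw, x$T_scaled, x$n,
              if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Standardized solution of a fitted model
#'
#' Rescales estimates so that every latent variable (including defined
#' neighbor-change states) has unit variance; in ordinal mode manifest
#' latent responses already have unit variance (delta parameterization), in
#' ML mode loadings are additionally divided by the implied manifest SD.
#' Under unit-variance identification the latent-level parameters are
#' already standardized and are returned unchanged.
#'
#' @param fit A converged `latsem_fit`.
#' @return List with `loadings` (matrix, standardized), `latent_cor`
#'   (correlations over all latents), `latent_mean` (means in latent SD
#'   units), and `scale` (the latent SDs used).
#' @export
standardize <- function(fit) {
  spec <- fit$spec
  imp <- fit$implied
  mats <- imp$mats
  sdl <- sqrt(pmax(diag(imp$latent_cov), 0))
  Lam_std <- sweep(mats$lambda, 2, sdl, "*")
  if (spec$moment_mode == "ml") {
    sdm <- sqrt(diag(imp$cov))
    Lam_std <- sweep(Lam_std, 1, sdm, "/")
  }
  D <- diag(1 / ifelse(sdl > 0, sdl, 1))
  lat_cor <- D %*% imp$latent_cov %*% D
  dimnames(lat_cor) <- list(spec$latents, spec$latents)
  dimnames(Lam_std) <- list(spec$manifest, spec$latents)
  lat_mean <- imp$latent_mean / ifelse(sdl > 0, sdl, 1)
  names(lat_mean) <- spec$latents
  list(loadings = Lam_std, latent_cor = lat_cor, latent_mean = lat_mean,
       scale = setNames(sdl, spec$latents))
}
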