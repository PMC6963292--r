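#' Estimate normal-ogive thresholds from category counts
#'
#' Threshold c is the standard-normal quantile of the cumulative proportion
#' of responses up to and including category c.  Empty boundary categories
#' are collapsed (they carry no threshold); an empty interior category yields
#' two coincident cumulative proportions and is likewise collapsed so the
#' returned thresholds stay strictly increasing.
#'
#' @param category_counts Non-negative integer vector of per-category counts
#'   (lowest category first).
#' @return Numeric vector of thresholds, one fewer than the number of
#'   non-collapsed categories.
#' @examples
#' estimate_thresholds(c(50, 50))      # 0
#' estimate_thresholds(c(25, 50, 25))  # -0.674, 0.674
#' @export
estimate_thresholds <- function(category_counts) {
  n <- sum(category_counts)
  if (n < 1) ls_stop("total count must be >= 1", "latsem_validation_error")
  counts <- category_counts[cumsum(category_counts) > 0 &
                            rev(cumsum(rev(category_counts))) > 0]
  counts <- counts[counts > 0]  # collapse empty interior categories
  if (length(counts) < 2)
    ls_stop("all observations fall in one category; variable is degenerate",
            "latsem_degenerate_error")
  qnorm(cumsum(counts[-length(counts)]) / n)
}

#' Polychoric (tetrachoric) correlation of a two-way table
#'
#' Two-stage maximum likelihood: thresholds are fixed at their univariate
#' estimates from the table margins, then the latent bivariate-normal
#' correlation maximizes the multinomial likelihood of the table.  The
#' standard error comes from the negative inverse second derivative of the
#' profile log-likelihood at the optimum.  Estimates are clipped to
#' +/- 0.999; a clipped solution is flagged as a boundary case (typical for
#' tables with empty off-diagonal cells).
#'
#' @param table Matrix of non-negative counts; both margins need at least two
#'   non-empty categories.
#' @return List with `rho`, `se`, `loglik`, `boundary` (logical), and the
#'   marginal `thresholds` used.
#' @export
polychoric <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || sum(tab) < 1)
    ls_stop("table must contain non-negative counts", "latsem_validation_error")
  rs <- rowSums(tab); cs <- colSums(tab)
  tab <- tab[rs > 0, cs > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    ls_stop("both margins need >= 2 non-empty categories",
            "latsem_degenerate_error")
  tau1 <- estimate_thresholds(rowSums(tab))
  tau2 <- estimate_thresholds(colSums(tab))
  clip <- 0.999
  nll <- function(r) -cpp_pair_loglik(tab, tau1, tau2, r)
  opt <- optimize(nll, c(-clip, clip), tol = 1e-10)
  rho <- opt$minimum
  # Newton polish on the analytic score for full precision
  for (i in 1:8) {
    g <- cpp_pair_dloglik(tab, tau1, tau2, rho)
    h <- (cpp_pair_dloglik(tab, tau1, tau2, min(rho + 1e-5, clip)) -
          cpp_pair_dloglik(tab, tau1, tau2, max(rho - 1e-5, -clip))) / 2e-5
    if (!is.finite(g) || !is.finite(h) || h >= 0) break
    step <- g / h
    cand <- max(-clip, min(clip, rho - step))
    if (abs(cand - rho) < 1e-12) { rho <- cand; break }
    rho <- cand
  }
  boundary <- abs(rho) >= clip - 1e-4
  if (boundary) rho <- sign(rho) * clip
  d2 <- (cpp_pair_dloglik(tab, tau1, tau2, min(rho + 1e-5, clip)) -
         cpp_pair_dloglik(tab, tau1, tau2, max(rho - 1e-5, -clip))) / 2e-5
  se <- if (!boundary && is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  ll <- cpp_pair_loglik(tab, tau1, tau2, rho)
  if (!is.finite(ll))
    ls_stop("non-finite likelihood in polychoric estimation",
            "latsem_estimation_error")
  list(rho = rho, se = se, loglik = ll, boundary = boundary,
       thresholds = list(tau1, tau2))
}

moment_names <- function(vars, ncat) {
  thr <- unlist(lapply(seq_along(vars), function(j)
    sprintf("%s|t%d", vars[j], seq_len(ncat[j] - 1))))
  lt <- which(lower.tri(diag(length(vars))), arr.ind = TRUE)
  cors <- sprintf("%s~~%s", vars[lt[, 2]], vars[lt[, 1]])
  c(thr, cors)
}

#' First- and second-stage ordinal sample moments with sandwich covariance
#'
#' Estimates, for every selected variable, its normal-ogive thresholds and,
#' for every variable pair, the two-stage polychoric correlation, and stacks
#' them into the moment vector DWLS estimation fits.  The asymptotic
#' covariance of the stacked moments is assembled from the per-person
#' influence functions of the pairwise-likelihood estimating equations
#' (thresholds enter the correlation influences through the two-stage
#' plug-in correction), so that `acov/n` approximates the sampling
#' covariance, diagonal entries match per-moment squared standard errors, and
#' off-diagonal blocks carry the shared-person dependence that robust test
#' statistics need.
#'
#' @param data A `latsem_data` object, or an integer matrix of item codes.
#' @param variables Column names to use (default: all ability then anxiety
#'   columns when `data` is a `latsem_data`).
#' @return An object of class `latsem_moments`: fields `thresholds` (list per
#'   variable), `rho` (correlation matrix), `moments` (stacked vector:
#'   thresholds then strict-lower-triangle correlations, column-major),
#'   `scores` (n x n_moments influence matrix), `n`, `n_cat`, `boundary`
#'   (logical matrix of clipped pairs), `se` (per-moment standard errors).
#' @export
estimate_moments <- function(data, variables = NULL) {
  if (inherits(data, "latsem_data")) {
    m <- cbind(data$ability,
               if (ncol(data$anxiety)) data$anxiety else NULL)
  } else m <- as.matrix(data)
  if (!is.null(variables)) m <- m[, variables, drop = FALSE]
  vars <- colnames(m)
  if (is.null(vars)) vars <- colnames(m) <- paste0("v", seq_len(ncol(m)))
  n <- nrow(m); p <- ncol(m)

  # per-variable category structure; codes are remapped to 1..K dropping
  # empty categories (collapse contract of estimate_thresholds)
  levs <- lapply(seq_len(p), function(j) sort(unique(m[, j])))
  ncat <- vapply(levs, length, 1L)
  if (any(ncat < 2))
    ls_stop(sprintf("degenerate variable(s): %s",
                    paste(vars[ncat < 2], collapse = ", ")),
            "latsem_degenerate_error")
  mc <- vapply(seq_len(p), function(j) match(m[, j], levs[[j]]),
               integer(n))
  if (n == 1L) mc <- matrix(mc, nrow = 1L)

  thresholds <- vector("list", p)
  thr_infl <- vector("list", p)   # per-variable n x (ncat-1) influence
  for (j in seq_len(p)) {
    counts <- tabulate(mc[, j], ncat[j])
    tau <- qnorm(cumsum(counts[-ncat[j]]) / n)
    thresholds[[j]] <- tau
    Fc <- cumsum(counts[-ncat[j]]) / n
    ind <- outer(mc[, j], seq_len(ncat[j] - 1), "<=")
    thr_infl[[j]] <- sweep(sweep(ind, 2, Fc), 2, dnorm(tau), "/")
  }
  names(thresholds) <- vars

  n_thr <- sum(ncat - 1)
  n_pair <- p * (p - 1) / 2
  S <- matrix(0, n, n_thr + n_pair)
  thr_off <- c(0L, cumsum(ncat - 1L))
  for (j in seq_len(p))
    S[, (thr_off[j] + 1):thr_off[j + 1]] <- thr_infl[[j]]

  rho <- diag(1, p); se_rho <- matrix(NA_real_, p, p)
  boundary <- matrix(FALSE, p, p)
  col <- n_thr
  for (b in seq_len(p - 1)) {
    for (a in (b + 1):p) {
      col <- col + 1L
      tab <- matrix(tabulate((mc[, a] - 1L) * ncat[b] + mc[, b],
                             ncat[a] * ncat[b]),
                    nrow = ncat[a], ncol = ncat[b], byrow = TRUE)
      pc <- tryCatch(polychoric(tab), latsem_error = function(e)
        ls_stop(sprintf("pair (%s, %s): %s", vars[a], vars[b],
                        conditionMessage(e)), "latsem_estimation_error"))
      rho[a, b] <- rho[b, a] <- pc$rho
      se_rho[a, b] <- se_rho[b, a] <- pc$se
      boundary[a, b] <- boundary[b, a] <- pc$boundary
      info <- cpp_pair_info(thresholds[[a]], thresholds[[b]], pc$rho)
      psi_i <- info$psi[cbind(mc[, a], mc[, b])]
      corr <- cbind(thr_infl[[a]], thr_infl[[b]]) %*% info$H_rt
      if (info$H_rr < 0)
        S[, col] <- -(psi_i + corr) / info$H_rr
      # boundary pairs keep a zero influence column: their sampling
      # variability is not identified; W falls back to a unit weight there
    }
  }

  nm <- moment_names(vars, ncat)
  moments <- c(unlist(thresholds),
               rho[lower.tri(rho)])
  names(moments) <- colnames(S) <- nm
  gamma_diag <- colSums(S^2) / n
  se <- sqrt(gamma_diag / n)
  structure(list(variables = vars, n = n, n_cat = ncat,
                 thresholds = thresholds, rho = rho, se_rho = se_rho,
                 boundary = boundary, moments = moments, scores = S,
                 gamma_diag = gamma_diag, se = se),
            class = "latsem_moments")
}

#' @export
print.latsem_moments <- function(x, ...) {
  cat(sprintf("latsem_moments: %d variables, n = %d, %d thresholds + %d correlations\n",
              length(x$variables), x$n, sum(x$n_cat - 1),
              length(x$moments) - sum(x$n_cat - 1)))
  if (any(x$boundary[lower.tri(x$boundary)]))
    cat(sprintf("  %d pair(s) clipped at the +/-0.999 boundary\n",
                sum(x$boundary[lower.tri(x$boundary)])))
  invisible(x)
}

#' Asymptotic covariance matrix of the stacked moments
#'
#' Materializes `Gamma = crossprod(scores)/n`, scaled so that `Gamma/n` is
#' the sampling covariance of the moment vector.  For large variable counts
#' prefer the score-matrix products the fitting functions use internally.
#'
#' @param moments A `latsem_moments` object.
#' @return Symmetric matrix, rows/columns named like the moment vector.
#' @export
moment_acov <- function(moments) {
  stopifnot(inherits(moments, "latsem_moments"))
  crossprod(moments$scores) / moments$n
}

#' Write a moment set as a CSV pair
#'
#' `<stem>_thresholds.csv` holds one row per threshold (variable, index,
#' estimate, se); `<stem>_correlations.csv` one row per pair (var1, var2,
#' rho, se, boundary).
#'
#' @param moments A `latsem_moments` object.
#' @param stem Output path stem.
#' @export
write_moments <- function(moments, stem) {
  thr <- do.call(rbind, lapply(seq_along(moments$variables), function(j) {
    tau <- moments$thresholds[[j]]
    if (!length(tau)) return(NULL)
    data.frame(variable = moments$variables[j], index = seq_along(tau),
               estimate = tau, stringsAsFactors = FALSE)
  }))
  n_thr <- sum(moments$n_cat - 1)
  thr$se <- moments$se[seq_len(n_thr)]
  write.csv(thr, paste0(stem, "_thresholds.csv"), row.names = FALSE)
  p <- length(moments$variables)
  lt <- which(lower.tri(diag(p)), arr.ind = TRUE)
  cors <- data.frame(var1 = moments$variables[lt[, 1]],
                     var2 = moments$variables[lt[, 2]],
                     rho = moments$rho[lt],
                     se = moments$se_rho[lt],
                     boundary = moments$boundary[lt],
                     stringsAsFactors = FALSE)
  write.csv(cors, paste0(stem, "_correlations.csv"), row.names = FALSE)
  invisible(stem)
}
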