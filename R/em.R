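#' Expectation-maximization imputation under a multivariate normal model
#'
#' Missing entries are imputed by the E-M algorithm for an incomplete
#' multivariate normal sample: the E-step replaces each row's missing
#' block with its conditional expectation given the observed block and
#' the current mean/covariance (accumulating the conditional covariance
#' into the sufficient statistics), the M-step re-estimates the mean and
#' covariance, and iteration stops when the largest parameter change
#' falls below `tolerance` or after `max_iter` iterations.  Observed
#' entries are never altered and the procedure is deterministic.  The
#' observed-data log-likelihood is monitored and must be non-decreasing
#' (checked every iteration); a singular covariance is ridge-regularized.
#'
#' @param x numeric matrix or data.frame with `NA`s (columns with more
#'   than 50% missing are refused).
#' @param tolerance convergence threshold on the parameter change
#'   (default 1e-6).
#' @param max_iter iteration cap (default 500); non-convergence returns
#'   the current result with a warning and `converged = FALSE`.
#' @param ridge ridge added to the covariance diagonal when it is
#'   numerically singular.
#' @return The completed data (same class as the input) with attributes
#'   `loglik` (per-iteration observed-data log-likelihood), `converged`,
#'   `iterations`, `mu`, `sigma`.
#' @export
em_impute <- function(x, tolerance = 1e-6, max_iter = 500, ridge = 1e-8) {
  is_df <- is.data.frame(x)
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  n <- nrow(xm); p <- ncol(xm)
  miss <- is.na(xm)
  if (!any(miss)) {
    attr(x, "loglik") <- numeric(0)
    attr(x, "converged") <- TRUE
    attr(x, "iterations") <- 0L
    return(x)
  }
  mfrac <- colMeans(miss)
  if (any(mfrac >= 0.5))
    stop("columns with >= 50% missing: ",
         paste(colnames(xm)[mfrac >= 0.5], collapse = ", "))
  if (any(rowSums(!miss) == 0)) stop("rows with no observed values")

  mu <- colMeans(xm, na.rm = TRUE)
  sigma <- stats::cov(xm, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0
  sigma <- make_pd(sigma, ridge)

  patterns <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  by_pat <- split(seq_len(n), patterns)

  loglik <- numeric(0)
  converged <- FALSE
  xc <- xm
  for (it in seq_len(max_iter)) {
    # E-step: conditional means; accumulate conditional covariance
    cc_acc <- matrix(0, p, p)
    ll <- 0
    for (rows in by_pat) {
      mi <- miss[rows[1], ]
      oi <- !mi
      xo <- xm[rows, oi, drop = FALSE]
      So <- sigma[oi, oi, drop = FALSE]
      ll <- ll + sum(dmvnorm_log(xo, mu[oi], So))
      if (any(mi)) {
        Soi <- chol2inv(chol(make_pd(So, ridge)))
        B <- sigma[mi, oi, drop = FALSE] %*% Soi
        cond_mean <- matrix(mu[mi], nrow = length(rows),
                            ncol = sum(mi), byrow = TRUE) +
          sweep(xo, 2, mu[oi]) %*% t(B)
        xc[rows, mi] <- cond_mean
        cond_cov <- sigma[mi, mi, drop = FALSE] -
          B %*% sigma[oi, mi, drop = FALSE]
        cc_acc[mi, mi] <- cc_acc[mi, mi] + length(rows) * cond_cov
      }
    }
    loglik <- c(loglik, ll)
    if (it > 1 && ll < loglik[it - 1] - 1e-6 * (abs(ll) + 1))
      warning("observed-data log-likelihood decreased at iteration ", it)
    # M-step
    mu_new <- colMeans(xc)
    sigma_new <- (crossprod(sweep(xc, 2, mu_new)) + cc_acc) / n
    sigma_new <- make_pd(sigma_new, ridge)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("E-M did not converge in ", max_iter, " iterations")
  out <- if (is_df) {
    x[] <- as.data.frame(xc)
    x
  } else xc
  attr(out, "loglik") <- loglik
  attr(out, "converged") <- converged
  attr(out, "iterations") <- length(loglik)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

# log-density of rows of x under N(mu, S)
dmvnorm_log <- function(x, mu, S) {
  x <- as.matrix(x)
  p <- ncol(x)
  ch <- chol(make_pd(S, 1e-10))
  z <- forwardsolve(t(ch), t(sweep(x, 2, mu)))
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

make_pd <- function(S, ridge) {
  S <- (S + t(S)) / 2
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  while (!ok) {
    S <- S + diag(max(ridge, 1e-10) * max(1, mean(diag(S))), nrow(S))
    ridge <- ridge * 10
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  }
  S
}

#' Impute the structural metric columns of a cohort table
#'
#' Applies [em_impute()] to the structural (per-branch) metric columns
#' only — demographics and functional variables are never missing by
#' construction.
#'
#' @param cohort a `cohort_table`.
#' @param ... passed to [em_impute()].
#' @return The cohort with structural columns completed; E-M diagnostics
#'   are copied to attributes `em_loglik`, `em_converged`.
#' @export
impute_structural <- function(cohort, ...) {
  cols <- structural_columns(cohort)
  if (!length(cols)) stop("no structural columns found")
  done <- em_impute(as.matrix(cohort[cols]), ...)
  cohort[cols] <- as.data.frame(unclass(done))
  attr(cohort, "em_loglik") <- attr(done, "loglik")
  attr(cohort, "em_converged") <- attr(done, "converged")
  cohort
}
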