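# Single-random-intercept Gaussian linear mixed model, fit by REML with the
# variance ratio profiled out, plus Satterthwaite degrees of freedom for
# fixed-effect t tests. One grouping factor keeps the problem 1-D, which a
# grid + golden-section refinement solves robustly, including the boundary
# at zero group variance.

# REML profile log-likelihood at variance ratio lambda = s2_group / s2_resid
reml_profile <- function(lambda, y, X, ZZt) {
  n <- length(y); p <- ncol(X)
  V0 <- diag(n) + lambda * ZZt
  cV <- chol(V0)
  Vi_X <- backsolve(cV, backsolve(cV, X, transpose = TRUE))
  Vi_y <- backsolve(cV, backsolve(cV, y, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(cV, backsolve(cV, r, transpose = TRUE))
  q <- drop(crossprod(r, Vi_r))
  s2e <- q / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * s2e) +
                  2 * sum(log(diag(cV))) +
                  determinant(XtViX, logarithm = TRUE)$modulus +
                  (n - p))
  ll <- as.numeric(ll)
  if (!is.finite(ll)) ll <- -1e10  # degenerate corner; keep optimize sane
  list(ll = ll, beta = drop(beta), s2e = s2e,
       XtViX = XtViX, lambda = lambda)
}

# full REML log-likelihood at theta = (s2_group, s2_resid)
reml_loglik_theta <- function(s2g, s2e, y, X, ZZt) {
  n <- length(y); p <- ncol(X)
  V <- s2e * diag(n) + s2g * ZZt
  cV <- chol(V)
  Vi_X <- backsolve(cV, backsolve(cV, X, transpose = TRUE))
  Vi_y <- backsolve(cV, backsolve(cV, y, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(cV, backsolve(cV, r, transpose = TRUE))
  as.numeric(-0.5 * (2 * sum(log(diag(cV))) +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       drop(crossprod(r, Vi_r)) +
                       (n - p) * log(2 * pi)))
}

# c' (X' V^{-1} X)^{-1} c for all unit contrasts (diagonal of cov(beta))
beta_cov_theta <- function(s2g, s2e, X, ZZt) {
  n <- nrow(X)
  V <- s2e * diag(n) + s2g * ZZt
  cV <- chol(V)
  Vi_X <- backsolve(cV, backsolve(cV, X, transpose = TRUE))
  solve(crossprod(X, Vi_X))
}

#' Fit a Gaussian random-intercept mixed model by REML
#'
#' Fits `y = X beta + Z u + e` with one random intercept per group,
#' `u ~ N(0, s2_group)`, `e ~ N(0, s2_resid)`. The variance ratio is
#' profiled and optimised on a log grid with golden-section refinement;
#' the boundary (zero group variance) is handled explicitly and reported
#' via the `singular` flag. Per-coefficient t tests use Satterthwaite
#' degrees of freedom obtained by the delta method on the REML
#' variance-component covariance (numeric derivatives in log-variance
#' coordinates); at the boundary the df collapse to the ordinary
#' least-squares residual df.
#'
#' @param y numeric response.
#' @param X fixed-effects design matrix (including intercept).
#' @param group factor of group (donor) membership, length `nrow(X)`.
#' @return object of class `mosaic_lmm`: coefficient table (`estimate`,
#'   `se`, `df`, `t`, `p`), variance components, `vcov_beta`, and
#'   `converged`/`singular` flags.
#' @export
fit_lmm <- function(y, X, group) {
  group <- droplevels(as.factor(group))
  n <- length(y); p <- qr(X)$rank
  if (ncol(X) != p) stop("fixed-effects design matrix is rank deficient",
                         call. = FALSE)
  if (stats::var(y) < .Machine$double.eps) {
    stop("response is constant; mixed model not identifiable",
         call. = FALSE)
  }
  Z <- stats::model.matrix(~ 0 + group)
  ZZt <- tcrossprod(Z)
  prof <- function(l) reml_profile(l, y, X, ZZt)$ll

  grid <- c(0, 10^seq(-4, 4, length.out = 41))
  ll_grid <- vapply(grid, prof, numeric(1))
  i <- which.max(ll_grid)
  if (i == 1) {
    lambda_hat <- 0
    # confirm the boundary: refine over the first open interval
    o <- stats::optimize(prof, c(1e-8, grid[2]), maximum = TRUE)
    if (o$objective > ll_grid[1] + 1e-8) lambda_hat <- o$maximum
  } else {
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    o <- stats::optimize(prof, c(max(lo, 1e-10), hi), maximum = TRUE)
    lambda_hat <- if (o$objective >= ll_grid[i]) o$maximum else grid[i]
  }
  fit <- reml_profile(lambda_hat, y, X, ZZt)
  s2e <- fit$s2e
  s2g <- lambda_hat * s2e
  singular <- s2g < 1e-8 * (s2g + s2e)
  vcov_beta <- beta_cov_theta(s2g, s2e, X, ZZt)
  se <- sqrt(diag(vcov_beta))

  df <- satterthwaite_df(s2g, s2e, y, X, ZZt, n - ncol(X), singular)
  est <- fit$beta
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df)
  coefs <- data.frame(term = colnames(X), estimate = est, se = se,
                      df = df, t = tval, p = pval,
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 varcomp = c(group = s2g, residual = s2e),
                 vcov_beta = vcov_beta,
                 n = n, n_groups = nlevels(group),
                 converged = TRUE, singular = singular),
            class = "mosaic_lmm")
}

# Satterthwaite df per coefficient: df = 2 f^2 / (g' A g), f = var(c'beta),
# g = gradient of f in log-variance coordinates, A = inverse negative
# Hessian of the REML log-likelihood in the same coordinates.
satterthwaite_df <- function(s2g, s2e, y, X, ZZt, df_resid, singular) {
  pfe <- ncol(X)
  if (singular) return(rep(df_resid, pfe))
  psi <- log(c(s2g, s2e))
  ll_psi <- function(ps) reml_loglik_theta(exp(ps[1]), exp(ps[2]), y, X, ZZt)
  H <- num_hessian(ll_psi, psi, h = 1e-4)
  A <- tryCatch(solve(-H), error = function(e) NULL)
  fallback <- rep(df_resid, pfe)
  if (is.null(A) || any(!is.finite(A)) || any(diag(A) <= 0)) {
    return(fallback)
  }
  fvar <- function(ps) diag(beta_cov_theta(exp(ps[1]), exp(ps[2]), X, ZZt))
  h <- 1e-5
  g1 <- (fvar(psi + c(h, 0)) - fvar(psi - c(h, 0))) / (2 * h)
  g2 <- (fvar(psi + c(0, h)) - fvar(psi - c(0, h))) / (2 * h)
  f0 <- fvar(psi)
  df <- vapply(seq_len(pfe), function(j) {
    g <- c(g1[j], g2[j])
    denom <- drop(t(g) %*% A %*% g)
    if (!is.finite(denom) || denom <= 0) return(df_resid)
    2 * f0[j]^2 / denom
  }, numeric(1))
  pmin(pmax(df, 1e-3), df_resid * 50)
}

num_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- rep(0, k); ei[i] <- h; ej[j] <- h
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f(x) + f(x - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) -
             f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

#' @export
print.mosaic_lmm <- function(x, ...) {
  cat("Random-intercept Gaussian mixed model (REML)\n")
  cat(sprintf("  %d observations, %d groups; variance components: group = %.4g, residual = %.4g%s\n",
              x$n, x$n_groups, x$varcomp["group"], x$varcomp["residual"],
              if (x$singular) " (singular: boundary fit)" else ""))
  printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "df", "t", "p")]),
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}
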