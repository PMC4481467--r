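#' Fit the null polygenic mixed model by maximum likelihood
#'
#' Fits y = X alpha + h + e with h ~ N(0, sigma_h^2 R) and
#' e ~ N(0, sigma_e^2 I), so the phenotype covariance is
#' Omega = sigma_h^2 R + sigma_e^2 I.  The relationship matrix is
#' eigendecomposed once, R = U D U', the likelihood is profiled over alpha
#' and the total variance, and the remaining one-dimensional problem in the
#' heritability h^2 = sigma_h^2 / (sigma_h^2 + sigma_e^2) is solved by
#' bounded search on [0, 1 - 1e-6].  The fit is reused by every regional
#' test for the same phenotype: alpha and Omega are held at their null
#' estimates throughout.
#'
#' @param y numeric phenotype vector (no missing values).
#' @param X covariate matrix including the intercept; `NULL` means
#'   intercept only.
#' @param R relationship matrix (2 x kinship or genomic); ignored when
#'   `eig` is supplied.
#' @param eig optional precomputed `eigen(R, symmetric = TRUE)`; lets many
#'   phenotype replicates on the same sample share the O(n^3) step.
#' @param reml use REML instead of ML for the variance components.
#' @param sigma_h2,sigma_e2 when both are supplied the variance components
#'   are fixed at these values (known-Omega mode; only alpha is estimated).
#' @return Object of class `flmm_null` with components `alpha`, `sigma_h2`,
#'   `sigma_e2`, `h2`, `loglik`, `eig`, `n`, `c` and cached rotated data.
#' @examples
#' ped <- sim_pedigree(sim_scenario(n_families = 2))
#' R <- kinship_matrix(ped)
#' y <- sim_trait(R = R, scenario = sim_scenario(h2 = 0.29))$y
#' fit <- flmm_null(y, R = R)
#' summary(fit)
#' @export
flmm_null <- function(y, X = NULL, R = NULL, eig = NULL, reml = FALSE,
                      sigma_h2 = NULL, sigma_e2 = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  if (stats::var(y) == 0) stop("degenerate phenotype")
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  cc <- ncol(X)
  if (nrow(X) != n) stop("dimension mismatch between y and X")
  if (n <= cc) stop("need n > number of covariates")
  if (qr(X)$rank < cc) stop("covariate matrix is rank-deficient")
  if (is.null(eig)) {
    if (is.null(R)) stop("supply R or its eigendecomposition")
    R <- as.matrix(R)
    if (nrow(R) != n) stop("dimension mismatch between y and R")
    eig <- eigen(R, symmetric = TRUE)
  }
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  Uty <- crossprod(U, y)
  UtX <- crossprod(U, X)

  # profile log-likelihood in h2: for fixed h2 the weights are
  # d_i = h2 * lambda_i + (1 - h2); alpha by GLS, total variance in closed form
  profile <- function(h2) {
    d <- h2 * lam + (1 - h2)
    w <- 1 / d
    XtWX <- crossprod(UtX, w * UtX)
    XtWy <- crossprod(UtX, w * Uty)
    alpha <- solve(XtWX, XtWy)
    r <- Uty - UtX %*% alpha
    rss <- sum(w * r^2)
    if (reml) {
      s2 <- rss / (n - cc)
      ll <- -0.5 * ((n - cc) * log(2 * pi * s2) + sum(log(d)) +
                      determinant(XtWX, logarithm = TRUE)$modulus + (n - cc))
    } else {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n)
    }
    list(ll = as.numeric(ll), alpha = alpha, s2 = s2)
  }

  if (!is.null(sigma_h2) && !is.null(sigma_e2)) {
    if (sigma_e2 <= 0) stop("sigma_e2 must be positive")
    d <- sigma_h2 * lam + sigma_e2
    w <- 1 / d
    alpha <- solve(crossprod(UtX, w * UtX), crossprod(UtX, w * Uty))
    r <- Uty - UtX %*% alpha
    ll <- -0.5 * (n * log(2 * pi) + sum(log(d)) + sum(w * r^2))
    h2 <- sigma_h2 / (sigma_h2 + sigma_e2)
    fixed <- TRUE
  } else {
    if (max(lam) - min(lam) < 1e-12) {
      h2 <- 0  # R proportional to I: only the total variance is identifiable
    } else {
      opt <- stats::optimize(function(g) profile(g)$ll,
                             interval = c(0, 1 - 1e-6),
                             maximum = TRUE, tol = 1e-8)
      h2 <- opt$maximum
      # accept boundary solutions when they dominate the interior optimum
      for (b in c(0, 1 - 1e-6))
        if (profile(b)$ll > profile(h2)$ll) h2 <- b
    }
    pr <- profile(h2)
    alpha <- pr$alpha
    sigma_h2 <- pr$s2 * h2
    sigma_e2 <- pr$s2 * (1 - h2)
    ll <- pr$ll
    fixed <- FALSE
  }
  rownames(alpha) <- colnames(X)
  structure(list(alpha = drop(alpha), sigma_h2 = sigma_h2,
                 sigma_e2 = sigma_e2, h2 = h2, loglik = ll,
                 eig = list(values = lam, vectors = U),
                 n = n, c = cc, reml = reml, fixed_vc = fixed,
                 y = y, X = X, Uty = Uty, UtX = UtX),
            class = "flmm_null")
}

# Omega^{-1/2}-rotated weights for the cached eigendecomposition
.omega_dinv <- function(fit) 1 / (fit$sigma_h2 * fit$eig$values + fit$sigma_e2)

#' Whiten a vector or matrix under the fitted null covariance
#'
#' Returns `D^{-1/2} U' M` where `Omega = U D U'` from the cached
#' eigendecomposition, so that `crossprod(whiten(fit, A), whiten(fit, B))`
#' equals `A' Omega^{-1} B` and weighted residual sums become ordinary sums
#' of squares.
#'
#' @param fit a [flmm_null()] fit.
#' @param M numeric vector or matrix with `fit$n` rows.
#' @return whitened matrix (or column vector).
#' @export
whiten <- function(fit, M) {
  stopifnot(inherits(fit, "flmm_null"))
  M <- as.matrix(M)
  if (nrow(M) != fit$n) stop("dimension mismatch in whiten()")
  sqrt(.omega_dinv(fit)) * crossprod(fit$eig$vectors, M)
}

#' @export
print.flmm_null <- function(x, ...) {
  cat("Null polygenic linear mixed model (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat(sprintf("  n = %d, covariates = %d\n", x$n, x$c))
  cat(sprintf("  sigma_h^2 = %.4f, sigma_e^2 = %.4f, h^2 = %.4f\n",
              x$sigma_h2, x$sigma_e2, x$h2))
  cat(sprintf("  log-likelihood = %.4f\n", x$loglik))
  invisible(x)
}

#' @export
summary.flmm_null <- function(object, ...) {
  ans <- list(alpha = object$alpha, sigma_h2 = object$sigma_h2,
              sigma_e2 = object$sigma_e2, h2 = object$h2,
              loglik = object$loglik, n = object$n, c = object$c,
              reml = object$reml)
  class(ans) <- "summary.flmm_null"
  ans
}

#' @export
print.summary.flmm_null <- function(x, ...) {
  cat("Null polygenic linear mixed model\n")
  cat("Fixed effects:\n")
  print(x$alpha)
  cat(sprintf("Variance components: sigma_h^2 = %.4f, sigma_e^2 = %.4f\n",
              x$sigma_h2, x$sigma_e2))
  cat(sprintf("Heritability h^2 = %.4f; log-likelihood (%s) = %.4f\n",
              x$h2, if (x$reml) "REML" else "ML", x$loglik))
  invisible(x)
}

#' @export
coef.flmm_null <- function(object, ...) object$alpha

#' @export
logLik.flmm_null <- function(object, ...) {
  structure(object$loglik, df = object$c + 2L, class = "logLik")
}

#' @export
fitted.flmm_null <- function(object, ...) drop(object$X %*% object$alpha)

#' @export
residuals.flmm_null <- function(object, type = c("response", "whitened"),
                                ...) {
  type <- match.arg(type)
  r <- object$y - fitted(object)
  if (type == "whitened") drop(whiten(object, r)) else r
}

#' Simulate phenotypes from a fitted null model
#'
#' @param object a [flmm_null()] fit.
#' @param nsim number of replicate phenotype vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return `n x nsim` matrix of phenotypes drawn from
#'   N(X alpha, sigma_h^2 R + sigma_e^2 I).
#' @export
simulate.flmm_null <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  sd_rot <- sqrt(object$sigma_h2 * object$eig$values + object$sigma_e2)
  Z <- matrix(stats::rnorm(n * nsim), n, nsim) * sd_rot
  drop(object$X %*% object$alpha) + object$eig$vectors %*% Z
}
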