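# Independent oracles used across the test files.

# Cox-de Boor recursive B-spline evaluation; independent of splineDesign.
deboor_eval <- function(knots, t, K, ord = 4L) {
  tmax <- max(knots)
  bspl <- function(tt, i, k) {
    if (k == 1L) {
      lo <- knots[i]; hi <- knots[i + 1L]
      return(as.numeric((tt >= lo & tt < hi) |
                          (tt == hi & hi == tmax & lo < hi)))
    }
    d1 <- knots[i + k - 1L] - knots[i]
    d2 <- knots[i + k] - knots[i + 1L]
    a <- if (d1 > 0) (tt - knots[i]) / d1 * bspl(tt, i, k - 1L) else 0
    b <- if (d2 > 0) (knots[i + k] - tt) / d2 * bspl(tt, i + 1L, k - 1L)
         else 0
    a + b
  }
  vapply(seq_len(K), function(i) bspl(t, i, ord), numeric(length(t)))
}

# adaptive-quadrature oracle for the basis cross-integral
quad_cross <- function(sysG, sysB) {
  M <- matrix(0, sysG$K, sysB$K)
  for (i in seq_len(sysG$K)) {
    for (j in seq_len(sysB$K)) {
      f <- function(t) eval_basis(sysG, t)[, i] * eval_basis(sysB, t)[, j]
      M[i, j] <- stats::integrate(f, 0, 1, rel.tol = 1e-12,
                                  abs.tol = 1e-13,
                                  subdivisions = 500L)$value
    }
  }
  M
}

# exact Gram matrix of the cubic Bernstein polynomials:
# int_0^1 b_{3,i} b_{3,j} dt = C(3,i) C(3,j) / (7 C(6,i+j))
bernstein_gram <- function() {
  M <- matrix(0, 4L, 4L)
  for (i in 0:3) for (j in 0:3)
    M[i + 1L, j + 1L] <- choose(3, i) * choose(3, j) /
      (7 * choose(6, i + j))
  M
}

# dense-matrix ML null fit: direct Omega inversion, same 1-D profile in h2
dense_null_fit <- function(y, X, R) {
  n <- length(y)
  prof <- function(h2) {
    Om <- h2 * R + (1 - h2) * diag(n)
    Oi <- solve(Om)
    a <- solve(t(X) %*% Oi %*% X, t(X) %*% Oi %*% y)
    r <- y - X %*% a
    s2 <- drop(t(r) %*% Oi %*% r) / n
    ll <- -0.5 * (n * log(2 * pi * s2) +
                    as.numeric(determinant(Om, TRUE)$modulus) + n)
    list(ll = ll, alpha = a, s2 = s2)
  }
  opt <- stats::optimize(function(g) prof(g)$ll, c(0, 1 - 1e-6),
                         maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  for (b in c(0, 1 - 1e-6)) if (prof(b)$ll > prof(h2)$ll) h2 <- b
  p <- prof(h2)
  list(alpha = drop(p$alpha), sigma_h2 = p$s2 * h2,
       sigma_e2 = p$s2 * (1 - h2), h2 = h2, loglik = p$ll,
       profile_ll = function(g) prof(g)$ll,
       profile_fit = prof)
}

# dense GLS regional statistics with explicit Omega: RSS under the null
# GLS intercept, joint GLS of y on [X, Z], and the projection score test
dense_region_stats <- function(y, X, Z, Omega) {
  n <- length(y)
  Oi <- solve(Omega)
  XtOiX <- t(X) %*% Oi %*% X
  a0 <- solve(XtOiX, t(X) %*% Oi %*% y)
  r0 <- y - X %*% a0
  rss0 <- drop(t(r0) %*% Oi %*% r0)
  A <- cbind(X, Z)
  cf <- solve(t(A) %*% Oi %*% A, t(A) %*% Oi %*% y)
  r1 <- y - A %*% cf
  rss1 <- drop(t(r1) %*% Oi %*% r1)
  P <- Oi - Oi %*% X %*% solve(XtOiX, t(X) %*% Oi)
  Uv <- t(Z) %*% Oi %*% r0
  V <- t(Z) %*% P %*% Z
  r <- ncol(Z)
  df2 <- n - r - 1L
  list(RSS0 = rss0, RSS1 = rss1,
       beta = drop(cf)[-seq_len(ncol(X))],
       F = ((rss0 - rss1) / r) / (rss1 / df2), df1 = r, df2 = df2,
       score = drop(t(Uv) %*% solve(V, Uv)))
}

# small family sample shared by several files
family_sample <- function(n_families = 1L, seed = 1L) {
  set.seed(seed)
  sc <- sim_scenario(n_families = n_families)
  ped <- sim_pedigree(sc)
  R <- kinship_matrix(ped)
  list(sc = sc, ped = ped, R = R,
       eig = eigen(R, symmetric = TRUE), n = nrow(R))
}
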