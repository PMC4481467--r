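#' Declare a basis system on [0, 1]
#'
#' A basis system is a family of \code{K} functions on the unit interval used
#' either to smooth genotype dosages across a region (the genetic variant
#' functions, GVF) or to smooth the variant effects (the beta-smoothing
#' function, BSF).  Two families are supported: cubic B-splines on equally
#' spaced knots and the orthonormal Fourier system
#' \{1, sqrt(2) sin(2 pi k t), sqrt(2) cos(2 pi k t)\}.
#'
#' @param family `"bspline"` or `"fourier"`.
#' @param K number of basis functions.  The Fourier family requires an odd
#'   `K` (the constant plus `(K-1)/2` sine/cosine pairs); the B-spline family
#'   requires `K >= 4` (cubic splines, order 4).
#' @param order spline order; fixed at 4 (cubic) and ignored for Fourier.
#' @return An object of class `basis_system`.
#' @examples
#' fb <- basis_system("fourier", 25)
#' bb <- basis_system("bspline", 15)
#' @export
basis_system <- function(family = c("bspline", "fourier"), K, order = 4L) {
  family <- match.arg(family)
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L)
    stop("K must be a positive integer")
  if (family == "fourier") {
    if (K %% 2L == 0L)
      stop("Fourier basis requires odd K (constant + sine/cosine pairs)")
    knots <- NULL
  } else {
    if (order != 4L)
      stop("only cubic B-splines (order 4) are supported")
    if (K < 4L)
      stop("B-spline basis requires K >= 4")
    # K functions of order 4 <=> K - 4 equally spaced interior knots
    breaks <- seq(0, 1, length.out = K - 2L)
    knots <- c(rep(0, 3L), breaks, rep(1, 3L))
  }
  structure(list(family = family, K = K, order = 4L, knots = knots),
            class = "basis_system")
}

#' @export
print.basis_system <- function(x, ...) {
  cat(sprintf("<basis_system: %s, K = %d%s>\n", x$family, x$K,
              if (x$family == "bspline") ", order 4" else ""))
  invisible(x)
}

#' Map physical variant positions to the unit interval
#'
#' Applies the affine map t -> (t - t1) / (tm - t1) so the region spans
#' [0, 1].  A single-variant region maps to the midpoint 0.5.  Runs of exact
#' duplicate coordinates are spread evenly between the scaled values of
#' their distinct neighbours (order preserving) so the result is strictly
#' increasing, as basis evaluation needs distinct points.
#'
#' @param raw sorted physical base-pair coordinates (non-decreasing).
#' @return Object of class `scaled_positions` with elements `raw` and
#'   `scaled`.
#' @export
scale_positions <- function(raw) {
  if (length(raw) == 0L) stop("empty region")
  raw <- as.numeric(raw)
  if (is.unsorted(raw)) stop("positions must be sorted non-decreasingly")
  m <- length(raw)
  if (m == 1L) {
    scaled <- 0.5
  } else if (raw[m] == raw[1L]) {
    # fully degenerate region: spread evenly over the whole interval
    scaled <- seq(0, 1, length.out = m)
  } else {
    scaled <- (raw - raw[1L]) / (raw[m] - raw[1L])
    scaled <- .separate_ties(scaled)
  }
  structure(list(raw = raw, scaled = scaled), class = "scaled_positions")
}

# spread each run of duplicated scaled values across the open interval
# between the half-way points towards its distinct neighbours; runs touching
# the boundary keep the boundary value (scaled[1] = 0, scaled[m] = 1)
.separate_ties <- function(s) {
  m <- length(s)
  r <- rle(s)
  if (all(r$lengths == 1L)) return(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- s
  for (i in seq_along(r$lengths)) {
    k <- r$lengths[i]
    if (k == 1L) next
    v <- r$values[i]
    a <- if (i == 1L) v else (r$values[i - 1L] + v) / 2
    b <- if (i == length(r$values)) v else (v + r$values[i + 1L]) / 2
    idx <- starts[i]:ends[i]
    if (i == 1L) {
      out[idx] <- seq(v, b, length.out = k + 1L)[1:k]
    } else if (i == length(r$values)) {
      out[idx] <- seq(a, v, length.out = k + 1L)[2:(k + 1L)]
    } else {
      out[idx] <- seq(a, b, length.out = k + 2L)[2:(k + 1L)]
    }
  }
  if (is.unsorted(out, strictly = TRUE))
    stop("could not resolve duplicated positions")
  out
}

#' Evaluate a basis system
#'
#' @param sys a [basis_system()].
#' @param t evaluation points in \[0, 1\].
#' @return `length(t) x K` matrix of basis values.
#' @export
eval_basis <- function(sys, t) {
  stopifnot(inherits(sys, "basis_system"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop("evaluation points must lie in [0, 1]")
  if (sys$family == "fourier") {
    K <- sys$K
    # the system is 1-periodic: evaluate t = 1 exactly as t = 0, so the
    # endpoint congruence of scaled positions is an exact (deterministic)
    # rank deficiency rather than floating-point noise
    tp <- ifelse(t == 1, 0, t)
    out <- matrix(1, length(t), K)
    if (K > 1L) {
      for (k in seq_len((K - 1L) %/% 2L)) {
        out[, 2L * k]      <- sqrt(2) * sin(2 * pi * k * tp)
        out[, 2L * k + 1L] <- sqrt(2) * cos(2 * pi * k * tp)
      }
    }
    out
  } else {
    splines::splineDesign(sys$knots, t, ord = 4L)
  }
}

#' Cross-integral Gram matrix of two basis systems
#'
#' Computes `W2[i, j] = integral_0^1 phi_i(t) psi_j(t) dt` by composite
#' Gauss--Legendre quadrature on a partition aligned to the B-spline knots
#' (exact for the polynomial pieces; 20 nodes per piece resolve the
#' trigonometric factors far beyond double precision for K <= 25).
#'
#' @param sysG,sysB [basis_system()] objects for the rows and columns.
#' @param nodes Gauss--Legendre nodes per partition piece.
#' @return `sysG$K x sysB$K` matrix.
#' @export
cross_integral <- function(sysG, sysB, nodes = 20L) {
  stopifnot(inherits(sysG, "basis_system"), inherits(sysB, "basis_system"))
  brk <- sort(unique(c(0, 1,
                       sysG$knots, sysB$knots,
                       seq(0, 1, length.out = 13L))))
  brk <- brk[brk >= 0 & brk <= 1]
  W2 <- matrix(0, sysG$K, sysB$K)
  for (i in seq_len(length(brk) - 1L)) {
    if (brk[i + 1L] <= brk[i]) next
    gl <- pracma::gaussLegendre(nodes, brk[i], brk[i + 1L])
    PG <- eval_basis(sysG, gl$x)
    PB <- eval_basis(sysB, gl$x)
    W2 <- W2 + crossprod(PG, gl$w * PB)
  }
  W2
}

#' Build the basis matrices of the functional design
#'
#' Constructs the position-evaluation matrices and the transition matrix
#' `W` that carries the smoothed regional design: `W = Phi (Phi'Phi)^{-1} W2`
#' when a GVF system is present (genotypes smoothed, then effects smoothed),
#' or simply `W = Psi` when only the effect function is smoothed.
#'
#' @param sysG [basis_system()] for the genotype smoothing, or `NULL` for
#'   the BSF-only models.
#' @param sysB [basis_system()] for the effect smoothing.
#' @param pos a [scale_positions()] result.
#' @return list with `Phi` (or NULL), `Psi`, `W1`, `W2`, `W`.
#' @export
build_basis_matrices <- function(sysG, sysB, pos) {
  stopifnot(inherits(pos, "scaled_positions"))
  t <- pos$scaled
  Psi <- eval_basis(sysB, t)
  if (is.null(sysG)) {
    return(list(Phi = NULL, Psi = Psi, W1 = NULL, W2 = NULL, W = Psi))
  }
  Phi <- eval_basis(sysG, t)
  PtP <- crossprod(Phi)
  if (rcond(PtP) < 1e-12)
    stop("GVF basis rank-deficient at these positions")
  W1 <- Phi %*% solve(PtP)
  W2 <- cross_integral(sysG, sysB)
  list(Phi = Phi, Psi = Psi, W1 = W1, W2 = W2, W = W1 %*% W2)
}
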