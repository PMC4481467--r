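#' Construct a region of genotyped variants
#'
#' @param G `n x m` minor-allele dosage matrix (entries 0/1/2; missing
#'   values are imputed by the variant mean dosage).
#' @param positions physical base-pair coordinates, one per variant.
#' @param name region label.
#' @param ids optional variant identifiers.
#' @param drop_monomorphic drop variants with MAF 0 instead of erroring.
#' @return Object of class `flm_region` with elements `name`, `ids`,
#'   `positions` ([scale_positions()] result), `G`, `maf`, `m`, `n`.
#' @export
flm_region <- function(G, positions, name = "region", ids = NULL,
                       drop_monomorphic = FALSE) {
  G <- as.matrix(G)
  if (length(positions) != ncol(G))
    stop("one position per variant required")
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(G)))
  ord <- order(positions)
  G <- G[, ord, drop = FALSE]
  positions <- positions[ord]
  ids <- ids[ord]
  # mean-dosage imputation keeps m stable in the presence of missing calls
  if (anyNA(G)) {
    for (j in which(colSums(is.na(G)) > 0L)) {
      mu <- mean(G[, j], na.rm = TRUE)
      G[is.na(G[, j]), j] <- mu
    }
  }
  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  mono <- maf <= 0
  if (any(mono)) {
    if (!drop_monomorphic && all(mono)) stop("monomorphic region")
    if (!drop_monomorphic) stop("monomorphic variant(s) in region: ",
                                paste(ids[mono], collapse = ", "))
    G <- G[, !mono, drop = FALSE]
    positions <- positions[!mono]
    ids <- ids[!mono]
    maf <- maf[!mono]
    if (ncol(G) == 0L) stop("monomorphic region")
  }
  structure(list(name = name, ids = ids,
                 positions = scale_positions(positions),
                 G = G, maf = maf, m = ncol(G), n = nrow(G)),
            class = "flm_region")
}

#' @export
print.flm_region <- function(x, ...) {
  cat(sprintf("<flm_region '%s': %d individuals, %d variants, MAF %.4g-%.4g>\n",
              x$name, x$n, x$m, min(x$maf), max(x$maf)))
  invisible(x)
}

.MODEL_LABELS <- c("B-B", "0-B", "F-B", "B-F", "0-F", "F-F")

# default basis counts: 15 B-spline, 25 Fourier
.default_K <- function(family) if (family == "fourier") 25L else 15L

.parse_label <- function(label) {
  if (!label %in% .MODEL_LABELS)
    stop("unknown model label: ", label)
  part <- strsplit(label, "-", fixed = TRUE)[[1]]
  fam <- c(B = "bspline", F = "fourier", `0` = "none")
  list(gvf = unname(fam[part[1]]), bsf = unname(fam[part[2]]))
}

#' Effective numbers of basis functions for a region
#'
#' Reduces the requested basis counts so that m >= K_G >= K_beta: each K is
#' capped at the number of variants m; a Fourier K is further reduced to the
#' largest odd value; a B-spline K cannot drop below 4, so for m < 4 any
#' model involving a B-spline basis falls back to the saturated design
#' (the traditional multiple-regression LMM on the raw dosages), as does
#' every model at m = 1 (single-variant Wald test).
#'
#' @param m number of variants in the region.
#' @param label model label, one of `"B-B"`, `"0-B"`, `"F-B"`, `"B-F"`,
#'   `"0-F"`, `"F-F"` (GVF basis - BSF basis, `0` = effect smoothing only).
#' @param K_G,K_beta requested counts; `NULL` uses the defaults
#'   (15 B-spline, 25 Fourier).
#' @return list with `K_G` (NA when no GVF basis), `K_beta`, and
#'   `saturated` (TRUE when the raw-dosage design is used).
#' @export
effective_K <- function(m, label, K_G = NULL, K_beta = NULL) {
  fam <- .parse_label(label)
  if (is.null(K_beta)) K_beta <- .default_K(fam$bsf)
  if (is.null(K_G) && fam$gvf != "none") K_G <- .default_K(fam$gvf)
  reduce <- function(K, family) {
    K <- min(K, m)
    if (family == "fourier" && K %% 2L == 0L) K <- K - 1L
    as.integer(K)
  }
  uses_bspline <- fam$bsf == "bspline" || fam$gvf == "bspline"
  if (m == 1L || (m < 4L && uses_bspline))
    return(list(K_G = NA_integer_, K_beta = as.integer(m), saturated = TRUE))
  KB <- reduce(K_beta, fam$bsf)
  if (fam$gvf == "none") {
    return(list(K_G = NA_integer_, K_beta = KB, saturated = FALSE))
  }
  KG <- reduce(K_G, fam$gvf)
  if (KB > KG) KB <- reduce(KG, fam$bsf)
  list(K_G = KG, K_beta = KB, saturated = FALSE)
}

# memoized W2 cross-integrals, keyed by both systems
.w2_cache <- new.env(parent = emptyenv())
.cross_integral_cached <- function(sysG, sysB) {
  key <- paste(sysG$family, sysG$K, sysB$family, sysB$K, sep = "|")
  got <- .w2_cache[[key]]
  if (is.null(got)) {
    got <- cross_integral(sysG, sysB)
    .w2_cache[[key]] <- got
  }
  got
}

# transition matrix W (m x K) for one model label on one region;
# NULL W means the saturated raw-dosage design.  A B-spline GVF basis can
# be rank-deficient at unfavourable position layouts even when K_G <= m
# (the Schoenberg-Whitney condition fails); K_G is then reduced further
# until Phi'Phi is well conditioned, with the saturated design as the
# final fallback.
.region_W <- function(region, label, K_G = NULL, K_beta = NULL,
                      strict = FALSE) {
  fam <- .parse_label(label)
  eff <- effective_K(region$m, label, K_G, K_beta)
  if (eff$saturated)
    return(list(W = NULL, K_G = eff$K_G, K_beta = eff$K_beta,
                saturated = TRUE, gvf_reduced = FALSE))
  if (fam$gvf == "none") {
    sysB <- basis_system(fam$bsf, eff$K_beta)
    W <- eval_basis(sysB, region$positions$scaled)
    return(list(W = W, K_G = eff$K_G, K_beta = eff$K_beta,
                saturated = FALSE, gvf_reduced = FALSE))
  }
  KG <- eff$K_G
  floorK <- if (fam$gvf == "bspline") 4L else 1L
  step <- if (fam$gvf == "fourier") 2L else 1L
  repeat {
    sysG <- basis_system(fam$gvf, KG)
    Phi <- eval_basis(sysG, region$positions$scaled)
    PtP <- crossprod(Phi)
    if (rcond(PtP) >= 1e-12) break
    if (strict) stop("GVF basis rank-deficient at these positions")
    KG <- KG - step
    if (KG < floorK)
      return(list(W = NULL, K_G = NA_integer_,
                  K_beta = as.integer(region$m), saturated = TRUE,
                  gvf_reduced = TRUE))
  }
  KB <- min(eff$K_beta, KG)
  if (fam$bsf == "fourier" && KB %% 2L == 0L) KB <- KB - 1L
  if (fam$bsf == "bspline" && KB < 4L)
    return(list(W = NULL, K_G = NA_integer_,
                K_beta = as.integer(region$m), saturated = TRUE,
                gvf_reduced = TRUE))
  sysB <- basis_system(fam$bsf, KB)
  W <- Phi %*% solve(PtP, .cross_integral_cached(sysG, sysB))
  list(W = W, K_G = as.integer(KG), K_beta = as.integer(KB),
       saturated = FALSE, gvf_reduced = KG < eff$K_G)
}

# core statistics on whitened quantities; Omega fixed at null.  The
# regional design is orthogonalised against the covariates in the
# whitened metric, which is equivalent to re-estimating alpha jointly
# with beta_F under the alternative and makes the F statistic exactly
# F(r, n - r - 1) when Omega is known (intercept-only X).
.flm_stats <- function(Zw, yw0, rss0, Xw, n, cc, df_conservative,
                       statistics) {
  Zw <- Zw - Xw %*% solve(crossprod(Xw), crossprod(Xw, Zw))
  qz <- qr(Zw, tol = 1e-8)
  r <- qz$rank
  if (r < 1L) stop("monomorphic region")
  keep <- sort(qz$pivot[seq_len(r)])
  Z1 <- Zw[, keep, drop = FALSE]
  beta <- drop(qr.coef(qr(Z1), yw0))
  res <- yw0 - Z1 %*% beta
  rss1 <- sum(res^2)
  df2 <- n - r - 1L - if (df_conservative) cc else 0L
  if (df2 <= 0L) stop("region too large for sample")
  out <- list(rank = r, keep = keep, beta = beta, RSS0 = rss0, RSS1 = rss1,
              F = NA_real_, df1 = r, df2 = df2, p_F = NA_real_,
              LRT = NA_real_, p_LRT = NA_real_,
              score = NA_real_, p_score = NA_real_)
  if ("F" %in% statistics) {
    out$F <- ((rss0 - rss1) / r) / (rss1 / df2)
    out$p_F <- stats::pf(out$F, r, df2, lower.tail = FALSE)
  }
  if ("LRT" %in% statistics) {
    # Gaussian profile form with Omega held at the null estimate
    out$LRT <- n * log(rss0 / rss1)
    out$p_LRT <- stats::pchisq(out$LRT, df = r, lower.tail = FALSE)
  }
  if ("score" %in% statistics) {
    # U' V^{-1} U with U = Z'Omega^{-1}(y - X alpha) and V = Z'PZ, P the
    # alpha-estimation projection: because Z is orthogonalised against X
    # in the whitened metric and the null GLS residual is orthogonal to
    # X, this quadratic form collapses to the weighted SS reduction
    out$score <- rss0 - rss1
    out$p_score <- stats::pchisq(out$score, df = r, lower.tail = FALSE)
  }
  out
}

#' Functional linear mixed model association test for one region
#'
#' Tests the association between a quantitative trait and the variants of a
#' region under one or more functional models.  The smoothed design is
#' `G W` (genotype smoothing through `K_G` basis functions followed by
#' effect smoothing through `K_beta` functions) or `G Psi` for the
#' effect-smoothing-only models.  The regional coefficients `beta_F` are
#' estimated by generalised least squares with alpha and Omega fixed at
#' their null-model values, and the F statistic
#' `((RSS0 - RSS1) / r) / (RSS1 / (n - r - 1))` is referred to an
#' F(r, n - r - 1) distribution, where r is the effective rank of the
#' whitened regional design.  A likelihood-ratio statistic
#' `n log(RSS0 / RSS1)` (chi-square, r df) and a score statistic that
#' accounts for the estimation of alpha (chi-square, r df) are also
#' available.
#'
#' @param region a [flm_region()].
#' @param fit the [flmm_null()] fit for the same phenotype and sample.
#' @param models character vector of model labels (see [effective_K()]).
#' @param K_G,K_beta requested basis counts, `NULL` for the defaults.
#' @param statistics subset of `c("F", "LRT", "score")`.
#' @param df_conservative subtract the covariate count from the F
#'   denominator df (`n - r - c - 1` instead of the default `n - r - 1`).
#' @param dominance replace additive dosages by heterozygote indicators.
#' @return Object of class `region_flm`: a data.frame with one row per
#'   model and columns `region`, `m`, `model`, `K_G`, `K_beta`, `rank`,
#'   `F`, `df1`, `df2`, `p_F`, `LRT`, `p_LRT`, `score`, `p_score`, `note`;
#'   the per-model `beta_F` vectors are attached as attribute `"beta_F"`.
#' @examples
#' sc <- sim_scenario(n_families = 2)
#' set.seed(1)
#' ped <- sim_pedigree(sc)
#' R <- kinship_matrix(ped)
#' reg <- sim_region_genotypes(ped, sc)
#' y <- sim_trait(R = R, scenario = sc)$y
#' fit <- flmm_null(y, R = R)
#' region_flm(reg, fit, models = c("0-F", "F-F"))
#' @export
region_flm <- function(region, fit, models = "F-F", K_G = NULL,
                       K_beta = NULL, statistics = c("F", "LRT", "score"),
                       df_conservative = FALSE, dominance = FALSE) {
  stopifnot(inherits(region, "flm_region"), inherits(fit, "flmm_null"))
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (region$n != fit$n)
    stop("region and null fit refer to different sample sizes")
  G <- region$G
  if (dominance) G <- (G == 1) * 1
  if (all(apply(G, 2L, function(g) max(g) == min(g))))
    stop("monomorphic region")
  n <- fit$n
  yw0 <- whiten(fit, fit$y - fit$X %*% fit$alpha)
  rss0 <- sum(yw0^2)
  Xw <- whiten(fit, fit$X)
  rows <- vector("list", length(models))
  betas <- vector("list", length(models))
  names(betas) <- models
  for (i in seq_along(models)) {
    lab <- models[i]
    wset <- .region_W(region, lab, K_G, K_beta)
    Z <- if (is.null(wset$W)) G else G %*% wset$W
    st <- .flm_stats(whiten(fit, Z), yw0, rss0, Xw, n, fit$c,
                     df_conservative, statistics)
    note <- if (region$m == 1L) "m=1 Wald fallback"
            else if (wset$saturated && wset$gvf_reduced)
              "saturated fallback (singular GVF basis)"
            else if (wset$saturated) "saturated fallback"
            else if (wset$gvf_reduced) "K_G reduced (singular GVF basis)"
            else ""
    rows[[i]] <- data.frame(
      region = region$name, m = region$m, model = lab,
      K_G = wset$K_G, K_beta = wset$K_beta, rank = st$rank,
      RSS0 = st$RSS0, RSS1 = st$RSS1,
      F = st$F, df1 = st$df1, df2 = st$df2, p_F = st$p_F,
      LRT = st$LRT, p_LRT = st$p_LRT,
      score = st$score, p_score = st$p_score,
      note = note, stringsAsFactors = FALSE)
    betas[[i]] <- drop(st$beta)
  }
  out <- do.call(rbind, rows)
  attr(out, "beta_F") <- betas
  class(out) <- c("region_flm", "data.frame")
  out
}

#' @export
print.region_flm <- function(x, digits = 4, ...) {
  cat(sprintf("Regional FLM association test: region '%s' (m = %d, n from fit)\n",
              x$region[1], x$m[1]))
  df <- as.data.frame(x)
  df$region <- NULL
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Run the regional test over many regions
#'
#' Fits the null model once and applies [region_flm()] to every region.
#' Per-region failures (for instance monomorphic regions) are recorded as
#' `NA` rows with the error message in `note`; the scan always completes.
#'
#' @param regions list of [flm_region()] objects.
#' @param y phenotype vector, or a ready [flmm_null()] fit in `fit`.
#' @param X covariate matrix (intercept added when `NULL`).
#' @param R relationship matrix.
#' @param fit optional pre-computed null fit (overrides `y`, `X`, `R`).
#' @param models model labels to run.
#' @param verbose log progress to stderr.
#' @param ... passed to [region_flm()].
#' @return data.frame with one row per region x model.
#' @export
region_scan <- function(regions, y = NULL, X = NULL, R = NULL, fit = NULL,
                        models = "F-F", verbose = FALSE, ...) {
  if (is.null(fit)) fit <- flmm_null(y, X = X, R = R)
  na_row <- function(name, m, msg) {
    data.frame(region = name, m = m, model = paste(models, collapse = ","),
               K_G = NA_integer_, K_beta = NA_integer_, rank = NA_integer_,
               RSS0 = NA_real_, RSS1 = NA_real_,
               F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
               p_F = NA_real_, LRT = NA_real_, p_LRT = NA_real_,
               score = NA_real_, p_score = NA_real_, note = msg,
               stringsAsFactors = FALSE)
  }
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    if (verbose && i %% 100L == 0L)
      message(sprintf("region %d / %d", i, length(regions)))
    out[[i]] <- tryCatch({
      res <- region_flm(reg, fit, models = models, ...)
      as.data.frame(res)
    }, error = function(e) na_row(reg$name, reg$m, conditionMessage(e)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
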