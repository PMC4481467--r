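#' Empirical type I error experiment
#'
#' Simulates a multi-family sample, a mini-exome of regions with 2-60
#' variants, and replicate purely polygenic traits; tests every region with
#' every requested functional model and pools the F-test P values.  The
#' per-region whitening-independent quantities (the rotated smoothed design
#' and its rank) are precomputed once, so the cost per replicate is one
#' null-model fit plus a cheap generalised least squares step per region
#' and model; a consistency test against [region_scan()] guards this fast
#' path.
#'
#' @param scenario a [sim_scenario()].
#' @param models model labels to calibrate.
#' @param n_regions number of simulated regions.
#' @param n_replicates number of null trait replicates (pooled tests =
#'   `n_regions * n_replicates` per model).
#' @param alphas nominal significance levels to report.
#' @param region_sizes optional integer vector of variant counts per
#'   region; by default drawn as `2 + NB(size = 1, mu = 5.4)` truncated at
#'   60, giving a mini-exome-like mean of about 7.4 variants.
#' @param omega `"fitted"` uses the per-replicate ML null fit;
#'   `"identity"` deliberately ignores relatedness (a mis-specification
#'   diagnostic that inflates the type I error on family data).
#' @param seed RNG seed.
#' @param verbose log progress.
#' @return list of class `type1_experiment` with `table` (model x alpha
#'   rows: empirical rate and binomial SE), `pvalues` (matrix, one column
#'   per model), `n`, `n_regions`, `n_replicates`.
#' @export
type1_experiment <- function(scenario = sim_scenario(),
                             models = c("0-B", "F-F"),
                             n_regions = 1702L, n_replicates = 12L,
                             alphas = c(0.05, 0.01, 1e-3),
                             region_sizes = NULL, omega = c("fitted",
                                                            "identity"),
                             seed = NULL, verbose = FALSE) {
  omega <- match.arg(omega)
  if (!is.null(seed)) set.seed(seed)
  ped <- sim_pedigree(scenario)
  R <- kinship_matrix(ped)
  eig <- eigen(R, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  n <- nrow(R)
  if (is.null(region_sizes))
    region_sizes <- pmin(2L + stats::rnbinom(n_regions, size = 1,
                                             mu = 5.4), 60L)
  n_regions <- length(region_sizes)

  if (verbose) message("building ", n_regions, " regions")
  pre <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    reg <- sim_region_genotypes(ped, scenario, m = region_sizes[i],
                                name = sprintf("R%05d", i))
    UtG <- crossprod(U, reg$G)
    per_model <- vector("list", length(models))
    for (k in seq_along(models)) {
      wset <- .region_W(reg, models[k])
      UtZ <- if (is.null(wset$W)) UtG else UtG %*% wset$W
      qz <- qr(UtZ, tol = 1e-8)       # rank is whitening-invariant
      r <- qz$rank
      per_model[[k]] <- list(
        UtZ = UtZ[, sort(qz$pivot[seq_len(r)]), drop = FALSE], r = r)
    }
    pre[[i]] <- per_model
  }

  Ut1 <- crossprod(U, matrix(1, n, 1L))
  pv <- matrix(NA_real_, n_regions * n_replicates, length(models),
               dimnames = list(NULL, models))
  row0 <- 0L
  for (rep_i in seq_len(n_replicates)) {
    if (verbose) message("replicate ", rep_i, " / ", n_replicates)
    # null trait simulated directly in the rotated basis
    Uty <- sqrt(scenario$h2 * lam + 1 - scenario$h2) * stats::rnorm(n)
    y <- U %*% Uty
    if (omega == "fitted") {
      fit <- flmm_null(y, eig = eig)
      w <- .omega_dinv(fit)
      alpha_hat <- fit$alpha
    } else {
      w <- rep(1, n)
      alpha_hat <- mean(y)
    }
    sw <- sqrt(w)
    Xw <- sw * Ut1
    yw0 <- sw * (Uty - Ut1 %*% alpha_hat)
    rss0 <- sum(yw0^2)
    for (i in seq_len(n_regions)) {
      for (k in seq_along(models)) {
        pm <- pre[[i]][[k]]
        Zw <- sw * pm$UtZ
        Zw <- Zw - Xw %*% crossprod(Xw, Zw) / sum(Xw^2)
        qz <- qr(Zw, tol = 1e-8)
        r <- qz$rank
        rss1 <- rss0 - sum(qr.qty(qz, yw0)[seq_len(r)]^2)
        df2 <- n - r - 1L
        Fst <- ((rss0 - rss1) / r) / (rss1 / df2)
        pv[row0 + i, k] <- stats::pf(Fst, r, df2, lower.tail = FALSE)
      }
    }
    row0 <- row0 + n_regions
  }

  tab <- do.call(rbind, lapply(seq_along(models), function(k) {
    do.call(rbind, lapply(alphas, function(a) {
      nt <- nrow(pv)
      rate <- if (nt > 0L) mean(pv[, k] < a) else NA_real_
      data.frame(model = models[k], alpha = a, n_tests = nt,
                 rate = rate,
                 se = if (nt > 0L) sqrt(a * (1 - a) / nt) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (n_replicates == 0L) tab <- tab[0L, ]
  structure(list(table = tab, pvalues = pv, n = n,
                 n_regions = n_regions, n_replicates = n_replicates),
            class = "type1_experiment")
}

#' @export
print.type1_experiment <- function(x, ...) {
  cat(sprintf("Type I error experiment: n = %d, %d regions x %d replicates\n",
              x$n, x$n_regions, x$n_replicates))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Power experiment over an effect-size grid
#'
#' Estimates the power of the regional F-test on a fixed simulated region
#' across a grid of effect-size constants `c` and unidirectional-fraction
#' values.  Replicates are paired across the whole grid and across models:
#' the causal set, effect signs and the polygenic/residual noise are drawn
#' once per replicate and shared, with the effect magnitudes rescaled by
#' `log(c)`; this removes between-cell Monte Carlo noise from comparisons.
#' Optionally a fraction of the non-causal variants is excluded from the
#' analysis (not from the trait) before testing.
#'
#' @param scenario a [sim_scenario()]; `causal_fraction`, `rare_only` and
#'   `prune_noncausal` are taken from here.
#' @param models model labels.
#' @param c_grid effect-size constants.
#' @param uni_grid unidirectional-fraction values.
#' @param n_replicates trait replicates per grid cell.
#' @param alpha significance threshold defining power.
#' @param seed RNG seed.
#' @param verbose log progress.
#' @return list of class `power_experiment` with `table`
#'   (model x c x unidirectional rows: power and binomial SE) and `hits`
#'   (logical array replicate x model x c x uni for paired analyses).
#' @export
power_experiment <- function(scenario = sim_scenario(),
                             models = c("0-F", "F-F"),
                             c_grid = c(2, 3, 5, 7),
                             uni_grid = scenario$unidirectional_fraction,
                             n_replicates = scenario$n_replicates,
                             alpha = scenario$alpha_level,
                             seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ped <- sim_pedigree(scenario)
  R <- kinship_matrix(ped)
  eig <- eigen(R, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  n <- nrow(R)
  region <- sim_region_genotypes(ped, scenario, name = "powerregion")
  m <- region$m
  n_causal <- ceiling(scenario$causal_fraction * m)
  cand <- if (scenario$rare_only)
    which(region$maf <= scenario$rare_maf) else seq_len(m)
  if (length(cand) < n_causal)
    stop("fewer eligible rare variants than requested causal count")
  prune <- scenario$prune_noncausal

  # region fixed when nothing is pruned: cache the rotated designs
  cache <- NULL
  if (prune == 0) {
    UtG <- crossprod(U, region$G)
    cache <- lapply(models, function(lab) {
      wset <- .region_W(region, lab)
      UtZ <- if (is.null(wset$W)) UtG else UtG %*% wset$W
      qz <- qr(UtZ, tol = 1e-8)
      r <- qz$rank
      list(UtZ = UtZ[, sort(qz$pivot[seq_len(r)]), drop = FALSE], r = r)
    })
  }
  Ut1 <- crossprod(U, matrix(1, n, 1L))
  hits <- array(NA, dim = c(n_replicates, length(models), length(c_grid),
                            length(uni_grid)),
                dimnames = list(NULL, models, paste0("c", c_grid),
                                paste0("uni", uni_grid)))
  sd_rot <- sqrt(scenario$h2 * lam + 1 - scenario$h2)
  for (rep_i in seq_len(n_replicates)) {
    if (verbose && rep_i %% 50L == 0L)
      message("replicate ", rep_i, " / ", n_replicates)
    pick <- sort(sample(cand, n_causal))
    b0 <- abs(log10(region$maf[pick])) / 2
    Uty_noise <- sd_rot * stats::rnorm(n)
    usign <- stats::runif(n_causal)
    if (prune > 0) {
      noncausal <- setdiff(seq_len(m), pick)
      keep <- sort(c(pick, sample(noncausal,
                                  round((1 - prune) * length(noncausal)))))
      subreg <- flm_region(region$G[, keep, drop = FALSE],
                           region$positions$raw[keep],
                           name = region$name, ids = region$ids[keep])
    }
    for (ui in seq_along(uni_grid)) {
      sgn <- ifelse(usign < uni_grid[ui], 1, -1)
      for (ci in seq_along(c_grid)) {
        beta <- log(c_grid[ci]) * b0 * sgn
        Utg <- crossprod(U, region$G[, pick, drop = FALSE] %*% beta)
        Uty <- Uty_noise + Utg
        y <- U %*% Uty
        fit <- flmm_null(y, eig = eig)
        if (prune > 0) {
          res <- region_flm(subreg, fit, models = models,
                            statistics = "F")
          hits[rep_i, , ci, ui] <- res$p_F < alpha
        } else {
          w <- .omega_dinv(fit)
          sw <- sqrt(w)
          Xw <- sw * Ut1
          yw0 <- sw * (Uty - Ut1 %*% fit$alpha)
          rss0 <- sum(yw0^2)
          for (k in seq_along(models)) {
            pm <- cache[[k]]
            Zw <- sw * pm$UtZ
            Zw <- Zw - Xw %*% crossprod(Xw, Zw) / sum(Xw^2)
            qz <- qr(Zw, tol = 1e-8)
            r <- qz$rank
            rss1 <- rss0 - sum(qr.qty(qz, yw0)[seq_len(r)]^2)
            df2 <- n - r - 1L
            Fst <- ((rss0 - rss1) / r) / (rss1 / df2)
            hits[rep_i, k, ci, ui] <-
              stats::pf(Fst, r, df2, lower.tail = FALSE) < alpha
          }
        }
      }
    }
  }
  grid <- expand.grid(model = models, c = c_grid, unidirectional = uni_grid,
                      stringsAsFactors = FALSE)
  grid$power <- NA_real_
  grid$se <- NA_real_
  for (g in seq_len(nrow(grid))) {
    h <- hits[, grid$model[g], paste0("c", grid$c[g]),
              paste0("uni", grid$unidirectional[g])]
    grid$power[g] <- mean(h)
    grid$se[g] <- sqrt(grid$power[g] * (1 - grid$power[g]) /
                         max(1L, n_replicates))
  }
  structure(list(table = grid, hits = hits, region_m = m, n = n,
                 n_replicates = n_replicates, alpha = alpha),
            class = "power_experiment")
}

#' @export
print.power_experiment <- function(x, ...) {
  cat(sprintf(
    "Power experiment: n = %d, region m = %d, %d replicates, alpha = %g\n",
    x$n, x$region_m, x$n_replicates, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}
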