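#' Simulation scenario settings
#'
#' Bundles the generator settings for pedigrees, the regional haplotype
#' pool, the polygenic trait model and the effect-size model.  The defaults
#' emulate a GAW17-like family sample: eight three-generation pedigrees of
#' 86 members (688 individuals in total), regions with a rare-shifted MAF
#' spectrum (median about 1%, range about 0.1%-35%) and within-region LD
#' from a finite founder-haplotype pool, and a polygenic quantitative trait
#' with narrow-sense heritability 0.29.  Causal effect sizes follow
#' |beta| = log(c) |log10(MAF)| / 2.
#'
#' @param n_families number of pedigrees.
#' @param n_children children of the founder couple per family (each with a
#'   married-in spouse).
#' @param n_grandchildren children per second-generation couple.
#' @param H founder-haplotype pool size per region (smaller pools give
#'   stronger LD).
#' @param m number of polymorphic variants per region.
#' @param region_bp physical region length in base pairs.
#' @param maf_shape shape parameters of the Beta distribution for the rare
#'   component of the site-frequency spectrum.
#' @param maf_range truncation range for pool allele frequencies.
#' @param maf_common_weight prior probability that a site is drawn from the
#'   common component instead of the rare Beta component.  Conditioning on
#'   polymorphism in the sample strongly favours common sites, so the
#'   spectrum is a calibrated mixture: the defaults give a sample MAF
#'   spectrum with median near 1%, about two thirds of variants below 3%
#'   and a tail reaching about 35%.
#' @param maf_common_range uniform range of the common component.
#' @param h2 narrow-sense heritability of the polygenic (non-variant) part.
#' @param causal_fraction fraction of region variants that are causal.
#' @param unidirectional_fraction probability that a causal effect is
#'   positive.
#' @param effect_c the constant c in |beta| = log(c) |log10(MAF)| / 2.
#' @param rare_only restrict causal variants to MAF <= `rare_maf`.
#' @param rare_maf rarity threshold.
#' @param prune_noncausal fraction of non-causal variants excluded from the
#'   analysis (0, 0.5 or 0.8 in the power experiments).
#' @param alpha_level significance level used for power estimation.
#' @param n_replicates trait replicates per experiment.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_families = 8L, n_children = 7L,
                         n_grandchildren = 10L, H = 600L, m = 50L,
                         region_bp = 20000L, maf_shape = c(0.08, 150),
                         maf_range = c(3e-4, 0.35),
                         maf_common_weight = 0.10,
                         maf_common_range = c(0.02, 0.35), h2 = 0.29,
                         causal_fraction = 0.1,
                         unidirectional_fraction = 1, effect_c = 3,
                         rare_only = FALSE, rare_maf = 0.03,
                         prune_noncausal = 0, alpha_level = 2.5e-6,
                         n_replicates = 1000L) {
  sc <- list(n_families = n_families, n_children = n_children,
             n_grandchildren = n_grandchildren, H = H, m = m,
             region_bp = region_bp, maf_shape = maf_shape,
             maf_range = maf_range,
             maf_common_weight = maf_common_weight,
             maf_common_range = maf_common_range, h2 = h2,
             causal_fraction = causal_fraction,
             unidirectional_fraction = unidirectional_fraction,
             effect_c = effect_c, rare_only = rare_only,
             rare_maf = rare_maf, prune_noncausal = prune_noncausal,
             alpha_level = alpha_level, n_replicates = n_replicates)
  stopifnot(sc$h2 >= 0, sc$h2 < 1, sc$effect_c > 1,
            sc$causal_fraction >= 0, sc$causal_fraction <= 1,
            sc$unidirectional_fraction >= 0,
            sc$unidirectional_fraction <= 1,
            sc$prune_noncausal >= 0, sc$prune_noncausal < 1)
  class(sc) <- "sim_scenario"
  sc
}

#' Simulate a multi-family three-generation pedigree sample
#'
#' Each family consists of a founder couple, their children with married-in
#' spouses, and grandchildren, mirroring the extended families of large
#' sequencing studies.
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional RNG seed (the construction is deterministic; the
#'   seed only matters for reproducibility bookkeeping).
#' @return a [pedigree()] of about
#'   `n_families * (2 + 2 n_children + n_children n_grandchildren)`
#'   individuals.
#' @export
sim_pedigree <- function(scenario = sim_scenario(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- scenario$n_children
  ng <- scenario$n_grandchildren
  rows <- list()
  for (f in seq_len(scenario$n_families)) {
    fam <- sprintf("FAM%d", f)
    pid <- function(i) sprintf("%s_I%d", fam, i)
    k <- 0L
    add <- function(father, mother, sex) {
      k <<- k + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        family = fam, id = pid(k), father = father, mother = mother,
        sex = sex, stringsAsFactors = FALSE)
      pid(k)
    }
    gf <- add(NA, NA, 1L)
    gm <- add(NA, NA, 2L)
    for (j in seq_len(nc)) {
      child_sex <- if (j %% 2L == 1L) 1L else 2L
      child <- add(gf, gm, child_sex)
      spouse <- add(NA, NA, 3L - child_sex)
      fa <- if (child_sex == 1L) child else spouse
      mo <- if (child_sex == 1L) spouse else child
      for (g in seq_len(ng)) add(fa, mo, if (g %% 2L == 1L) 1L else 2L)
    }
  }
  tab <- do.call(rbind, rows)
  pedigree(id = tab$id, father = tab$father, mother = tab$mother,
           family = tab$family, sex = tab$sex)
}

#' Simulate LD-structured regional genotypes by gene dropping
#'
#' Draws `H` founder haplotypes per region from a rare-shifted
#' site-frequency spectrum (Beta allele frequencies truncated to
#' `maf_range`), assigns each pedigree founder a haplotype pair sampled
#' from this finite pool (which induces within-region LD), and transmits
#' whole haplotypes through the pedigree by Mendelian gene dropping
#' (no recombination within the gene-sized region).  Sites monomorphic in
#' the sample are redrawn.
#'
#' @param ped a [pedigree()].
#' @param scenario a [sim_scenario()].
#' @param m number of polymorphic variants (default `scenario$m`).
#' @param seed optional RNG seed.
#' @param name region label.
#' @param max_retries redraw attempts per monomorphic site.
#' @return a [flm_region()] whose rows follow the pedigree order.
#' @export
sim_region_genotypes <- function(ped, scenario = sim_scenario(),
                                 m = scenario$m, seed = NULL,
                                 name = "simregion", max_retries = 200L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(ped, "pedigree_df"))
  n <- nrow(ped)
  H <- scenario$H
  rfreq <- function(k) {
    common <- stats::runif(k) < scenario$maf_common_weight
    p <- numeric(k)
    p[common] <- stats::runif(sum(common), scenario$maf_common_range[1],
                              scenario$maf_common_range[2])
    nr <- sum(!common)
    if (nr > 0L) {
      out <- numeric(0)
      while (length(out) < nr) {
        cand <- stats::rbeta(4L * nr, scenario$maf_shape[1],
                             scenario$maf_shape[2])
        out <- c(out, cand[cand >= scenario$maf_range[1] &
                             cand <= scenario$maf_range[2]])
      }
      p[!common] <- out[seq_len(nr)]
    }
    p
  }
  p <- rfreq(m)
  pool <- matrix(stats::rbinom(H * m, 1L, rep(p, each = H)), H, m)

  # transmit pool indices: whole-haplotype Mendelian gene dropping
  idx <- seq_len(n); names(idx) <- ped$id
  fa <- unname(idx[ped$father]); mo <- unname(idx[ped$mother])
  h1 <- integer(n); h2 <- integer(n)
  founder <- is.na(fa)
  nf <- sum(founder)
  h1[founder] <- sample.int(H, nf, replace = TRUE)
  h2[founder] <- sample.int(H, nf, replace = TRUE)
  coin1 <- stats::runif(n) < 0.5
  coin2 <- stats::runif(n) < 0.5
  for (i in which(!founder)) {   # pedigree order puts parents first
    h1[i] <- if (coin1[i]) h1[fa[i]] else h2[fa[i]]
    h2[i] <- if (coin2[i]) h1[mo[i]] else h2[mo[i]]
  }
  G <- pool[h1, , drop = FALSE] + pool[h2, , drop = FALSE]

  af <- colMeans(G) / 2
  for (j in which(af == 0 | af == 1)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      pj <- rfreq(1L)
      colj <- stats::rbinom(H, 1L, pj)
      gj <- colj[h1] + colj[h2]
      if (stats::var(gj) > 0) { G[, j] <- gj; ok <- TRUE; break }
    }
    if (!ok) stop("could not obtain ", m, " polymorphic sites")
  }
  # minor-allele orientation
  af <- colMeans(G) / 2
  flip <- af > 0.5
  if (any(flip)) G[, flip] <- 2L - G[, flip]
  positions <- sort(sample.int(scenario$region_bp, m))
  rownames(G) <- ped$id
  flm_region(G, positions, name = name)
}

#' Simulate a polygenic quantitative trait
#'
#' Generates `y = G beta + h + e` with polygenic effect
#' `h ~ N(0, sigma_h^2 R)` and residual `e ~ N(0, sigma_e^2 I)`, where the
#' non-genetic variance is scaled to 1 so that `sigma_h^2 = h2` and
#' `sigma_e^2 = 1 - h2`.  Under the null (no region supplied, or a causal
#' fraction of zero) the trait is purely polygenic.  Under the alternative,
#' `ceiling(causal_fraction * m)` causal variants are drawn uniformly at
#' random (restricted to MAF <= `rare_maf` when `rare_only`), with effect
#' sizes `|beta_j| = log(c) |log10(MAF_j)| / 2` and positive sign with
#' probability `unidirectional_fraction`.
#'
#' @param R relationship matrix (ignored when `eig` is given).
#' @param eig optional precomputed `eigen(R, symmetric = TRUE)`.
#' @param region optional [flm_region()] carrying the causal candidates.
#' @param scenario a [sim_scenario()].
#' @param seed optional RNG seed.
#' @return list with `y`, `X` (intercept), and `causal` (data.frame with
#'   `index`, `maf`, `beta`; empty under the null).
#' @export
sim_trait <- function(R = NULL, eig = NULL, region = NULL,
                      scenario = sim_scenario(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(eig)) {
    if (is.null(R)) stop("supply R or its eigendecomposition")
    eig <- eigen(as.matrix(R), symmetric = TRUE)
  }
  lam <- pmax(eig$values, 0)
  n <- length(lam)
  sigma_h2 <- scenario$h2
  sigma_e2 <- 1 - scenario$h2
  h <- eig$vectors %*% (sqrt(sigma_h2 * lam) * stats::rnorm(n))
  y <- drop(h) + stats::rnorm(n, sd = sqrt(sigma_e2))
  causal <- data.frame(index = integer(0), maf = numeric(0),
                       beta = numeric(0))
  if (!is.null(region)) {
    n_causal <- ceiling(scenario$causal_fraction * region$m)
    if (n_causal > 0L) {
      cand <- if (scenario$rare_only)
        which(region$maf <= scenario$rare_maf) else seq_len(region$m)
      if (length(cand) < n_causal)
        stop("fewer eligible rare variants than requested causal count")
      pick <- sort(sample(cand, n_causal))
      maf <- region$maf[pick]
      beta <- log(scenario$effect_c) * abs(log10(maf)) / 2
      sign <- ifelse(stats::runif(n_causal) <
                       scenario$unidirectional_fraction, 1, -1)
      beta <- beta * sign
      y <- y + drop(region$G[, pick, drop = FALSE] %*% beta)
      causal <- data.frame(index = pick, maf = maf, beta = beta)
    }
  }
  list(y = y, X = matrix(1, n, 1L), causal = causal)
}
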