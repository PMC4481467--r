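test_that("pedigree templates give GAW17-like multi-family samples", {
  ped <- sim_pedigree(sim_scenario())
  expect_equal(nrow(ped), 688L)     # 8 families x 86 members
  expect_equal(length(unique(ped$family)), 8L)

  # minimal template: founder couple, one child + spouse, one grandchild
  small <- sim_pedigree(sim_scenario(n_families = 1, n_children = 1,
                                     n_grandchildren = 1))
  R <- kinship_matrix(small)
  expect_equal(nrow(small), 5L)
  kid <- small$id[!is.na(small$father)][1]
  expect_equal(R[small$father[small$id == kid], kid], 0.5)
})

test_that("gene dropping is Mendelian-consistent and seed-reproducible", {
  sc <- sim_scenario(n_families = 2)
  ped <- sim_pedigree(sc)
  reg <- sim_region_genotypes(ped, sc, m = 30, seed = 7)
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  off <- which(!is.na(ped$father))
  Gf <- reg$G[idx[ped$father[off]], , drop = FALSE]
  Gm <- reg$G[idx[ped$mother[off]], , drop = FALSE]
  Gc <- reg$G[off, , drop = FALSE]
  # allele-count bounds implied by Mendelian transmission (invariant under
  # the minor-allele flip, which recodes whole columns)
  expect_true(all(Gc >= (Gf == 2) + (Gm == 2)))
  expect_true(all(Gc <= 2 - (Gf == 0) - (Gm == 0)))

  reg2 <- sim_region_genotypes(ped, sc, m = 30, seed = 7)
  expect_identical(reg$G, reg2$G)
  expect_false(identical(
    reg$G, sim_region_genotypes(ped, sc, m = 30, seed = 8)$G))
})

test_that("a two-haplotype pool produces complete within-region LD", {
  sc <- sim_scenario(n_families = 1, H = 2L)
  ped <- sim_pedigree(sc)
  reg <- sim_region_genotypes(ped, sc, m = 10, seed = 9)
  cors <- abs(stats::cor(reg$G))
  expect_true(all(cors > 1 - 1e-12))
})

test_that("the simulated MAF spectrum is rare-shifted with median near 1%", {
  sc <- sim_scenario()
  set.seed(13)
  ped <- sim_pedigree(sc)
  meds <- replicate(100, median(sim_region_genotypes(ped, sc)$maf))
  expect_gt(median(meds), 0.005)
  expect_lt(median(meds), 0.02)
})

test_that("trait simulation follows the polygenic covariance and the
           printed effect-size rule", {
  # covariance of replicated traits matches Omega = 0.29 R + 0.71 I
  ped <- pedigree(
    id = c("f", "m", paste0("k", 1:4)),
    father = c(NA, NA, rep("f", 4)), mother = c(NA, NA, rep("m", 4)))
  R <- kinship_matrix(ped)
  sc <- sim_scenario(h2 = 0.29)
  set.seed(14)
  Y <- replicate(4000, sim_trait(R = R, scenario = sc)$y)
  emp <- stats::cov(t(Y))
  Omega <- 0.29 * R + 0.71 * diag(6)
  expect_lt(max(abs(emp - Omega)), 0.12)   # ~4 MC SEs at 4000 replicates

  # |beta| = log(c) |log10(MAF)| / 2: MAF 1%, c = 2 gives exactly ln 2
  G <- matrix(0, 200, 2)
  G[1:4, 1] <- 1            # MAF = 4 / 400 = 0.01
  G[5:30, 2] <- 1
  reg <- flm_region(G, c(100, 200))
  set.seed(15)
  tr <- sim_trait(R = diag(200), region = reg,
                  scenario = sim_scenario(causal_fraction = 0.5,
                                          effect_c = 2, rare_only = TRUE,
                                          unidirectional_fraction = 1))
  expect_equal(nrow(tr$causal), 1L)
  expect_equal(tr$causal$maf, 0.01)
  expect_equal(tr$causal$beta, log(2))

  # zero causal fraction gives a pure null trait
  tr0 <- sim_trait(R = diag(200), region = reg,
                   scenario = sim_scenario(causal_fraction = 0))
  expect_equal(nrow(tr0$causal), 0L)

  # too few rare candidates errors
  expect_error(
    sim_trait(R = diag(200), region = reg,
              scenario = sim_scenario(causal_fraction = 1,
                                      rare_only = TRUE, rare_maf = 0.02)),
    "rare")
})

test_that("type I error experiment pools calibrated P values and flags
           mis-specification", {
  sc <- sim_scenario(n_families = 2)
  ex <- type1_experiment(sc, models = c("0-F", "B-B"), n_regions = 60L,
                         n_replicates = 5L, alphas = c(0.05, 0.01),
                         seed = 16)
  expect_equal(nrow(ex$table), 4L)
  expect_equal(unique(ex$table$n_tests), 300L)
  expect_true(all(ex$table$rate >= 0 & ex$table$rate <= 1))
  # calibrated: within 5 binomial SEs at this small scale
  r05 <- ex$table$rate[ex$table$alpha == 0.05]
  expect_true(all(abs(r05 - 0.05) < 5 * sqrt(0.05 * 0.95 / 300)))

  # ignoring relatedness on family data inflates the type I error
  exI <- type1_experiment(sim_scenario(), models = "0-F",
                          n_regions = 200L, n_replicates = 3L,
                          alphas = 0.05, omega = "identity", seed = 17)
  expect_gt(exI$table$rate, 0.10)

  # zero replicates: empty table, no crash
  ex0 <- type1_experiment(sc, models = "0-F", n_regions = 10L,
                          n_replicates = 0L, seed = 18)
  expect_equal(nrow(ex0$table), 0L)
})

test_that("the experiment fast path reproduces the full regional test", {
  s <- family_sample(n_families = 2, seed = 121)
  set.seed(122)
  y <- sim_trait(eig = s$eig, scenario = s$sc)$y
  fit <- flmm_null(y, eig = s$eig)
  reg <- sim_region_genotypes(s$ped, s$sc, m = 11)
  res <- region_flm(reg, fit, models = "0-F", statistics = "F")

  # same algebra as the cached path inside the experiments
  U <- s$eig$vectors
  w <- 1 / (fit$sigma_h2 * pmax(s$eig$values, 0) + fit$sigma_e2)
  sw <- sqrt(w)
  W <- build_basis_matrices(NULL, basis_system("fourier", res$K_beta),
                            reg$positions)$W
  UtZ <- crossprod(U, reg$G %*% W)
  Ut1 <- crossprod(U, matrix(1, s$n, 1))
  Xw <- sw * Ut1
  yw0 <- sw * (crossprod(U, y) - Ut1 %*% fit$alpha)
  Zw <- sw * UtZ
  Zw <- Zw - Xw %*% crossprod(Xw, Zw) / sum(Xw^2)
  qz <- qr(Zw, tol = 1e-8)
  r <- qz$rank
  rss0 <- sum(yw0^2)
  rss1 <- rss0 - sum(qr.qty(qz, yw0)[seq_len(r)]^2)
  Fst <- ((rss0 - rss1) / r) / (rss1 / (s$n - r - 1))
  expect_equal(res$rank, r)
  expect_equal(res$F, Fst, tolerance = 1e-10)
})

test_that("power experiments are paired, seeded and vanish in the null
           limit", {
  sc <- sim_scenario(n_families = 2, causal_fraction = 0.1)
  pw <- power_experiment(sc, models = "0-F", c_grid = c(1.0001, 5),
                         uni_grid = 1, n_replicates = 20, seed = 19)
  expect_equal(dim(pw$hits), c(20L, 1L, 2L, 1L))
  p_null <- pw$table$power[pw$table$c == 1.0001]
  expect_lte(p_null, 0.05)         # c -> 1 collapses to the null
  pw2 <- power_experiment(sc, models = "0-F", c_grid = c(1.0001, 5),
                          uni_grid = 1, n_replicates = 20, seed = 19)
  expect_identical(pw$hits, pw2$hits)

  # pruning non-causal variants shrinks the analyzed region
  sc2 <- sim_scenario(n_families = 2, causal_fraction = 0.1,
                      prune_noncausal = 0.8)
  pw3 <- power_experiment(sc2, models = "0-F", c_grid = 5, uni_grid = 1,
                          n_replicates = 5, seed = 20)
  expect_true(all(is.finite(pw3$table$power)))
})
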