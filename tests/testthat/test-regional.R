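test_that("basis counts reduce to satisfy m >= K_G >= K_beta", {
  expect_equal(effective_K(50, "F-F"), list(K_G = 25L, K_beta = 25L,
                                            saturated = FALSE))
  # Fourier requested 25 at m = 10: largest odd value <= 10
  expect_equal(effective_K(10, "0-F")$K_beta, 9L)
  # F-B requested (25, 15) at m = 20
  eff <- effective_K(20, "F-B", K_G = 25, K_beta = 15)
  expect_equal(eff$K_G, 19L)
  expect_equal(eff$K_beta, 15L)
  expect_true(eff$K_G >= eff$K_beta)
  # B-spline models fall back to the saturated design below m = 4
  expect_true(effective_K(3, "0-B")$saturated)
  expect_true(effective_K(3, "B-F")$saturated)
  expect_false(effective_K(3, "0-F")$saturated)
  expect_true(effective_K(1, "F-F")$saturated)
})

test_that("regions validate dosages, order variants and impute missing
           values", {
  G <- cbind(c(0, 1, 2, 0), c(2, 2, 2, 2), c(0, NA, 1, 1))
  expect_error(flm_region(G[, 2, drop = FALSE], 10), "monomorphic")
  reg <- flm_region(G, c(30, 10, 20), drop_monomorphic = TRUE)
  expect_equal(reg$m, 2L)                     # constant column dropped
  expect_equal(reg$positions$raw, c(20, 30))  # ordered by position
  expect_equal(reg$G[2, 1], 2 / 3)            # mean-dosage imputation
  expect_error(flm_region(matrix(0, 4, 2), c(1, 2)), "monomorphic")
})

test_that("equivalent model pairs and the K = m reduction give identical
           F statistics", {
  s <- family_sample(n_families = 1, seed = 61)
  set.seed(62)
  y <- sim_trait(eig = s$eig, scenario = s$sc)$y
  fit <- flmm_null(y, eig = s$eig)
  reg <- sim_region_genotypes(s$ped, s$sc, m = 14)
  a <- region_flm(reg, fit, models = "B-B", K_G = 8, K_beta = 8)
  b <- region_flm(reg, fit, models = "0-B", K_beta = 8)
  expect_equal(a$F, b$F, tolerance = 1e-10)
  d <- region_flm(reg, fit, models = "F-F", K_G = 9, K_beta = 9)
  e <- region_flm(reg, fit, models = "0-F", K_beta = 9)
  expect_equal(d$F, e$F, tolerance = 1e-10)

  # K = m on equally spaced positions: the labels whose position-evaluated
  # bases are non-degenerate (the periodic Fourier system collapses rows
  # at the scaled endpoints 0 and 1) match the saturated linear mixed
  # model computed by dense GLS
  Gm <- reg$G[, 1:9]
  regm <- flm_region(Gm, seq(100, 900, by = 100))
  res <- region_flm(regm, fit, models = c("B-B", "0-B", "B-F"),
                    K_G = 9, K_beta = 9)
  Omega <- fit$sigma_h2 * s$R + fit$sigma_e2 * diag(s$n)
  oracle <- dense_region_stats(y, fit$X, regm$G, Omega)
  expect_lt(max(abs(res$F - oracle$F)), 1e-8)
  expect_true(all(res$rank == 9L))
  # the Fourier-evaluated design at K = m carries exactly m - 1 df
  resf <- region_flm(regm, fit, models = "0-F", K_beta = 9)
  expect_equal(resf$rank, 8L)
})

test_that("statistics match dense GLS formulas and OLS in the independent
           case", {
  s <- family_sample(n_families = 1, seed = 71)
  set.seed(72)
  y <- sim_trait(eig = s$eig, scenario = s$sc)$y
  fit <- flmm_null(y, eig = s$eig)
  reg <- sim_region_genotypes(s$ped, s$sc, m = 12)
  res <- region_flm(reg, fit, models = "0-F")
  W <- build_basis_matrices(NULL, basis_system("fourier", res$K_beta),
                            reg$positions)$W
  Omega <- fit$sigma_h2 * s$R + fit$sigma_e2 * diag(s$n)
  oracle <- dense_region_stats(y, fit$X, reg$G %*% W, Omega)
  expect_equal(res$RSS0, oracle$RSS0, tolerance = 1e-8)
  expect_equal(res$RSS1, oracle$RSS1, tolerance = 1e-8)
  expect_equal(res$F, oracle$F, tolerance = 1e-8)
  expect_equal(res$score, oracle$score, tolerance = 1e-8)
  expect_equal(unname(sort(abs(attr(res, "beta_F")[["0-F"]]))),
               unname(sort(abs(oracle$beta))), tolerance = 1e-8)

  # independent sample: beta_F equals the joint OLS coefficients
  n <- s$n
  fitI <- flmm_null(y, R = diag(n), sigma_h2 = 0, sigma_e2 = 1)
  resI <- region_flm(reg, fitI, models = "0-F")
  Z <- reg$G %*% W
  ols <- lm.fit(cbind(fitI$X, Z), y)
  expect_equal(unname(attr(resI, "beta_F")[["0-F"]]),
               unname(ols$coefficients[-1]), tolerance = 1e-8)
})

test_that("rank deficiency, oversized regions and dominance coding are
           handled", {
  s <- family_sample(n_families = 1, seed = 81)
  set.seed(82)
  y <- sim_trait(eig = s$eig, scenario = s$sc)$y
  fit <- flmm_null(y, eig = s$eig)
  reg <- sim_region_genotypes(s$ped, s$sc, m = 7)

  # duplicated variant column in a saturated design: rank m - 1
  reg3 <- sim_region_genotypes(s$ped, s$sc, m = 2)
  Gd <- cbind(reg3$G, reg3$G[, 2])
  regd <- flm_region(Gd, c(reg3$positions$raw,
                           reg3$positions$raw[2] + 5))
  resd <- region_flm(regd, fit, models = "0-B")  # m = 3: saturated
  expect_equal(resd$rank, 2L)
  expect_equal(resd$df1, 2L)

  # more design columns than residual degrees of freedom
  nsmall <- 12
  Gs <- matrix(rbinom(nsmall * 15, 2, 0.4), nsmall, 15)
  regs <- flm_region(Gs, sort(sample.int(1e4, 15)))
  fits <- flmm_null(rnorm(nsmall), R = diag(nsmall),
                    sigma_h2 = 0, sigma_e2 = 1)
  expect_error(region_flm(regs, fits, models = "0-F", K_beta = 13),
               "region too large")

  resdom <- region_flm(reg, fit, models = "0-F", dominance = TRUE)
  resadd <- region_flm(reg, fit, models = "0-F")
  expect_false(isTRUE(all.equal(resdom$F, resadd$F)))
})

test_that("single-variant regions fall back to the mixed-model Wald test", {
  s <- family_sample(n_families = 1, seed = 91)
  set.seed(92)
  y <- sim_trait(eig = s$eig, scenario = s$sc)$y
  fit <- flmm_null(y, eig = s$eig)
  reg1 <- sim_region_genotypes(s$ped, s$sc, m = 1)
  res <- region_flm(reg1, fit, models = "F-F")
  expect_equal(res$rank, 1L)
  expect_match(res$note, "m=1")
  Omega <- fit$sigma_h2 * s$R + fit$sigma_e2 * diag(s$n)
  oracle <- dense_region_stats(y, fit$X, reg1$G, Omega)
  expect_equal(res$F, oracle$F, tolerance = 1e-8)
})

test_that("residual sums are monotone under nested saturated designs", {
  s <- family_sample(n_families = 1, seed = 101)
  set.seed(102)
  y <- sim_trait(eig = s$eig, scenario = s$sc)$y
  fit <- flmm_null(y, eig = s$eig)
  reg3 <- sim_region_genotypes(s$ped, s$sc, m = 3)
  reg2 <- flm_region(reg3$G[, 1:2], reg3$positions$raw[1:2])
  r2 <- region_flm(reg2, fit, models = "0-B")   # saturated fallback
  r3 <- region_flm(reg3, fit, models = "0-B")
  expect_equal(r2$RSS0, r3$RSS0, tolerance = 1e-12)
  expect_lte(r3$RSS1, r2$RSS1 + 1e-10)
  expect_true(all(c(r2$RSS1, r3$RSS1) >= 0))
  expect_true(r2$RSS0 >= r2$RSS1)
})

test_that("genome scans record per-region failures and are deterministic", {
  s <- family_sample(n_families = 1, seed = 111)
  set.seed(112)
  y <- sim_trait(eig = s$eig, scenario = s$sc)$y
  regions <- lapply(1:3, function(i)
    sim_region_genotypes(s$ped, s$sc, m = 6, name = paste0("ok", i)))
  # a region whose rows do not match the fitted sample errors inside the
  # scan and is recorded as an NA row
  nbad <- 10
  badreg <- flm_region(matrix(rbinom(nbad * 4, 2, 0.4), nbad, 4),
                       sort(sample.int(1e4, 4)), name = "badsample")
  fit <- flmm_null(y, R = s$R)
  res <- region_scan(c(regions, list(badreg)), fit = fit,
                     models = c("0-F", "F-F"))
  expect_equal(sum(is.na(res$p_F)), 1L)
  expect_match(res$note[is.na(res$p_F)], "sample sizes")
  expect_equal(nrow(res), 3L * 2L + 1L)
  res2 <- region_scan(c(regions, list(badreg)), fit = fit,
                      models = c("0-F", "F-F"))
  expect_identical(res, res2)
})
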