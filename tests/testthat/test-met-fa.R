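test_that("stratified and dense likelihood paths agree at the same parameters", {
  up <- simulate_met_unit(site_means = c(2.2, 2.5, 2.8, 2.4), g = 8, r = 2,
                         lambda = c(0.5, -0.4, 0.6, 0.3),
                         specific = rep(0.05, 4),
                         sigma2_g = 0.08, sigma2_rep = 0.01, sigma2_e = 0.1,
                         seed = 21)
  f1 <- fit_met(up, 1)
  f2 <- fit_met(up, 1, method = "dense")
  expect_equal(f1$method, "stratified")
  expect_equal(f2$method, "dense")
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-4)
  expect_equal(unname(f1$sigma2_e), unname(f2$sigma2_e), tolerance = 1e-2)
})

test_that("the optimum beats a random search over the parameter space", {
  up <- simulate_met_unit(site_means = c(2.3, 2.6, 3.0), g = 10, r = 2,
                         lambda = c(0.5, 0.4, -0.3), specific = rep(0.04, 3),
                         sigma2_g = 0.06, sigma2_rep = 0.01, sigma2_e = 0.1,
                         seed = 33)
  fit <- fit_met(up, 1)
  site <- factor(up$site_id); geno <- factor(up$genotype_id)
  ril <- factor(up$replicate)
  pm <- metgains:::fa_par_map(3L, 1L, 2L, list())
  st <- metgains:::fa_strata(up$yield_t_ha, site, geno, ril)
  set.seed(77)
  best_rand <- -Inf
  for (i in 1:10000) {
    th <- c(log(runif(1, 0.01, 0.5)),            # sigma2_e
            log(runif(3, 0.001, 0.2)),           # rep variances
            log(runif(1, 0.005, 0.4)),           # sigma2_g
            runif(3, -1, 1),                     # loadings
            log(runif(3, 0.001, 0.3)))           # specific variances
    best_rand <- max(best_rand, metgains:::fa_loglik_strat(th, pm, st))
  }
  expect_gte(fit$reml_loglik, best_rand)
})

test_that("BLUPs match an independently coded dense mixed-model solve", {
  up <- simulate_met_unit(site_means = c(2.1, 2.7, 3.2, 2.5), g = 9, r = 2,
                         lambda = c(0.4, -0.3, 0.5, 0.2), specific = rep(0.06, 4),
                         sigma2_g = 0.07, sigma2_rep = 0.02, sigma2_e = 0.12,
                         seed = 55)
  fit <- fit_met(up, 1)
  des <- oracle_met_design(up)
  s <- fit$n_sites; g <- fit$n_genotypes
  Sge <- fit$ge_cov
  Gu <- matrix(0, ncol(des$Zr) + g + s * g, ncol(des$Zr) + g + s * g)
  site_of_rep <- sub(":.*$", "", colnames(des$Zr))
  site_of_rep <- sub("^repl", "", site_of_rep)
  rv <- fit$rep_variances[site_of_rep]
  diag(Gu)[seq_along(rv)] <- rv
  idx_g <- ncol(des$Zr) + seq_len(g)
  diag(Gu)[idx_g] <- fit$sigma2_g
  idx_ge <- ncol(des$Zr) + g + seq_len(s * g)
  Gu[idx_ge, idx_ge] <- Sge %x% diag(g)
  or <- oracle_blup(des$y, des$X, cbind(des$Zr, des$Zg, des$Zge), Gu,
                    fit$sigma2_e)
  expect_equal(unname(fit$blups_g), unname(or$u[idx_g]), tolerance = 1e-8)
  expect_equal(as.vector(fit$blups_ge), unname(or$u[idx_ge]), tolerance = 1e-8)
  expect_equal(unname(fit$site_effects), unname(or$beta), tolerance = 1e-8)
})

test_that("a single site reduces to the single-trial genotype-random fit", {
  cfg <- sim_config(n_series = 1, sites_per_class = c(low = 1, medium = 0, high = 0),
                    entries_per_trial = 40, n_subblocks = 1, sigma2_subblock = 0,
                    sigma2_rep = 0.04, seed = 8)
  tp <- generate_met(cfg)$plots
  f_st <- fit_single_trial(tp)
  f_met <- fit_met(tp, n_factors = 0)
  expect_equal(f_met$sigma2_g, f_st$sigma2_g, tolerance = 1e-6)
  expect_equal(unname(f_met$blups_g[names(f_st$blups_g)]),
               unname(f_st$blups_g), tolerance = 1e-6)
})

test_that("shrinkage limits behave as the mixed model dictates", {
  up <- simulate_met_unit(site_means = c(2.4, 2.6, 2.8), g = 12, r = 2,
                         lambda = rep(0, 3), specific = rep(0.03, 3),
                         sigma2_g = 0.05, sigma2_rep = 0.01, sigma2_e = 0.08,
                         seed = 4)
  f0 <- fit_met(up, 1, fix = list(sigma2_g = 0))
  expect_true(all(f0$blups_g == 0))
  fe <- fit_met(up, 1)
  fbig <- fit_met(up, 1, fix = list(sigma2_g = 1e6 * fe$sigma2_e))
  bt <- blup_table(fbig)
  gls_means <- tapply(up$yield_t_ha, up$genotype_id, mean)  # balanced: GLS = raw
  expect_lt(max(abs(bt$predicted_yield_t_ha - gls_means[bt$genotype_id])), 1e-3)
})

test_that("site order does not affect the fit", {
  up <- simulate_met_unit(site_means = c(2.2, 2.9, 2.5), g = 10, r = 2,
                         lambda = c(0.5, -0.3, 0.4), specific = rep(0.05, 3),
                         sigma2_g = 0.06, sigma2_rep = 0.01, sigma2_e = 0.1,
                         seed = 66)
  f1 <- fit_met(up, 1)
  up2 <- up[order(match(up$site_id, c("SITE03", "SITE01", "SITE02"))), ]
  up2$site_id <- factor(up2$site_id, levels = c("SITE03", "SITE01", "SITE02"))
  f2 <- fit_met(up2, 1)
  perm <- names(f1$specific_vars)
  # compare identifiable quantities: the implied GE covariance and the BLUPs
  expect_lt(max(abs(f2$ge_cov[perm, perm] - f1$ge_cov[perm, perm])), 1e-4)
  expect_lt(max(abs(f2$blups_g[names(f1$blups_g)] - f1$blups_g)), 1e-5)
})

test_that("the implied GE covariance is a valid covariance", {
  up <- simulate_met_unit(site_means = c(2.1, 2.4, 2.8, 3.1, 2.6), g = 15, r = 2,
                         lambda = c(0.6, -0.5, 0.4, 0.3, -0.2),
                         specific = rep(0.05, 5),
                         sigma2_g = 0.07, sigma2_rep = 0.01, sigma2_e = 0.1,
                         seed = 91)
  fit <- fit_met(up, 2)
  ev <- eigen(fit$ge_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  rho <- fit$ge_cov / sqrt(outer(diag(fit$ge_cov), diag(fit$ge_cov)))
  expect_true(all(rho >= -1 - 1e-10 & rho <= 1 + 1e-10))
  # identifiability: zeros above the diagonal of the leading k x k block,
  # first nonzero entry of each column nonnegative
  expect_equal(unname(fit$loadings[1, 2]), 0)
  for (q in 1:2) {
    col <- fit$loadings[, q]
    nz <- col[abs(col) > 1e-10]
    if (length(nz)) expect_gte(nz[1], 0)
  }
  # random BLUPs of a balanced design sum to ~0
  expect_lt(abs(sum(fit$blups_g)), 1e-8)
})

test_that("structure comparison prefers the generating structure", {
  # diagonal truth: AIC should usually keep k = 0; factor truth: k >= 1
  n_diag_pref <- 0L; n_fa_pref <- 0L
  for (i in 1:12) {
    ud <- simulate_met_unit(site_means = c(2.4, 2.7, 3.0, 2.5), g = 30, r = 2,
                           lambda = rep(0, 4), specific = rep(0.08, 4),
                           sigma2_g = 0.06, sigma2_rep = 0.01, sigma2_e = 0.1,
                           seed = 400 + i)
    cd <- compare_structures(ud, k_list = 1L)
    n_diag_pref <- n_diag_pref + (attr(cd, "best_k") == 0L)
    uf <- simulate_met_unit(site_means = c(2.4, 2.7, 3.0, 2.5), g = 30, r = 2,
                           lambda = c(0.7, -0.6, 0.5, 0.6), specific = rep(0.03, 4),
                           sigma2_g = 0.06, sigma2_rep = 0.01, sigma2_e = 0.1,
                           seed = 500 + i)
    cf <- compare_structures(uf, k_list = 1L)
    n_fa_pref <- n_fa_pref + (attr(cf, "best_k") >= 1L)
  }
  expect_gte(n_diag_pref, 9L)   # >= 75% of 12
  expect_gte(n_fa_pref, 9L)
})

test_that("a one-site instance yields a one-row comparison matching fit_met", {
  cfg <- sim_config(n_series = 1, sites_per_class = c(low = 1, medium = 0, high = 0),
                    entries_per_trial = 10, n_subblocks = 1, seed = 14)
  tp <- generate_met(cfg)$plots
  tab <- compare_structures(tp, k_list = 0L)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$reml_loglik, fit_met(tp, 0)$reml_loglik, tolerance = 1e-8)
})
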