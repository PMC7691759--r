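test_that("REML components match a brute-force restricted-likelihood grid", {
  # tiny trial: 4 genotypes, 2 reps, 2 sub-blocks
  tp <- make_trial(g = 4L, r = 2L, n_sb = 2L, sigma2_g = 0.4, sigma2_sb = 0.2,
                   sigma2_e = 0.15, seed = 11)
  fit <- fit_single_trial(tp)
  geno <- factor(tp$genotype_id)
  repl <- factor(tp$replicate)
  sb <- factor(paste(tp$replicate, tp$sub_block, sep = ":"))
  X <- stats::model.matrix(~ repl)
  Zg <- stats::model.matrix(~ 0 + geno)
  Zsb <- stats::model.matrix(~ 0 + sb)
  grid_g <- seq(0.01, 1.2, length.out = 25)
  grid_sb <- seq(0.01, 1.2, length.out = 25)
  grid_e <- seq(0.02, 0.8, length.out = 25)
  best <- -Inf; arg <- NULL
  for (a in grid_g) for (b in grid_sb) for (e in grid_e) {
    ll <- oracle_reml_loglik(tp$yield_t_ha, X, list(Zg, Zsb), c(a, b), e)
    if (ll > best) { best <- ll; arg <- c(a, b, e) }
  }
  # the optimizer must do at least as well as the best grid point...
  ll_fit <- oracle_reml_loglik(tp$yield_t_ha, X, list(Zg, Zsb),
                               c(fit$sigma2_g, fit$sigma2_sb),
                               max(fit$sigma2_e, 1e-10))
  expect_gte(ll_fit, best - 1e-8)
  # ...and land within one grid step of the grid argmax
  expect_lt(abs(fit$sigma2_g - arg[1]), diff(grid_g[1:2]) + 1e-9)
  expect_lt(abs(fit$sigma2_sb - arg[2]), diff(grid_sb[1:2]) + 1e-9)
  expect_lt(abs(fit$sigma2_e - arg[3]), diff(grid_e[1:2]) + 1e-9)
})

test_that("variance components agree with an independent REML implementation", {
  skip_if_not_installed("lme4")
  tp <- make_trial(g = 30L, r = 2L, n_sb = 5L, sigma2_g = 0.5, sigma2_sb = 0.15,
                   sigma2_e = 0.25, seed = 23)
  fit <- fit_single_trial(tp)
  d <- data.frame(y = tp$yield_t_ha, geno = factor(tp$genotype_id),
                  repl = factor(tp$replicate),
                  sb = factor(paste(tp$replicate, tp$sub_block)))
  lf <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ repl + (1 | geno) + (1 | sb), data = d, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(lf))
  s2g_l <- vc$vcov[vc$grp == "geno"]
  s2sb_l <- vc$vcov[vc$grp == "sb"]
  s2e_l <- vc$vcov[vc$grp == "Residual"]
  expect_equal(fit$sigma2_g, s2g_l, tolerance = 1e-4)
  expect_equal(fit$sigma2_sb, s2sb_l, tolerance = 1e-3)
  expect_equal(fit$sigma2_e, s2e_l, tolerance = 1e-4)
})

test_that("repeatability centers on the closed-form value", {
  # sigma2_g = sigma2_e = 1, 2 reps: expectation 1 / (1 + 1/2) = 2/3
  reps <- vapply(1:60, function(s) {
    tp <- make_trial(g = 40L, r = 2L, n_sb = 4L, sigma2_g = 1, sigma2_sb = 0.05,
                     sigma2_e = 1, seed = 100 + s)
    fit_single_trial(tp)$repeatability
  }, 0)
  se3 <- 3 * stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 2 / 3), se3)
})

test_that("adjusted entry means equal raw means on complete balanced data", {
  # orthogonality: with every genotype in every replicate, GLS adjustment
  # cannot move the entry means
  tp <- make_trial(g = 12L, r = 2L, n_sb = 1L, sigma2_g = 0.4, sigma2_sb = 0,
                   sigma2_e = 0.2, seed = 31)
  fit <- fit_single_trial(tp)
  raw <- tapply(tp$yield_t_ha, tp$genotype_id, mean)
  expect_equal(unname(fit$adjusted_means[names(raw)]), as.vector(raw),
               tolerance = 1e-8)
})

test_that("repeatability is invariant to shifting and rescaling yields", {
  tp <- make_trial(g = 20L, r = 2L, n_sb = 4L, seed = 17)
  f0 <- fit_single_trial(tp)
  tp_shift <- tp; tp_shift$yield_t_ha <- tp$yield_t_ha + 7
  tp_scale <- tp; tp_scale$yield_t_ha <- tp$yield_t_ha * 3.2
  expect_equal(fit_single_trial(tp_shift)$repeatability, f0$repeatability,
               tolerance = 1e-6)
  expect_equal(fit_single_trial(tp_scale)$repeatability, f0$repeatability,
               tolerance = 1e-6)
})

test_that("a constant trial has repeatability 0 and degenerate components", {
  tp <- make_trial(g = 8L, r = 2L, n_sb = 2L, sigma2_g = 0, sigma2_sb = 0,
                   sigma2_e = 0, seed = 1)
  fit <- fit_single_trial(tp)
  expect_equal(fit$sigma2_g, 0)
  expect_equal(fit$sigma2_e, 0)
  expect_equal(fit$repeatability, 0)
  expect_true(fit$converged)
})

test_that("malformed trials are rejected with the trial named", {
  tp <- make_trial(g = 8L, r = 2L, seed = 2)
  expect_error(fit_single_trial(tp[tp$replicate == 1, ]), "T1")
  tp2 <- rbind(tp, tp[1, ])
  expect_error(fit_single_trial(tp2), "duplicated")
})

test_that("the repeatability filter applies a strict < threshold", {
  sm <- data.frame(trial_id = sprintf("T%d", 1:4), series = 1,
                   mean_yield = 2, sigma2_g = 1, sigma2_sb = 0, sigma2_e = 1,
                   repeatability = c(0.0, 0.049, 0.05, 0.8),
                   converged = TRUE, retained = TRUE)
  out <- filter_trials(sm, quiet = TRUE)
  expect_equal(out$trial_id, c("T3", "T4"))
  expect_equal(attr(out, "n_discarded"), 2L)
  # empty input passes through empty
  empty <- filter_trials(sm[0, ], quiet = TRUE)
  expect_equal(nrow(empty), 0L)
})
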