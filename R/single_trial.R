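# Single-trial alpha-lattice analysis.
#
# The individual-site model is
#   y_ijk = mu + R_j + SB_k(R_j) + G_i + eps_ijk
# with replicates fixed, sub-blocks within replicates random and iid, and an
# iid plot residual. Two companion fits are performed: genotypes fixed (for
# generalized-least-squares adjusted entry means) and genotypes random (for
# the genetic variance feeding the entry-mean repeatability
# sigma2_g / (sigma2_g + sigma2_e / r)).
#
# REML is maximized on error contrasts: with V = sigma2_e (I + sum_m gamma_m
# Z_m Z_m'), the residual scale profiles out and only the variance ratios
# gamma_m are optimized, which keeps the fit fast and honours the
# non-negativity constraints through a log parameterization.

# Orthonormal basis of the orthogonal complement of col(X).
null_basis <- function(X) {
  qx <- qr(X)
  n <- nrow(X)
  if (qx$rank >= n) stop("model has no residual degrees of freedom", call. = FALSE)
  qr.Q(qx, complete = TRUE)[, (qx$rank + 1L):n, drop = FALSE]
}

# Profiled restricted log-likelihood for V = sigma2_e (I + sum gamma_m A_m)
# on contrasts z, with A_m = U_m U_m' of low rank (U_m = L' Z_m). The residual
# scale is profiled out; the determinant and quadratic form are evaluated in
# the rank-q subspace via the Woodbury identity, so each evaluation costs one
# q x q Cholesky instead of an n x n one.
profiled_reml <- function(lgamma, G, Uz, zz, sizes, nu) {
  dvec <- sqrt(exp(rep(lgamma, sizes)))
  M <- diag(length(dvec)) + (dvec %o% dvec) * G
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  b <- dvec * Uz
  w <- backsolve(ch, forwardsolve(t(ch), b))
  ss <- zz - sum(b * w)
  if (ss <= 0) return(-1e10)
  s2 <- ss / nu
  -0.5 * (2 * sum(log(diag(ch))) + nu * log(s2) + nu + nu * log(2 * pi))
}

# Maximize the profiled restricted likelihood over log variance ratios.
# Multi-start L-BFGS-B; returns ratios, sigma2_e, loglik and convergence.
reml_ratios <- function(Umats, z, starts) {
  nu <- length(z)
  zz <- sum(z^2)
  if (zz < 1e-26 * nu) {             # degenerate: no residual variation at all
    return(list(gamma = rep(0, length(Umats)), sigma2_e = 0,
                loglik = Inf, converged = TRUE, degenerate = TRUE))
  }
  if (length(Umats) == 0L) {
    s2 <- zz / nu
    return(list(gamma = numeric(0), sigma2_e = s2,
                loglik = -0.5 * (nu * log(s2) + nu + nu * log(2 * pi)),
                converged = TRUE, degenerate = FALSE))
  }
  U <- do.call(cbind, Umats)
  sizes <- vapply(Umats, ncol, 0L)
  G <- crossprod(U)
  Uz <- drop(crossprod(U, z))
  lower <- rep(log(1e-10), length(Umats))
  upper <- rep(log(1e8), length(Umats))

  if (length(Umats) == 1L) {
    # one ratio: diagonalize once, profile in closed form, optimize in 1-D
    eg <- eigen(G, symmetric = TRUE)
    cc <- drop(crossprod(eg$vectors, Uz))^2
    f1 <- function(lg) {
      gam <- exp(lg)
      ss <- zz - sum(gam * cc / (1 + gam * eg$values))
      if (ss <= 0) return(1e10)
      0.5 * (sum(log1p(gam * eg$values)) + nu * log(ss / nu) + nu +
               nu * log(2 * pi))
    }
    op <- stats::optimize(f1, c(lower, upper), tol = 1e-9)
    # the boundary (ratio ~ 0) can beat the interior optimum
    cand <- if (f1(lower) <= op$objective) lower else op$minimum
    gam <- exp(cand)
    ss <- zz - sum(gam * cc / (1 + gam * eg$values))
    s2 <- ss / nu
    if (gam <= 1.5e-10) gam <- 0
    return(list(gamma = gam, sigma2_e = s2,
                loglik = -if (cand == lower) f1(lower) else op$objective,
                converged = TRUE, degenerate = FALSE))
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(st, lower), upper),
                   function(p) -profiled_reml(p, G, Uz, zz, sizes, nu),
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$convergence == 0) break   # converged: skip the backup starts
  }
  if (is.null(best))
    return(list(gamma = rep(NA_real_, length(Umats)), sigma2_e = NA_real_,
                loglik = NA_real_, converged = FALSE, degenerate = FALSE))
  gam <- exp(best$par)
  dvec <- sqrt(rep(gam, sizes))
  M <- diag(length(dvec)) + (dvec %o% dvec) * G
  b <- dvec * Uz
  ss <- zz - sum(b * solve(M, b))
  s2 <- ss / nu
  gam[gam <= 1.5e-10] <- 0
  list(gamma = gam, sigma2_e = s2, loglik = -best$value,
       converged = best$convergence == 0, degenerate = FALSE)
}

#' Fit the single-trial alpha-lattice model
#'
#' Fits the individual-site model (fixed replicates, random sub-blocks within
#' replicates) twice: with genotypes fixed, to obtain generalized
#' least-squares adjusted entry means at the REML variance estimates, and with
#' genotypes random, to obtain the genetic variance used for the entry-mean
#' repeatability \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_\varepsilon / r)}.
#'
#' A trial with neither genetic nor residual variance has repeatability
#' defined as 0 so it is filtered out rather than producing 0/0.
#'
#' @param plots data frame of plot records for one trial with columns
#'   `genotype_id`, `replicate`, `sub_block`, `yield_t_ha` (and optionally
#'   `trial_id`, `series`).
#' @return an object of class `trial_fit` with the variance components of both
#'   companion fits, the repeatability, the adjusted entry means, the
#'   genotype BLUPs of the random fit and the restricted log-likelihood.
#' @export
fit_single_trial <- function(plots) {
  trial_id <- if ("trial_id" %in% names(plots)) as.character(plots$trial_id[1]) else "trial"
  req <- c("genotype_id", "replicate", "sub_block", "yield_t_ha")
  miss <- setdiff(req, names(plots))
  if (length(miss))
    stop("trial '", trial_id, "': missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  plots <- plots[stats::complete.cases(plots[req]), , drop = FALSE]
  y <- plots$yield_t_ha
  geno <- factor(plots$genotype_id)
  repl <- factor(plots$replicate)
  if (nlevels(repl) < 2L)
    stop("trial '", trial_id, "': fewer than 2 replicates", call. = FALSE)
  if (any(table(geno) < 1L) || nlevels(geno) < 2L)
    stop("trial '", trial_id, "': degenerate genotype structure", call. = FALSE)
  if (anyDuplicated(paste(geno, repl)))
    stop("trial '", trial_id, "': duplicated (genotype, replicate) plots",
         call. = FALSE)
  sb <- factor(paste(plots$replicate, plots$sub_block, sep = ":"))
  n <- length(y)
  r_eff <- length(y) / nlevels(geno)   # plots per entry (balanced: n_reps)

  Zsb <- stats::model.matrix(~ 0 + sb)
  Zg <- stats::model.matrix(~ 0 + geno)

  # --- companion fit (a): genotypes fixed -> adjusted means -----------------
  Xf <- stats::model.matrix(~ repl + geno)
  fit_a <- tryCatch({
    L <- null_basis(Xf)
    z <- drop(crossprod(L, y))
    reml_ratios(list(crossprod(L, Zsb)), z, starts = list(log(0.25), log(2)))
  }, error = function(e) stop("trial '", trial_id, "': ", conditionMessage(e),
                              call. = FALSE))
  s2_sb_fix <- if (length(fit_a$gamma)) fit_a$gamma[1] * fit_a$sigma2_e else 0
  # GLS adjusted entry means at the estimates
  Vfull <- fit_a$sigma2_e * diag(n) + s2_sb_fix * tcrossprod(Zsb)
  if (fit_a$sigma2_e <= 0 && s2_sb_fix <= 0) Vfull <- diag(n)  # noise-free: OLS
  Vi <- solve(Vfull)
  XtVi <- crossprod(Xf, Vi)
  beta <- drop(solve(XtVi %*% Xf, XtVi %*% y))
  gl <- levels(geno)
  gcoef <- c(0, beta[grep("^geno", names(beta))])
  rcoef <- c(0, beta[grep("^repl", names(beta))])
  adj_means <- beta[["(Intercept)"]] + gcoef + mean(rcoef)
  names(adj_means) <- gl

  # --- companion fit (b): genotypes random -> repeatability -----------------
  Xr <- stats::model.matrix(~ repl)
  fit_b <- tryCatch({
    L <- null_basis(Xr)
    z <- drop(crossprod(L, y))
    # moment-based start: within-genotype scatter approximates
    # sigma2_e + sigma2_sb, between-genotype scatter adds sigma2_g
    wv <- mean(tapply(y, geno, stats::var), na.rm = TRUE)
    s2e0 <- max(wv, 1e-6)
    gv <- max(stats::var(tapply(y, geno, mean)) - s2e0 / r_eff, 1e-3 * s2e0)
    reml_ratios(list(crossprod(L, Zg), crossprod(L, Zsb)), z,
                starts = list(c(log(gv / s2e0), log(0.2)),
                              c(log(0.05), log(1))))
  }, error = function(e) stop("trial '", trial_id, "': ", conditionMessage(e),
                              call. = FALSE))

  if (fit_b$degenerate) {
    s2_g <- 0; s2_sb <- 0; s2_e <- 0
  } else {
    s2_g <- fit_b$gamma[1] * fit_b$sigma2_e
    s2_sb <- fit_b$gamma[2] * fit_b$sigma2_e
    s2_e <- fit_b$sigma2_e
  }
  denom <- s2_g + s2_e / r_eff
  repeatability <- if (is.na(denom) || denom <= .VAR_FLOOR * max(1, stats::var(y)))
    0 else s2_g / denom
  repeatability <- min(max(repeatability, 0), 1)

  # genotype BLUPs from the random fit
  blups <- stats::setNames(rep(0, nlevels(geno)), gl)
  if (isTRUE(fit_b$converged) && !fit_b$degenerate && s2_g > 0) {
    Vb <- s2_e * diag(n) + s2_g * tcrossprod(Zg) + s2_sb * tcrossprod(Zsb)
    Vbi <- solve(Vb)
    XtVi <- crossprod(Xr, Vbi)
    bb <- drop(solve(XtVi %*% Xr, XtVi %*% y))
    blups <- drop(s2_g * crossprod(Zg, Vbi %*% (y - Xr %*% bb)))
    names(blups) <- gl
  }

  structure(list(trial_id = trial_id,
                 series = if ("series" %in% names(plots)) plots$series[1] else NA_integer_,
                 n_plots = n,
                 n_entries = nlevels(geno),
                 n_reps = nlevels(repl),
                 mean_yield = mean(y),
                 sigma2_g = s2_g,
                 sigma2_sb = s2_sb,
                 sigma2_e = s2_e,
                 sigma2_sb_fixedfit = s2_sb_fix,
                 sigma2_e_fixedfit = fit_a$sigma2_e,
                 repeatability = repeatability,
                 repeatability_basis = "entry-mean",
                 adjusted_means = adj_means,
                 blups_g = blups,
                 reml_loglik = fit_b$loglik,
                 converged = isTRUE(fit_a$converged) && isTRUE(fit_b$converged)),
            class = "trial_fit")
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("Single-trial fit:", x$trial_id, "\n")
  cat(sprintf("  %d entries x %d reps (%d plots), mean yield %.3f t/ha\n",
              x$n_entries, x$n_reps, x$n_plots, x$mean_yield))
  cat(sprintf("  sigma2_g = %.4g  sigma2_sb = %.4g  sigma2_e = %.4g\n",
              x$sigma2_g, x$sigma2_sb, x$sigma2_e))
  cat(sprintf("  repeatability (%s) = %.3f%s\n", x$repeatability_basis,
              x$repeatability,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.trial_fit <- function(object, ...) object$adjusted_means

#' Summarise a list of single-trial fits as one table
#'
#' @param fits a list of `trial_fit` objects.
#' @return data frame with one row per trial: identifiers, mean yield,
#'   variance components, repeatability and a `retained` flag (`TRUE` for
#'   converged fits; the repeatability filter refines it).
#' @export
trial_summaries <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(trial_id = f$trial_id, series = f$series,
               mean_yield = f$mean_yield,
               sigma2_g = f$sigma2_g, sigma2_sb = f$sigma2_sb,
               sigma2_e = f$sigma2_e,
               repeatability = f$repeatability,
               converged = f$converged,
               retained = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discard trials with low repeatability
#'
#' Keeps exactly the converged trials whose repeatability is at or above the
#' threshold; the boundary is strict on the discard side (a trial with
#' repeatability exactly equal to the threshold is retained).
#'
#' @param summaries data frame from [trial_summaries()].
#' @param threshold repeatability threshold (default 0.05).
#' @param quiet suppress the message reporting the discard count.
#' @return the retained rows, with `retained = TRUE`; the number of discarded
#'   trials is attached as attribute `n_discarded`.
#' @export
filter_trials <- function(summaries, threshold = 0.05, quiet = FALSE) {
  if (NROW(summaries) == 0L) {
    out <- summaries
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  keep <- summaries$converged & !is.na(summaries$repeatability) &
    summaries$repeatability >= threshold
  out <- summaries[keep, , drop = FALSE]
  if (nrow(out)) out$retained <- TRUE
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  if (!quiet)
    message(sum(!keep), " of ", length(keep),
            " trials discarded (repeatability < ", threshold, " or not converged)")
  out
}
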