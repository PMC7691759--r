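# Combined multi-site mixed model with a factor-analytic GE covariance.
#
#   y = X b + Z_r r + Z_g g + Z_ge ge + e
#
# with fixed site effects b, random replicates within sites
# (Sigma_r = diag(sigma2_rj)), random genotype main effects (sigma2_g I),
# random genotype-by-site deviations with between-site covariance
# Sigma_ge = Lambda Lambda' + D (factor-analytic, rank k), and iid residuals.
#
# REML is maximized by quasi-Newton (L-BFGS-B) on log-variance / free-loading
# parameters. For complete balanced units the restricted likelihood is
# evaluated through an exact stratum factorization (genotype-by-replicate
# interaction stratum, per-site replicate strata, genotype-mean stratum),
# which reduces every evaluation to an s x s problem; otherwise a dense n x n
# covariance path is used. BLUPs come from closed forms in the balanced case
# and from Henderson's mixed-model equations in the dense case.

# ---- parameter bookkeeping -------------------------------------------------

# A parameter map for a unit with s sites, k factors, replication r.
# Slots: log_s2e, log_s2r (s), log_s2g, lambda (free entries), log_d (s).
fa_par_map <- function(s, k, r, fix = list()) {
  has_e <- r > 1L && !("sigma2_e" %in% names(fix))
  has_r <- r > 1L
  has_ge <- s > 1L
  lam_free <- if (has_ge && k > 0L) {
    which(outer(seq_len(s), seq_len(k), ">="))  # Lambda[i,q] free iff i >= q
  } else integer(0)
  list(s = s, k = k, r = r, fix = fix,
       has_e = has_e, has_r = has_r, has_ge = has_ge,
       opt_g = !("sigma2_g" %in% names(fix)),
       lam_free = lam_free,
       n_par = sum(has_e, has_r * s, !("sigma2_g" %in% names(fix)),
                   length(lam_free), has_ge * s))
}

# Unpack an optimizer vector into named components.
fa_unpack <- function(theta, pm) {
  i <- 0L
  take <- function(m) { v <- theta[(i + 1L):(i + m)]; i <<- i + m; v }
  s2e <- if (pm$has_e) unname(exp(take(1L))) else if (pm$r > 1L) pm$fix$sigma2_e else 0
  s2r <- if (pm$has_r) unname(exp(take(pm$s))) else rep(0, pm$s)
  s2g <- if (pm$opt_g) unname(exp(take(1L))) else pm$fix$sigma2_g
  Lam <- matrix(0, pm$s, max(pm$k, 1L))
  if (length(pm$lam_free)) Lam[pm$lam_free] <- take(length(pm$lam_free))
  d <- if (pm$has_ge) exp(take(pm$s)) else rep(0, pm$s)
  list(s2e = s2e, s2r = s2r, s2g = s2g,
       Lambda = Lam[, seq_len(max(pm$k, 0L)), drop = FALSE], d = d)
}

fa_bounds <- function(pm) {
  lo <- hi <- numeric(0)
  add <- function(l, h, m) { lo <<- c(lo, rep(l, m)); hi <<- c(hi, rep(h, m)) }
  if (pm$has_e) add(log(1e-8), log(1e4), 1L)
  if (pm$has_r) add(log(1e-8), log(1e4), pm$s)
  if (pm$opt_g) add(log(1e-8), log(1e4), 1L)
  if (length(pm$lam_free)) add(-100, 100, length(pm$lam_free))
  if (pm$has_ge) add(log(1e-8), log(1e4), pm$s)
  list(lower = lo, upper = hi)
}

# ---- balanced-stratum machinery -------------------------------------------

# Sufficient statistics of a complete balanced unit.
fa_strata <- function(y, site, geno, repl) {
  s <- nlevels(site); g <- nlevels(geno); r <- nlevels(repl)
  # genotype x site means
  Y <- matrix(0, g, s, dimnames = list(levels(geno), levels(site)))
  cnt <- matrix(0L, g, s)
  ig <- as.integer(geno); is <- as.integer(site); ir <- as.integer(repl)
  for (a in seq_along(y)) {
    Y[ig[a], is[a]] <- Y[ig[a], is[a]] + y[a]
    cnt[ig[a], is[a]] <- cnt[ig[a], is[a]] + 1L
  }
  Y <- Y / cnt
  # replicate means per site and interaction SS
  repmean <- matrix(0, s, r)
  for (a in seq_along(y)) repmean[is[a], ir[a]] <- repmean[is[a], ir[a]] + y[a]
  repmean <- repmean / g
  sitemean <- rowMeans(repmean)
  SS_rep <- g * rowSums((repmean - sitemean)^2)
  fitted <- Y[cbind(ig, is)] + repmean[cbind(is, ir)] - sitemean[is]
  SS_int <- sum((y - fitted)^2)
  Dc <- sweep(Y, 2L, colMeans(Y))
  S <- crossprod(Dc) / (g - 1L)
  list(s = s, g = g, r = r, Y = Y, Dc = Dc, S = S,
       SS_rep = SS_rep, SS_int = SS_int, nu_int = s * (g - 1L) * (r - 1L),
       repmean = repmean, sitemean = sitemean)
}

# Exact restricted log-likelihood via the stratum factorization.
fa_loglik_strat <- function(theta, pm, st) {
  p <- fa_unpack(theta, pm)
  ll <- 0
  if (st$r > 1L) {
    if (p$s2e <= 0) return(-1e10)
    ll <- ll - 0.5 * (st$nu_int * log(p$s2e) + st$SS_int / p$s2e +
                        st$nu_int * log(2 * pi))
    v <- st$g * p$s2r + p$s2e
    ll <- ll - 0.5 * sum((st$r - 1L) * log(v) + st$SS_rep / v +
                           (st$r - 1L) * log(2 * pi))
  }
  Sig <- fa_sigma_tot(p, st$r)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% st$S))
  # the orthonormal genotype contrasts of replicate means carry a factor
  # sqrt(r): account for the Jacobian so the value matches the dense path
  ll - 0.5 * (st$g - 1L) * (logdet + tr + st$s * (log(2 * pi) + log(st$r)))
}

# Analytic gradient of fa_loglik_strat with respect to the optimizer vector
# (log-variances and free loadings). Uses d log|S|/dS = S^-1 and
# d tr(S^-1 A)/dS = -S^-1 A S^-1, chained through the parameterization.
fa_grad_strat <- function(theta, pm, st) {
  p <- fa_unpack(theta, pm)
  g_e <- 0
  g_r <- numeric(pm$s)
  if (st$r > 1L) {
    g_e <- -0.5 * (st$nu_int - st$SS_int / p$s2e)          # d/dlog s2e, stratum 1
    v <- st$g * p$s2r + p$s2e
    base <- -0.5 * ((st$r - 1L) / v - st$SS_rep / v^2)
    g_r <- base * st$g * p$s2r                              # d/dlog s2r_s
    g_e <- g_e + sum(base) * p$s2e                          # s2e enters each v_s
  }
  Sig <- fa_sigma_tot(p, st$r)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(rep(0, length(theta)))
  Si <- chol2inv(ch)
  G3 <- -0.5 * (st$g - 1L) * (Si - Si %*% st$S %*% Si)
  if (st$r > 1L) g_e <- g_e + sum(diag(G3)) * p$s2e / st$r
  g_g <- p$s2g * sum(G3)
  grad <- numeric(0)
  if (pm$has_e) grad <- c(grad, g_e)
  if (pm$has_r) grad <- c(grad, g_r)
  if (pm$opt_g) grad <- c(grad, g_g)
  if (length(pm$lam_free)) {
    GL <- 2 * (G3 %*% p$Lambda)
    grad <- c(grad, GL[pm$lam_free])
  }
  if (pm$has_ge) grad <- c(grad, diag(G3) * p$d)
  grad
}

# Between-site covariance of genotype-by-replicate means:
# sigma2_g J + Lambda Lambda' + D + sigma2_e / r I
fa_sigma_tot <- function(p, r) {
  s <- length(p$d)
  Sig <- matrix(p$s2g, s, s)
  if (ncol(p$Lambda) > 0L) Sig <- Sig + tcrossprod(p$Lambda)
  diag(Sig) <- diag(Sig) + p$d + if (r > 1L) p$s2e / r else 0
  Sig
}

# ---- dense machinery -------------------------------------------------------

fa_dense_prep <- function(y, site, geno, repl) {
  n <- length(y)
  X <- stats::model.matrix(~ 0 + site)
  Eg <- outer(as.integer(geno), as.integer(geno), "==")
  sr <- paste(as.integer(site), as.integer(repl))
  Esr <- outer(sr, sr, "==")
  qx <- qr(X)
  list(n = n, X = X, qrX = qx, Eg = Eg, Esr = Esr,
       site_i = as.integer(site), geno_i = as.integer(geno),
       nu = n - qx$rank, ldXtX = determinant(crossprod(X))$modulus[1])
}

fa_build_V <- function(p, dn) {
  V <- p$s2g * dn$Eg
  if (length(p$d) > 1L || ncol(p$Lambda) > 0L) {
    Sge <- fa_sigma_ge(p)
    V <- V + Sge[dn$site_i, dn$site_i] * dn$Eg
  }
  V <- V + dn$Esr * matrix(p$s2r[dn$site_i], dn$n, dn$n)
  diag(V) <- diag(V) + p$s2e
  V
}

fa_sigma_ge <- function(p) {
  s <- length(p$d)
  Sge <- if (ncol(p$Lambda) > 0L) tcrossprod(p$Lambda) else matrix(0, s, s)
  diag(Sge) <- diag(Sge) + p$d
  Sge
}

fa_loglik_dense <- function(theta, pm, dn, y) {
  p <- fa_unpack(theta, pm)
  if (dn$nu <= 0) return(-1e10)
  V <- fa_build_V(p, dn)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  Vi <- chol2inv(ch)
  XtVi <- crossprod(dn$X, Vi)
  A <- XtVi %*% dn$X
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(-1e10)
  beta <- drop(backsolve(chA, forwardsolve(t(chA), XtVi %*% y)))
  res <- y - dn$X %*% beta
  quad <- drop(crossprod(res, Vi %*% res))
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chA))) - dn$ldXtX +
            quad + dn$nu * log(2 * pi))
}

# ---- starting values -------------------------------------------------------

fa_starts <- function(pm, st) {
  s2e0 <- if (st$r > 1L) max(st$SS_int / max(st$nu_int, 1L), 1e-4) else 1e-4
  s2r0 <- pmax((st$SS_rep / max(st$r - 1L, 1L) - s2e0) / st$g, 1e-4)
  S <- st$S
  off <- S[upper.tri(S)]
  s2g0 <- if (length(off)) max(mean(off), 1e-4) else max(mean(diag(S)) / 2, 1e-4)
  base <- list()
  i <- 1L
  make_theta <- function(lam0, d0) {
    th <- numeric(0)
    if (pm$has_e) th <- c(th, log(s2e0))
    if (pm$has_r) th <- c(th, log(s2r0))
    if (pm$opt_g) th <- c(th, log(s2g0))
    if (length(pm$lam_free)) {
      L <- matrix(0, pm$s, pm$k); L[pm$lam_free] <- NA
      full <- matrix(rep_len(lam0, pm$s * pm$k), pm$s, pm$k)
      th <- c(th, full[pm$lam_free])
    }
    if (pm$has_ge) th <- c(th, log(pmax(d0, 1e-4)))
    th
  }
  starts <- list()
  if (pm$has_ge) {
    C0 <- S - s2g0 - diag(s2e0 / st$r, pm$s)
    C0 <- (C0 + t(C0)) / 2
    ev <- eigen(C0, symmetric = TRUE)
    lam0 <- if (pm$k > 0L) sqrt(max(ev$values[1], 1e-4)) * ev$vectors[, 1] else 0
    d0 <- pmax(diag(C0) - if (pm$k > 0L) lam0^2 else 0, 1e-3)
    starts[[1]] <- make_theta(lam0, d0)
    starts[[2]] <- make_theta(rep(sqrt(max(mean(diag(S)) / 4, 1e-4)), pm$s),
                              rep(max(mean(diag(S)) / 4, 1e-4), pm$s))
  } else {
    starts[[1]] <- make_theta(0, 1)
    starts[[2]] <- starts[[1]] * 0.5
  }
  starts
}

# ---- main fit --------------------------------------------------------------

#' Fit the factor-analytic multi-environment mixed model
#'
#' Fits the combined model with fixed site effects, random replicates within
#' sites, random genotype main effects and a genotype-by-site deviation whose
#' between-site covariance has the factor-analytic form
#' \eqn{\Lambda \Lambda' + D} with `n_factors` columns in \eqn{\Lambda}.
#' Identifiability is imposed by zeros above the diagonal of the leading
#' k x k block of \eqn{\Lambda} and by requiring the first nonzero entry of
#' each column to be nonnegative. With a single site the GE term is dropped
#' (it is confounded with the genotype main effect) and the model reduces to
#' the single-trial model with genotypes random.
#'
#' For complete balanced units (every genotype in every replicate of every
#' site) the restricted likelihood is evaluated exactly through its stratum
#' factorization; otherwise a dense covariance path is used (practical up to
#' a few thousand plots).
#'
#' @param plots plot records of one analysis unit: columns `site_id` (or
#'   `trial_id`), `genotype_id`, `replicate`, `yield_t_ha`, optionally
#'   `is_check`.
#' @param n_factors number of multiplicative terms k (0 = diagonal GE).
#' @param method `"auto"` picks the stratified path for balanced data.
#' @param fix optional named list fixing `sigma2_g` and/or `sigma2_e` instead
#'   of estimating them.
#' @param control list: `maxit` (default 400).
#' @return an object of class `met_fa` with loadings, specific variances, the
#'   implied GE covariance, variance components, site effects, genotype and
#'   GE BLUPs, the restricted log-likelihood and convergence metadata.
#' @export
fit_met <- function(plots, n_factors = 1L,
                    method = c("auto", "stratified", "dense"),
                    fix = list(), control = list()) {
  method <- match.arg(method)
  sid <- if ("site_id" %in% names(plots)) plots$site_id else plots$trial_id
  site <- factor(sid)
  geno <- factor(plots$genotype_id)
  repl <- factor(paste(sid, plots$replicate, sep = ":"))
  # replicate index within site
  rep_in_site <- factor(plots$replicate)
  y <- plots$yield_t_ha
  if (length(y) == 0L) stop("empty analysis unit", call. = FALSE)
  s <- nlevels(site); g <- nlevels(geno)
  n_factors <- as.integer(n_factors)
  if (n_factors > s) stop("n_factors must not exceed the number of sites",
                          call. = FALSE)
  k <- if (s == 1L) 0L else n_factors

  tab <- table(site, geno, rep_in_site)
  balanced <- all(tab == 1L)
  r <- if (balanced) nlevels(rep_in_site) else NA_integer_
  use_strat <- balanced && method != "dense" && g >= 3L
  if (!use_strat && length(y) > 2500L)
    stop("unit too large for the dense path; supply complete balanced data",
         call. = FALSE)

  maxit <- if (is.null(control$maxit)) 400L else control$maxit

  if (use_strat) {
    st <- fa_strata(y, site, geno, rep_in_site)
    pm <- fa_par_map(s, k, st$r, fix)
    objective <- function(th) -fa_loglik_strat(th, pm, st)
    gradient <- function(th) -fa_grad_strat(th, pm, st)
    starts <- fa_starts(pm, st)
  } else {
    r_dense <- if (balanced) nlevels(rep_in_site) else 2L
    pm <- fa_par_map(s, k, max(r_dense, 2L), fix)
    dn <- fa_dense_prep(y, site, geno, repl)
    objective <- function(th) -fa_loglik_dense(th, pm, dn, y)
    gradient <- NULL                       # numeric gradient: instances are small
    st_apx <- tryCatch(fa_strata(y, site, geno, rep_in_site),
                       error = function(e) NULL)
    starts <- if (balanced && !is.null(st_apx)) fa_starts(pm, st_apx) else {
      v <- stats::var(y)
      th0 <- numeric(0)
      if (pm$has_e) th0 <- c(th0, log(v / 2))
      if (pm$has_r) th0 <- c(th0, rep(log(v / 10), s))
      if (pm$opt_g) th0 <- c(th0, log(v / 4))
      if (length(pm$lam_free)) th0 <- c(th0, rep(sqrt(v / 10), length(pm$lam_free)))
      if (pm$has_ge) th0 <- c(th0, rep(log(v / 5), s))
      list(th0, th0 + log(2) * c(rep(1, pm$n_par)))
    }
  }

  bd <- fa_bounds(pm)
  best <- NULL
  trace <- list()
  if (pm$n_par > 0L) {
    for (th0 in starts) {
      opt <- tryCatch(
        stats::optim(pmin(pmax(th0, bd$lower), bd$upper), objective, gradient,
                     method = "L-BFGS-B", lower = bd$lower, upper = bd$upper,
                     control = list(maxit = maxit, factr = 1e7)),
        error = function(e) NULL)
      if (is.null(opt)) next
      trace[[length(trace) + 1L]] <- c(value = -opt$value, conv = opt$convergence)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best))
      stop("REML fit failed for every starting value; trace: ",
           paste(vapply(trace, function(x) sprintf("%.3f", x[1]), ""),
                 collapse = ", "), call. = FALSE)
    theta <- best$par
    loglik <- -best$value
    converged <- best$convergence == 0
  } else {
    theta <- numeric(0)
    loglik <- -objective(theta)
    converged <- TRUE
  }
  p <- fa_unpack(theta, pm)

  # sign convention: first nonzero entry of each loading column nonnegative
  if (ncol(p$Lambda) > 0L) {
    for (q in seq_len(ncol(p$Lambda))) {
      col <- p$Lambda[, q]
      nz <- which(abs(col) > 1e-10)
      if (length(nz) && col[nz[1]] < 0) p$Lambda[, q] <- -col
    }
  }
  heywood <- pm$has_ge && any(p$d <= 1.5e-8)
  # snap boundary estimates to zero before computing BLUPs so the stored
  # components and the predictions are mutually consistent
  if (any(p$s2r <= 1.5e-8)) p$s2r[p$s2r <= 1.5e-8] <- 0
  if (pm$opt_g && p$s2g <= 1.5e-8) p$s2g <- 0

  site_lev <- levels(site); geno_lev <- levels(geno)
  Sge <- if (s > 1L) fa_sigma_ge(p) else matrix(0, 1, 1)
  dimnames(Sge) <- list(site_lev, site_lev)

  if (use_strat) {
    Sig <- fa_sigma_tot(p, st$r)
    W <- st$Dc %*% solve(Sig)
    blups_g <- p$s2g * rowSums(W)
    blups_ge <- if (s > 1L) W %*% Sge else matrix(0, g, 1)
    site_eff <- colMeans(st$Y)
    shrink <- (st$g * p$s2r) / (st$g * p$s2r + p$s2e)
    blups_rep <- sweep(st$repmean - st$sitemean, 1L, shrink, "*")
  } else {
    hb <- fa_mme_blups(p, y, site, geno, repl, s, g)
    blups_g <- hb$g
    blups_ge <- hb$ge
    site_eff <- hb$b
    blups_rep <- hb$rep
  }
  names(blups_g) <- geno_lev
  dimnames(blups_ge) <- list(geno_lev, if (s > 1L) site_lev else site_lev[1])
  names(site_eff) <- site_lev
  if (p$s2g == 0) blups_g[] <- 0

  structure(list(n_factors = k,
                 loadings = structure(p$Lambda, dimnames = list(site_lev, NULL)),
                 specific_vars = stats::setNames(p$d, site_lev),
                 ge_cov = Sge,
                 sigma2_g = p$s2g,
                 rep_variances = stats::setNames(p$s2r, site_lev),
                 sigma2_e = p$s2e,
                 site_effects = site_eff,
                 blups_g = blups_g,
                 blups_ge = blups_ge,
                 blups_rep = blups_rep,
                 reml_loglik = loglik,
                 n_params = pm$n_par,
                 converged = converged,
                 heywood = heywood,
                 method = if (use_strat) "stratified" else "dense",
                 n_sites = s, n_genotypes = g,
                 n_plots = length(y),
                 is_check = tapply(if (is.null(plots$is_check))
                   rep(FALSE, length(y)) else as.logical(plots$is_check),
                   geno, any),
                 trace = trace),
            class = "met_fa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Henderson mixed-model-equation BLUPs for the dense path.
fa_mme_blups <- function(p, y, site, geno, repl, s, g) {
  X <- stats::model.matrix(~ 0 + site)
  site_of_rep <- as.integer(factor(sub(":.*$", "", levels(repl)),
                                   levels = levels(site)))
  rv <- p$s2r[site_of_rep]
  use_r <- any(rv > 0)
  # a replicate term with zero variance has BLUP zero: drop it from the MME
  Zr <- if (use_r) stats::model.matrix(~ 0 + repl)[, rv > 0, drop = FALSE]
  use_g <- p$s2g > 0
  Zg <- if (use_g) stats::model.matrix(~ 0 + geno)
  use_ge <- s > 1L
  if (use_ge) {
    gef <- factor(paste(as.integer(geno), as.integer(site), sep = ":"),
                  levels = as.vector(outer(seq_len(g), seq_len(s),
                                           function(a, b) paste(a, b, sep = ":"))))
    Zge <- stats::model.matrix(~ 0 + gef)
  } else Zge <- NULL
  Z <- cbind(Zr, Zg, Zge)
  Ginv_blocks <- list()
  if (use_r) Ginv_blocks <- list(diag(1 / rv[rv > 0], sum(rv > 0)))
  if (use_g) Ginv_blocks <- c(Ginv_blocks, list(diag(1 / p$s2g, g)))
  if (use_ge) {
    Sge <- fa_sigma_ge(p)
    Sgei <- tryCatch(solve(Sge), error = function(e) {
      diag(Sge) <- diag(Sge) + 1e-12
      solve(Sge)
    })
    Ginv_blocks <- c(Ginv_blocks, list(Sgei %x% diag(g)))
  }
  Ginv <- matrix(0, ncol(Z), ncol(Z))
  at <- 0L
  for (B in Ginv_blocks) {
    idx <- at + seq_len(nrow(B)); Ginv[idx, idx] <- B; at <- at + nrow(B)
  }
  s2e <- max(p$s2e, 1e-10)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + s2e * Ginv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  b <- sol[seq_len(ncol(X))]
  u <- sol[-seq_len(ncol(X))]
  at <- 0L
  u_r <- stats::setNames(rep(0, nlevels(repl)), levels(repl))
  if (use_r) {
    u_r[rv > 0] <- u[seq_len(sum(rv > 0))]; at <- sum(rv > 0)
  }
  u_g <- if (use_g) { v <- u[at + seq_len(g)]; at <- at + g; v } else rep(0, g)
  u_ge <- if (use_ge) matrix(u[at + seq_len(s * g)], g, s) else matrix(0, g, 1)
  list(b = b, g = u_g, ge = u_ge, rep = u_r)
}

#' @export
print.met_fa <- function(x, ...) {
  cat(sprintf("Factor-analytic MET fit: %d sites x %d genotypes (%d plots), FA(%d), %s path\n",
              x$n_sites, x$n_genotypes, x$n_plots, x$n_factors, x$method))
  cat(sprintf("  sigma2_g = %.4g  sigma2_e = %.4g  REML loglik = %.3f (%d variance params)\n",
              x$sigma2_g, x$sigma2_e, x$reml_loglik, x$n_params))
  if (x$n_sites > 1L) {
    rho <- stats::cov2cor(x$ge_cov + diag(1e-12, x$n_sites))
    cat(sprintf("  GE correlations in [%.2f, %.2f]%s\n",
                min(rho[upper.tri(rho)]), max(rho[upper.tri(rho)]),
                if (x$heywood) "  [specific variance at floor]" else ""))
  }
  invisible(x)
}

#' @export
summary.met_fa <- function(object, ...) {
  out <- list(fit = object,
              varcomp = c(sigma2_g = object$sigma2_g,
                          sigma2_e = object$sigma2_e,
                          mean_rep_var = mean(object$rep_variances)),
              blups = blup_table(object))
  class(out) <- "summary.met_fa"
  out
}

#' @export
print.summary.met_fa <- function(x, ...) {
  print(x$fit)
  cat("\nTop predicted lines:\n")
  bt <- x$blups[order(-x$blups$predicted_yield_t_ha), ]
  print(utils::head(bt, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.met_fa <- function(object, ...) {
  c(sigma2_g = object$sigma2_g, sigma2_e = object$sigma2_e,
    stats::setNames(object$rep_variances,
                    paste0("sigma2_r.", names(object$rep_variances))),
    stats::setNames(object$specific_vars,
                    paste0("d.", names(object$specific_vars))))
}

#' @export
logLik.met_fa <- function(object, ...) {
  structure(object$reml_loglik, df = object$n_params, class = "logLik")
}

#' Per-genotype predicted yield for an analysis unit
#'
#' Predicted yield of each line for the unit: the mean of the fixed site
#' effects plus the genotype BLUP plus the mean of the genotype's GE BLUPs
#' over the unit's sites (so the prediction does not depend on how the fitted
#' covariance splits genotype main effect and a near-constant loading
#' column). Checks and entries are reported identically.
#'
#' @param fit a [fit_met()] object.
#' @return data frame `genotype_id, is_check, predicted_yield_t_ha`.
#' @export
blup_table <- function(fit) {
  stopifnot(inherits(fit, "met_fa"))
  pred <- mean(fit$site_effects) + fit$blups_g +
    if (fit$n_sites > 1L) rowMeans(fit$blups_ge) else 0
  data.frame(genotype_id = names(fit$blups_g),
             is_check = as.logical(fit$is_check[names(fit$blups_g)]),
             predicted_yield_t_ha = unname(pred),
             stringsAsFactors = FALSE)
}

#' Compare factor-analytic structures of increasing rank
#'
#' Fits the diagonal GE baseline (k = 0) and FA(k) for each requested k, and
#' reports the restricted log-likelihood, the variance-parameter count and
#' AIC computed from the restricted likelihood. All fits share the same fixed
#' effects, so the restricted likelihoods are comparable.
#'
#' @param plots plot records of one analysis unit (see [fit_met()]).
#' @param k_list integer vector of factor counts to fit.
#' @param ... passed to [fit_met()].
#' @return data frame `k, reml_loglik, n_params, AIC`, best structure first
#'   attached as attribute `best_k`.
#' @export
compare_structures <- function(plots, k_list = c(1L, 2L), ...) {
  ks <- sort(unique(c(0L, as.integer(k_list))))
  rows <- lapply(ks, function(k) {
    f <- fit_met(plots, n_factors = k, ...)
    data.frame(k = k, reml_loglik = f$reml_loglik, n_params = f$n_params,
               AIC = -2 * f$reml_loglik + 2 * f$n_params)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_k") <- out$k[which.min(out$AIC)]
  out
}
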