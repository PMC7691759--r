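# Independent oracle routines used across the test files. Each one is coded
# from the model definition directly (dense matrices, enumeration, brute
# force) and shares no code path with the package internals it checks.

# Restricted log-likelihood of y = X beta + sum_m Z_m u_m + e evaluated from
# scratch on orthonormal error contrasts.
oracle_reml_loglik <- function(y, X, Zlist, varcomps, sigma2_e) {
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (m in seq_along(Zlist)) V <- V + varcomps[m] * tcrossprod(Zlist[[m]])
  qx <- qr(X)
  L <- qr.Q(qx, complete = TRUE)[, (qx$rank + 1L):n, drop = FALSE]
  Vc <- crossprod(L, V %*% L)
  z <- drop(crossprod(L, y))
  ld <- determinant(Vc, logarithm = TRUE)$modulus[1]
  -0.5 * (ld + sum(z * solve(Vc, z)) + length(z) * log(2 * pi))
}

# BLUP via the projection identity u_hat = G Z' P y with P built from a dense
# V inverse (independent of both the package's Henderson solve and its
# balanced closed forms). `Gu` is the full covariance of u = (u_1', u_2',...)'.
oracle_blup <- function(y, X, Z, Gu, sigma2_e) {
  n <- length(y)
  V <- Z %*% Gu %*% t(Z) + diag(sigma2_e, n)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  resid <- y - X %*% beta
  list(beta = drop(beta), u = drop(Gu %*% crossprod(Z, Vi %*% resid)))
}

# Dense V and design pieces of the factor-analytic MET model for a unit, as
# plain incidence matrices; used to drive oracle_blup against fit_met.
oracle_met_design <- function(plots) {
  site <- factor(plots$site_id)
  geno <- factor(plots$genotype_id)
  repl <- factor(paste(plots$site_id, plots$replicate, sep = ":"))
  X <- stats::model.matrix(~ 0 + site)
  Zr <- stats::model.matrix(~ 0 + repl)
  Zg <- stats::model.matrix(~ 0 + geno)
  gef <- factor(paste(as.integer(geno), as.integer(site), sep = ":"),
                levels = as.vector(outer(seq_len(nlevels(geno)),
                                         seq_len(nlevels(site)),
                                         function(a, b) paste(a, b, sep = ":"))))
  Zge <- stats::model.matrix(~ 0 + gef)
  list(y = plots$yield_t_ha, X = X, Zr = Zr, Zg = Zg, Zge = Zge,
       site = site, geno = geno, repl = repl)
}

# Exact coancestry by enumerating every gametic inheritance configuration of
# the non-founders (feasible for small pedigrees). Founders carry unique
# allele labels; unknown parents contribute fresh unique alleles.
oracle_cop_enum <- function(ped, i, j) {
  ids <- ped$id
  p1 <- match(ped$parent1, ids)
  p2 <- match(ped$parent2, ids)
  nf <- which(!is.na(p1) | !is.na(p2))
  n_choice <- 2L * length(nf)
  stopifnot(n_choice <= 14L)   # at most 2^14 configurations (R-loop feasible)
  ii <- match(i, ids); jj <- match(j, ids)
  total <- 0
  next_allele <- 0L
  for (cfg in 0:(2^n_choice - 1)) {
    bits <- as.integer(intToBits(cfg))[seq_len(n_choice)]
    allele <- matrix(NA_integer_, nrow(ped), 2)
    a_count <- 0L
    for (r in seq_len(nrow(ped))) {
      for (side in 1:2) {
        par <- if (side == 1L) p1[r] else p2[r]
        if (is.na(par)) {
          a_count <- a_count + 1L
          allele[r, side] <- a_count + r * 1000L  # unique per (indiv, side)
        } else {
          pos <- 2L * (match(r, nf) - 1L) + side
          pick <- bits[pos] + 1L
          allele[r, side] <- allele[par, pick]
        }
      }
    }
    # probability random alleles from i and j are identical
    m <- mean(outer(allele[ii, ], allele[jj, ], "=="))
    total <- total + m
  }
  total / 2^n_choice
}

# Brute-force optimal 1-D k-means by enumerating contiguous partitions of the
# sorted values.
oracle_kmeans1d <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  cuts <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (cix in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, cix], n)
    w <- 0
    for (m in seq_len(k)) {
      seg <- xs[(b[m] + 1L):b[m + 1L]]
      w <- w + sum((seg - mean(seg))^2)
    }
    if (w < best) best <- w
  }
  best
}

# Adjusted Rand index.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  nc2 <- choose(sum(tab), 2)
  exp_ <- si * sj / nc2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Textbook pedigree: A x B -> C, D (full sibs); A x E -> H (half sib of C);
# C x X -> G1 and D x Y -> G2 (first cousins).
classic_ped <- function() {
  as_pedigree(data.frame(
    id      = c("A", "B", "E", "X", "Y", "C", "D", "H", "G1", "G2"),
    parent1 = c(NA, NA, NA, NA, NA, "A", "A", "A", "C", "D"),
    parent2 = c(NA, NA, NA, NA, NA, "B", "B", "E", "X", "Y")))
}

# A small balanced trial in the plot-table layout, built directly (not via
# the package generator) so generator and fitter can be tested against each
# other independently.
make_trial <- function(g = 6L, r = 2L, n_sb = 2L, sigma2_g = 0.3,
                       sigma2_sb = 0.1, sigma2_e = 0.2, mu = 3, seed = 1) {
  set.seed(seed)
  geno <- sprintf("G%02d", seq_len(g))
  u <- rnorm(g, 0, sqrt(sigma2_g))
  rows <- list()
  for (j in seq_len(r)) {
    ord <- sample(geno)
    sb <- rep(seq_len(n_sb), each = g / n_sb)
    sbe <- rnorm(n_sb, 0, sqrt(sigma2_sb))
    rows[[j]] <- data.frame(trial_id = "T1", genotype_id = ord,
                            replicate = j, sub_block = sb,
                            yield_t_ha = mu + u[match(ord, geno)] + sbe[sb] +
                              rnorm(g, 0, sqrt(sigma2_e)),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
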