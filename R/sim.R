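#' Configuration for a synthetic multi-environment trial series
#'
#' Collects every constant the generator needs to emit a trial series with the
#' structure the downstream analysis assumes: alpha-lattice trials of a fixed
#' entry list (recurring checks plus new lines each year), several sites per
#' annual series split into low/medium/high yield environments, a low-rank
#' (single factor by default) genotype-by-environment component plus
#' site-specific noise, and an upward trend in the genetic merit of new lines
#' expressed as a percentage of check yield per year.
#'
#' Genotype merit acts proportionally to the site yield level: the
#' contribution of line \eqn{i} at a site with expected level \eqn{m_s} is
#' \eqn{(m_s/M)\,g_i}, where \eqn{M} is the mean level of the generated
#' low/medium classes. A percentage trend therefore translates into the same
#' check-relative slope in every environment class, which is what an era-trial
#' regression of check-relative yield on year estimates. The proportional part
#' is a rank-one genotype-by-environment component, matching the factor
#' analytic structure fitted downstream.
#'
#' @param n_series number of annual trial series (years).
#' @param entries_per_trial entries per trial, checks included.
#' @param n_checks number of long-term checks recurring across series.
#' @param n_reps replicates per trial.
#' @param n_subblocks sub-blocks per replicate; must divide
#'   `entries_per_trial`.
#' @param sites_per_class integer vector `c(low=, medium=, high=)`: sites per
#'   series in each yield class.
#' @param class_mean_yield numeric vector `c(low=, medium=, high=)`: expected
#'   site mean yield (t/ha) per class.
#' @param site_sd within-class standard deviation of site mean yield (t/ha).
#' @param trend_pct_per_year annual increase of new-line genetic merit, in
#'   percent of check yield.
#' @param sigma2_g genetic variance among lines, (t/ha)^2 at the reference
#'   yield level.
#' @param sigma2_ge_factor variance of per-site factor loadings (t/ha)^2.
#' @param sigma2_ge_specific site-specific genotype-by-environment variance.
#' @param sigma2_rep replicate-within-site variance.
#' @param sigma2_subblock sub-block-within-replicate variance.
#' @param sigma2_e plot residual variance.
#' @param check_presence optional logical matrix (`n_checks` x `n_series`):
#'   which checks are distributed in which series. Default: all checks in all
#'   series.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   plot table exactly.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_series = 12L,
                       entries_per_trial = 50L,
                       n_checks = 3L,
                       n_reps = 2L,
                       n_subblocks = 5L,
                       sites_per_class = c(low = 18L, medium = 18L, high = 5L),
                       class_mean_yield = c(low = 2.4, medium = 4.6, high = 6.5),
                       site_sd = 0.35,
                       trend_pct_per_year = 1.8,
                       sigma2_g = 0.08,
                       sigma2_ge_factor = 0.01,
                       sigma2_ge_specific = 0.02,
                       sigma2_rep = 0.01,
                       sigma2_subblock = 0.01,
                       sigma2_e = 0.10,
                       check_presence = NULL,
                       seed = 1L) {
  cfg <- list(n_series = as.integer(n_series),
              entries_per_trial = as.integer(entries_per_trial),
              n_checks = as.integer(n_checks),
              n_reps = as.integer(n_reps),
              n_subblocks = as.integer(n_subblocks),
              sites_per_class = stats::setNames(as.integer(sites_per_class),
                                               c("low", "medium", "high")),
              class_mean_yield = stats::setNames(as.numeric(class_mean_yield),
                                                 c("low", "medium", "high")),
              site_sd = as.numeric(site_sd),
              trend_pct_per_year = as.numeric(trend_pct_per_year),
              sigma2_g = as.numeric(sigma2_g),
              sigma2_ge_factor = as.numeric(sigma2_ge_factor),
              sigma2_ge_specific = as.numeric(sigma2_ge_specific),
              sigma2_rep = as.numeric(sigma2_rep),
              sigma2_subblock = as.numeric(sigma2_subblock),
              sigma2_e = as.numeric(sigma2_e),
              check_presence = check_presence,
              seed = as.integer(seed))
  vars <- c("sigma2_g", "sigma2_ge_factor", "sigma2_ge_specific",
            "sigma2_rep", "sigma2_subblock", "sigma2_e")
  for (v in vars) {
    if (is.na(cfg[[v]]) || cfg[[v]] < 0)
      stop("variance component '", v, "' must be >= 0", call. = FALSE)
  }
  if (cfg$site_sd < 0) stop("site_sd must be >= 0", call. = FALSE)
  if (cfg$n_series < 1L) stop("n_series must be >= 1", call. = FALSE)
  if (cfg$entries_per_trial <= cfg$n_checks)
    stop("entries_per_trial must exceed n_checks", call. = FALSE)
  if (any(cfg$sites_per_class < 0L))
    stop("sites_per_class entries must be >= 0", call. = FALSE)
  if (cfg$sites_per_class[["low"]] == 0L && cfg$sites_per_class[["medium"]] == 0L)
    stop("at least one of the low/medium classes must have sites", call. = FALSE)
  if (cfg$entries_per_trial %% cfg$n_subblocks != 0L)
    stop("entries_per_trial must be divisible by n_subblocks", call. = FALSE)
  if (cfg$n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (!is.null(check_presence)) {
    check_presence <- as.matrix(check_presence)
    if (!is.logical(check_presence) ||
        nrow(check_presence) != cfg$n_checks ||
        ncol(check_presence) != cfg$n_series)
      stop("check_presence must be a logical n_checks x n_series matrix",
           call. = FALSE)
    cfg$check_presence <- check_presence
  }
  class(cfg) <- "sim_config"
  cfg
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic multi-environment trial series
#'
#' Realises the generative counterpart of the two-stage analysis model: plot
#' yield = site level + replicate effect + sub-block effect + proportional
#' genotype merit + site loading x genotype score + site-specific GE noise +
#' residual. Checks keep the same true merit in every series; new lines enter
#' once, with merit drawn around a mean that climbs by
#' `trend_pct_per_year` percent of check yield per series.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `met_sim` with elements
#'   \describe{
#'     \item{plots}{data frame with columns `trial_id, series, site_id,
#'       genotype_id, is_check, replicate, sub_block, yield_t_ha`.}
#'     \item{truth}{the generative truth: per-genotype merit, per-site class
#'       and loading, the injected trend, check identities and the reference
#'       yield level. Emitted for parameter-recovery testing only; never
#'       consumed by the estimation stages.}
#'   }
#' @export
generate_met <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_met_impl(config))
}

generate_met_impl <- function(cfg) {
  n_chk <- cfg$n_checks
  check_ids <- sprintf("CHK%d", seq_len(n_chk))
  presence <- cfg$check_presence
  if (is.null(presence))
    presence <- matrix(TRUE, n_chk, cfg$n_series)
  rownames(presence) <- check_ids

  # reference yield level: mean of the target (low/medium) class levels that
  # are actually generated
  target <- c("low", "medium")[cfg$sites_per_class[c("low", "medium")] > 0L]
  M <- mean(cfg$class_mean_yield[target])

  merit_chk <- rnorm(n_chk, 0, sqrt(cfg$sigma2_g))
  names(merit_chk) <- check_ids
  mean_chk <- mean(merit_chk)

  plot_rows <- vector("list", cfg$n_series)
  geno_truth <- list(data.frame(genotype_id = check_ids,
                                series = NA_integer_,
                                is_check = TRUE,
                                merit_t_ha = unname(merit_chk),
                                stringsAsFactors = FALSE))
  site_truth <- vector("list", cfg$n_series)

  classes <- c("low", "medium", "high")
  for (t in seq_len(cfg$n_series)) {
    chk_t <- check_ids[presence[, t]]
    n_new <- cfg$entries_per_trial - length(chk_t)
    new_ids <- sprintf("S%02d_L%03d", t, seq_len(n_new))
    mu_t <- cfg$trend_pct_per_year / 100 * t * (M + mean_chk)
    merit_new <- rnorm(n_new, mu_t, sqrt(cfg$sigma2_g))
    names(merit_new) <- new_ids
    entries <- c(chk_t, new_ids)
    merit <- c(merit_chk[chk_t], merit_new)
    scores <- rnorm(length(entries))  # latent factor scores, one per entry
    names(scores) <- entries
    geno_truth[[t + 1L]] <- data.frame(genotype_id = new_ids,
                                       series = t,
                                       is_check = FALSE,
                                       merit_t_ha = unname(merit_new),
                                       stringsAsFactors = FALSE)

    st_rows <- list()
    for (cl in classes) {
      n_site <- cfg$sites_per_class[[cl]]
      if (n_site == 0L) next
      for (ix in seq_len(n_site)) {
        site_id <- sprintf("S%02d_%s%02d", t, toupper(substr(cl, 1, 1)), ix)
        m_s <- cfg$class_mean_yield[[cl]] + rnorm(1, 0, cfg$site_sd)
        lam_s <- rnorm(1, 0, sqrt(cfg$sigma2_ge_factor))
        ge_spec <- rnorm(length(entries), 0, sqrt(cfg$sigma2_ge_specific))
        rep_eff <- rnorm(cfg$n_reps, 0, sqrt(cfg$sigma2_rep))
        sb_size <- cfg$entries_per_trial %/% cfg$n_subblocks
        rows_rep <- vector("list", cfg$n_reps)
        for (j in seq_len(cfg$n_reps)) {
          ord <- sample.int(length(entries))
          sb <- rep(seq_len(cfg$n_subblocks), each = sb_size)
          sb_eff <- rnorm(cfg$n_subblocks, 0, sqrt(cfg$sigma2_subblock))
          gidx <- entries[ord]
          y <- m_s + rep_eff[j] + sb_eff[sb] +
            (m_s / M) * merit[gidx] + lam_s * scores[gidx] + ge_spec[match(gidx, entries)] +
            rnorm(length(entries), 0, sqrt(cfg$sigma2_e))
          rows_rep[[j]] <- data.frame(trial_id = site_id,
                                      series = t,
                                      site_id = site_id,
                                      genotype_id = gidx,
                                      is_check = gidx %in% chk_t,
                                      replicate = j,
                                      sub_block = sb,
                                      yield_t_ha = unname(y),
                                      stringsAsFactors = FALSE)
        }
        st_rows[[site_id]] <- do.call(rbind, rows_rep)
        site_truth[[t]] <- rbind(site_truth[[t]],
                                 data.frame(site_id = site_id, series = t,
                                            class_true = cl, site_mean = m_s,
                                            loading = lam_s,
                                            stringsAsFactors = FALSE))
      }
    }
    plot_rows[[t]] <- do.call(rbind, st_rows)
  }

  plots <- do.call(rbind, plot_rows)
  rownames(plots) <- NULL
  truth <- list(genotypes = do.call(rbind, geno_truth),
                sites = do.call(rbind, site_truth),
                trend_pct = cfg$trend_pct_per_year,
                check_ids = check_ids,
                check_presence = presence,
                ref_level = M)
  rownames(truth$genotypes) <- NULL
  structure(list(plots = plots, truth = truth, config = cfg),
            class = "met_sim")
}

#' Simulate one balanced multi-environment unit from an explicit factor model
#'
#' Low-level generator for a single analysis unit: `g` genotypes at `s` sites
#' with `r` replicates, genotype main effects with variance `sigma2_g`, a
#' genotype-by-environment deviation with covariance
#' `tcrossprod(lambda) + diag(specific)` across sites, per-site replicate
#' effects and iid plot residuals. Used for variance-recovery studies where
#' the site loadings must be held fixed across simulation replicates.
#'
#' @param site_means numeric vector of fixed site levels (t/ha); its length
#'   sets the number of sites.
#' @param g number of genotypes.
#' @param r replicates per site.
#' @param lambda site loadings (length s) of the single latent factor.
#' @param specific site-specific GE variances (length s).
#' @param sigma2_g,sigma2_rep,sigma2_e variance components.
#' @param seed integer seed.
#' @return a data frame in the plot-table layout accepted by [fit_met()].
#' @export
simulate_met_unit <- function(site_means, g, r = 2L, lambda, specific,
                              sigma2_g, sigma2_rep, sigma2_e, seed = 1L) {
  s <- length(site_means)
  stopifnot(length(lambda) == s, length(specific) == s)
  with_seed(seed, {
    geno <- sprintf("G%03d", seq_len(g))
    u_g <- rnorm(g, 0, sqrt(sigma2_g))
    f <- rnorm(g)
    rows <- vector("list", s)
    for (j in seq_len(s)) {
      ge <- lambda[j] * f + rnorm(g, 0, sqrt(specific[j]))
      rep_eff <- rnorm(r, 0, sqrt(sigma2_rep))
      per_rep <- lapply(seq_len(r), function(jj) {
        data.frame(trial_id = sprintf("SITE%02d", j),
                   series = 1L,
                   site_id = sprintf("SITE%02d", j),
                   genotype_id = geno,
                   is_check = FALSE,
                   replicate = jj,
                   sub_block = 1L,
                   yield_t_ha = site_means[j] + rep_eff[jj] + u_g + ge +
                     rnorm(g, 0, sqrt(sigma2_e)),
                   stringsAsFactors = FALSE)
      })
      rows[[j]] <- do.call(rbind, per_rep)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a structured synthetic pedigree
#'
#' Builds a pedigree of unrelated founders followed by derived lines whose two
#' parents are drawn preferentially from the line's own ancestor group, giving
#' the block-relatedness structure that principal-component grouping of a
#' coancestry matrix is expected to recover. Parents always precede their
#' offspring, so the pedigree is acyclic by construction.
#'
#' @param n_founders number of founders (must be at least `2 * n_groups`).
#' @param n_lines number of derived lines; 0 gives a founders-only pedigree.
#' @param n_groups number of ancestor groups.
#' @param seed integer seed.
#' @param line_ids optional character vector of identifiers for the derived
#'   lines (length `n_lines`).
#' @param within_prob probability that both parents are drawn from the line's
#'   own group.
#' @return an object of class `pedigree`: a data frame with columns
#'   `id, parent1, parent2` (`NA` = unknown parent) and a `groups` attribute
#'   holding the true group label of every individual.
#' @export
generate_pedigree <- function(n_founders, n_lines, n_groups, seed = 1L,
                              line_ids = NULL, within_prob = 0.98) {
  n_founders <- as.integer(n_founders)
  n_lines <- as.integer(n_lines)
  n_groups <- as.integer(n_groups)
  if (n_founders < 2L * n_groups)
    stop("n_founders must be >= 2 * n_groups", call. = FALSE)
  if (!is.null(line_ids) && length(line_ids) != n_lines)
    stop("line_ids must have length n_lines", call. = FALSE)
  with_seed(seed, {
    fid <- sprintf("F%02d", seq_len(n_founders))
    fgrp <- rep(seq_len(n_groups), length.out = n_founders)
    if (n_lines > 0L) {
      lid <- if (is.null(line_ids)) sprintf("L%03d", seq_len(n_lines)) else line_ids
      lgrp <- sample(rep(seq_len(n_groups), length.out = n_lines))
    } else {
      lid <- character(0); lgrp <- integer(0)
    }
    ids <- c(fid, lid)
    grp <- c(fgrp, lgrp)
    p1 <- p2 <- rep(NA_character_, length(ids))
    for (i in seq_len(n_lines)) {
      pos <- n_founders + i
      earlier <- seq_len(pos - 1L)
      own <- earlier[grp[earlier] == grp[pos]]
      other <- earlier[grp[earlier] != grp[pos]]
      pick <- function(pool, exclude = NULL) {
        pool <- setdiff(pool, exclude)
        if (length(pool) == 0L) pool <- setdiff(earlier, exclude)
        pool[sample.int(length(pool), 1L)]
      }
      a <- pick(own)
      pool_b <- if (runif(1) < within_prob || length(other) == 0L) own else other
      b <- pick(pool_b, exclude = a)
      p1[pos] <- ids[a]; p2[pos] <- ids[b]
    }
    ped <- data.frame(id = ids, parent1 = p1, parent2 = p2,
                      stringsAsFactors = FALSE)
    ped <- as_pedigree(ped)
    attr(ped, "groups") <- data.frame(id = ids, group = grp,
                                      stringsAsFactors = FALSE)
    ped
  })
}

#' Write the plot table, truth tables and configuration of a simulated series
#'
#' @param sim a `met_sim` object from [generate_met()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_met_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "met_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(plots = file.path(dir, "plots.csv"),
             genotype_truth = file.path(dir, "genotype_truth.csv"),
             site_truth = file.path(dir, "site_truth.csv"),
             config = file.path(dir, "config.json"))
  utils::write.csv(sim$plots, paths[["plots"]], row.names = FALSE)
  utils::write.csv(sim$truth$genotypes, paths[["genotype_truth"]], row.names = FALSE)
  utils::write.csv(sim$truth$sites, paths[["site_truth"]], row.names = FALSE)
  cfg <- sim$config
  cfg$check_presence <- NULL
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
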