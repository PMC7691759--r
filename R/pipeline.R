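# End-to-end orchestration: simulate or load plot data, fit every trial,
# filter on repeatability, classify environments and drop the high class, fit
# the factor-analytic MET model per series within each environment class (and
# pooled across classes), express BLUP-based predictions relative to checks,
# select the top decile, regress on series, and group the selected lines by
# coancestry PCA.

#' Pipeline configuration
#'
#' Collects every tuning constant of the analysis in one audited place.
#' Exactly one of `sim` (simulate mode) or `plots_csv` (load mode) must be
#' supplied.
#'
#' @param sim a [sim_config()] for simulate mode.
#' @param plots_csv,pedigree_csv input paths for load mode; `pedigree_csv` is
#'   optional in simulate mode (a pedigree matching the simulated lines is
#'   generated).
#' @param check_ids check identifiers for load mode (simulate mode takes them
#'   from the generator truth).
#' @param repeatability_threshold trials below it are discarded (default
#'   0.05).
#' @param k_env clusters for environment classification (default 3).
#' @param n_factors factor-analytic rank for the MET fits (default 1).
#' @param hyl_fraction selected fraction of highest yielding lines (default
#'   0.10).
#' @param n_groups coancestry PCA groups (default 4).
#' @param gyc_mode gain regression on per-line points (default) or per-series
#'   means.
#' @param classes which analysis units to run, a subset of
#'   `c("LYE", "MYE", "Across")`.
#' @param run_pedigree logical: run the COP/PCA grouping stage.
#' @param seed master seed; every stage derives its own substream.
#' @param out_dir optional output directory for intermediate CSVs and the
#'   report JSON.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, plots_csv = NULL, pedigree_csv = NULL,
                            check_ids = NULL,
                            repeatability_threshold = 0.05,
                            k_env = 3L, n_factors = 1L, hyl_fraction = 0.10,
                            n_groups = 4L,
                            gyc_mode = c("per_line", "series_mean"),
                            classes = c("LYE", "MYE", "Across"),
                            run_pedigree = TRUE,
                            seed = 1L, out_dir = NULL) {
  gyc_mode <- match.arg(gyc_mode)
  if (is.null(sim) == is.null(plots_csv))
    stop("supply exactly one of `sim` or `plots_csv`", call. = FALSE)
  if (!is.null(plots_csv) && !file.exists(plots_csv))
    stop("plots_csv does not exist: ", plots_csv, call. = FALSE)
  if (!is.null(pedigree_csv) && !file.exists(pedigree_csv))
    stop("pedigree_csv does not exist: ", pedigree_csv, call. = FALSE)
  stopifnot(repeatability_threshold >= 0, repeatability_threshold <= 1,
            hyl_fraction > 0, hyl_fraction <= 1, k_env >= 2L)
  classes <- match.arg(classes, several.ok = TRUE)
  structure(list(sim = sim, plots_csv = plots_csv,
                 pedigree_csv = pedigree_csv, check_ids = check_ids,
                 repeatability_threshold = repeatability_threshold,
                 k_env = as.integer(k_env), n_factors = as.integer(n_factors),
                 hyl_fraction = hyl_fraction, n_groups = as.integer(n_groups),
                 gyc_mode = gyc_mode, classes = classes,
                 run_pedigree = isTRUE(run_pedigree),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a plot table CSV in the package's dialect
#' @param path CSV with header `trial_id, series, site_id, genotype_id,
#'   is_check, replicate, sub_block, yield_t_ha`.
#' @return data frame of plot records.
#' @export
read_plot_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("trial_id", "series", "site_id", "genotype_id", "is_check",
           "replicate", "sub_block", "yield_t_ha")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("plot table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$is_check <- as.logical(df$is_check)
  df
}

#' Run the full genetic-gain pipeline
#'
#' Stages, in order: single-trial fits, repeatability filter, k-means
#' environment classification (high class dropped), per-series
#' factor-analytic MET fits within each retained class and pooled across
#' classes, check-relative yield (GYC), top-decile selection, gain regression
#' per class, and coancestry PCA grouping of the selected lines. Identical
#' configuration and seed reproduce the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # ---- stage 0: data -------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- generate_met(config$sim)
    plots <- sim$plots
    check_ids <- sim$truth$check_ids
    truth <- sim$truth
  } else {
    plots <- read_plot_data(config$plots_csv)
    check_ids <- config$check_ids
    if (is.null(check_ids))
      check_ids <- sort(unique(plots$genotype_id[plots$is_check]))
    truth <- NULL
  }

  # ---- stage 1: single-trial fits -----------------------------------------
  fits <- lapply(split(plots, plots$trial_id), function(tp) {
    tryCatch(fit_single_trial(tp), error = function(e)
      stop("stage single_trial, trial '", tp$trial_id[1], "': ",
           conditionMessage(e), call. = FALSE))
  })
  summaries <- trial_summaries(fits)

  # ---- stage 2: repeatability filter --------------------------------------
  retained <- filter_trials(summaries, config$repeatability_threshold,
                            quiet = TRUE)
  if (nrow(retained) == 0L)
    stop("stage filter_trials: no trial retained", call. = FALSE)

  # ---- stage 3: environment classification, high class dropped ------------
  env <- tryCatch(
    classify_environments(retained, k = config$k_env,
                          seed = stage_seed(config$seed, "env_class")),
    error = function(e) stop("stage env_class: ", conditionMessage(e),
                             call. = FALSE))
  env_kept <- env[env$class_label != "HYE", , drop = FALSE]
  series_of <- stats::setNames(retained$series, retained$trial_id)

  # ---- stage 4-6: per-series MET fits, GYC, HYL ---------------------------
  unit_sets <- list(LYE = "LYE", MYE = "MYE", Across = c("LYE", "MYE"))
  unit_sets <- unit_sets[names(unit_sets) %in% config$classes]
  gyc_records <- list()
  unit_log <- list()
  for (cl in names(unit_sets)) {
    trials_cl <- env_kept$trial_id[env_kept$class_label %in% unit_sets[[cl]]]
    for (t in sort(unique(series_of[trials_cl]))) {
      unit_trials <- trials_cl[series_of[trials_cl] == t]
      up <- plots[plots$trial_id %in% unit_trials, , drop = FALSE]
      if (nrow(up) == 0L) next
      s_here <- length(unique(up$site_id))
      k_use <- if (s_here == 1L) 0L else min(config$n_factors, s_here)
      fit <- tryCatch(fit_met(up, n_factors = k_use), error = function(e)
        stop("stage met_fa, class ", cl, ", series ", t, ": ",
             conditionMessage(e), call. = FALSE))
      bt <- blup_table(fit)
      gyc <- tryCatch(compute_gyc(bt, check_ids, series = t, class_label = cl),
                      error = function(e)
                        stop("stage gains, class ", cl, ", series ", t, ": ",
                             conditionMessage(e), call. = FALSE))
      gyc_records[[paste(cl, t)]] <- gyc
      unit_log[[paste(cl, t)]] <-
        data.frame(class_label = cl, series = t, n_sites = s_here,
                   n_genotypes = fit$n_genotypes, n_factors = k_use,
                   reml_loglik = fit$reml_loglik, converged = fit$converged,
                   stringsAsFactors = FALSE)
    }
  }
  gyc_all <- do.call(rbind, gyc_records)
  if (is.null(gyc_all))
    stop("stage gains: no analysis unit produced GYC records", call. = FALSE)
  rownames(gyc_all) <- NULL
  gyc_all <- select_hyl(gyc_all, config$hyl_fraction)

  # ---- stage 7: gain regressions ------------------------------------------
  gains <- list()
  for (cl in names(unit_sets)) {
    rec <- gyc_all[gyc_all$class_label == cl, , drop = FALSE]
    gains[[cl]] <- tryCatch(gain_regression(rec, mode = config$gyc_mode),
                            error = function(e)
                              stop("stage gains, class ", cl, ": ",
                                   conditionMessage(e), call. = FALSE))
  }

  # ---- stage 8: pedigree grouping of the HYLs -----------------------------
  hyl_ids <- sort(unique(gyc_all$genotype_id[gyc_all$is_hyl]))
  groups <- NULL
  group_table <- NULL
  if (config$run_pedigree && length(hyl_ids) >= config$n_groups) {
    ped <- NULL
    if (!is.null(config$pedigree_csv)) {
      ped <- read_pedigree(config$pedigree_csv)
    } else if (!is.null(config$sim)) {
      new_lines <- sort(unique(plots$genotype_id[!plots$genotype_id %in% check_ids]))
      ped <- generate_pedigree(n_founders = max(4L * config$n_groups, 2L * config$n_groups),
                               n_lines = length(new_lines),
                               n_groups = config$n_groups,
                               seed = stage_seed(config$seed, "pedigree"),
                               line_ids = new_lines)
    }
    if (!is.null(ped) && all(hyl_ids %in% ped$id)) {
      copm <- cop_matrix(ped, hyl_ids)
      groups <- tryCatch(
        group_lines(copm, n_groups = config$n_groups,
                    seed = stage_seed(config$seed, "group_lines")),
        error = function(e) stop("stage pedigree: ", conditionMessage(e),
                                 call. = FALSE))
      # Table layout: lines per group, split by the class(es) where they
      # ranked in the top decile
      group_table <- make_group_table(groups, gyc_all)
    }
  }

  # ---- report --------------------------------------------------------------
  env_counts <- table(class = env$class_label,
                      series = series_of[env$trial_id])
  report <- structure(list(
    n_trials_in = nrow(summaries),
    n_trials_retained = nrow(retained),
    n_trials_dropped = attr(retained, "n_discarded"),
    env_centers = attr(env, "centers"),
    env_counts = as.data.frame.matrix(env_counts),
    trial_summaries = summaries,
    env_assignments = env,
    unit_log = do.call(rbind, unit_log),
    gyc = gyc_all,
    gains = gains,
    groups = groups,
    group_table = group_table,
    truth = truth,
    provenance = list(seed = config$seed,
                      repeatability_threshold = config$repeatability_threshold,
                      k_env = config$k_env, n_factors = config$n_factors,
                      hyl_fraction = config$hyl_fraction,
                      n_groups = config$n_groups, gyc_mode = config$gyc_mode,
                      classes = config$classes,
                      package_version = as.character(utils::packageVersion("metgains")))),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Lines per coancestry group split by the class where they were selected.
make_group_table <- function(groups, gyc_all) {
  classes <- unique(gyc_all$class_label)
  rows <- lapply(sort(unique(groups$group)), function(gr) {
    ids <- groups$id[groups$group == gr]
    cnt <- vapply(classes, function(cl)
      length(unique(gyc_all$genotype_id[gyc_all$is_hyl &
                                          gyc_all$class_label == cl &
                                          gyc_all$genotype_id %in% ids])), 0L)
    data.frame(group = gr, t(cnt), total = length(ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:(1 + length(classes))] <- classes
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Genetic-gain pipeline report\n")
  cat(sprintf("  trials: %d in, %d retained, %d dropped (repeatability filter)\n",
              x$n_trials_in, x$n_trials_retained, x$n_trials_dropped))
  cat("  environment cluster centers (t/ha):",
      paste(sprintf("%s=%.2f", names(x$env_centers), x$env_centers),
            collapse = "  "), "\n")
  for (g in x$gains) print(g)
  if (!is.null(x$group_table)) {
    cat("  HYL coancestry groups:\n")
    print(x$group_table, row.names = FALSE)
  }
  invisible(x)
}

# Serialize the report: CSV per tabular stage plus a JSON summary.
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$trial_summaries,
                   file.path(dir, "trial_summaries.csv"), row.names = FALSE)
  utils::write.csv(report$env_assignments,
                   file.path(dir, "env_assignments.csv"), row.names = FALSE)
  utils::write.csv(report$gyc, file.path(dir, "gyc.csv"), row.names = FALSE)
  if (!is.null(report$groups))
    utils::write.csv(report$groups, file.path(dir, "groups.csv"),
                     row.names = FALSE)
  gains <- lapply(report$gains, function(g) unclass(g))
  summary_json <- list(
    n_trials_in = report$n_trials_in,
    n_trials_retained = report$n_trials_retained,
    n_trials_dropped = report$n_trials_dropped,
    env_centers = as.list(report$env_centers),
    gains = gains,
    group_table = report$group_table,
    provenance = report$provenance)
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Validate pipeline input files
#'
#' Schema checks that return a machine-readable violation list instead of
#' failing: column presence and types, replicate/sub-block nesting and
#' duplicate plots in the plot table; parent resolvability and acyclicity in
#' the pedigree.
#'
#' @param plots_csv optional plot-table path.
#' @param pedigree_csv optional pedigree path.
#' @return data frame `file, check, detail`; zero rows when everything is
#'   well-formed.
#' @export
validate_inputs <- function(plots_csv = NULL, pedigree_csv = NULL) {
  v <- list()
  bad <- function(file, check, detail)
    v[[length(v) + 1L]] <<- data.frame(file = file, check = check,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  if (!is.null(plots_csv)) {
    if (!file.exists(plots_csv))
      stop("unreadable file: ", plots_csv, call. = FALSE)
    df <- utils::read.csv(plots_csv, stringsAsFactors = FALSE)
    req <- c("trial_id", "series", "site_id", "genotype_id", "is_check",
             "replicate", "sub_block", "yield_t_ha")
    for (col in setdiff(req, names(df)))
      bad(plots_csv, "missing_column", col)
    if (all(req %in% names(df))) {
      if (!is.numeric(df$yield_t_ha))
        bad(plots_csv, "type", "yield_t_ha must be numeric")
      if (anyNA(df$yield_t_ha))
        bad(plots_csv, "missing_value", "yield_t_ha contains NA")
      key <- paste(df$trial_id, df$genotype_id, df$replicate)
      if (anyDuplicated(key))
        bad(plots_csv, "duplicate_plot",
            paste(unique(key[duplicated(key)])[1], "..."))
      nest <- unique(df[c("trial_id", "replicate", "sub_block", "genotype_id")])
      per_sb <- stats::aggregate(genotype_id ~ trial_id + replicate + sub_block,
                                 data = nest, FUN = length)
      if (any(per_sb$genotype_id < 1L))
        bad(plots_csv, "nesting", "empty sub-block")
    }
  }
  if (!is.null(pedigree_csv)) {
    if (!file.exists(pedigree_csv))
      stop("unreadable file: ", pedigree_csv, call. = FALSE)
    pd <- utils::read.csv(pedigree_csv, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
    for (col in setdiff(c("id", "parent1", "parent2"), names(pd)))
      bad(pedigree_csv, "missing_column", col)
    if (all(c("id", "parent1", "parent2") %in% names(pd))) {
      res <- tryCatch({ as_pedigree(pd); NULL }, error = function(e)
        conditionMessage(e))
      if (!is.null(res)) bad(pedigree_csv, "pedigree", res)
    }
  }
  if (length(v) == 0L)
    return(data.frame(file = character(0), check = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, v)
}
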