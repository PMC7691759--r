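# Check-relative yield and genetic-gain regression.
#
# Line BLUP-based predictions are expressed relative to the predicted mean
# yield of the long-term checks present in the same analysis unit,
#   GYC = (BLUP - MeanGY) / MeanGY x 100,
# the top decile of lines per unit is flagged, and the flagged values are
# regressed on the trial-series year to estimate the annual rate of gain.

#' Express predicted yields relative to the check mean
#'
#' @param blups data frame from [blup_table()] (columns `genotype_id`,
#'   `is_check`, `predicted_yield_t_ha`).
#' @param check_ids identifiers of the checks distributed in this series; only
#'   those actually present in `blups` enter the check mean.
#' @param series integer series (year) index of the analysis unit.
#' @param class_label environment class of the unit (e.g. "LYE", "MYE",
#'   "Across").
#' @return data frame of class records: `genotype_id, series, class_label,
#'   gyc, predicted_yield, is_check, is_hyl` (the HYL flag starts `FALSE`;
#'   see [select_hyl()]). The mean GYC of the checks used is zero by
#'   construction.
#' @export
compute_gyc <- function(blups, check_ids, series, class_label) {
  present <- intersect(check_ids, blups$genotype_id)
  if (length(present) == 0L)
    stop("no check present in series ", series, ", class ", class_label,
         call. = FALSE)
  mean_gy <- mean(blups$predicted_yield_t_ha[blups$genotype_id %in% present])
  if (!is.finite(mean_gy) || mean_gy <= 0)
    stop("non-positive check mean in series ", series, ", class ", class_label,
         call. = FALSE)
  data.frame(genotype_id = blups$genotype_id,
             series = as.integer(series),
             class_label = class_label,
             gyc = (blups$predicted_yield_t_ha - mean_gy) / mean_gy * 100,
             predicted_yield = blups$predicted_yield_t_ha,
             is_check = blups$genotype_id %in% check_ids | blups$is_check,
             is_hyl = FALSE,
             stringsAsFactors = FALSE)
}

#' Flag the highest yielding lines of each analysis unit
#'
#' Within every (series x class) unit, flags the top
#' `ceiling(fraction * n)` non-check entries by GYC, where n is the number of
#' non-check entries in the unit. Ties are broken by genotype identifier so
#' the selection is reproducible.
#'
#' @param records GYC records from [compute_gyc()] (possibly several units
#'   row-bound together).
#' @param fraction selected fraction, in (0, 1].
#' @return `records` with `is_hyl` set.
#' @export
select_hyl <- function(records, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  records$is_hyl <- FALSE
  units <- unique(records[c("series", "class_label")])
  for (u in seq_len(nrow(units))) {
    in_unit <- records$series == units$series[u] &
      records$class_label == units$class_label[u]
    cand <- which(in_unit & !records$is_check)
    if (length(cand) == 0L) next
    n_sel <- ceiling(fraction * length(cand))
    ord <- cand[order(-records$gyc[cand], records$genotype_id[cand])]
    records$is_hyl[ord[seq_len(n_sel)]] <- TRUE
  }
  records
}

#' Estimate the annual rate of yield gain for one environment class
#'
#' Ordinary least squares of the HYL check-relative yields on the trial-series
#' year. The slope in percent per year is converted to kg/ha per year through
#' the class's mean predicted check yield. By default every flagged line
#' contributes one point per unit; `mode = "series_mean"` regresses the
#' per-series HYL means instead.
#'
#' @param records GYC records of one class with the HYL flag set.
#' @param mode `"per_line"` (default) or `"series_mean"`.
#' @return an object of class `gain_fit`: slope in % per year and kg/ha per
#'   year, intercept, R^2, slope p-value, number of points and the HYL
#'   roster.
#' @export
gain_regression <- function(records, mode = c("per_line", "series_mean")) {
  mode <- match.arg(mode)
  class_label <- unique(records$class_label)
  if (length(class_label) != 1L)
    stop("gain_regression expects records of a single class", call. = FALSE)
  hyl <- records[records$is_hyl & !records$is_check, , drop = FALSE]
  if (length(unique(hyl$series)) < 2L)
    stop("gain regression needs HYL points from at least 2 series", call. = FALSE)
  if (mode == "series_mean") {
    agg <- stats::aggregate(gyc ~ series, data = hyl, FUN = mean)
    dat <- data.frame(series = agg$series, gyc = agg$gyc)
  } else {
    dat <- hyl[c("series", "gyc")]
  }
  fit <- stats::lm(gyc ~ series, data = dat)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)["series"])
  r2 <- sm$r.squared
  if (stats::var(dat$gyc) < 1e-18 * (1 + mean(dat$gyc)^2)) {
    slope <- 0; r2 <- 0              # constant response: no trend, no fit
  }
  if (!is.finite(r2)) r2 <- 0
  mean_check_t <- mean(records$predicted_yield[records$is_check])
  slope_kg <- slope / 100 * mean_check_t * 1000
  p_val <- if (nrow(dat) > 2L) unname(sm$coefficients["series", "Pr(>|t|)"])
  else NA_real_
  structure(list(class_label = class_label,
                 slope_pct_per_year = slope,
                 slope_kg_per_ha_year = slope_kg,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = r2,
                 p_value_slope = p_val,
                 n_points = nrow(dat),
                 mean_check_yield_t_ha = mean_check_t,
                 mode = mode,
                 hyl_ids = sort(unique(hyl$genotype_id))),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("Genetic gain, %s: %.3f %%/yr (%.2f kg/ha/yr)\n",
              x$class_label, x$slope_pct_per_year, x$slope_kg_per_ha_year))
  cat(sprintf("  R^2 = %.3f, p(slope) = %.3g, n = %d points (%s), check mean %.2f t/ha\n",
              x$r_squared, x$p_value_slope, x$n_points, x$mode,
              x$mean_check_yield_t_ha))
  invisible(x)
}

#' @export
coef.gain_fit <- function(object, ...) {
  c(intercept = object$intercept, slope_pct_per_year = object$slope_pct_per_year)
}
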