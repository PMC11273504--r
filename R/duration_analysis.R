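# Truncated-test analysis: recompute intake, gain, midweight and RFI on
# shortened windows and compare them with the full-test values.

#' Growth summaries for a truncated test window
#'
#' Recomputes the per-animal growth summary as if the test had ended at
#' day `d`: mean DMI over days `1..d`, ADG1 from the weigh points at or
#' before day `d`, ADG2 from the day-`d` weight (the single weight --
#' mid-test truncations have no consecutive-day pair; at the full test
#' length the day `d - 1`/`d` pair is averaged as usual), and the
#' metabolic midweights from the truncated final weight and ADGs.
#'
#' @param weights Long weigh data (`id`, `day`, `bw_kg`).
#' @param intake Long intake data (`id`, `day`, `dmi_kg`).
#' @param d Truncation day; must be one of the weigh days.
#' @param heifers Animal metadata (`id`, `group`, optional `ubf_mm`).
#' @return A growth summary data frame with `days = d`.
#' @export
truncate_trial <- function(weights, intake, d, heifers) {
  valid <- sort(unique(weights$day[weights$day > 0]))
  if (!d %in% valid) {
    stop(sprintf("day %s is not a weigh day; valid durations: %s",
                 d, paste(valid, collapse = ", ")))
  }
  growth_summary_table(heifers,
                       weights[weights$day <= d, ],
                       intake[intake$day <= d, ],
                       days = d)
}

#' Compare full-test values with truncated-test values for one metric
#'
#' Regresses the full-test per-animal values on the truncated-test values
#' (simple OLS), and computes Pearson and Spearman correlations with
#' two-sided t-approximation p-values.
#'
#' @param full Named numeric vector of full-test values.
#' @param short Named numeric vector of truncated-test values over the
#'   same ids.
#' @param metric Label recorded in the output row.
#' @param duration Truncation length recorded in the output row.
#' @return One-row data frame: metric, duration_d, slope, slope_se,
#'   r_squared, pearson, spearman, p_slope, p_pearson, p_spearman.
#' @export
compare_durations <- function(full, short, metric = NA_character_,
                              duration = NA_integer_) {
  if (!is.null(names(full)) && !is.null(names(short))) {
    if (!setequal(names(full), names(short))) {
      stop("full and short must cover the same animals")
    }
    short <- short[names(full)]
  }
  if (length(full) < 3L) stop("need at least 3 animals")
  if (stats::sd(full) == 0 || stats::sd(short) == 0) {
    stop("undefined correlation: zero variance in full or truncated values")
  }
  reg <- suppressWarnings(regress_pair(short, full))
  pe <- pearson_r(short, full)
  sp <- spearman_rho(short, full)
  data.frame(
    metric = metric, duration_d = as.integer(duration),
    slope = reg$slope, slope_se = reg$se, r_squared = reg$r_squared,
    pearson = pe$r, spearman = sp$rho,
    p_slope = reg$p_value, p_pearson = pe$p, p_spearman = sp$p,
    stringsAsFactors = FALSE
  )
}

metric_values <- function(summary_tab, metric, fits = NULL) {
  v <- switch(metric,
              DMI = summary_tab$mean_dmi,
              ADG1 = summary_tab$adg1,
              ADG2 = summary_tab$adg2,
              MMWT1 = summary_tab$mmwt1,
              MMWT2 = summary_tab$mmwt2,
              RFI1 = return(fits$RFI_1$residuals),
              RFI2 = return(fits$RFI_2$residuals),
              stop("unknown metric: ", metric))
  stats::setNames(v, summary_tab$id)
}

#' Full-versus-truncated comparison table across durations
#'
#' For each requested duration the trial is truncated, the growth
#' summaries recomputed, and -- for the RFI metrics -- the expected-DMI
#' models refit on the truncated summaries (RFI at a shorter duration is
#' the residual of a model fit to that duration's own gain, midweight and
#' intake, not a truncation of the full-test residuals). Backfat is never
#' included in the truncated models because ultrasound is only collected
#' at the end of the full test.
#'
#' @param heifers,weights,intake Trial data as elsewhere.
#' @param durations Truncation days; each must be a weigh day.
#' @param metrics Subset of DMI, ADG1, ADG2, MMWT1, MMWT2, RFI1, RFI2.
#' @param fit_scope Passed to [fit_dmi_model()] for the RFI metrics.
#' @param full_days Full test length; defaults to the last weigh day.
#' @return Data frame with one row per (metric, duration).
#' @export
duration_table <- function(heifers, weights, intake,
                           durations = c(14, 28, 42, 56),
                           metrics = c("DMI", "ADG1", "ADG2", "MMWT1",
                                       "MMWT2", "RFI1", "RFI2"),
                           fit_scope = "pooled", full_days = NULL) {
  full_days <- as.integer(full_days %||% max(weights$day))
  need_rfi <- any(c("RFI1", "RFI2") %in% metrics)
  full_tab <- growth_summary_table(heifers, weights, intake, days = full_days)
  full_fits <- if (need_rfi) list(
    RFI_1 = fit_dmi_model(full_tab, "regression", FALSE, fit_scope),
    RFI_2 = fit_dmi_model(full_tab, "difference", FALSE, fit_scope)
  )
  rows <- list()
  for (d in durations) {
    tab_d <- truncate_trial(weights, intake, d, heifers)
    fits_d <- if (need_rfi) list(
      RFI_1 = fit_dmi_model(tab_d, "regression", FALSE, fit_scope),
      RFI_2 = fit_dmi_model(tab_d, "difference", FALSE, fit_scope)
    )
    for (m in metrics) {
      rows[[length(rows) + 1L]] <- compare_durations(
        metric_values(full_tab, m, full_fits),
        metric_values(tab_d, m, fits_d),
        metric = m, duration = d)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
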