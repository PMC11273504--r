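# End-to-end orchestration: simulate (or load) -> QC -> growth -> RFI ->
# duration analysis -> agreement -> report bundle on disk.

#' Configure a pipeline run
#'
#' @param out_dir Directory for the report bundle.
#' @param simulate Generate data with [generate_trial()]? Otherwise
#'   `input_dir` must hold `heifers.csv`, `intake.csv`, `weights.csv`.
#' @param sim_config Simulation configuration (simulate mode).
#' @param input_dir Directory of input CSVs (data mode).
#' @param seed Root seed (simulate mode).
#' @param min_start_age,max_end_age,intake_sd_k QC thresholds.
#' @param fit_scope Scope for all expected-DMI model fits.
#' @param durations Truncation days for the duration analysis.
#' @param legacy_lb_mode Passed to [growth_summary_table()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       simulate = TRUE,
                       sim_config = default_sim_config(),
                       input_dir = NULL,
                       seed = 1L,
                       min_start_age = 240,
                       max_end_age = 390,
                       intake_sd_k = 4,
                       fit_scope = "pooled",
                       durations = c(14, 28, 42, 56),
                       legacy_lb_mode = FALSE) {
  if (!simulate && is.null(input_dir)) {
    stop("either simulate = TRUE or an input_dir is required")
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 sim_config = sim_config, input_dir = input_dir,
                 seed = as.integer(seed),
                 min_start_age = min_start_age, max_end_age = max_end_age,
                 intake_sd_k = intake_sd_k, fit_scope = fit_scope,
                 durations = durations, legacy_lb_mode = legacy_lb_mode),
            class = "run_config")
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
}

write_csv_fixed <- function(df, path, digits = 4) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- fmt_num(out[[nm]], digits)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Run the full evaluation pipeline
#'
#' Executes simulate/load, QC, growth summaries, the four RFI models with
#' classification, the duration analysis, and the model-agreement
#' statistics, writing `qc_report.csv`, `growth_summary.csv`,
#' `rfi_results.csv`, `model_fits.json`, `duration_table.csv`,
#' `agreement_report.json` and `run_log.txt` to `config$out_dir`.
#' Identical config and seed reproduce the bundle byte-for-byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list (class `rfi_bundle`) with the in-memory
#'   objects and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(sprintf("rfitrial %s | R %s.%s", as.character(utils::packageVersion("rfitrial")),
                   R.version$major, R.version$minor),
           sprintf("seed: %d", config$seed),
           sprintf("fit_scope: %s", config$fit_scope))

  # -- data -----------------------------------------------------------
  if (config$simulate) {
    trial <- generate_trial(config$sim_config, seed = config$seed)
    write_trial(trial, config$out_dir, true_values = TRUE)
    write_sim_config(config$sim_config,
                     file.path(config$out_dir, "sim_config.yaml"))
    log <- c(log, sprintf("simulated %d heifers in %d groups",
                          nrow(trial$heifers), length(config$sim_config$groups)))
  } else {
    trial <- read_trial(config$input_dir)
    log <- c(log, sprintf("loaded %d heifers from %s",
                          nrow(trial$heifers), config$input_dir))
  }

  # -- qc -------------------------------------------------------------
  qc <- run_qc(trial$heifers, trial$intake,
               min_start_age = config$min_start_age,
               max_end_age = config$max_end_age,
               intake_sd_k = config$intake_sd_k)
  utils::write.csv(qc_report_table(qc),
                   file.path(config$out_dir, "qc_report.csv"),
                   row.names = FALSE)
  heifers <- trial$heifers[trial$heifers$id %in% qc$retained_ids, ]
  weights <- trial$weights[trial$weights$id %in% qc$retained_ids, ]
  intake <- trial$intake[trial$intake$id %in% qc$retained_ids, ]
  log <- c(log, sprintf("qc: %d retained, %d excluded",
                        length(qc$retained_ids), nrow(qc$excluded)))

  # -- growth ---------------------------------------------------------
  summary_tab <- growth_summary_table(heifers, weights, intake,
                                      legacy_lb_mode = config$legacy_lb_mode)
  write_csv_fixed(summary_tab,
                  file.path(config$out_dir, "growth_summary.csv"))

  # -- rfi ------------------------------------------------------------
  fits <- withCallingHandlers(
    compute_rfi_models(summary_tab, fit_scope = config$fit_scope),
    message = function(m) {
      log <<- c(log, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  classifications <- lapply(fits, classify_rfi)
  rfi_results <- data.frame(id = summary_tab$id, group = summary_tab$group,
                            stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    key <- tolower(nm)
    rfi_results[[key]] <- unname(fits[[nm]]$residuals[rfi_results$id])
    rfi_results[[paste0("class_", key)]] <-
      as.character(classifications[[nm]]$classes[rfi_results$id])
  }
  write_csv_fixed(rfi_results, file.path(config$out_dir, "rfi_results.csv"))
  model_meta <- lapply(fits, function(f) list(
    adg_variant = f$spec$adg_variant, include_ubf = f$spec$include_ubf,
    fit_scope = f$spec$fit_scope, coefficients = f$coefficients,
    r_squared = as.list(f$r_squared), n = f$n,
    n_dropped_ubf = f$n_dropped_ubf))
  jsonlite::write_json(model_meta,
                       file.path(config$out_dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- duration -------------------------------------------------------
  dur <- duration_table(heifers, weights, intake,
                        durations = config$durations,
                        fit_scope = config$fit_scope)
  write_csv_fixed(dur, file.path(config$out_dir, "duration_table.csv"))

  # -- agreement ------------------------------------------------------
  pairs <- list(c("RFI_1", "RFI_2"), c("RFI_1", "RFI_bf1"),
                c("RFI_2", "RFI_bf2"), c("RFI_bf1", "RFI_bf2"))
  agreement <- list()
  for (pr in pairs) {
    if (!all(pr %in% names(fits))) next
    a <- fits[[pr[1]]]; b <- fits[[pr[2]]]
    shared <- intersect(names(a$residuals), names(b$residuals))
    ka <- cohen_kappa(classifications[[pr[1]]]$classes[shared],
                      classifications[[pr[2]]]$classes[shared])
    tal <- rank_change_tally(classifications[[pr[1]]]$classes[shared],
                             classifications[[pr[2]]]$classes[shared])
    pe <- pearson_r(a$residuals[shared], b$residuals[shared])
    sp <- spearman_rho(a$residuals[shared], b$residuals[shared])
    reg <- regress_pair(b$residuals[shared], a$residuals[shared])
    agreement[[paste(pr, collapse = "_vs_")]] <- list(
      n = length(shared),
      kappa = ka$kappa, kappa_se = ka$se, kappa_ci = ka$ci,
      kappa_interpretation = ka$interpretation,
      weighted_kappa = ka$weighted_kappa, weighted_se = ka$weighted_se,
      weighted_ci = ka$weighted_ci, weighted_p = ka$weighted_p_value,
      weighted_interpretation = ka$weighted_interpretation,
      pearson = pe$r, spearman = sp$rho,
      slope = reg$slope, slope_se = reg$se, slope_ci = reg$ci,
      slope_ci_contains_1 = reg$slope_ci_contains_1,
      confusion = ka$confusion, n_changed = tal$total_changed)
  }
  jsonlite::write_json(agreement,
                       file.path(config$out_dir, "agreement_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(structure(list(
    config = config, trial = trial, qc = qc, summary = summary_tab,
    fits = fits, classifications = classifications,
    duration = dur, agreement = agreement, out_dir = config$out_dir
  ), class = "rfi_bundle"))
}

#' Render a human-readable report from a pipeline bundle
#'
#' Produces per-group trait means (+/- SD) with a Total row, the
#' unadjusted per-class summary for the base model, the duration
#' comparison table, and the agreement statistics.
#'
#' @param bundle An `rfi_bundle` from [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "rfi_bundle"))
  s <- bundle$summary
  lines <- "== Per-group performance (mean ± SD) =="
  traits <- c(initial_bw = "Initial BW, kg", final_bw = "Final BW, kg",
              mean_dmi = "DMI, kg/d", adg1 = "ADG1, kg/d", adg2 = "ADG2, kg/d",
              mmwt1 = "MMWT1", mmwt2 = "MMWT2")
  hdr <- paste0(formatC("Group", width = 6), formatC("N", width = 4),
                paste(vapply(traits, formatC, "", width = 17), collapse = ""))
  lines <- c(lines, hdr)
  fmt_row <- function(label, d) {
    cells <- vapply(names(traits), function(tr) {
      sprintf("%8.2f ± %5.2f", mean(d[[tr]]), stats::sd(d[[tr]]))
    }, "")
    paste0(formatC(label, width = 6), formatC(nrow(d), width = 4),
           paste(formatC(cells, width = 17), collapse = ""))
  }
  for (g in sort(unique(s$group))) lines <- c(lines, fmt_row(g, s[s$group == g, ]))
  lines <- c(lines, fmt_row("Total", s), "")

  base <- names(bundle$fits)[1]
  cs <- class_summary(s, bundle$classifications[[base]])
  lines <- c(lines, sprintf("== Class summary (%s, unadjusted means) ==", base))
  tab <- cs$table
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf(
      "%-7s n=%3d  RFI %6.2f  DMI %5.2f  ADG1 %4.2f  initial BW %6.1f  final BW %6.1f",
      tab$class[i], tab$n[i], tab$rfi_mean[i], tab$mean_dmi_mean[i],
      tab$adg1_mean[i], tab$initial_bw_mean[i], tab$final_bw_mean[i]))
  }
  if (!is.na(cs$pct_dmi_excess_high_vs_low)) {
    lines <- c(lines, sprintf("high eats %d%% more feed/day than low",
                              cs$pct_dmi_excess_high_vs_low))
  }
  lines <- c(lines, "", "== Duration comparison (full test regressed on truncated) ==",
             utils::capture.output(print(bundle$duration, digits = 3, row.names = FALSE)))

  if (length(bundle$agreement)) {
    lines <- c(lines, "", "== Model agreement ==")
    for (nm in names(bundle$agreement)) {
      ag <- bundle$agreement[[nm]]
      lines <- c(lines, sprintf(
        "%-18s kappa %5.2f (%s)  weighted %5.2f  pearson %5.2f  spearman %5.2f  changed %d/%d",
        nm, ag$kappa, ag$kappa_interpretation, ag$weighted_kappa,
        ag$pearson, ag$spearman, ag$n_changed, ag$n))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Recompute a bundle and diff it against what is on disk
#'
#' Re-runs the pipeline for the same configuration into a temporary
#' directory and compares every output file byte-for-byte, verifying the
#' bundle is reproducible from the inputs alone.
#'
#' @param config The [run_config()] of the original run.
#' @return `TRUE` if everything matches; otherwise the names of the
#'   differing files, invisibly, with a warning.
#' @export
verify_pipeline <- function(config) {
  tmp <- file.path(tempfile("rfitrial_verify_"))
  cfg2 <- config
  cfg2$out_dir <- tmp
  on.exit(unlink(tmp, recursive = TRUE))
  suppressMessages(run_pipeline(cfg2))
  files <- list.files(config$out_dir)
  bad <- character()
  for (f in files) {
    a <- file.path(config$out_dir, f)
    b <- file.path(tmp, f)
    if (!file.exists(b) ||
        !identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))) {
      bad <- c(bad, f)
    }
  }
  if (length(bad)) {
    warning("bundle not reproducible; differing files: ",
            paste(bad, collapse = ", "))
    return(invisible(bad))
  }
  TRUE
}
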