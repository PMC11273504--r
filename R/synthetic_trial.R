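#' Configure one contemporary group for a simulated feed trial
#'
#' A contemporary group is a set of heifers tested together (same trial
#' period and source farm). Group-level means and SDs drive the draws of
#' initial body weight, average daily gain, and age at the start of test.
#'
#' @param group_id Label for the group.
#' @param farm Label for the source farm.
#' @param n Number of heifers in the group (>= 2).
#' @param initial_bw_mean,initial_bw_sd Day-0 body weight distribution, kg.
#' @param adg_mean,adg_sd True average daily gain distribution, kg/d.
#' @param age_on_test_mean,age_on_test_sd Age at start of test, days.
#' @param on_test_date Date the group went on test (`Date` or ISO string).
#'
#' @return A list of class `group_config`.
#' @export
group_config <- function(group_id, farm, n,
                         initial_bw_mean, initial_bw_sd,
                         adg_mean, adg_sd,
                         age_on_test_mean = 280, age_on_test_sd = 15,
                         on_test_date = as.Date("2015-06-01")) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop_field("n", "must be an integer >= 2")
  }
  assert_number(initial_bw_mean, "initial_bw_mean", lower = 0)
  assert_number(initial_bw_sd, "initial_bw_sd", lower = 0)
  assert_number(adg_mean, "adg_mean")
  assert_number(adg_sd, "adg_sd", lower = 0)
  assert_number(age_on_test_mean, "age_on_test_mean", lower = 0)
  assert_number(age_on_test_sd, "age_on_test_sd", lower = 0)
  structure(list(
    group_id = as.character(group_id),
    farm = as.character(farm),
    n = as.integer(n),
    initial_bw_mean = initial_bw_mean,
    initial_bw_sd = initial_bw_sd,
    adg_mean = adg_mean,
    adg_sd = adg_sd,
    age_on_test_mean = age_on_test_mean,
    age_on_test_sd = age_on_test_sd,
    on_test_date = as.Date(on_test_date)
  ), class = "group_config")
}

#' Configure a simulated multi-group feed trial
#'
#' The simulator draws, per heifer, a true average daily gain (ADG) and a
#' day-0 body weight from its group, an animal-level efficiency residual
#' (true RFI) with SD `sigma_rfi`, and an ultrasound backfat depth (UBF)
#' correlated `ubf_rfi_corr` with the efficiency residual. Latent mean
#' dry-matter intake follows a linear energy-demand model,
#' `intercept + coef_adg * ADG + coef_mmwt * MMWT + coef_ubf * UBF + RFI`,
#' where MMWT is the metabolic midweight `(BW_mid)^0.75`. Daily intakes and
#' biweekly weighings are the latent values plus independent Gaussian noise.
#'
#' @param groups List of [group_config()] objects.
#' @param dmi_intercept Intercept of the latent intake model, kg/d.
#' @param dmi_coef_adg kg DMI per kg/d of ADG.
#' @param dmi_coef_mmwt kg DMI per kg^0.75 of metabolic midweight.
#' @param dmi_coef_ubf kg DMI per mm of backfat.
#' @param sigma_rfi Animal-level efficiency residual SD, kg/d.
#' @param sigma_daily_intake Day-to-day intake noise SD, kg/d.
#' @param sigma_weighing Per-weighing measurement noise SD, kg.
#' @param ubf_mean,ubf_sd Backfat depth distribution, mm.
#' @param ubf_rfi_corr Correlation between backfat and the efficiency
#'   residual, in \[-1, 1\].
#' @param days_on_test Test length in days; must be divisible by
#'   `weigh_interval`.
#' @param weigh_interval Days between mid-test weighings.
#' @param seed Default root seed used by [generate_trial()].
#'
#' @return A list of class `sim_config`.
#' @seealso [default_sim_config()] for the seven-group default trial.
#' @export
sim_config <- function(groups,
                       dmi_intercept = -0.5,
                       dmi_coef_adg = 1.8,
                       dmi_coef_mmwt = 0.105,
                       dmi_coef_ubf = 0.05,
                       sigma_rfi = 0.95,
                       sigma_daily_intake = 2.5,
                       sigma_weighing = 4,
                       ubf_mean = 7.7,
                       ubf_sd = 2.5,
                       ubf_rfi_corr = 0.2,
                       days_on_test = 70,
                       weigh_interval = 14,
                       seed = 1L) {
  cfg <- structure(list(
    groups = groups,
    dmi_intercept = dmi_intercept,
    dmi_coef_adg = dmi_coef_adg,
    dmi_coef_mmwt = dmi_coef_mmwt,
    dmi_coef_ubf = dmi_coef_ubf,
    sigma_rfi = sigma_rfi,
    sigma_daily_intake = sigma_daily_intake,
    sigma_weighing = sigma_weighing,
    ubf_mean = ubf_mean,
    ubf_sd = ubf_sd,
    ubf_rfi_corr = ubf_rfi_corr,
    days_on_test = as.integer(days_on_test),
    weigh_interval = as.integer(weigh_interval),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config object", call. = FALSE)
  }
  if (!length(config$groups)) stop_field("groups", "must contain at least one group")
  for (g in config$groups) {
    if (!inherits(g, "group_config")) {
      stop_field("groups", "every element must be a group_config object")
    }
  }
  for (f in c("sigma_rfi", "sigma_daily_intake", "sigma_weighing", "ubf_sd")) {
    assert_number(config[[f]], f, lower = 0)
  }
  assert_number(config$ubf_rfi_corr, "ubf_rfi_corr", lower = -1, upper = 1)
  assert_number(config$days_on_test, "days_on_test", lower = 1)
  assert_number(config$weigh_interval, "weigh_interval", lower = 1)
  if (config$days_on_test %% config$weigh_interval != 0) {
    stop_field("days_on_test", "must be divisible by weigh_interval")
  }
  ids <- vapply(config$groups, `[[`, character(1), "group_id")
  if (anyDuplicated(ids)) stop_field("groups", "group_id values must be unique")
  invisible(config)
}

#' Default seven-group trial configuration
#'
#' Recreates the structure of a 186-heifer evaluation spread over seven
#' contemporary groups from two farms, with group sizes 20, 46, 22, 23,
#' 22, 12 and 41 and group-level initial body weight and gain
#' distributions typical of growing Brangus replacement heifers on a
#' 70-day test with 14-day weighings.
#'
#' @return A `sim_config` object.
#' @export
default_sim_config <- function() {
  groups <- list(
    group_config("1", "1", 20, 301.87, 32.68, 1.30, 0.18,
                 on_test_date = "2014-06-10"),
    group_config("2", "1", 46, 301.70, 31.98, 1.29, 0.13,
                 on_test_date = "2015-06-09"),
    group_config("3", "2", 22, 278.24, 24.97, 1.19, 0.15,
                 on_test_date = "2014-06-10"),
    group_config("4", "2", 23, 292.08, 29.62, 1.50, 0.23,
                 on_test_date = "2015-08-18"),
    group_config("5", "1", 22, 323.72, 33.85, 1.61, 0.21,
                 on_test_date = "2015-09-22"),
    group_config("6", "1", 12, 325.38, 28.98, 1.55, 0.27,
                 on_test_date = "2014-12-09"),
    group_config("7", "2", 41, 299.49, 25.44, 1.46, 0.24,
                 on_test_date = "2014-12-09")
  )
  sim_config(groups)
}

#' Weigh-day schedule for a test
#'
#' Animals are weighed on two consecutive days at each end of the test
#' (days -1/0 and days D-1/D) and every `weigh_interval` days in between.
#'
#' @param days_on_test Test length, days.
#' @param weigh_interval Interval between mid-test weighings, days.
#' @return Sorted integer vector of weigh days.
#' @export
weigh_schedule <- function(days_on_test, weigh_interval) {
  mid <- seq(weigh_interval, days_on_test - weigh_interval, by = weigh_interval)
  sort(unique(c(-1L, 0L, as.integer(mid),
                as.integer(days_on_test) - 1L, as.integer(days_on_test))))
}

#' Generate a synthetic feed trial
#'
#' Draws a complete trial dataset under `config`: animal metadata, daily
#' dry-matter intake, dated body weights, and the latent ground truth used
#' by recovery tests. Identical `(config, seed)` pairs reproduce the
#' output exactly; each heifer has its own deterministic RNG substream so
#' appending groups to the config leaves earlier animals untouched.
#'
#' `true_initial_bw` is recorded as the expected on-test two-day average
#' weight (the day -1/0 mean of the noise-free growth line), so with zero
#' measurement noise the endpoint average recovers it exactly.
#'
#' @param config A [sim_config()] object.
#' @param seed Root integer seed; defaults to `config$seed`.
#'
#' @return A list of class `feed_trial` with data frames `heifers`
#'   (id, group, farm, birth_date, on_test_date, days_on_test, ubf_mm),
#'   `intake` (id, day, dmi_kg), `weights` (id, day, bw_kg), and
#'   `true_values` (id, true_adg, true_rfi, true_mean_dmi, true_initial_bw).
#' @export
generate_trial <- function(config, seed = config$seed) {
  validate_sim_config(config)
  assert_number(seed, "seed")
  days <- config$days_on_test
  sched <- weigh_schedule(days, config$weigh_interval)
  n_sched <- length(sched)
  n_total <- sum(vapply(config$groups, `[[`, integer(1), "n"))

  ids <- sprintf("H%04d", seq_len(n_total))
  grp <- farm <- character(n_total)
  birth <- on_test <- as.Date(rep(NA_integer_, n_total))
  ubf_v <- adg_v <- rfi_v <- dmi_v <- bw0_v <- numeric(n_total)
  intake_mat <- matrix(NA_real_, n_total, days)
  weight_mat <- matrix(NA_real_, n_total, n_sched)

  rho <- config$ubf_rfi_corr
  idx <- 0L
  with_local_rng({
    for (g in config$groups) {
      for (k in seq_len(g$n)) {
        idx <- idx + 1L
        set.seed(heifer_seed(seed, idx))

        # fixed draw order per animal: age, BW, ADG, efficiency, backfat,
        # daily intake noise, weighing noise
        age <- round(stats::rnorm(1, g$age_on_test_mean, g$age_on_test_sd))
        age <- min(max(age, 240), 390 - days)  # keep inside the BIF window
        bw0 <- stats::rnorm(1, g$initial_bw_mean, g$initial_bw_sd)
        adg <- stats::rnorm(1, g$adg_mean, g$adg_sd)
        z_rfi <- stats::rnorm(1)
        z_ubf <- stats::rnorm(1)
        rfi <- config$sigma_rfi * z_rfi
        ubf <- config$ubf_mean +
          config$ubf_sd * (rho * z_rfi + sqrt(1 - rho^2) * z_ubf)

        mmwt_true <- (bw0 + adg * days / 2)^0.75
        latent_dmi <- config$dmi_intercept +
          config$dmi_coef_adg * adg +
          config$dmi_coef_mmwt * mmwt_true +
          config$dmi_coef_ubf * ubf +
          rfi

        grp[idx] <- g$group_id
        farm[idx] <- g$farm
        birth[idx] <- g$on_test_date - age
        on_test[idx] <- g$on_test_date
        ubf_v[idx] <- ubf; adg_v[idx] <- adg; rfi_v[idx] <- rfi
        dmi_v[idx] <- latent_dmi; bw0_v[idx] <- bw0
        intake_mat[idx, ] <- pmax(
          latent_dmi + stats::rnorm(days, 0, config$sigma_daily_intake), 0)
        weight_mat[idx, ] <- bw0 + adg * sched +
          stats::rnorm(n_sched, 0, config$sigma_weighing)
      }
    }
  })

  structure(list(
    heifers = data.frame(id = ids, group = grp, farm = farm,
                         birth_date = birth, on_test_date = on_test,
                         days_on_test = days, ubf_mm = ubf_v,
                         stringsAsFactors = FALSE),
    intake = data.frame(id = rep(ids, each = days),
                        day = rep(seq_len(days), n_total),
                        dmi_kg = as.vector(t(intake_mat)),
                        stringsAsFactors = FALSE),
    weights = data.frame(id = rep(ids, each = n_sched),
                         day = rep(sched, n_total),
                         bw_kg = as.vector(t(weight_mat)),
                         stringsAsFactors = FALSE),
    true_values = data.frame(id = ids, true_adg = adg_v, true_rfi = rfi_v,
                             true_mean_dmi = dmi_v,
                             true_initial_bw = bw0_v - adg_v / 2,
                             stringsAsFactors = FALSE)
  ), class = "feed_trial")
}

#' Write a simulated trial to CSV files
#'
#' Emits `heifers.csv`, `intake.csv`, `weights.csv` and (optionally)
#' `true_values.csv` with ISO-8601 dates, '.' decimals and LF newlines so
#' repeated runs diff byte-for-byte.
#'
#' @param trial A `feed_trial` object from [generate_trial()].
#' @param dir Output directory (created if missing).
#' @param true_values Also write the latent ground truth?
#' @return Invisibly, the named vector of file paths.
#' @export
write_trial <- function(trial, dir, true_values = FALSE) {
  stopifnot(inherits(trial, "feed_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    heifers = file.path(dir, "heifers.csv"),
    intake = file.path(dir, "intake.csv"),
    weights = file.path(dir, "weights.csv")
  )
  h <- trial$heifers
  h$birth_date <- as.character(h$birth_date)
  h$on_test_date <- as.character(h$on_test_date)
  utils::write.csv(h, paths["heifers"], row.names = FALSE, quote = FALSE)
  utils::write.csv(trial$intake, paths["intake"], row.names = FALSE, quote = FALSE)
  utils::write.csv(trial$weights, paths["weights"], row.names = FALSE, quote = FALSE)
  if (true_values) {
    paths <- c(paths, true_values = file.path(dir, "true_values.csv"))
    utils::write.csv(trial$true_values, paths["true_values"],
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Read a trial from CSV files
#'
#' Counterpart of [write_trial()]; also accepts user data in the same
#' dialect (long-format intake and weights keyed by animal id and day).
#'
#' @param dir Directory holding `heifers.csv`, `intake.csv`, `weights.csv`.
#' @return A `feed_trial` object (without `true_values` unless present).
#' @export
read_trial <- function(dir) {
  h <- utils::read.csv(file.path(dir, "heifers.csv"), stringsAsFactors = FALSE,
                       colClasses = c(id = "character", group = "character",
                                      farm = "character"))
  h$birth_date <- as.Date(h$birth_date)
  h$on_test_date <- as.Date(h$on_test_date)
  out <- list(
    heifers = h,
    intake = utils::read.csv(file.path(dir, "intake.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(id = "character")),
    weights = utils::read.csv(file.path(dir, "weights.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(id = "character"))
  )
  tv <- file.path(dir, "true_values.csv")
  if (file.exists(tv)) {
    out$true_values <- utils::read.csv(tv, stringsAsFactors = FALSE,
                                       colClasses = c(id = "character"))
  }
  structure(out, class = "feed_trial")
}

#' Serialize a simulation configuration to YAML
#'
#' Field names in the file mirror the `sim_config` fields exactly.
#'
#' @param config A `sim_config` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  x <- unclass(config)
  x$groups <- lapply(x$groups, function(g) {
    g <- unclass(g)
    g$on_test_date <- as.character(g$on_test_date)
    g
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path File written by [write_sim_config()].
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  groups <- lapply(x$groups, function(g) do.call(group_config, g))
  x$groups <- NULL
  do.call(sim_config, c(list(groups = groups), x))
}
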