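# Expected-DMI regressions, residual feed intake, and efficiency classes.
#
# RFI is the residual of an ordinary-least-squares regression of mean
# daily DMI on gain and metabolic midweight (optionally plus ultrasound
# backfat): animals that eat less than the model predicts for their gain
# and body size have negative RFI and are the efficient ones.

#' Fit an expected-DMI model and extract RFI residuals
#'
#' Regresses per-animal mean daily DMI on ADG and metabolic midweight,
#' using either the regression-based (`adg1`/`mmwt1`) or the
#' difference-based (`adg2`/`mmwt2`) gain definition, optionally adding
#' ultrasound backfat (`ubf_mm`) as a covariate. Residuals (observed
#' minus fitted DMI) are the RFI values.
#'
#' The four standard model specs are:
#' * Model 1 (`RFI_1`): `adg_variant = "regression"`, no backfat
#' * Model 2 (`RFI_bf1`): `adg_variant = "regression"`, with backfat
#' * Model 3 (`RFI_2`): `adg_variant = "difference"`, no backfat
#' * Model 4 (`RFI_bf2`): `adg_variant = "difference"`, with backfat
#'
#' @param table Growth summary data frame from [growth_summary_table()].
#' @param adg_variant `"regression"` (ADG1/MMWT1) or `"difference"`
#'   (ADG2/MMWT2).
#' @param include_ubf Add backfat depth to the model? Animals without a
#'   backfat record are dropped from backfat models (with a message), not
#'   from the plain models.
#' @param fit_scope `"pooled"` (one regression over all animals),
#'   `"per_group"` (separate regression per contemporary group), or
#'   `"group_fixed_effect"` (one regression with group as a fixed
#'   effect).
#' @return An object of class `rfi_fit`: list with `spec`, `coefficients`
#'   (vector, or list per group), `r_squared` (named by scope),
#'   `residuals` and `fitted` (named by id), `groups`, `n`,
#'   `n_dropped_ubf`.
#' @export
fit_dmi_model <- function(table,
                          adg_variant = c("regression", "difference"),
                          include_ubf = FALSE,
                          fit_scope = c("pooled", "per_group",
                                        "group_fixed_effect")) {
  adg_variant <- match.arg(adg_variant)
  fit_scope <- match.arg(fit_scope)
  adg_col <- if (adg_variant == "regression") "adg1" else "adg2"
  mmwt_col <- if (adg_variant == "regression") "mmwt1" else "mmwt2"

  df <- data.frame(id = table$id,
                   group = if ("group" %in% names(table)) table$group else "all",
                   y = table$mean_dmi,
                   adg = table[[adg_col]],
                   mmwt = table[[mmwt_col]],
                   stringsAsFactors = FALSE)
  n_dropped <- 0L
  if (include_ubf) {
    df$ubf <- table$ubf_mm
    drop <- is.na(df$ubf)
    n_dropped <- sum(drop)
    if (n_dropped) {
      message(sprintf("dropping %d animal(s) without a backfat record from the backfat-adjusted model",
                      n_dropped))
      df <- df[!drop, ]
    }
  }

  rhs <- c("adg", "mmwt", if (include_ubf) "ubf")
  p <- length(rhs)

  fit_one <- function(d, label) {
    if (nrow(d) < p + 2L) {
      stop(sprintf("scope '%s' has %d rows; need at least %d to fit %d predictors",
                   label, nrow(d), p + 2L, p))
    }
    form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
    X <- stats::model.matrix(form, data = d)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
      stop(sprintf("singular design in scope '%s': collinear column(s) %s",
                   label, paste(bad, collapse = ", ")))
    }
    stats::lm(form, data = d)
  }

  if (fit_scope == "pooled") {
    m <- fit_one(df, "pooled")
    res <- stats::setNames(stats::residuals(m), df$id)
    fitted <- stats::setNames(stats::fitted(m), df$id)
    coefs <- stats::coef(m)
    r2 <- c(pooled = summary(m)$r.squared)
  } else if (fit_scope == "per_group") {
    pieces <- split(df, df$group)
    fits <- lapply(names(pieces), function(g) fit_one(pieces[[g]], g))
    names(fits) <- names(pieces)
    res <- fitted <- numeric()
    for (g in names(fits)) {
      res <- c(res, stats::setNames(stats::residuals(fits[[g]]), pieces[[g]]$id))
      fitted <- c(fitted, stats::setNames(stats::fitted(fits[[g]]), pieces[[g]]$id))
    }
    res <- res[df$id]; fitted <- fitted[df$id]
    coefs <- lapply(fits, stats::coef)
    r2 <- vapply(fits, function(m) summary(m)$r.squared, numeric(1))
  } else {
    d <- df
    if (length(unique(d$group)) > 1L) {
      form <- stats::as.formula(paste("y ~ group +", paste(rhs, collapse = " + ")))
      m <- stats::lm(form, data = d)
    } else {
      m <- fit_one(d, "group_fixed_effect")
    }
    res <- stats::setNames(stats::residuals(m), d$id)
    fitted <- stats::setNames(stats::fitted(m), d$id)
    coefs <- stats::coef(m)
    r2 <- c(group_fixed_effect = summary(m)$r.squared)
  }

  structure(list(
    spec = list(adg_variant = adg_variant, include_ubf = include_ubf,
                fit_scope = fit_scope),
    coefficients = coefs,
    r_squared = r2,
    residuals = res,
    fitted = fitted,
    groups = stats::setNames(df$group, df$id),
    n = nrow(df),
    n_dropped_ubf = n_dropped
  ), class = "rfi_fit")
}

#' @export
print.rfi_fit <- function(x, ...) {
  cat(sprintf("Expected-DMI model (%s ADG%s, scope %s), n = %d\n",
              x$spec$adg_variant,
              if (x$spec$include_ubf) " + backfat" else "",
              x$spec$fit_scope, x$n))
  cat("R-squared:", paste(sprintf("%s = %.3f", names(x$r_squared),
                                  x$r_squared), collapse = ", "), "\n")
  invisible(x)
}

#' Fit the four standard RFI models
#'
#' Runs [fit_dmi_model()] for the regression- and difference-based gain
#' definitions, each with and without the backfat covariate, under one
#' shared fit scope. If no animal has a backfat record the two adjusted
#' models are skipped with a message.
#'
#' @inheritParams fit_dmi_model
#' @return Named list of `rfi_fit` objects: `RFI_1`, `RFI_bf1`, `RFI_2`,
#'   `RFI_bf2` (backfat entries absent when no backfat data exist).
#' @export
compute_rfi_models <- function(table, fit_scope = "pooled") {
  out <- list(
    RFI_1 = fit_dmi_model(table, "regression", FALSE, fit_scope),
    RFI_2 = fit_dmi_model(table, "difference", FALSE, fit_scope)
  )
  if (all(is.na(table$ubf_mm))) {
    message("no backfat records: skipping backfat-adjusted models RFI_bf1 and RFI_bf2")
  } else {
    out$RFI_bf1 <- fit_dmi_model(table, "regression", TRUE, fit_scope)
    out$RFI_bf2 <- fit_dmi_model(table, "difference", TRUE, fit_scope)
  }
  out[intersect(c("RFI_1", "RFI_bf1", "RFI_2", "RFI_bf2"), names(out))]
}

#' Classify animals as low/medium/high RFI within contemporary group
#'
#' Within each group, animals more than 1 group-SD above the group mean
#' RFI are `high` (inefficient), animals more than 1 SD below are `low`
#' (efficient), and the rest -- including animals exactly at +/-1 SD --
#' are `medium`. The SD is the within-group sample SD (n - 1 denominator)
#' of the model residuals. A group with zero residual SD is classified
#' entirely `medium`.
#'
#' @param x An `rfi_fit`, or a named numeric vector of RFI values.
#' @param groups Named character vector mapping ids to groups; defaults
#'   to the groups stored in the fit (or a single group for a bare
#'   vector).
#' @param sd_multiplier Threshold in group-SD units.
#' @return An `rfi_classification`: list with `classes` (named factor
#'   low/medium/high), `by` (data frame id, group, rfi, class) and
#'   `thresholds` (group, n, mean, sd).
#' @export
classify_rfi <- function(x, groups = NULL, sd_multiplier = 1) {
  if (inherits(x, "rfi_fit")) {
    rfi <- x$residuals
    groups <- groups %||% x$groups
  } else {
    rfi <- x
    if (is.null(names(rfi))) names(rfi) <- sprintf("A%04d", seq_along(rfi))
    groups <- groups %||% stats::setNames(rep("all", length(rfi)), names(rfi))
  }
  grp <- groups[names(rfi)]
  if (anyNA(grp)) stop("every classified id needs a group mapping")

  thresholds <- do.call(rbind, lapply(unique(grp), function(g) {
    v <- rfi[grp == g]
    if (length(v) < 2L) stop(sprintf("group '%s' has fewer than 2 members", g))
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  }))

  cls <- character(length(rfi))
  for (i in seq_len(nrow(thresholds))) {
    g <- thresholds$group[i]
    m <- thresholds$mean[i]; s <- thresholds$sd[i]
    v <- rfi[grp == g]
    lab <- rep("medium", length(v))
    if (s > 0) {
      lab[v > m + sd_multiplier * s] <- "high"
      lab[v < m - sd_multiplier * s] <- "low"
    }
    cls[grp == g] <- lab
  }
  classes <- factor(cls, levels = c("low", "medium", "high"))
  names(classes) <- names(rfi)
  structure(list(
    classes = classes,
    by = data.frame(id = names(rfi), group = unname(grp), rfi = unname(rfi),
                    class = unname(classes), stringsAsFactors = FALSE),
    thresholds = thresholds
  ), class = "rfi_classification")
}

#' Per-class summary of growth and performance traits
#'
#' Unadjusted arithmetic class means and standard errors for RFI, body
#' weights, intake, gain, metabolic midweight and backfat, by efficiency
#' class, plus the percent excess intake of the high class over the low
#' class, `round(100 * (DMI_high - DMI_low) / DMI_low)`.
#'
#' These are raw means, not least-squares means adjusted for farm, sire
#' or trial.
#'
#' @param table Growth summary data frame (see [growth_summary_table()]).
#' @param classification An `rfi_classification` for the same animals.
#' @return List of class `rfi_class_summary` with `table` (one row per
#'   class: n plus `<trait>_mean` / `<trait>_sem` columns) and
#'   `pct_dmi_excess_high_vs_low` (integer percent, `NA` if a class is
#'   empty).
#' @export
class_summary <- function(table, classification) {
  stopifnot(inherits(classification, "rfi_classification"))
  by <- classification$by
  merged <- merge(by, table, by = "id")
  traits <- c("rfi", "initial_bw", "final_bw", "mean_dmi",
              "adg1", "adg2", "mmwt1", "mmwt2", "ubf_mm")
  traits <- intersect(traits, names(merged))
  rows <- lapply(levels(classification$classes), function(cl) {
    d <- merged[merged$class == cl, ]
    out <- data.frame(class = cl, n = nrow(d), stringsAsFactors = FALSE)
    for (tr in traits) {
      v <- d[[tr]][!is.na(d[[tr]])]
      out[[paste0(tr, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(tr, "_sem")]] <- if (length(v) > 1)
        stats::sd(v) / sqrt(length(v)) else NA_real_
    }
    out
  })
  tab <- do.call(rbind, rows)
  lo <- tab$mean_dmi_mean[tab$class == "low"]
  hi <- tab$mean_dmi_mean[tab$class == "high"]
  pct <- if (length(lo) && length(hi) && !is.na(lo) && !is.na(hi) && lo > 0) {
    as.integer(round(100 * (hi - lo) / lo))
  } else {
    message("empty efficiency class: percent DMI excess not defined")
    NA_integer_
  }
  structure(list(table = tab, pct_dmi_excess_high_vs_low = pct),
            class = "rfi_class_summary")
}

as_class_vector <- function(x) {
  if (inherits(x, "rfi_classification")) return(x$classes)
  lv <- c("low", "medium", "high")
  if (is.factor(x)) x <- as.character(x)
  if (!all(x %in% lv)) stop("labels must be 'low', 'medium' or 'high'")
  f <- factor(x, levels = lv)
  names(f) <- names(x)
  f
}

#' Tally classification changes between two model rankings
#'
#' Counts every ordered (class under a, class under b) pair and the total
#' number of animals whose class changed (the off-diagonal sum).
#'
#' @param a,b `rfi_classification` objects or named label vectors over
#'   the same ids.
#' @return List with `matrix` (3 x 3 transition counts, rows = a), `n`,
#'   and `total_changed`.
#' @export
rank_change_tally <- function(a, b) {
  a <- as_class_vector(a)
  b <- as_class_vector(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    only_a <- setdiff(names(a), names(b))
    only_b <- setdiff(names(b), names(a))
    if (length(only_a) || length(only_b)) {
      stop(sprintf("id sets differ; only in a: %s; only in b: %s",
                   paste(only_a, collapse = ",") ,
                   paste(only_b, collapse = ",")))
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("label vectors must have equal length")
  }
  m <- table(a = a, b = b)
  list(matrix = unclass(m), n = length(a),
       total_changed = sum(m) - sum(diag(m)))
}
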