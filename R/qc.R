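# Data-editing (QC) filters applied before any growth or intake modelling.

new_qc_report <- function(retained_ids, excluded) {
  if (is.null(excluded) || !nrow(excluded)) {
    excluded <- data.frame(id = character(), rule = character(),
                           detail = character(), stringsAsFactors = FALSE)
  }
  structure(list(retained_ids = retained_ids, excluded = excluded),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d retained, %d excluded\n",
              length(x$retained_ids), nrow(x$excluded)))
  if (nrow(x$excluded)) print(table(x$excluded$rule))
  invisible(x)
}

#' Filter animals by age window at the start and end of test
#'
#' Performance-test guidelines require animals to be at least
#' `min_start_age` days old when the intake test starts and no older than
#' `max_end_age` days when it ends. Both boundaries are inclusive. Ages
#' are whole days between `birth_date` and `on_test_date`.
#'
#' @param heifers Data frame with columns `id`, `birth_date`,
#'   `on_test_date`, `days_on_test`.
#' @param min_start_age Minimum age at test initiation, days.
#' @param max_end_age Maximum age at test completion, days.
#' @return A `qc_report` with `retained_ids` and an `excluded` data frame
#'   of (id, rule, detail). Records with a missing birth date are
#'   excluded under rule `"missing-field"` rather than aborting.
#' @export
check_age_window <- function(heifers, min_start_age = 240, max_end_age = 390) {
  excl <- list()
  keep <- character()
  for (i in seq_len(nrow(heifers))) {
    id <- heifers$id[i]
    bd <- heifers$birth_date[i]
    if (is.na(bd)) {
      excl[[length(excl) + 1L]] <- data.frame(
        id = id, rule = "missing-field", detail = "birth_date is missing",
        stringsAsFactors = FALSE)
      next
    }
    age <- as.integer(heifers$on_test_date[i] - bd)
    if (age < 0) stop(sprintf("birth_date after on_test_date for '%s'", id))
    age_end <- age + heifers$days_on_test[i]
    if (age < min_start_age) {
      excl[[length(excl) + 1L]] <- data.frame(
        id = id, rule = "age-window",
        detail = sprintf("age %d d at start of test < %d", age, min_start_age),
        stringsAsFactors = FALSE)
    } else if (age_end > max_end_age) {
      excl[[length(excl) + 1L]] <- data.frame(
        id = id, rule = "age-window",
        detail = sprintf("age %d d at end of test > %d", age_end, max_end_age),
        stringsAsFactors = FALSE)
    } else {
      keep <- c(keep, id)
    }
  }
  new_qc_report(keep, do.call(rbind, excl))
}

#' Screen total test intake against the contemporary-group spread
#'
#' Within each contemporary group the sample mean and SD (n - 1
#' denominator) of total test dry-matter intake are computed with the
#' candidate animal included; animals farther than `k` SD from the group
#' mean are excluded. A group with zero SD retains all of its members,
#' and a group of one retains its member with a warning since the screen
#' is undefined. Note that with the candidate included the largest
#' attainable |z| in a group of n is (n - 1)/sqrt(n), so a lone outlier
#' in a group of 12 (max |z| = 3.18) can never breach the default k = 4.
#'
#' @param totals Named numeric vector of per-animal total test DMI, kg.
#' @param groups Named character vector mapping the same ids to groups.
#' @param k SD multiplier for the screen.
#' @return A `qc_report`.
#' @export
screen_intake_outliers <- function(totals, groups, k = 4) {
  ids <- names(totals)
  if (is.null(ids)) stop("`totals` must be named by animal id")
  if (!all(ids %in% names(groups))) {
    stop("every id in `totals` must be mapped in `groups`")
  }
  grp <- groups[ids]
  keep <- character()
  excl <- list()
  for (g in unique(grp)) {
    gid <- ids[grp == g]
    x <- totals[gid]
    if (length(x) == 1L) {
      warning(sprintf(
        "group '%s' has a single member; intake screen undefined, retaining '%s'",
        g, gid))
      keep <- c(keep, gid)
      next
    }
    m <- mean(x)
    s <- stats::sd(x)
    if (s == 0) {
      keep <- c(keep, gid)
      next
    }
    z <- (x - m) / s
    ok <- abs(z) <= k
    keep <- c(keep, gid[ok])
    for (j in which(!ok)) {
      excl[[length(excl) + 1L]] <- data.frame(
        id = gid[j], rule = "intake-outlier",
        detail = sprintf("total DMI %.2f kg is %.2f SD from group '%s' mean %.2f",
                         x[j], z[j], g, m),
        stringsAsFactors = FALSE)
    }
  }
  new_qc_report(ids[ids %in% keep], do.call(rbind, excl))
}

#' Drop animals with incomplete daily feed records
#'
#' Retains animals that have a recorded DMI value for every day
#' `1..required_days`.
#'
#' @param intake Long data frame with columns `id`, `day`, `dmi_kg`.
#' @param required_days Number of feeding days each animal must cover.
#' @return A `qc_report`; exclusions list the missing days.
#' @export
drop_incomplete_records <- function(intake, required_days) {
  ids <- unique(intake$id)
  keep <- character()
  excl <- list()
  for (id in ids) {
    rows <- intake[intake$id == id & !is.na(intake$dmi_kg), ]
    missing <- setdiff(seq_len(required_days), rows$day)
    if (!length(missing)) {
      keep <- c(keep, id)
    } else {
      excl[[length(excl) + 1L]] <- data.frame(
        id = id, rule = "incomplete-record",
        detail = paste0("missing days: ",
                        paste(missing[seq_len(min(10, length(missing)))],
                              collapse = ",") ,
                        if (length(missing) > 10) sprintf(" (+%d more)",
                                                          length(missing) - 10)
                        else ""),
        stringsAsFactors = FALSE)
    }
  }
  new_qc_report(keep, do.call(rbind, excl))
}

#' Run the full data-editing sequence
#'
#' Applies, in order: incomplete-record removal, the age window, and the
#' contemporary-group intake screen, with group intake statistics
#' recomputed on the survivors of the first two edits.
#'
#' @param heifers,intake As in the component filters.
#' @param min_start_age,max_end_age,intake_sd_k Thresholds passed through.
#' @param required_days Feeding days required per animal; defaults to the
#'   per-trial `days_on_test` from `heifers`.
#' @return A `qc_report` combining all exclusions.
#' @export
run_qc <- function(heifers, intake, min_start_age = 240, max_end_age = 390,
                   intake_sd_k = 4, required_days = NULL) {
  required_days <- required_days %||% max(heifers$days_on_test)
  r1 <- drop_incomplete_records(intake[intake$id %in% heifers$id, ],
                                required_days)
  h2 <- heifers[heifers$id %in% r1$retained_ids, ]
  r2 <- check_age_window(h2, min_start_age, max_end_age)
  h3 <- h2[h2$id %in% r2$retained_ids, ]
  ok <- intake$id %in% h3$id & intake$day >= 1 & intake$day <= required_days
  totals <- tapply(intake$dmi_kg[ok], intake$id[ok], sum)
  totals <- stats::setNames(as.numeric(totals), names(totals))[h3$id]
  names(totals) <- h3$id
  groups <- stats::setNames(h3$group, h3$id)
  r3 <- screen_intake_outliers(totals, groups, k = intake_sd_k)
  new_qc_report(r3$retained_ids,
                rbind(r1$excluded, r2$excluded, r3$excluded))
}

#' Tabulate a QC report for export
#'
#' @param report A `qc_report`.
#' @return Data frame with one row per animal: id, status
#'   (retained/excluded), rule, detail.
#' @export
qc_report_table <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  ret <- data.frame(id = report$retained_ids, status = "retained",
                    rule = "", detail = "", stringsAsFactors = FALSE)
  exc <- report$excluded
  if (nrow(exc)) {
    exc <- data.frame(id = exc$id, status = "excluded", rule = exc$rule,
                      detail = exc$detail, stringsAsFactors = FALSE)
  } else {
    exc <- ret[0, ]
  }
  rbind(ret, exc)
}
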