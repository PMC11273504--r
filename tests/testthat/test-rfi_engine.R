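test_that("exact linear intake data give zero residuals and unit R-squared", {
  tab <- toy_summary()
  tab$mean_dmi <- 1 + 2 * tab$adg1 + 0.1 * tab$mmwt1
  fit <- suppressWarnings(fit_dmi_model(tab, "regression"))
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(unname(fit$r_squared), 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(1, 2, 0.1), tolerance = 1e-8)
})

test_that("model coefficients match the explicit normal-equations oracle", {
  tab <- toy_summary(6)
  fit <- fit_dmi_model(tab, "regression", include_ubf = FALSE)
  X <- cbind(1, tab$adg1, tab$mmwt1)
  oracle <- ols_oracle(X, tab$mean_dmi)
  expect_equal(unname(fit$coefficients), oracle$beta, tolerance = 1e-8)
  expect_equal(unname(fit$residuals), oracle$residuals, tolerance = 1e-8)
  expect_equal(unname(fit$r_squared), oracle$r_squared, tolerance = 1e-8)

  fit_bf <- fit_dmi_model(tab, "difference", include_ubf = TRUE)
  Xb <- cbind(1, tab$adg2, tab$mmwt2, tab$ubf_mm)
  oracle_bf <- ols_oracle(Xb, tab$mean_dmi)
  expect_equal(unname(fit_bf$coefficients), oracle_bf$beta, tolerance = 1e-8)
})

test_that("residuals sum to zero and are orthogonal to predictors in every scope", {
  tab <- default_summary()
  n <- nrow(tab)
  for (scope in c("pooled", "per_group", "group_fixed_effect")) {
    fit <- fit_dmi_model(tab, "regression", fit_scope = scope)
    res <- fit$residuals[tab$id]
    expect_lt(abs(sum(res)), 1e-8 * n)
    if (scope != "pooled") {
      # with group-scoped fits each fitted scope balances separately
      for (g in unique(tab$group)) {
        expect_lt(abs(sum(res[tab$group == g])), 1e-8 * n)
      }
    }
  }
  fit <- fit_dmi_model(tab, "regression")
  res <- fit$residuals[tab$id]
  for (col in c("adg1", "mmwt1")) {
    scale <- mean(abs(tab[[col]]))
    expect_lt(abs(sum(res * tab[[col]])), 1e-6 * n * scale)
  }
})

test_that("adding the backfat covariate never decreases R-squared", {
  tab <- default_summary()  # every animal has a backfat record
  fits <- compute_rfi_models(tab)
  expect_gte(fits$RFI_bf1$r_squared, fits$RFI_1$r_squared)
  expect_gte(fits$RFI_bf2$r_squared, fits$RFI_2$r_squared)
  expect_named(fits, c("RFI_1", "RFI_bf1", "RFI_2", "RFI_bf2"))
})

test_that("animals without backfat are dropped only from backfat models", {
  tab <- default_summary()
  tab$ubf_mm[1:10] <- NA
  expect_message(fits <- compute_rfi_models(tab), "10 animal")
  expect_equal(fits$RFI_1$n, nrow(tab))
  expect_equal(fits$RFI_bf1$n, nrow(tab) - 10)
  expect_equal(fits$RFI_bf1$n_dropped_ubf, 10L)
  expect_false(any(tab$id[1:10] %in% names(fits$RFI_bf1$residuals)))

  tab$ubf_mm <- NA_real_
  expect_message(fits2 <- compute_rfi_models(tab), "skipping")
  expect_named(fits2, c("RFI_1", "RFI_2"))
})

test_that("rank-deficient designs raise a singular-design error naming columns", {
  tab <- toy_summary()
  tab$adg1 <- 1.4  # constant, collinear with the intercept
  expect_error(fit_dmi_model(tab, "regression"), "singular design.*adg")
})

test_that("classification uses strict 1-SD thresholds within group", {
  # mean 0, SD exactly 1: -1 and 1 sit exactly on the boundaries -> medium
  cls <- classify_rfi(setNames(c(-1, 0, 1), c("a", "b", "c")))
  expect_true(all(cls$classes == "medium"))

  x <- setNames(c(-5, -0.2, 0, 0.2, 5), sprintf("h%d", 1:5))
  cls2 <- classify_rfi(x)
  m <- mean(x); s <- sd(x)
  expect_equal(unname(as.character(cls2$classes)),
               unname(ifelse(x > m + s, "high",
                             ifelse(x < m - s, "low", "medium"))))
  expect_equal(as.character(cls2$classes[["h5"]]), "high")
  expect_equal(as.character(cls2$classes[["h1"]]), "low")
})

test_that("a zero-SD group is classified entirely medium", {
  cls <- classify_rfi(setNames(rep(0.3, 4), sprintf("z%d", 1:4)))
  expect_true(all(cls$classes == "medium"))
})

test_that("classification is invariant to per-group constant shifts", {
  tab <- default_summary()
  fit <- fit_dmi_model(tab)
  cls <- classify_rfi(fit)
  shifted <- fit$residuals
  groups <- fit$groups
  for (g in unique(groups)) {
    shifted[groups == g] <- shifted[groups == g] + as.numeric(g) * 3.7
  }
  cls2 <- classify_rfi(shifted, groups)
  expect_identical(as.character(cls$classes), as.character(cls2$classes))
})

test_that("class summaries are plain arithmetic means with SEM", {
  tab <- toy_summary(6)
  cls <- classify_rfi(setNames(c(-2, -0.1, 0, 0.1, 0.2, 2.2), tab$id))
  cs <- class_summary(tab, cls)
  expect_equal(cs$table$class, c("low", "medium", "high"))
  med <- tab[cls$by$class == "medium", ]
  expect_equal(cs$table$mean_dmi_mean[2], mean(med$mean_dmi))
  expect_equal(cs$table$mean_dmi_sem[2], sd(med$mean_dmi) / sqrt(nrow(med)))
  expect_equal(cs$table$n, c(1L, 4L, 1L))
})

test_that("percent DMI excess of high over low matches hand arithmetic", {
  tab <- toy_summary(6)
  tab$mean_dmi <- c(8.27, 8.27, 9.61, 9.61, 11.01, 11.01)
  cls <- structure(list(
    classes = setNames(factor(c("low", "low", "medium", "medium",
                                "high", "high"),
                              levels = c("low", "medium", "high")), tab$id),
    by = data.frame(id = tab$id, group = "all", rfi = 0,
                    class = c("low", "low", "medium", "medium", "high", "high"),
                    stringsAsFactors = FALSE)
  ), class = "rfi_classification")
  cs <- class_summary(tab, cls)
  expect_equal(cs$pct_dmi_excess_high_vs_low, 33L)

  tab$mean_dmi <- 9.5
  expect_equal(class_summary(tab, cls)$pct_dmi_excess_high_vs_low, 0L)
})

test_that("rank-change tallies count off-diagonal transitions", {
  ids <- sprintf("x%03d", 1:176)
  a <- rep(c("low", "medium", "high"), c(29, 119, 28))
  b <- a
  b[1:9] <- "medium"                    # low -> medium (9)
  b[30:37] <- "low"                     # medium -> low (8)
  b[38:41] <- "high"                    # medium -> high (4)
  b[149:155] <- "medium"                # high -> medium (7)
  tal <- rank_change_tally(setNames(a, ids), setNames(b, ids))
  expect_equal(tal$total_changed, 28L)
  expect_equal(tal$matrix["low", "medium"], 9L)
  expect_equal(tal$matrix["medium", "low"], 8L)
  expect_equal(tal$matrix["medium", "high"], 4L)
  expect_equal(tal$matrix["high", "medium"], 7L)

  b2 <- a
  b2[149:150] <- "medium"               # high -> medium (2)
  b2[30:38] <- "high"                   # medium -> high (9)
  b2[1:7] <- "medium"                   # low -> medium (7)
  b2[40:45] <- "low"                    # medium -> low (6)
  expect_equal(rank_change_tally(setNames(a, ids),
                                 setNames(b2, ids))$total_changed, 24L)

  expect_equal(rank_change_tally(setNames(a, ids),
                                 setNames(a, ids))$total_changed, 0L)
  expect_error(rank_change_tally(setNames(a, ids),
                                 setNames(b[-1], ids[-1])), "only in a")
})

test_that("true efficiency residuals are recovered on the default cohort", {
  tr <- default_trial()
  tab <- default_summary()
  fit <- fit_dmi_model(tab, "regression")
  tv <- tr$true_values[match(names(fit$residuals), tr$true_values$id), ]
  expect_gte(cor(tv$true_rfi, fit$residuals), 0.80)
})
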