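test_that("pearson correlation matches hand computation and cor.test", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  # 3 / sqrt(2 * 14/3) by hand
  r <- pearson_r(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(r$r, 0.9820, tolerance = 5e-5)

  set.seed(5)
  x <- rnorm(25); y <- x + rnorm(25)
  ct <- cor.test(x, y)
  got <- pearson_r(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-10)

  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("spearman correlation uses midranks and matches the rank-then-pearson oracle", {
  x <- c(3, 1, 4, 1, 5, 9)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)                 # monotone map
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(10, 20, 20, 40))$rho, 1)

  y <- c(2, 7, 1, 8, 2, 8)
  got <- spearman_rho(x, y)
  oracle <- cor(rank(x), rank(y))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_equal(got$rho,
               unname(suppressWarnings(
                 cor.test(x, y, method = "spearman")$estimate)),
               tolerance = 1e-12)
})

test_that("kappa is 1 for identical ratings and matches hand arithmetic on a 2x2", {
  a <- rep(c("low", "medium", "high"), times = c(5, 8, 4))
  k <- cohen_kappa(a, a)
  expect_equal(k$kappa, 1)
  expect_equal(k$weighted_kappa, 1)

  # confusion [[45,5],[5,45]]: po = 0.90, pe = 0.50, kappa = 0.80
  a2 <- rep(c("low", "low", "high", "high"), times = c(45, 5, 5, 45))
  b2 <- rep(c("low", "high", "low", "high"), times = c(45, 5, 5, 45))
  k2 <- cohen_kappa(a2, b2, levels = c("low", "high"))
  expect_equal(k2$kappa, 0.80, tolerance = 1e-12)
  # with two categories the linear-weighted kappa equals the unweighted one
  expect_equal(k2$weighted_kappa, k2$kappa, tolerance = 1e-12)
  expect_equal(unclass(k2$confusion),
               matrix(c(45L, 5L, 5L, 45L), 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("kappa respects the invariances of its weighting scheme", {
  set.seed(8)
  lv <- c("low", "medium", "high")
  a <- sample(lv, 120, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  b <- ifelse(runif(120) < 0.6, a, sample(lv, 120, replace = TRUE))

  perm <- c(low = "medium", medium = "high", high = "low")  # arbitrary relabel
  k_orig <- cohen_kappa(a, b)
  k_perm <- cohen_kappa(perm[a], perm[b])
  expect_equal(k_perm$kappa, k_orig$kappa, tolerance = 1e-12)

  rev_map <- c(low = "high", medium = "medium", high = "low")  # order-reversing
  k_rev <- cohen_kappa(rev_map[a], rev_map[b])
  expect_equal(k_rev$weighted_kappa, k_orig$weighted_kappa, tolerance = 1e-12)
  expect_equal(k_rev$kappa, k_orig$kappa, tolerance = 1e-12)
})

test_that("independent ratings give kappa near zero", {
  set.seed(13)
  lv <- c("low", "medium", "high")
  a <- sample(lv, 10000, replace = TRUE)
  b <- sample(lv, 10000, replace = TRUE)
  k <- cohen_kappa(a, b)
  expect_lt(abs(k$kappa), 0.05)
  expect_lt(abs(k$weighted_kappa), 0.05)
  expect_gt(k$weighted_p_value, 1e-4)  # no real agreement to detect
})

test_that("asymptotic kappa SE matches a numeric delta-method oracle", {
  set.seed(21)
  lv <- c("low", "medium", "high")
  a <- sample(lv, 200, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  b <- ifelse(runif(200) < 0.5, a, sample(lv, 200, replace = TRUE))
  n <- length(a)
  counts <- table(factor(a, lv), factor(b, lv))
  p <- as.vector(counts) / n

  kappa_of <- function(pvec, W) {
    P <- matrix(pvec, 3, 3) / sum(pvec)
    po <- sum(W * P)
    pe <- sum(W * outer(rowSums(P), colSums(P)))
    (po - pe) / (1 - pe)
  }
  delta_se <- function(W) {
    g <- vapply(seq_along(p), function(i) {
      h <- 1e-6
      pp <- p; pp[i] <- pp[i] + h
      pm <- p; pm[i] <- max(pm[i] - h, 0)
      (kappa_of(pp, W) - kappa_of(pm, W)) / (pp[i] - pm[i])
    }, numeric(1))
    sqrt((sum(p * g^2) - sum(p * g)^2) / n)
  }

  got <- cohen_kappa(a, b, weighting = "linear")
  W_id <- diag(3)
  W_lin <- 1 - abs(outer(1:3, 1:3, `-`)) / 2
  expect_equal(got$se, delta_se(W_id), tolerance = 1e-4)
  expect_equal(got$weighted_se, delta_se(W_lin), tolerance = 1e-4)
})

test_that("the null-hypothesis kappa SE matches Monte-Carlo spread under independence", {
  set.seed(33)
  lv <- c("low", "medium", "high")
  n <- 400
  sims <- replicate(400, {
    a <- sample(lv, n, replace = TRUE, prob = c(0.2, 0.55, 0.25))
    b <- sample(lv, n, replace = TRUE, prob = c(0.2, 0.55, 0.25))
    k <- cohen_kappa(a, b)
    c(k$weighted_kappa, k$weighted_kappa / qnorm(1 - k$weighted_p_value / 2))
  })
  se0_implied <- abs(sims[2, ])
  ratio <- sd(sims[1, ]) / mean(se0_implied)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("degenerate identical constant ratings are rejected", {
  expect_error(cohen_kappa(rep("medium", 10), rep("medium", 10)),
               "degenerate agreement")
  expect_error(cohen_kappa(c("low", "mid"), c("low", "low")), "category set")
})

test_that("kappa bands follow the published interpretation cut-offs", {
  expect_equal(interpret_kappa(0.84), "high")
  expect_equal(interpret_kappa(0.76), "high")
  expect_equal(interpret_kappa(0.75), "fair-good")
  expect_equal(interpret_kappa(0.40), "fair-good")
  expect_equal(interpret_kappa(0.39), "low")
  expect_equal(interpret_kappa(-0.2), "low")
  expect_error(interpret_kappa(1.2), "<= 1")
})

test_that("pair regression reports slope equivalence against the identity line", {
  x <- c(1.2, 1.5, 1.7, 2.0, 2.3, 2.6, 2.8, 3.1, 3.3, 3.6)
  same <- suppressWarnings(regress_pair(x, x))
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$r_squared, 1, tolerance = 1e-12)
  expect_true(same$slope_ci_contains_1)

  doubled <- suppressWarnings(regress_pair(x, 2 * x))
  expect_equal(doubled$slope, 2, tolerance = 1e-12)
  expect_false(doubled$slope_ci_contains_1)

  set.seed(14)
  y <- 0.4 + 0.95 * x + rnorm(10, 0, 0.1)
  got <- regress_pair(x, y)
  oracle <- ols_oracle(cbind(1, x), y)
  expect_equal(got$slope, oracle$beta[2], tolerance = 1e-8)
  expect_equal(got$se, unname(oracle$se[2]), tolerance = 1e-8)
  tq <- qt(0.975, oracle$df)
  expect_equal(got$ci,
               c(oracle$beta[2] - tq * oracle$se[2],
                 oracle$beta[2] + tq * oracle$se[2]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(regress_pair(rep(1, 5), 1:5), "undefined slope")
})
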