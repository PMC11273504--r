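# Correlation, regression-equivalence, and chance-corrected agreement
# statistics for comparing RFI models and test durations.

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("undefined correlation: x is constant")
  if (stats::sd(y) == 0) stop("undefined correlation: y is constant")
  list(x = x, y = y)
}

cor_t_test <- function(r, n) {
  # two-sided p for H0: rho = 0 via the t approximation
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Pearson product-moment correlation with a two-sided test
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs,
#'   neither constant).
#' @return List with `r`, `p` (t approximation for H0: r = 0), and `n`.
#' @export
pearson_r <- function(x, y) {
  d <- check_cor_input(x, y)
  x <- d$x; y <- d$y
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  list(r = r, p = cor_t_test(r, length(x)), n = length(x))
}

#' Spearman rank correlation with midranks for ties
#'
#' The Pearson correlation of the average ranks of `x` and `y`; the
#' p-value uses the same t approximation as [pearson_r()].
#'
#' @inheritParams pearson_r
#' @return List with `rho`, `p`, and `n`.
#' @export
spearman_rho <- function(x, y) {
  d <- check_cor_input(x, y)
  r <- pearson_r(rank(d$x, ties.method = "average"),
                 rank(d$y, ties.method = "average"))
  list(rho = r$r, p = r$p, n = r$n)
}

kappa_weights <- function(C, weighting) {
  i <- matrix(seq_len(C), C, C)
  j <- t(i)
  switch(weighting,
         none = diag(C) * 1,
         linear = 1 - abs(i - j) / (C - 1),
         quadratic = 1 - ((i - j) / (C - 1))^2,
         stop("unknown weighting: ", weighting))
}

kappa_from_props <- function(P, W) {
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  po <- sum(W * P)
  pc <- sum(W * outer(pi_, pj_))
  (po - pc) / (1 - pc)
}

# Asymptotic variance of weighted kappa (Fleiss, Cohen & Everitt 1969).
# With identity weights this reduces to the standard unweighted form.
# `null` selects the H0: kappa = 0 variance used for the z test.
kappa_var <- function(P, W, n, null = FALSE) {
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  pc <- sum(W * outer(pi_, pj_))
  wbar_i <- as.vector(W %*% pj_)   # row expectation: sum_j p.j w_ij
  wbar_j <- as.vector(pi_ %*% W)   # col expectation: sum_i pi. w_ij
  if (null) {
    term <- outer(wbar_i, wbar_j, `+`)
    (sum(outer(pi_, pj_) * (W - term)^2) - pc^2) / (n * (1 - pc)^2)
  } else {
    k <- kappa_from_props(P, W)
    po <- sum(W * P)
    term <- outer(wbar_i, wbar_j, `+`) * (1 - k)
    (sum(P * (W - term)^2) - (k - pc * (1 - k))^2) / (n * (1 - pc)^2)
  }
}

#' Cohen's kappa and weighted kappa for ordered efficiency classes
#'
#' Chance-corrected agreement between two classifications over the
#' ordered categories low < medium < high. Both the unweighted kappa and
#' a weighted kappa are reported; linear (Cicchetti-Allen) weights
#' `w_ij = 1 - |i - j| / (C - 1)` give partial credit for near-miss
#' disagreements, with quadratic weights available as an option.
#'
#' Standard errors use the asymptotic (Fleiss-Cohen-Everitt) variance;
#' the 95% CI is `kappa +/- 1.96 * SE`, and the p-value tests
#' H0: kappa = 0 with a z statistic using the null-hypothesis SE.
#'
#' @param a,b Label vectors of equal length (>= 2) over `levels`.
#' @param weighting `"linear"` (default), `"quadratic"`, or `"none"`
#'   (the weighted results then equal the unweighted ones).
#' @param levels Ordered category set; the confusion matrix always uses
#'   this order.
#' @param conf_level Confidence level for the CIs.
#' @return An object of class `kappa_result`: `kappa`, `se`, `ci`,
#'   `p_value`, `interpretation` and the `weighted_*` counterparts, plus
#'   the `confusion` matrix, `n`, and `weighting`.
#' @export
cohen_kappa <- function(a, b, weighting = c("linear", "quadratic", "none"),
                        levels = c("low", "medium", "high"),
                        conf_level = 0.95) {
  weighting <- match.arg(weighting)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need at least 2 rated items")
  a <- factor(as.character(a), levels = levels)
  b <- factor(as.character(b), levels = levels)
  if (anyNA(a) || anyNA(b)) stop("labels outside the declared category set")
  n <- length(a)
  counts <- table(a, b)
  P <- counts / n
  C <- length(levels)

  one_kappa <- function(W) {
    pc <- sum(W * outer(rowSums(P), colSums(P)))
    if (1 - pc < .Machine$double.eps) {
      stop("degenerate agreement: both classifications are constant and identical; kappa undefined")
    }
    k <- kappa_from_props(P, W)
    se <- sqrt(max(kappa_var(P, W, n), 0))
    se0 <- sqrt(max(kappa_var(P, W, n, null = TRUE), 0))
    z <- if (se0 > 0) k / se0 else Inf * sign(k)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    list(kappa = k, se = se, ci = c(k - q * se, k + q * se),
         z = z, p = 2 * stats::pnorm(-abs(z)))
  }

  unw <- one_kappa(kappa_weights(C, "none"))
  wgt <- one_kappa(kappa_weights(C, weighting))

  structure(list(
    kappa = unw$kappa, se = unw$se, ci = unw$ci, p_value = unw$p,
    interpretation = interpret_kappa(unw$kappa),
    weighted_kappa = wgt$kappa, weighted_se = wgt$se, weighted_ci = wgt$ci,
    weighted_p_value = wgt$p,
    weighted_interpretation = interpret_kappa(wgt$kappa),
    confusion = unclass(counts), n = n, weighting = weighting
  ), class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (SE %.3f, 95%% CI %.3f-%.3f) -- %s agreement\n",
              x$kappa, x$se, x$ci[1], x$ci[2], x$interpretation))
  cat(sprintf("Weighted kappa (%s): %.3f (SE %.3f, 95%% CI %.3f-%.3f), p = %.2g\n",
              x$weighting, x$weighted_kappa, x$weighted_se,
              x$weighted_ci[1], x$weighted_ci[2], x$weighted_p_value))
  invisible(x)
}

#' Interpret a kappa coefficient as an agreement band
#'
#' Below 0.4: low agreement beyond chance; 0.40 to 0.75 (inclusive):
#' fair-to-good; above 0.75: high.
#'
#' @param kappa A kappa value (<= 1).
#' @return `"low"`, `"fair-good"`, or `"high"`.
#' @export
interpret_kappa <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa > 1) {
    stop("kappa must be a single number <= 1")
  }
  if (kappa < 0.4) "low" else if (kappa <= 0.75) "fair-good" else "high"
}

#' Simple regression of y on x with a slope-equivalence flag
#'
#' Ordinary least squares of `y` on `x` reporting the slope, its standard
#' error, R-squared, and the t-based confidence interval, plus a flag for
#' whether the interval contains 1 (the two measures interchangeable on
#' the identity line).
#'
#' @param x,y Numeric vectors, n >= 3, `x` non-constant.
#' @param conf_level Confidence level for the slope CI.
#' @return List with `slope`, `se`, `r_squared`, `intercept`, `ci`,
#'   `p_value` (slope = 0), `slope_ci_contains_1`, `n`.
#' @export
regress_pair <- function(x, y, conf_level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("undefined slope: x is constant")
  m <- stats::lm(y ~ x)
  sm <- summary(m)
  ci <- stats::confint(m, "x", level = conf_level)
  list(
    slope = unname(stats::coef(m)["x"]),
    se = sm$coefficients["x", "Std. Error"],
    r_squared = sm$r.squared,
    intercept = unname(stats::coef(m)["(Intercept)"]),
    ci = as.numeric(ci),
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    slope_ci_contains_1 = ci[1] <= 1 && 1 <= ci[2],
    n = length(x)
  )
}
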