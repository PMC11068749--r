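#' Shapiro-Wilk normality gate
#'
#' Thin wrapper around [stats::shapiro.test()] with the pipeline's input
#' checks. In the cohort analysis this test only gates the choice of
#' nonparametric comparisons: volume-change distributions are typically
#' skewed, which is why the group tests below are rank-based.
#'
#' @param sample numeric vector, 3 <= n <= 5000, not all equal.
#' @return A list with elements `W` and `p`.
#' @export
shapiro_wilk <- function(sample) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  if (diff(range(sample)) == 0)
    stop("Shapiro-Wilk is undefined for a constant sample", call. = FALSE)
  ht <- stats::shapiro.test(sample)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Mann-Whitney U test (exact enumeration or tie-corrected approximation)
#'
#' Two-sided comparison of two independent samples by the Mann-Whitney U
#' statistic computed from mid-ranks. In `"exact"` mode the p-value is the
#' permutation probability over all `choose(n1 + n2, n1)` group labelings of
#' the pooled sample (valid with ties, where the classical exact tables are
#' not); in `"normal"` mode the tie-corrected normal approximation with
#' continuity correction is used. `"auto"` switches to exact when
#' `n1 + n2 <= 12`.
#'
#' @param x,y nonempty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A `cv_comparison` object (see [tidy.cv_comparison()]): group
#'   labels/sizes, per-group mean and SD, test name, the U statistic of the
#'   first group, the two-sided p-value and the significance flag at 0.05.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty", call. = FALSE)
  if (mode == "auto") mode <- if (n1 + n2 <= 12) "exact" else "normal"

  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (mode == "exact") {
    combos <- utils::combn(n1 + n2, n1)
    r1 <- n1 * (n1 + 1) / 2
    us <- colSums(matrix(r[combos], nrow = n1)) - r1
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    test <- "Mann-Whitney U (exact enumeration)"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0)
      stop("all observations identical: U test undefined", call. = FALSE)
    cc <- sign(u_obs - mu) * 0.5  # continuity correction toward the mean
    z <- (u_obs - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    test <- "Mann-Whitney U (tie-corrected normal approximation)"
  }
  new_comparison(
    groups = c("x", "y"), n = c(n1, n2),
    mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
    test = test, statistic = u_obs, p = p
  )
}

#' Kruskal-Wallis rank-sum test
#'
#' k-group nonparametric comparison: the tie-corrected H statistic referred
#' to a chi-square with k - 1 degrees of freedom, computed by
#' [stats::kruskal.test()]. All observations identical is an error (H is
#' undefined after tie correction).
#'
#' @param groups list of (>= 2) nonempty numeric vectors.
#' @return A `cv_comparison` object.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0)) stop("all groups must be nonempty", call. = FALSE)
  pooled <- unlist(groups)
  if (diff(range(pooled)) == 0)
    stop("all observations identical: H is undefined after tie correction",
         call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(pooled, g)
  labs <- names(groups) %||% paste0("g", seq_along(groups))
  new_comparison(
    groups = labs, n = lengths(groups),
    mean = vapply(groups, mean, 0), sd = vapply(groups, stats::sd, 0),
    test = "Kruskal-Wallis (tie-corrected H, chi-square reference)",
    statistic = unname(ht$statistic), p = ht$p.value
  )
}

#' Spearman rank correlation
#'
#' Tie-safe Spearman correlation: the Pearson correlation of mid-ranks, with
#' the p-value from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3 complete pairs, neither constant.
#' @return A list with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("Spearman correlation requires n >= 3 pairs", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("Spearman correlation is undefined for a constant variable", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Multiple linear regression (ordinary least squares)
#'
#' Least-squares fit with intercept via [stats::lm()], with an explicit
#' full-rank check that names the collinear columns.
#'
#' @param response numeric vector.
#' @param covariates data frame or matrix of numeric covariates,
#'   `n > ncol + 1`.
#' @return A list with `coefficients` (a tibble: term, estimate, std.error,
#'   statistic, p.value), `r_squared`, `adj_r_squared` and the underlying
#'   `lm` fit.
#' @export
ols_regression <- function(response, covariates) {
  covariates <- as.data.frame(covariates)
  n <- length(response)
  if (n != nrow(covariates))
    stop("response and covariates must have the same length", call. = FALSE)
  if (n <= ncol(covariates) + 1)
    stop("need n > number of covariates + 1", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- cbind(.response = response, covariates)
  fit <- stats::lm(.response ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  list(
    coefficients = tibble::tibble(
      term = rownames(co), estimate = unname(co[, 1]),
      std.error = unname(co[, 2]), statistic = unname(co[, 3]),
      p.value = unname(co[, 4])
    ),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    fit = fit
  )
}

new_comparison <- function(groups, n, mean, sd, test, statistic, p) {
  structure(
    list(groups = groups, n = as.integer(n), mean = mean, sd = sd,
         test = test, statistic = statistic, p = p,
         significant = p < 0.05),
    class = "cv_comparison"
  )
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat("<cv_comparison> ", x$test, "\n", sep = "")
  for (i in seq_along(x$groups))
    cat("  ", x$groups[i], " (n = ", x$n[i], "): ",
        signif(x$mean[i], 6), " +/- ", signif(x$sd[i], 6), "\n", sep = "")
  cat("  statistic = ", signif(x$statistic, 6), ", p = ", signif(x$p, 4),
      if (x$significant) "  (significant at 0.05)" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy a group comparison
#'
#' One row per group with the shared test statistic and p-value, in the
#' broom style.
#'
#' @param x a `cv_comparison`.
#' @param ... unused.
#' @export
tidy.cv_comparison <- function(x, ...) {
  tibble::tibble(
    group = x$groups, n = x$n, mean = x$mean, sd = x$sd,
    test = x$test, statistic = x$statistic, p.value = x$p,
    significant = x$significant
  )
}

#' @export
#' @importFrom generics tidy
generics::tidy
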