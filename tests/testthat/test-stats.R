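test_that("exact Mann-Whitney matches direct enumeration of small cases", {
  # hand case: complete separation of {1,2} vs {3,4}
  got <- mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(got$statistic, 0)
  expect_equal(got$p, 2 / 6, tolerance = 1e-12)
  # identical samples: perfect symmetry
  expect_equal(mann_whitney_u(c(3, 1, 2), c(3, 1, 2), mode = "exact")$p, 1)
  # tie-free cases agree with wilcox.test's exact p
  set.seed(33)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(100, n1); y <- sample(1000, n2) / 3
    got <- mann_whitney_u(x, y, mode = "exact")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$statistic, unname(ref$statistic))
  }
  # with ties: against an independent permutation-sampling oracle
  set.seed(34)
  for (i in 1:5) {
    x <- sample(4, 5, replace = TRUE)
    y <- sample(4, 6, replace = TRUE)
    got <- mann_whitney_u(x, y, mode = "exact")
    pooled <- c(x, y)
    mu <- length(x) * length(y) / 2
    r <- rank(pooled)
    u_obs <- sum(r[1:5]) - 15
    sim <- replicate(20000, {
      pick <- sample(11, 5)
      sum(rank(pooled)[pick]) - 15
    })
    p_mc <- mean(abs(sim - mu) >= abs(u_obs - mu) - 1e-9)
    expect_equal(got$p, p_mc, tolerance = 0.02)
  }
})

test_that("the normal approximation tracks the exact p and wilcox.test", {
  set.seed(35)
  for (i in 1:10) {
    x <- rnorm(sample(4:6, 1)); y <- rnorm(sample(4:6, 1), 0.5)
    pe <- mann_whitney_u(x, y, mode = "exact")$p
    pa <- mann_whitney_u(x, y, mode = "normal")$p
    expect_lt(abs(pe - pa), 0.05)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(pa, ref$p.value, tolerance = 1e-10)
  }
  # tie-corrected approximation matches wilcox.test with ties
  x <- c(1, 2, 2, 3, 5, 5, 7); y <- c(2, 3, 3, 4, 5, 8)
  expect_equal(mann_whitney_u(x, y, mode = "normal")$p,
               suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value),
               tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Kruskal-Wallis reproduces the closed-form rank computation", {
  got <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # ranks 1..6 without ties: H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7
  expect_equal(got$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-9)
  expect_equal(got$statistic, 3.857, tolerance = 1e-3)
  # a group of identical values runs, ties handled
  expect_silent(kruskal_wallis(list(c(2, 2, 2), c(1, 3, 4), c(5, 5, 6))))
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_error(kruskal_wallis(list(1:3)), "length")
})

test_that("Kruskal-Wallis with two groups orders like the Mann-Whitney U", {
  set.seed(36)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(7, runif(1, 0, 2))
    kw <- kruskal_wallis(list(x, y))
    mw <- mann_whitney_u(x, y, mode = "normal")
    # tie-free: H is a monotone function of |U - mu|, so p-values order
    # identically up to the continuity correction
    expect_lt(abs(pchisq(kw$statistic, 1, lower.tail = FALSE) - mw$p), 0.05)
  }
})

test_that("Spearman rho equals the mid-rank Pearson oracle", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^2)$rho, -1)
  set.seed(37)
  for (i in 1:10) {
    x <- sample(5, 12, replace = TRUE)   # heavy ties
    y <- sample(6, 12, replace = TRUE) + 0.1 * x
    got <- spearman_cor(x, y)
    rx <- rank(x); ry <- rank(y)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(got$rho, oracle, tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), "n >= 3")
})

test_that("Shapiro-Wilk gate behaves as a normality test", {
  set.seed(38)
  # skewed alternative: rejected in at least 95% of replicates
  rej <- mean(replicate(200, shapiro_wilk(rexp(50))$p < 0.05))
  expect_gte(rej, 0.95)
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "n")
  w <- shapiro_wilk(rnorm(30))
  expect_true(w$W > 0 && w$W <= 1)
})

test_that("OLS regression matches the normal-equations solution", {
  got <- ols_regression(2 * (1:10) + 1, data.frame(x = 1:10))
  expect_equal(got$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(got$r_squared, 1)
  # intercept-only: coefficient is the sample mean
  y <- c(4, 8, 15, 16, 23, 42)
  got0 <- ols_regression(y, data.frame()[seq_along(y), , drop = FALSE])
  expect_equal(got0$coefficients$estimate, mean(y))
  # random design against an independently solved normal-equations system
  set.seed(39)
  X <- data.frame(a = rnorm(25), b = rnorm(25), c = rnorm(25))
  yy <- rnorm(25)
  got2 <- ols_regression(yy, X)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% yy)
  expect_equal(got2$coefficients$estimate, as.numeric(beta), tolerance = 1e-9)
  # rank-deficient design names the collinear column
  X$d <- X$a + X$b
  expect_error(ols_regression(yy, X), "d")
})

test_that("comparison objects tidy into one-row-per-group tibbles", {
  cmp <- mann_whitney_u(rnorm(10), rnorm(12, 1))
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(td$n, c(10L, 12L))
  expect_equal(unique(td$significant), cmp$p < 0.05)
})
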