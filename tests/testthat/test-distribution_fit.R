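test_that("hyperbolic regression recovers a noiseless curve exactly", {
  x <- seq(50, 1000, by = 50)
  y <- 6.05937 + 651.62 / x
  fit <- fit_hyperbolic(x, y)
  expect_equal(fit$a, 6.05937, tolerance = 1e-6)
  expect_equal(fit$b, 651.62, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("hyperbolic regression handles degenerate responses", {
  x <- c(100, 200, 300, 400)
  fit <- fit_hyperbolic(x, rep(7, 4))
  expect_equal(fit$b, 0)
  expect_equal(fit$r_squared, 0)
  expect_error(fit_hyperbolic(rep(100, 4), c(1, 2, 3, 4)),
               "rank-deficient")
  expect_error(fit_hyperbolic(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_error(fit_hyperbolic(c(1, 2), c(1, 2)), "at least 3")
})

test_that("hyperbolic coefficients equal the normal-equation solution", {
  set.seed(137)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    x <- sample(50:900, n, replace = TRUE)
    y <- 8 + 1500 / x + rnorm(n, sd = 2)
    fit <- fit_hyperbolic(x, y)
    X <- cbind(1, 1 / x)
    ab <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(c(fit$a, fit$b), as.numeric(ab), tolerance = 1e-8)
    # residuals orthogonal to the design
    expect_lt(max(abs(t(X) %*% fit$residuals)), 1e-8 * max(abs(y)) * n)
  }
})

test_that("the kernel density surface integrates to one", {
  set.seed(139)
  x <- rlnorm(300, log(400), 0.5)
  y <- pmin(100, pmax(0, rnorm(300, 10, 5)))
  k <- kde2d_surface(x, y, n = 128L)
  dx <- diff(k$x[1:2]); dy <- diff(k$y[1:2])
  expect_equal(sum(k$z) * dx * dy, 1, tolerance = 0.01)
  expect_true(all(k$z >= 0))
})

test_that("density values match a direct double-loop kernel sum", {
  set.seed(149)
  x <- rnorm(40, 0, 2); y <- rnorm(40, 5, 1)
  h <- c(0.8, 0.5)
  k <- kde2d_surface(x, y, bandwidths = h, n = 50L)
  idx <- cbind(sample(50, 10, replace = TRUE),
               sample(50, 10, replace = TRUE))
  for (r in 1:10) {
    gx <- k$x[idx[r, 1]]; gy <- k$y[idx[r, 2]]
    oracle <- mean(dnorm(gx, x, h[1]) * dnorm(gy, y, h[2]))
    expect_equal(k$z[idx[r, 1], idx[r, 2]], oracle, tolerance = 1e-10)
  }
})

test_that("kde peaks at duplicated points and rejects flat dimensions", {
  k <- kde2d_surface(c(2, 2), c(3, 3), bandwidths = c(0.5, 0.5),
                     n = 41L, lims = c(0, 4, 1, 5))
  peak <- which(k$z == max(k$z), arr.ind = TRUE)
  expect_equal(k$x[peak[1]], 2, tolerance = 0.11)
  expect_equal(k$y[peak[2]], 3, tolerance = 0.11)
  expect_error(kde2d_surface(c(1, 1, 1), c(1, 2, 3)), "bandwidth")
})

test_that("the Welch test matches the hand-computed formula", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  res <- welch_ttest(a, b)
  se <- sqrt(var(a) / 5 + var(b) / 5)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(res$t_statistic, t_hand)
  expect_equal(res$degrees_of_freedom, df_hand)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand))
  # identical non-constant groups: no difference
  same <- welch_ttest(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("the Welch test is symmetric and guards degenerate input", {
  set.seed(151)
  a <- rnorm(12); b <- rnorm(9, 1)
  r1 <- welch_ttest(a, b); r2 <- welch_ttest(b, a)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$t_statistic, -r2$t_statistic)
  expect_error(welch_ttest(c(3, 3), c(3, 3)), "identical constants")
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
  pooled <- welch_ttest(a, b, pooled = TRUE)
  oracle <- t.test(a, b, var.equal = TRUE)
  expect_equal(pooled$t_statistic, unname(oracle$statistic))
  expect_equal(pooled$degrees_of_freedom, unname(oracle$parameter))
})

test_that("discrete summaries match a sort-based recomputation", {
  s <- discrete_summary(8.36)
  expect_equal(unlist(s), c(minimum = 8.36, maximum = 8.36, mean = 8.36,
                            median = 8.36, mode = 8.36))
  s2 <- discrete_summary(c(1, 2, 3, 4))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$median, 2.5)
  s3 <- discrete_summary(c(1.2, 1.3, 5.7))
  expect_equal(s3$mode, 1.5)   # most populated unit bin is [1, 2)
  set.seed(157)
  for (rep in 1:50) {
    v <- runif(sample(2:60, 1), 0, 40)
    s <- discrete_summary(v)
    sv <- sort(v)
    expect_equal(s$minimum, sv[1])
    expect_equal(s$maximum, sv[length(sv)])
    expect_equal(s$mean, sum(v) / length(v))
    expect_equal(s$median, median(sv))
    expect_true(s$minimum <= s$median && s$median <= s$maximum)
    expect_true(s$mean >= s$minimum && s$mean <= s$maximum)
  }
})
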