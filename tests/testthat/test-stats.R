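# Direct-formula oracles, written from the textbook definitions and kept
# independent of the package implementation.
oracle_pearson <- function(x, y, conf = 0.95) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- 0.5 * log((1 + r) / (1 - r))
  q <- qnorm(1 - (1 - conf) / 2)
  lo <- z - q / sqrt(n - 3); hi <- z + q / sqrt(n - 3)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ci_low = (exp(2 * lo) - 1) / (exp(2 * lo) + 1),
       ci_high = (exp(2 * hi) - 1) / (exp(2 * hi) + 1),
       p = 2 * pt(-abs(tt), n - 2))
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1); vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  sp <- sqrt(((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       d = (mean(x) - mean(y)) / sp)
}

test_that("pearson_ci matches perfect, orthogonal and fixture cases", {
  x <- 1:20
  expect_equal(pearson_ci(x, 2 * x + 1)$r, 1)

  xo <- c(-2, -1, 0, 1, 2)
  yo <- c(1, -2, 0, -2, 1) # orthogonal to xo after centering
  expect_equal(pearson_ci(xo, yo)$r, 0)

  fx <- c(3.1, 4.7, 2.8, 5.9, 4.2, 3.3, 6.1, 2.2, 4.9, 5.5,
          3.8, 4.1, 2.6, 5.2, 4.4, 3.6, 5.8, 2.9, 4.6, 5.1)
  fy <- c(2.4, 5.1, 3.0, 6.2, 3.9, 2.8, 5.7, 2.5, 5.3, 4.8,
          4.2, 3.7, 2.1, 5.6, 4.0, 3.1, 6.0, 3.4, 4.3, 5.0)
  got <- pearson_ci(fx, fy)
  want <- oracle_pearson(fx, fy)
  expect_equal(got$r, want$r, tolerance = 1e-10)
  expect_equal(got$ci_low, want$ci_low, tolerance = 1e-10)
  expect_equal(got$ci_high, want$ci_high, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$n, 20L)

  # cross-check against the standard library implementation
  ct <- cor.test(fx, fy)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)

  # pairwise-complete deletion
  fx2 <- c(fx, NA); fy2 <- c(fy, 4)
  expect_equal(pearson_ci(fx2, fy2)$n, 20L)

  expect_error(pearson_ci(c(1, 1, 1, 1), 1:4), "zero variance")
  expect_error(pearson_ci(1:3, 3:1), "at least 4")
})

test_that("welch_t matches the null case, antisymmetry, and the formula oracle", {
  x <- c(1, 2, 3, 4)
  w0 <- welch_t(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$d, 0)

  gx <- c(4.1, 5.3, 3.8, 6.2, 4.9, 5.5, 4.4, 5.8, 3.5, 5.0)
  gy <- c(3.2, 4.0, 2.9, 4.8, 3.6, 4.3, 3.1, 4.5, 2.7, 3.9)
  got <- welch_t(gx, gy)
  want <- oracle_welch(gx, gy)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$d, want$d, tolerance = 1e-10)

  sw <- welch_t(gy, gx)
  expect_equal(sw$t, -got$t)
  expect_equal(sw$d, -got$d)
  expect_equal(sw$p, got$p)

  # t is invariant under a common rescaling of both groups
  expect_equal(welch_t(2 * gx, 2 * gy)$t, got$t)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(2, 2), c(3, 3)), "zero variance")
})

test_that("fisher-z intervals achieve nominal coverage under the null", {
  set.seed(1234)
  n <- 30
  covered <- vapply(1:2000, function(i) {
    x <- rnorm(n); y <- rnorm(n)
    ci <- pearson_ci(x, y)
    ci$ci_low <= 0 && 0 <= ci$ci_high
  }, TRUE)
  expect_equal(mean(covered), 0.95, tolerance = 0.021)
})

test_that("the correlation matrix is pairwise, symmetric and starred", {
  set.seed(9)
  df <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  df$b[1:5] <- NA
  df$d <- df$a * 0.8 + rnorm(60, 0, 0.3)
  cm <- correlation_matrix(df, c("a", "b", "c", "d"))
  expect_equal(cm$r["a", "b"], cm$r["b", "a"])
  expect_equal(cm$n["a", "b"], 55)    # pairwise-complete, not listwise
  expect_equal(cm$n["a", "c"], 60)
  expect_equal(cm$r["a", "d"], pearson_ci(df$a, df$d)$r)
  expect_true(cm$stars["a", "d"] %in% c("*", "**", "***"))

  # constant variable: cells unavailable, matrix still returned
  df$k <- 1
  cmk <- correlation_matrix(df, c("a", "k"))
  expect_true(is.na(cmk$r["a", "k"]))

  # reordering variables permutes, not changes, the cells
  cm2 <- correlation_matrix(df, c("d", "a", "b", "c"))
  expect_equal(cm2$r["a", "d"], cm$r["a", "d"])
})

test_that("independent simulated variables show near-zero correlation at large n", {
  set.seed(11)
  df <- data.frame(u = rnorm(10000), v = rnorm(10000))
  cm <- correlation_matrix(df, c("u", "v"))
  expect_lt(abs(cm$r["u", "v"]), 0.05)
})

test_that("moderated regression recovers planted main and interaction effects", {
  set.seed(55)
  n <- 2000
  x <- rnorm(n); m <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  fit <- moderated_regression(y, x, m)
  inter <- fit$coefficients[fit$coefficients$term == "x:m", ]
  expect_lt(abs(inter$beta), 0.06)
  expect_true(inter$ci_low <= 0 && 0 <= inter$ci_high)
  main <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_equal(main$beta, 0.5 / sd(y), tolerance = 0.1)

  y2 <- 0.4 * x + 0.2 * m + 0.3 * x * m + rnorm(n)
  fit2 <- moderated_regression(y2, x, m)
  inter2 <- fit2$coefficients[fit2$coefficients$term == "x:m", ]
  expect_lt(inter2$p, 0.05)

  # swapping predictor and moderator leaves the interaction unchanged
  fit3 <- moderated_regression(y2, m, x)
  inter3 <- fit3$coefficients[fit3$coefficients$term == "x:m", ]
  expect_equal(inter3$beta, inter2$beta, tolerance = 1e-12)

  expect_error(moderated_regression(y[1:4], x[1:4], m[1:4]), "n > 4")
  expect_error(moderated_regression(y, x, rep(1, n)), "zero-variance")
})
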