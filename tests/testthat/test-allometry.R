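# Allometric fits, power screening, Wilcoxon comparisons, agreement stats.

test_that("linear fit is exact on a noiseless line and matches normal equations", {
  x <- c(0.1, 0.4, 0.9, 1.4, 2.2, 3.1, 4.0, 5.5, 6.1, 7.7)
  y <- 2 * x + 1
  f <- suppressWarnings(fit_linear(x, y))
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$rmse_g, 0, tolerance = 1e-10)
  expect_equal(f$slope, 2, tolerance = 1e-12)

  set.seed(71)
  y2 <- 3 * x - 2 + rnorm(10)
  f2 <- fit_linear(x, y2)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y2 - mean(y2))) / sxx   # normal equations
  a <- mean(y2) - b * mean(x)
  expect_equal(f2$slope, b, tolerance = 1e-10)
  expect_equal(f2$intercept, a, tolerance = 1e-10)
  expect_equal(f2$r_squared, cor(x, y2)^2, tolerance = 1e-10)

  expect_error(fit_linear(rep(1, 5), 1:5), "variance")
  expect_error(fit_linear(1:5, rep(2, 5)), "variance")
})

test_that("log-log fit recovers exact power laws and degrades with outliers", {
  set.seed(72)
  v <- rlnorm(50, log(1e-3), 0.7)
  b <- 850 * (v / 1e-3)^1.42
  f <- suppressWarnings(fit_log(v, b))
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$slope, 1.42, tolerance = 1e-9)
  expect_lt(f$rmse_g, 1e-6)

  b_out <- b
  b_out[25] <- b_out[25] * 10
  expect_lt(fit_log(v, b_out)$r_squared, 1 - 1e-6)

  expect_error(fit_log(c(v[-1], 0), b), "positive")
})

test_that("log-model exponent is recovered under multiplicative noise", {
  # cohort-scale simulation with a known generator
  hits <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    v <- rlnorm(288, log(1e-3), 0.8)
    b <- 800 * (v / 1e-3)^1.0 * rlnorm(288, 0, 0.5)
    f <- fit_log(v, b)
    if (abs(f$slope - 1.0) <= 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("power screening follows the noncentral-F quadrature oracle", {
  r <- suppressWarnings(fit_linear(1:10, 2 * (1:10)))
  r$r_squared <- 0.5
  expect_equal(power_screen(r)$f_squared, 1.0)

  r$r_squared <- 0.30
  r$n <- 288L
  scr <- power_screen(r)
  f2 <- 0.3 / 0.7
  crit <- qf(0.95, 1, 286)
  oracle <- integrate(function(q) df(q, 1, 286, ncp = f2 * 288),
                      crit, Inf, rel.tol = 1e-10)$value
  expect_equal(scr$achieved_power, oracle, tolerance = 1e-6)
  expect_true(scr$significant)

  r$r_squared <- 0
  expect_equal(power_screen(r)$achieved_power, 0.05, tolerance = 1e-6)
})

test_that("power is monotone in both R^2 and n", {
  base <- suppressWarnings(fit_linear(1:10, 2 * (1:10)))
  pow <- function(r2, n) {
    base$r_squared <- r2; base$n <- n
    power_screen(base)$achieved_power
  }
  r2s <- seq(0.05, 0.6, by = 0.05)
  expect_false(is.unsorted(vapply(r2s, pow, numeric(1), n = 50)))
  ns <- c(10, 20, 50, 100, 288)
  expect_false(is.unsorted(vapply(ns, function(n) pow(0.2, n), numeric(1))))
})

test_that("exact signed-rank p equals full sign-assignment enumeration", {
  a <- as.numeric(1:8)
  b <- a + 1
  got <- wilcoxon_signed_exact(b, a, alternative = "greater")
  expect_equal(got$p_value, 1 / 2^8)

  # oracle: enumerate all 2^8 sign assignments on the (tied) midranks
  set.seed(73)
  d <- rnorm(8)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  v_all <- signs %*% r
  p_oracle <- mean(v_all >= v_obs - 1e-12)
  expect_equal(wilcoxon_signed_exact(d, rep(0, 8),
                                     alternative = "greater")$p_value,
               p_oracle, tolerance = 1e-12)
})

test_that("pairwise voxel-size comparisons flag ties and adjust with Holm", {
  set.seed(74)
  v <- matrix(rlnorm(8 * 3, -7, 0.5), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  v[, 2] <- v[, 1]                 # identical pair -> tie flag, p = 1
  tab <- compare_voxel_distributions(v)
  ab <- tab[tab$edge_a == "a" & tab$edge_b == "b", ]
  expect_true(ab$tie_flag)
  expect_equal(ab$p_value, 1)
  expect_true(all(tab$p_adjusted >= tab$p_value))
  expect_error(compare_voxel_distributions(v[1:4, ]), "6")
})

test_that("nested-doubling volumes differ significantly across a cohort", {
  set.seed(75)
  n <- 100
  base <- rlnorm(n, -7, 0.4)
  v <- cbind(e1 = base, e2 = base * runif(n, 1.3, 1.8),
             e4 = base * runif(n, 2.5, 3.5))
  tab <- compare_voxel_distributions(v)
  expect_true(all(tab$p_adjusted < 0.05))
})

test_that("Lin's CCC follows its moment definition and bounds", {
  x <- c(1, 2, 3, 4)
  expect_equal(lins_ccc(x, x), 1)
  expect_equal(lins_ccc(x - 2.5, -(x - 2.5)), -1)

  y <- c(1.1, 2.1, 2.9, 4.2)
  mx <- mean(x); my <- mean(y)
  num <- 2 * mean((x - mx) * (y - my))
  den <- mean((x - mx)^2) + mean((y - my)^2) + (mx - my)^2
  expect_equal(lins_ccc(x, y), num / den, tolerance = 1e-12)

  set.seed(76)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    expect_lte(abs(lins_ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  # CCC equals Pearson r when means and variances agree
  a <- rnorm(100)
  b <- sample(a)  # same moments exactly
  expect_equal(lins_ccc(a, b), cor(a, b), tolerance = 1e-12)
})

test_that("TLS fits noiseless lines and beats OLS on orthogonal residuals", {
  x <- c(0, 1, 2, 3, 4)
  f <- tls_fit(x, 3 * x - 2)
  expect_equal(f$slope, 3, tolerance = 1e-12)
  expect_equal(f$intercept, -2, tolerance = 1e-12)

  # vertical-dominant data
  v <- tls_fit(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_true(v$vertical)

  orth_ss <- function(slope, intercept, x, y)
    sum((y - slope * x - intercept)^2) / (1 + slope^2)
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(5); y <- 0.8 * x + rnorm(5, 0, 0.6)
    t <- tls_fit(x, y)
    o1 <- lm(y ~ x)$coefficients
    o2 <- lm(x ~ y)$coefficients
    s2 <- 1 / o2[2]; i2 <- -o2[1] / o2[2]
    expect_lte(orth_ss(t$slope, t$intercept, x, y),
               orth_ss(o1[2], o1[1], x, y) + 1e-12)
    expect_lte(orth_ss(t$slope, t$intercept, x, y),
               orth_ss(s2, i2, x, y) + 1e-12)
  }

  # axis swap inverts the slope
  set.seed(78)
  x <- rnorm(20); y <- 2 * x + rnorm(20, 0, 0.3)
  expect_equal(tls_fit(x, y)$slope, 1 / tls_fit(y, x)$slope, tolerance = 1e-9)
})
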