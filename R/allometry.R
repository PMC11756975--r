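## Volume -> biomass allometric regression and the statistics used to screen
## and compare the volumetric estimators.

.regression_result <- function(form, slope, intercept, r2, rmse_g, n) {
  structure(list(form = form, slope = slope, intercept = intercept,
                 r_squared = r2, rmse_g = rmse_g, n = n,
                 f_squared = NA_real_, achieved_power = NA_real_,
                 significant = NA),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<%s fit: n = %d, slope = %.4g, intercept = %.4g, R^2 = %.3f, RMSE = %.1f g",
              x$form, x$n, x$slope, x$intercept, x$r_squared, x$rmse_g))
  if (!is.na(x$achieved_power))
    cat(sprintf(", f^2 = %.3f, power = %.3f%s", x$f_squared, x$achieved_power,
                if (isTRUE(x$significant)) " *" else ""))
  cat(">\n")
  invisible(x)
}

#' Linear volume-to-biomass fit
#'
#' Ordinary least squares `biomass = a + b * volume`, with R^2 and RMSE in
#' grams on the observed scale.
#'
#' @param volume per-plot volumes (m^3).
#' @param biomass_g per-plot dry weights (g).
#' @return a `regression_result`; feed it to [power_screen()] for the
#'   effect-size screening.
#' @export
fit_linear <- function(volume, biomass_g) {
  x <- as.numeric(volume); y <- as.numeric(biomass_g)
  n <- length(x)
  if (n < 3L || length(y) != n) stop("fit_linear needs paired vectors, n >= 3")
  if (var(x) == 0) stop("fit_linear: zero variance in volume")
  if (var(y) == 0) stop("fit_linear: zero variance in biomass")
  fit <- lm(y ~ x)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  .regression_result("linear", coef(fit)[["x"]], coef(fit)[["(Intercept)"]],
                     r2, sqrt(mean(fit$residuals^2)), n)
}

#' Logarithmic (log-log) volume-to-biomass fit
#'
#' OLS on `ln(biomass) = a + b * ln(volume)` — the allometric power law
#' `biomass = exp(a) * volume^b`. R^2 is reported on the log-log scale; the
#' RMSE is back-transformed to grams (root mean square of
#' `biomass - exp(fitted)`) so linear and log models are comparable.
#'
#' @inheritParams fit_linear
#' @return a `regression_result` with `slope` the recovered exponent.
#' @export
fit_log <- function(volume, biomass_g) {
  x <- as.numeric(volume); y <- as.numeric(biomass_g)
  n <- length(x)
  if (n < 3L || length(y) != n) stop("fit_log needs paired vectors, n >= 3")
  bad <- which(x <= 0 | y <= 0)
  if (length(bad))
    stop("fit_log needs positive volumes and biomass; offending plots: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  lx <- log(x); ly <- log(y)
  if (var(lx) == 0) stop("fit_log: zero variance in log volume")
  if (var(ly) == 0) stop("fit_log: zero variance in log biomass")
  fit <- lm(ly ~ lx)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  .regression_result("log", coef(fit)[["lx"]], coef(fit)[["(Intercept)"]],
                     r2, sqrt(mean((y - exp(fit$fitted.values))^2)), n)
}

#' Effect-size power screening of a regression
#'
#' Cohen's `f^2 = R^2 / (1 - R^2)`; achieved power from the noncentral F
#' distribution with 1 and `n - 2` degrees of freedom and noncentrality
#' `f^2 * n` at test size `alpha`. A fit is flagged significant when the
#' achieved power reaches `min_power`.
#'
#' @param result a `regression_result` from [fit_linear()] or [fit_log()].
#' @param alpha test size (default 0.05).
#' @param min_power minimum power to report a relationship (default 0.90).
#' @return the `regression_result` with `f_squared`, `achieved_power` and
#'   `significant` filled in.
#' @export
power_screen <- function(result, alpha = 0.05, min_power = 0.90) {
  stopifnot(inherits(result, "regression_result"), result$n >= 3L)
  r2 <- result$r_squared
  f2 <- r2 / (1 - r2)
  df2 <- result$n - 2L
  crit <- qf(1 - alpha, 1, df2)
  pow <- pf(crit, 1, df2, ncp = f2 * result$n, lower.tail = FALSE)
  result$f_squared <- f2
  result$achieved_power <- pow
  result$significant <- pow >= min_power
  result
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Exact null distribution of the signed-rank statistic (sum of the
#' ranks of positive differences, zeros dropped, midranks for ties) by
#' dynamic-programming convolution over all `2^n` sign assignments — so the
#' exact p-value is available even with tied ranks, where
#' [stats::wilcox.test()] falls back to the normal approximation.
#'
#' @param x,y paired samples.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger),
#'   or `"less"`.
#' @return a list: `statistic` (V), `p_value`, `n_nonzero`.
#' @export
wilcoxon_signed_exact <- function(x, y,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p_value = 1, n_nonzero = 0L))
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled midranks are integers
  v2 <- sum(r2[d > 0])
  tot <- sum(r2)
  # counts[s + 1] = number of sign assignments with doubled statistic s
  counts <- rep(0, tot + 1L)
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(tot + 1L - r)])
    counts <- counts + shifted
  }
  counts <- counts / 2^n
  p_ge <- sum(counts[(v2 + 1L):(tot + 1L)])
  p_le <- sum(counts[seq_len(v2 + 1L)])
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(statistic = v2 / 2, p_value = p, n_nonzero = n)
}

#' Pairwise Wilcoxon comparison of voxel-volume distributions
#'
#' Per-plot voxel volumes measured at several edge lengths are repeated
#' measurements of the same plots, so each pair of edge lengths is compared
#' with a paired Wilcoxon signed-rank test (exact null for n <= 25 via
#' [wilcoxon_signed_exact()], normal approximation with continuity correction
#' otherwise). P-values are Holm-adjusted across the pairs.
#'
#' @param volumes numeric matrix, plots x edge lengths (column names used as
#'   labels).
#' @param exact_max largest n for the exact null distribution (default 25).
#' @param adjust p-adjustment method (default `"holm"`; any
#'   [stats::p.adjust()] method).
#' @return a data.frame with one row per pair: `edge_a`, `edge_b`,
#'   `p_value`, `p_adjusted`, `tie_flag` (TRUE when all paired differences
#'   are zero, where p is 1 by convention).
#' @export
compare_voxel_distributions <- function(volumes, exact_max = 25L,
                                        adjust = "holm") {
  volumes <- as.matrix(volumes)
  if (ncol(volumes) < 2L) stop("need at least two edge lengths")
  if (nrow(volumes) < 6L) stop("need at least 6 plots")
  labs <- colnames(volumes)
  if (is.null(labs)) labs <- as.character(seq_len(ncol(volumes)))
  pairs <- utils::combn(ncol(volumes), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(q) {
    a <- pairs[1, q]; b <- pairs[2, q]
    d <- volumes[, b] - volumes[, a]
    if (all(d == 0))
      return(data.frame(edge_a = labs[a], edge_b = labs[b], p_value = 1,
                        tie_flag = TRUE))
    p <- if (nrow(volumes) <= exact_max) {
      wilcoxon_signed_exact(volumes[, a], volumes[, b])$p_value
    } else {
      suppressWarnings(
        wilcox.test(volumes[, a], volumes[, b], paired = TRUE,
                    exact = FALSE, correct = TRUE))$p.value
    }
    data.frame(edge_a = labs[a], edge_b = labs[b], p_value = p,
               tie_flag = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out[c("edge_a", "edge_b", "p_value", "p_adjusted", "tie_flag")]
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (n-denominator) moments. Measures agreement with the identity
#' line: it penalizes both location and scale shifts, so `|CCC| <= |r|`.
#'
#' @param x,y paired measurements, length >= 2.
#' @return a scalar in `[-1, 1]`.
#' @export
lins_ccc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 2L || length(y) != n) stop("lins_ccc needs paired vectors, n >= 2")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) stop("lins_ccc undefined: zero variance and equal means")
  2 * sxy / den
}

#' Total least squares (orthogonal regression) line
#'
#' The line minimizing orthogonal distances: direction of the principal
#' eigenvector of the centered 2 x 2 covariance, intercept through the
#' means. Appropriate when both variables carry error (e.g. two volume
#' estimates of the same plots).
#'
#' @param x,y paired vectors, length >= 3, nonzero variance in at least one.
#' @return a list: `slope`, `intercept`, `vertical` (TRUE when the principal
#'   direction is vertical, in which case slope is `Inf` and the intercept is
#'   the x-location of the line).
#' @export
tls_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3L || length(y) != n) stop("tls_fit needs paired vectors, n >= 3")
  cx <- x - mean(x); cy <- y - mean(y)
  sxx <- mean(cx^2); syy <- mean(cy^2); sxy <- mean(cx * cy)
  if (sxx == 0 && syy == 0) stop("tls_fit: zero variance in both variables")
  # principal eigenvector of [[sxx, sxy], [sxy, syy]]
  tr <- sxx + syy
  disc <- sqrt(max((sxx - syy)^2 + 4 * sxy^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (abs(l1 - l2) <= 1e-14 * max(l1, 1e-300))
    stop("tls_fit: isotropic scatter, orientation is ambiguous")
  # eigenvector (sxy, l1 - sxx); fall back for the diagonal case
  vx <- sxy; vy <- l1 - sxx
  if (abs(vx) < 1e-300 && abs(vy) < 1e-300) {
    vx <- l1 - syy; vy <- sxy
  }
  if (abs(vx) <= 1e-14 * abs(vy)) {
    return(list(slope = Inf, intercept = mean(x), vertical = TRUE))
  }
  slope <- vy / vx
  list(slope = slope, intercept = mean(y) - slope * mean(x), vertical = FALSE)
}
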