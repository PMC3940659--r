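#' Negative hyperbolic length-content regression
#'
#' Least-squares fit of `y = a + b / x` (linear in `1/x`): `a` is the
#' asymptotic content percentage at large protein length, `b` the
#' curvature in percent x residues. Degenerate constant responses return
#' `b = 0, r_squared = 0`.
#'
#' @param x positive predictor (protein length, residues).
#' @param y response (content percentage).
#' @return A list of class `hyperbolic_fit` with fields `a`, `b`,
#'   `r_squared`, `fitted`, `residuals`.
#' @export
fit_hyperbolic <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 (x, y) pairs")
  if (any(x <= 0)) stop("protein lengths must be positive")
  if (length(unique(x)) < 2L)
    stop("rank-deficient fit: all x values identical")
  if (var(y) == 0) {
    fit <- list(a = y[1], b = 0, r_squared = 0,
                fitted = rep(y[1], length(y)),
                residuals = rep(0, length(y)))
    class(fit) <- "hyperbolic_fit"
    return(fit)
  }
  u <- 1 / x
  m <- lm(y ~ u)
  r2 <- 1 - sum(m$residuals^2) / sum((y - mean(y))^2)
  fit <- list(a = unname(coef(m)[1]), b = unname(coef(m)[2]),
              r_squared = r2,
              fitted = unname(m$fitted.values),
              residuals = unname(m$residuals))
  class(fit) <- "hyperbolic_fit"
  fit
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("hyperbolic fit: y = %.6g + %.6g / x   (R^2 = %.6g)\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' Bivariate smoothed kernel density surface
#'
#' Product-Gaussian kernel density on a regular grid (length on one axis,
#' content percentage on the other in the intended use). Default
#' bandwidth is Silverman's rule-of-thumb per dimension; the bandwidths
#' are plain kernel standard deviations.
#'
#' @param x,y numeric samples of equal length (n >= 2).
#' @param bandwidths optional `c(hx, hy)` kernel standard deviations.
#' @param n grid points per axis.
#' @param lims `c(xmin, xmax, ymin, ymax)`; defaults to the data range
#'   extended by three bandwidths.
#' @return A list of class `kde_surface`: `x`, `y` (grid vectors), `z`
#'   (density matrix), `bandwidths`.
#' @export
kde2d_surface <- function(x, y, bandwidths = NULL, n = 64L, lims = NULL) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("need at least 2 (x, y) pairs")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("non-finite values")
  if (is.null(bandwidths)) {
    if (var(x) == 0 || var(y) == 0)
      stop("zero variance in one dimension: supply explicit bandwidths")
    bandwidths <- c(bw.nrd0(x), bw.nrd0(y))
  }
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  if (is.null(lims))
    lims <- c(min(x) - 3 * bandwidths[1], max(x) + 3 * bandwidths[1],
              min(y) - 3 * bandwidths[2], max(y) + 3 * bandwidths[2])
  # MASS::kde2d divides its h by 4 internally; pre-scale so `bandwidths`
  # are the actual Gaussian kernel standard deviations.
  k <- MASS::kde2d(x, y, h = 4 * bandwidths, n = n, lims = lims)
  structure(list(x = k$x, y = k$y, z = k$z, bandwidths = bandwidths),
            class = "kde_surface")
}

#' Welch's unequal-variance t test
#'
#' Two-sided t test with Welch-Satterthwaite degrees of freedom (the
#' defensible default for comparing region contents between disorder
#' classes); a pooled-variance Student test is available by flag.
#'
#' @param group_a,group_b numeric samples, each n >= 2.
#' @param pooled use the pooled-variance Student test instead.
#' @return A list with `t_statistic`, `degrees_of_freedom`, `p_value`.
#' @export
welch_ttest <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  if (var(group_a) == 0 && var(group_b) == 0 &&
      group_a[1] == group_b[1])
    stop("both groups are identical constants: t test undefined")
  ht <- t.test(group_a, group_b, var.equal = pooled)
  list(t_statistic = unname(ht$statistic),
       degrees_of_freedom = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Discrete summary of a sample
#'
#' Minimum, maximum, mean, median and the mode defined as the midpoint of
#' the most populated unit-width histogram bin (first such bin on ties).
#'
#' @param values non-empty numeric vector.
#' @return A list with `minimum`, `maximum`, `mean`, `median`, `mode`.
#' @export
discrete_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) stop("non-empty numeric input required")
  if (length(values) == 1L)
    return(list(minimum = values, maximum = values, mean = values,
                median = values, mode = values))
  lo <- floor(min(values)); hi <- ceiling(max(values))
  if (hi == lo) hi <- lo + 1
  breaks <- seq(lo, hi, by = 1)
  counts <- table(cut(values, breaks, include.lowest = TRUE,
                      right = FALSE))
  k <- which.max(counts)
  list(minimum = min(values), maximum = max(values),
       mean = mean(values), median = median(values),
       mode = breaks[k] + 0.5)
}
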