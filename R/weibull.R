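## Two-parameter Weibull (characteristic-length) statistics over microfracture
## lengths. The cumulative model is P = 1 - exp(-(a/a0)^alpha); probability-
## plot linearization gives ln(-ln(1-P)) = alpha*ln(a) - alpha*ln(a0), and the
## fit is rank regression on that line. alpha = 1 reduces to the exponential
## model (constant failure rate); alpha > 1 has increasing, alpha < 1
## decreasing failure rate.

#' Weibull cumulative distribution of fracture length
#'
#' @param a Fracture length(s), `>= 0`.
#' @param alpha Shape parameter, `> 0`.
#' @param a0 Characteristic length (same units as `a`), `> 0`; the length at
#'   which the cumulative probability is `1 - exp(-1)`.
#' @return `P = 1 - exp(-(a/a0)^alpha)`.
#' @export
weibull_cdf <- function(a, alpha, a0) {
  assert_positive(alpha, "alpha"); assert_positive(a0, "a0")
  if (any(a < 0)) stop("`a` must be >= 0")
  1 - exp(-(a / a0)^alpha)
}

#' Weibull quantile (inverse CDF)
#'
#' @param P Cumulative probability in `[0, 1)`.
#' @inheritParams weibull_cdf
#' @return `a = a0 * (-ln(1 - P))^(1/alpha)`.
#' @export
weibull_quantile <- function(P, alpha, a0) {
  assert_positive(alpha, "alpha"); assert_positive(a0, "a0")
  if (any(P < 0 | P >= 1)) stop("`P` must be in [0, 1)")
  a0 * (-log(1 - P))^(1 / alpha)
}

#' Weibull hazard (failure rate)
#'
#' @inheritParams weibull_cdf
#' @return `alpha/a0 * (a/a0)^(alpha - 1)`.
#' @export
weibull_hazard <- function(a, alpha, a0) {
  assert_positive(alpha, "alpha"); assert_positive(a0, "a0")
  alpha / a0 * (a / a0)^(alpha - 1)
}

#' Probability-plot linearization
#'
#' Maps `(a, P)` pairs to `(x, y) = (ln a, ln(-ln(1 - P)))`; for exact Weibull
#' probabilities the points satisfy `y = alpha * (x - ln a0)`.
#'
#' @param a Lengths, `> 0`.
#' @param P Probabilities strictly inside `(0, 1)`.
#' @return Tibble with columns `x`, `y`.
#' @export
linearize <- function(a, P) {
  if (any(a <= 0)) stop("`a` must be > 0")
  if (any(P <= 0 | P >= 1)) stop("`P` must be in (0, 1)")
  tibble::tibble(x = log(a), y = log(-log(1 - P)))
}

#' Plotting positions for ranked data
#'
#' @param n Sample size, `>= 1`.
#' @param scheme `"median_rank"` (Bernard, `(i - 0.3)/(n + 0.4)`; default) or
#'   `"mean_rank"` (`i/(n + 1)`).
#' @return Strictly increasing vector of probabilities in `(0, 1)`.
#' @export
plotting_positions <- function(n, scheme = c("median_rank", "mean_rank")) {
  scheme <- match.arg(scheme)
  if (n < 1) stop("`n` must be >= 1")
  i <- seq_len(n)
  switch(scheme, median_rank = (i - 0.3) / (n + 0.4), mean_rank = i / (n + 1))
}

#' Fit a two-parameter Weibull by probability-plot rank regression
#'
#' Sorts the lengths, assigns plotting positions, linearizes, and regresses
#' `y` on `x` by least squares. The slope is the shape `alpha`; the
#' characteristic length is recovered from the intercept
#' (`intercept = -alpha * ln a0`). Invariant to input order.
#'
#' @param lengths Positive lengths, `n >= 2`, not all equal.
#' @param scheme Plotting-position scheme, see [plotting_positions()].
#' @return An object of class `weibull_fit`: `alpha`, `a0`, `r_squared`, `n`,
#'   `plotting_position`, and the linearized `points` tibble.
#' @examples
#' set.seed(1)
#' fit <- fit_weibull(20 * (-log(1 - runif(200)))^(1 / 1.5))
#' fit$alpha
#' @export
fit_weibull <- function(lengths, scheme = c("median_rank", "mean_rank")) {
  scheme <- match.arg(scheme)
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (length(lengths) < 2) stop("need at least 2 lengths")
  if (max(lengths) == min(lengths)) {
    stop("degenerate sample: all lengths equal (infinite slope)")
  }
  a <- sort(lengths)
  P <- plotting_positions(length(a), scheme)
  pts <- linearize(a, P)
  fit <- stats::lm(y ~ x, data = pts)
  alpha <- unname(stats::coef(fit)[2])
  a0 <- exp(-unname(stats::coef(fit)[1]) / alpha)
  # direct R^2; summary.lm() warns on numerically perfect fits
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((pts$y - mean(pts$y))^2)
  structure(list(alpha = alpha, a0 = a0,
                 r_squared = r2,
                 n = length(a), plotting_position = scheme,
                 points = pts),
            class = "weibull_fit")
}

#' Maximum-likelihood Weibull fit (cross-check utility)
#'
#' Direct numerical MLE of the same two-parameter model, provided as an
#' independent cross-check of the rank-regression estimate.
#'
#' @param lengths Positive lengths.
#' @return List with `alpha`, `a0`.
#' @export
fit_weibull_mle <- function(lengths) {
  if (any(lengths <= 0)) stop("lengths must be positive")
  nll <- function(par) {
    -sum(stats::dweibull(lengths, shape = exp(par[1]), scale = exp(par[2]),
                         log = TRUE))
  }
  opt <- stats::optim(c(0, log(mean(lengths))), nll)
  list(alpha = exp(opt$par[1]), a0 = exp(opt$par[2]))
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(paste0("Two-parameter Weibull fit (rank regression, %s)\n",
                     "  shape alpha = %.4f\n  characteristic length a0 = %.4f\n",
                     "  R^2 = %.4f on n = %d\n"),
              x$plotting_position, x$alpha, x$a0, x$r_squared, x$n))
  invisible(x)
}
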