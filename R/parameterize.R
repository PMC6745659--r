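# Parameterization fits: Weibull emergence phenology from quadrat counts and
# the exponential fecundity-vs-emergence-date regression, plus the
# panicle-ratio adjustment chain that converts a common-garden panicle
# regression into field seed production.

#' Fit the Weibull emergence curve to quadrat count data
#'
#' Fits the two-parameter Weibull CDF to cumulative emergence proportions
#' (proportion of all emerged plants observed by each evaluation date).
#' The default is least squares on the cumulative proportions; an
#' interval-censored maximum-likelihood fit (multinomial over the
#' inter-evaluation intervals, conditioned on emergence by the last date)
#' is available with `method = "ml"`.
#'
#' @param date evaluation dates (DASS), increasing; at least 3 distinct.
#' @param count emergence counts, per interval by default.
#' @param cumulative logical: are `count`s already cumulative?
#' @param method `"ls"` (default) or `"ml"`.
#' @return object of class `jg_weibull_fit` with elements `shape`, `scale`,
#'   `fitted` (fitted cumulative proportions) and the input data.
#' @examples
#' x <- c(150, 165, 180, 200, 230)
#' p <- pweibull(x, 10.5, 169)
#' fit <- fit_weibull_emergence(x, round(1000 * c(p[1], diff(p))))
#' coef(fit)
#' @export
fit_weibull_emergence <- function(date, count, cumulative = FALSE,
                                  method = c("ls", "ml")) {
  method <- match.arg(method)
  stopifnot(length(date) == length(count), all(count >= 0))
  if (length(date) < 3) stop("need at least 3 evaluation dates")
  if (is.unsorted(date, strictly = TRUE))
    stop("dates must be strictly increasing within a series")
  cum <- if (cumulative) count else cumsum(count)
  if (is.unsorted(cum)) stop("cumulative counts must be non-decreasing")
  total <- cum[length(cum)]
  if (total <= 0) stop("no emergence observed")
  inc <- if (cumulative) diff(c(0, count)) else count
  if (sum(inc > 0) < 2)
    stop("degenerate data: all emergence on a single date")
  p <- cum / total

  # linearized Weibull plot for starting values
  ok <- p > 0 & p < 1
  if (sum(ok) >= 2) {
    f <- stats::lm(log(-log(1 - p[ok])) ~ log(date[ok]))
    k0 <- max(stats::coef(f)[[2L]], 0.1)
    l0 <- exp(-stats::coef(f)[[1L]] / k0)
  } else {
    k0 <- 2
    l0 <- stats::weighted.mean(date, inc)
  }

  obj <- if (method == "ls") {
    function(par) {
      F <- stats::pweibull(date, exp(par[1L]), exp(par[2L]))
      sum((p - F)^2)
    }
  } else {
    function(par) {
      F <- stats::pweibull(c(0, date), exp(par[1L]), exp(par[2L]))
      pr <- diff(F)
      if (any(pr <= 0) || F[length(F)] <= 0) return(1e10)
      -(sum(inc * log(pr)) - total * log(F[length(F)]))
    }
  }
  opt <- stats::optim(log(c(k0, l0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  shape <- exp(opt$par[[1L]])
  scale <- exp(opt$par[[2L]])
  structure(list(shape = shape, scale = scale, method = method,
                 date = date, proportion = p,
                 fitted = stats::pweibull(date, shape, scale),
                 convergence = opt$convergence),
            class = "jg_weibull_fit")
}

#' @export
coef.jg_weibull_fit <- function(object, ...) {
  c(shape = object$shape, scale = object$scale)
}

#' @export
print.jg_weibull_fit <- function(x, ...) {
  cat("Weibull emergence fit (", x$method, "): shape k = ",
      signif(x$shape, 4), ", scale lambda = ", signif(x$scale, 5),
      " days\n", sep = "")
  invisible(x)
}

#' @export
plot.jg_weibull_fit <- function(x, ...) {
  graphics::plot(x$date, x$proportion, pch = 16,
                 xlab = "days after start of season",
                 ylab = "cumulative emergence proportion", ...)
  xs <- seq(0, max(x$date) * 1.1, length.out = 200)
  graphics::lines(xs, stats::pweibull(xs, x$shape, x$scale), col = "blue")
  invisible(x)
}

#' Fit the exponential fecundity decline
#'
#' Log-linear least squares of counts (panicles or seeds per plant) on
#' emergence date: `y = a * exp(b * x)` becomes `ln y = ln a + b x`, fitted
#' by `lm()`. R-squared is reported on the log scale.
#'
#' @param x emergence dates (DASS).
#' @param y positive counts.
#' @return object of class `jg_exp_fit` with `a_hat`, `b_hat`,
#'   `r_squared`, and the `lm` fit.
#' @examples
#' x <- c(40, 80, 120, 160)
#' fit <- fit_exponential_fecundity(x, 4098.5 * exp(-0.066 * x))
#' coef(fit)
#' @export
fit_exponential_fecundity <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (any(y <= 0)) stop("counts must be positive for the log-linear fit")
  fit <- stats::lm(log(y) ~ x)
  b <- stats::coef(fit)[[2L]]
  # R squared on the log scale, computed directly (summary.lm warns on
  # noiseless data)
  ss_tot <- sum((log(y) - mean(log(y)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(a_hat = exp(stats::coef(fit)[[1L]]), b_hat = b,
                 r_squared = r2, lm = fit),
            class = "jg_exp_fit")
}

#' @export
coef.jg_exp_fit <- function(object, ...) {
  c(a = object$a_hat, b = object$b_hat)
}

#' @export
print.jg_exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fecundity fit: y = %.4g * exp(%.4g x), R2 = %.4f (log scale)\n",
              x$a_hat, x$b_hat, x$r_squared))
  invisible(x)
}

#' Adjust a common-garden panicle regression to field seed production
#'
#' The panicle-count regression is fitted on plants grown under favourable
#' common-garden conditions. Field seed production is obtained by scaling
#' the intercept by the ratio of field to garden panicles per plant and by
#' the field seeds-per-panicle count; the rate `b` is unchanged.
#'
#' @param fit a [fit_exponential_fecundity()] result (panicles vs date).
#' @param field_panicles_per_plant mean panicles per plant in the field.
#' @param garden_panicles_per_plant mean panicles per plant in the common
#'   garden (4).
#' @param seeds_per_panicle mean seeds per panicle in the field.
#' @param max_seeds field cap on seeds per plant for the resulting
#'   [fecundity_params()] (default `Inf`).
#' @return a [fecundity_params()].
#' @export
adjust_fecundity <- function(fit, field_panicles_per_plant,
                             garden_panicles_per_plant = 4,
                             seeds_per_panicle, max_seeds = Inf) {
  stopifnot(field_panicles_per_plant > 0, garden_panicles_per_plant > 0,
            seeds_per_panicle > 0)
  fecundity_params(
    a = fit$a_hat * (field_panicles_per_plant / garden_panicles_per_plant) *
      seeds_per_panicle,
    b = fit$b_hat, max_seeds = max_seeds)
}
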