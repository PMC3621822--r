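#' Length-of-stay distribution from an elicited estimate
#'
#' Ward staff submit an expected discharge time (days after admission) and an
#' uncertainty, read as one standard deviation of the stay length in days.
#' Both are interpreted on the natural (day) scale and moment-matched to a
#' log-normal law: with natural mean \eqn{m} and variance \eqn{v},
#' \deqn{\sigma_{\log}^2 = \log(1 + v/m^2), \qquad
#'       \mu_{\log} = \log m - \sigma_{\log}^2 / 2.}
#'
#' @param mean_days Expected length of stay in days (> 0).
#' @param sd_days Uncertainty of the estimate as a standard deviation in days
#'   (> 0). Values below `1e-3` are capped at `1e-3`, which degenerates the
#'   law towards a point mass at `mean_days`.
#' @return An object of class `los_dist`: a list with natural-scale
#'   `mean_days`, `sd_days`, `variance_days2` and log-scale `meanlog`,
#'   `sdlog`.
#' @examples
#' d <- los_estimate(5, 2)
#' los_survival(d, 0:10)
#' @export
los_estimate <- function(mean_days, sd_days) {
  check_scalar_number(mean_days, "mean_days", min = 0, strict = TRUE)
  check_scalar_number(sd_days, "sd_days", min = 0, strict = TRUE)
  sd_days <- max(sd_days, 1e-3)
  p <- los_params(mean_days, sd_days)
  structure(
    list(
      mean_days = mean_days,
      sd_days = sd_days,
      variance_days2 = sd_days^2,
      meanlog = p$meanlog,
      sdlog = p$sdlog
    ),
    class = "los_dist"
  )
}

# vectorised moment matching (used by the population generator)
los_params <- function(mean_days, sd_days) {
  v <- sd_days^2
  s2 <- log1p(v / mean_days^2)
  list(meanlog = log(mean_days) - s2 / 2, sdlog = sqrt(s2))
}

#' @export
print.los_dist <- function(x, ...) {
  cat(sprintf(
    "<los_dist> log-normal LoS: mean %.3g d, sd %.3g d (meanlog %.4f, sdlog %.4f)\n",
    x$mean_days, x$sd_days, x$meanlog, x$sdlog
  ))
  invisible(x)
}

#' Survival probability of a stay
#'
#' Probability that a patient with length-of-stay law `dist` is still
#' occupying a bed `t` days after admission, \eqn{p_{it} = P(D_i \ge t)}.
#' The support of the log-normal is positive, so `los_survival(d, 0)` is 1 and
#' the curve is non-increasing in `t`.
#'
#' @param dist A [los_estimate()] object.
#' @param t Non-negative day offsets since admission (vectorised).
#' @return Probabilities in \[0, 1\].
#' @export
los_survival <- function(dist, t) {
  stopifnot(inherits(dist, "los_dist"))
  if (any(t < 0)) abort("`t` must be non-negative")
  surv_vec(t, dist$meanlog, dist$sdlog)
}

# vectorised survival; offsets before admission (negative t) contribute 0
surv_vec <- function(t, meanlog, sdlog) {
  p <- plnorm(t, meanlog = meanlog, sdlog = sdlog, lower.tail = FALSE)
  p[t < 0] <- 0
  p
}

# one realized integer LoS per row, >= 1 day; consumes the current RNG stream
sample_realized_los <- function(meanlog, sdlog) {
  pmax(1L, as.integer(ceiling(rlnorm(length(meanlog), meanlog, sdlog))))
}
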