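#' Parametric survival families
#'
#' The six families used for fitting and extrapolating progression-free and
#' overall survival: exponential, Weibull, Gompertz, log-logistic, log-normal
#' and generalized gamma (Prentice parameterisation).  All families are
#' parameterised on the natural scale; times are in days.
#'
#' Parameter vectors (named, in order):
#' \describe{
#'   \item{exponential}{\code{rate} (> 0), hazard per day.}
#'   \item{weibull}{\code{shape}, \code{scale} (both > 0), as in
#'     \code{\link[stats]{pweibull}}.}
#'   \item{gompertz}{\code{shape} (any sign), \code{rate} (> 0):
#'     hazard \eqn{h(t) = rate \cdot e^{shape \cdot t}}.  A negative shape
#'     gives an improper distribution with a surviving fraction
#'     \eqn{\exp(rate/shape)}.}
#'   \item{loglogistic}{\code{shape}, \code{scale} (both > 0):
#'     \eqn{S(t) = 1/(1 + (t/scale)^{shape})}; the median equals the scale.}
#'   \item{lognormal}{\code{meanlog}, \code{sdlog} (> 0), as in
#'     \code{\link[stats]{plnorm}}.}
#'   \item{gengamma}{\code{mu}, \code{sigma} (> 0), \code{q} (any sign),
#'     Prentice form.  \code{q = 0} is the log-normal limit (handled by an
#'     explicit switch at \code{|q| < 1e-5}), \code{q = 1} the Weibull with
#'     shape \code{1/sigma} and scale \code{exp(mu)}.}
#' }
#'
#' @return \code{surv_families()} returns the character vector of family ids;
#'   \code{surv_n_params()} the number of parameters of one family.
#' @examples
#' surv_families()
#' surv_prob("loglogistic", c(shape = 1, scale = 502), months_to_days(16.5))
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gompertz", "loglogistic", "lognormal",
    "gengamma")
}

#' @rdname surv_families
#' @param family one of \code{surv_families()}.
#' @export
surv_n_params <- function(family) {
  check_family(family)
  c(exponential = 1L, weibull = 2L, gompertz = 2L, loglogistic = 2L,
    lognormal = 2L, gengamma = 3L)[[family]]
}

check_family <- function(family) {
  if (length(family) != 1L || !family %in% surv_families()) {
    stop("unknown survival family '", paste(family, collapse = ","), "'",
         call. = FALSE)
  }
  invisible(family)
}

#' Validity of a parameter vector for a family
#'
#' @param family family id.
#' @param params numeric parameter vector on the natural scale.
#' @return logical flag.
#' @export
surv_params_ok <- function(family, params) {
  check_family(family)
  if (length(params) != surv_n_params(family) || any(!is.finite(params))) {
    return(FALSE)
  }
  switch(family,
    exponential = params[1] > 0,
    weibull     = all(params[1:2] > 0),
    gompertz    = params[2] > 0,
    loglogistic = all(params[1:2] > 0),
    lognormal   = params[2] > 0,
    gengamma    = params[2] > 0
  )
}

# cumulative hazard of the Gompertz, stable through shape -> 0
gompertz_cumhaz <- function(shape, rate, t) {
  if (abs(shape) < 1e-12) rate * t else rate * expm1(shape * t) / shape
}

gengamma_logdens <- function(mu, sigma, q, t) {
  if (abs(q) < 1e-5) {
    return(stats::dlnorm(t, meanlog = mu, sdlog = sigma, log = TRUE))
  }
  g <- q^-2
  w <- (log(t) - mu) / sigma
  log(abs(q)) - log(sigma) - log(t) + g * log(g) - lgamma(g) +
    g * (q * w - exp(q * w))
}

gengamma_surv <- function(mu, sigma, q, t) {
  if (abs(q) < 1e-5) {
    return(stats::plnorm(t, meanlog = mu, sdlog = sigma, lower.tail = FALSE))
  }
  g <- q^-2
  w <- (log(pmax(t, .Machine$double.xmin)) - mu) / sigma
  u <- g * exp(q * w)
  if (q > 0) stats::pgamma(u, g, lower.tail = FALSE) else stats::pgamma(u, g)
}

#' Log-density of a survival family
#'
#' @inheritParams surv_params_ok
#' @param t vector of times in days (> 0).
#' @return vector of log-densities; \code{-Inf} where the density is 0.
#' @export
surv_logdens <- function(family, params, t) {
  check_family(family)
  unname(switch(family,
    exponential = log(params[1]) - params[1] * t,
    weibull = stats::dweibull(t, shape = params[1], scale = params[2],
                              log = TRUE),
    gompertz = log(params[2]) + params[1] * t -
      gompertz_cumhaz(params[1], params[2], t),
    loglogistic = {
      z <- params[1] * (log(t) - log(params[2]))
      l1p <- ifelse(z > 30, z, log1p(exp(z)))
      log(params[1]) - log(t) + z - 2 * l1p
    },
    lognormal = stats::dlnorm(t, meanlog = params[1], sdlog = params[2],
                              log = TRUE),
    gengamma = gengamma_logdens(params[1], params[2], params[3], t)
  ))
}

#' Survival function of a family
#'
#' @inheritParams surv_logdens
#' @param t vector of times in days (>= 0).
#' @return vector of survival probabilities S(t) in [0, 1].
#' @export
surv_prob <- function(family, params, t) {
  check_family(family)
  s <- switch(family,
    exponential = exp(-params[1] * t),
    weibull = stats::pweibull(t, shape = params[1], scale = params[2],
                              lower.tail = FALSE),
    gompertz = exp(-gompertz_cumhaz(params[1], params[2], t)),
    loglogistic = stats::plogis(-params[1] *
                                  (log(pmax(t, 0)) - log(params[2]))),
    lognormal = stats::plnorm(t, meanlog = params[1], sdlog = params[2],
                              lower.tail = FALSE),
    gengamma = gengamma_surv(params[1], params[2], params[3], t)
  )
  unname(pmin(pmax(s, 0), 1))
}

#' Inverse survival function
#'
#' Returns the time t at which S(t) equals a given survival probability;
#' used both for analytic medians and for random generation by inversion.
#' \code{Inf} is returned where the probability is below an improper
#' distribution's surviving fraction (negative-shape Gompertz).
#'
#' @inheritParams surv_logdens
#' @param s vector of survival probabilities in (0, 1].
#' @return vector of times in days.
#' @export
surv_inverse <- function(family, params, s) {
  check_family(family)
  stopifnot(all(s > 0 & s <= 1))
  unname(switch(family,
    exponential = -log(s) / params[1],
    weibull = stats::qweibull(s, shape = params[1], scale = params[2],
                              lower.tail = FALSE),
    gompertz = {
      a <- params[1]; b <- params[2]
      if (abs(a) < 1e-12) {
        -log(s) / b
      } else {
        arg <- 1 - a * log(s) / b
        ifelse(arg <= 0, Inf, log(arg) / a)
      }
    },
    loglogistic = params[2] * ((1 - s) / s)^(1 / params[1]),
    lognormal = stats::qlnorm(s, meanlog = params[1], sdlog = params[2],
                              lower.tail = FALSE),
    gengamma = {
      mu <- params[1]; sigma <- params[2]; q <- params[3]
      if (abs(q) < 1e-5) {
        stats::qlnorm(s, meanlog = mu, sdlog = sigma, lower.tail = FALSE)
      } else {
        g <- q^-2
        u <- if (q > 0) stats::qgamma(s, g, lower.tail = FALSE) else
          stats::qgamma(s, g)
        exp(mu + sigma * log(u / g) / q)
      }
    }
  ))
}

#' Random event times by inversion
#'
#' @inheritParams surv_logdens
#' @param n number of draws.
#' @return vector of n event times in days.  Uses the current RNG stream.
#' @export
surv_rand <- function(family, params, n) {
  surv_inverse(family, params, stats::runif(n))
}

#' Analytic median survival time
#'
#' @inheritParams surv_logdens
#' @return median time in days.
#' @export
surv_median <- function(family, params) {
  surv_inverse(family, params, 0.5)
}
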