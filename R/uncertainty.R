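#' Method-of-moments beta parameters
#'
#' Solves \eqn{\alpha/(\alpha+\beta) = m} and the beta variance identity for
#' a stated mean and standard error:
#' \eqn{\nu = m(1-m)/se^2 - 1}, \eqn{\alpha = m\nu}, \eqn{\beta = (1-m)\nu}.
#'
#' @param mean mean in (0, 1).
#' @param se standard error with \eqn{se^2 < mean(1-mean)}.
#' @return named vector \code{c(alpha, beta)}.
#' @examples
#' beta_from_moments(0.5, 0.1)  # alpha = beta = 12
#' @export
beta_from_moments <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("beta moments need 0 < mean < 1", call. = FALSE)
  }
  if (!is.finite(se) || se <= 0 || se^2 >= mean * (1 - mean)) {
    stop("beta moment condition violated: need 0 < se^2 < mean(1-mean)",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma parameters
#'
#' \eqn{shape = (mean/se)^2}, \eqn{scale = se^2/mean}; a cost with
#' SE = mean/4 gives shape 16.
#'
#' @param mean mean (> 0).
#' @param se standard error (> 0).
#' @return named vector \code{c(shape, scale)}.
#' @examples
#' gamma_from_moments(310.16, 77.54)  # shape 16, scale 19.385
#' @export
gamma_from_moments <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || !is.finite(se) || se <= 0) {
    stop("gamma moments need mean > 0 and se > 0", call. = FALSE)
  }
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Re-evaluates the model with each registry parameter set to its lower and
#' upper deterministic bound, all others at baseline, and ranks parameters
#' by the width of the resulting ICER interval.  A patient-assistance
#' scenario row contrasts baseline pricing against the programme.  Bound
#' evaluations that fail, or that leave the interior ICER undefined
#' (dominance), are flagged rather than dropped.
#'
#' @param params baseline \code{cea_params}.
#' @param model evaluator from \code{\link{psm_evaluator}}.
#' @param registry sensitivity registry; defaults to the one attached to
#'   \code{params}.
#' @param include_pap add the patient-assistance scenario row.
#' @return \code{data.frame} sorted by descending bar width: id, bounds,
#'   ICERs at the bounds and baseline, width, flagged.
#' @export
run_dsa <- function(params, model, registry = param_registry(params),
                    include_pap = TRUE) {
  base_ce <- model(params)
  reg <- registry[is.finite(registry$dsa_low) & is.finite(registry$dsa_high),
                  , drop = FALSE]
  eval_at <- function(p) {
    tryCatch(model(p)$icer_value, error = function(e) NA_real_)
  }
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    lo <- eval_at(set_param(params, r$id, r$dsa_low))
    hi <- eval_at(set_param(params, r$id, r$dsa_high))
    data.frame(id = r$id, low = r$dsa_low, high = r$dsa_high,
               icer_low = lo, icer_high = hi,
               icer_base = base_ce$icer_value,
               width = abs(hi - lo),
               flagged = is.na(lo) || is.na(hi))
  })
  if (include_pap) {
    pap_ce <- eval_at(apply_scenario_pap(params))
    rows[[length(rows) + 1]] <- data.frame(
      id = "pap_scenario", low = 0, high = 1,
      icer_low = base_ce$icer_value, icer_high = pap_ce,
      icer_base = base_ce$icer_value,
      width = abs(pap_ce - base_ce$icer_value),
      flagged = is.na(pap_ce))
  }
  out <- do.call(rbind, rows)
  out[order(-out$width, out$id, na.last = TRUE), , drop = FALSE]
}

sample_registry_value <- function(r) {
  v <- switch(r$kind,
    beta = stats::rbeta(1, r$alpha, r$beta),
    gamma = stats::rgamma(1, shape = r$shape, scale = r$scale),
    stop("cannot sample parameter '", r$id, "' of kind '", r$kind, "'",
         call. = FALSE))
  if (isTRUE(r$negate)) -v else v
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of input uncertainty: each iteration samples
#' every non-fixed registry parameter from its beta or gamma distribution
#' (disutilities sampled as magnitudes and negated, mixture weights
#' renormalised to sum to one after joint sampling), re-evaluates the
#' model, and records the incremental cost and QALYs.  Bit-reproducible for
#' a fixed seed.
#'
#' @inheritParams run_dsa
#' @param n_iter number of iterations (>= 1); 500 in the base analysis.
#' @param seed RNG seed.
#' @return list with \code{draws} (\code{data.frame}: iteration,
#'   delta_cost, delta_qaly, icer_value) and \code{samples} (matrix of
#'   sampled parameter values, one column per parameter id).
#' @export
run_psa <- function(params, model, n_iter = 500, seed = 1,
                    registry = param_registry(params)) {
  stopifnot(n_iter >= 1)
  reg <- registry[registry$kind %in% c("beta", "gamma"), , drop = FALSE]
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    ok <- if (r$kind == "beta") {
      is.finite(r$alpha) && is.finite(r$beta) && r$alpha > 0 && r$beta > 0
    } else {
      is.finite(r$shape) && is.finite(r$scale) && r$shape > 0 && r$scale > 0
    }
    if (!ok) {
      stop("invalid sampling distribution for parameter '", r$id, "'",
           call. = FALSE)
    }
  }
  set.seed(seed)
  samples <- matrix(NA_real_, nrow = n_iter, ncol = nrow(reg),
                    dimnames = list(NULL, reg$id))
  dc <- dq <- iv <- numeric(n_iter)
  groups <- unique(stats::na.omit(reg$group))
  for (it in seq_len(n_iter)) {
    p <- params
    for (i in seq_len(nrow(reg))) {
      v <- sample_registry_value(reg[i, ])
      samples[it, i] <- v
      p <- set_param(p, reg$id[i], v)
    }
    for (g in groups) {
      ids <- reg$id[!is.na(reg$group) & reg$group == g]
      w <- vapply(ids, function(id) get_param(p, id), 0)
      w <- w / sum(w)
      for (j in seq_along(ids)) p <- set_param(p, ids[j], w[[j]])
    }
    ce <- model(p)
    dc[it] <- ce$delta_cost
    dq[it] <- ce$delta_qaly
    iv[it] <- ce$icer_value
  }
  list(draws = data.frame(iteration = seq_len(n_iter), delta_cost = dc,
                          delta_qaly = dq, icer_value = iv),
       samples = samples)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of probabilistic draws
#' with positive net monetary benefit \eqn{\lambda \Delta QALY - \Delta C}.
#'
#' @param draws draws \code{data.frame} from \code{\link{run_psa}} (needs
#'   \code{delta_cost}, \code{delta_qaly}).
#' @param wtp_grid vector of willingness-to-pay values, USD per QALY.
#' @return \code{data.frame(wtp, prob_cost_effective)}.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 60000, by = 500)) {
  if (length(wtp_grid) == 0) stop("empty willingness-to-pay grid",
                                  call. = FALSE)
  stopifnot(nrow(draws) >= 1)
  pce <- vapply(wtp_grid, function(l) {
    mean(l * draws$delta_qaly - draws$delta_cost > 0)
  }, 0)
  data.frame(wtp = wtp_grid, prob_cost_effective = pce)
}

#' Patient-assistance-programme scenario
#'
#' Switches first-line checkpoint-inhibitor acquisition from list price to
#' the assistance programme: a fixed annual fee prorated per cycle, capped
#' at the programme's lifetime total.  All other parameters are untouched.
#'
#' @param params a \code{cea_params} with a \code{pap} section.
#' @return modified \code{cea_params}.
#' @export
apply_scenario_pap <- function(params) {
  if (is.null(params$pap)) {
    stop("parameter set has no patient-assistance-programme section",
         call. = FALSE)
  }
  params$pap$enabled <- TRUE
  params
}
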