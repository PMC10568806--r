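#' Discount factor at a point in time
#'
#' Annual discounting on a day scale: \eqn{(1 + r)^{-t/365.25}}.
#'
#' @param time_days time in days (>= 0).
#' @param annual_rate annual discount rate (>= 0).
#' @return discount factor(s) in (0, 1].
#' @examples
#' discount_factor(365.25, 0.05)  # 1/1.05
#' @export
discount_factor <- function(time_days, annual_rate) {
  stopifnot(all(time_days >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-time_days / 365.25)
}

#' Build the cohort trace of a partitioned survival model
#'
#' State occupancy is read directly off the two survival curves at each
#' cycle boundary: progression-free is \eqn{\min(S_{PFS}, S_{OS})} (the
#' clamp guards against crossing extrapolations), progressed is
#' \eqn{S_{OS} - S_{PFS}} after clamping, dead is \eqn{1 - S_{OS}}.  The
#' trace runs until overall survival first drops below the lifetime-horizon
#' threshold (fewer than 1\% survivors by default) or the hard cap in years.
#'
#' @param s_pfs,s_os survival evaluators: either \code{surv_fit} objects or
#'   functions of time in days returning probabilities.
#' @param params a \code{cea_params}.
#' @return \code{data.frame} with columns \code{cycle}, \code{time_days},
#'   \code{pfs}, \code{pd}, \code{dead}; occupancies sum to 1 each cycle.
#' @export
build_trace <- function(s_pfs, s_os, params) {
  f_pfs <- as_surv_evaluator(s_pfs)
  f_os <- as_surv_evaluator(s_os)
  k_cap <- ceiling(params$horizon_cap_years * 365.25 / params$cycle_days)
  tt <- params$cycle_days * (0:k_cap)
  spfs <- f_pfs(tt)
  sos <- f_os(tt)
  bad <- !is.finite(spfs) | !is.finite(sos) | spfs < 0 | spfs > 1 |
    sos < 0 | sos > 1
  if (any(bad)) {
    stop("survival evaluator returned values outside [0, 1] at t = ",
         tt[which(bad)[1]], call. = FALSE)
  }
  pfs <- pmin(spfs, sos)
  hit <- which(sos < params$horizon_threshold)
  last <- if (length(hit) > 0) hit[1] else k_cap + 1L
  idx <- seq_len(last)
  data.frame(cycle = 0:(last - 1L), time_days = tt[idx], pfs = pfs[idx],
             pd = sos[idx] - pfs[idx], dead = 1 - sos[idx])
}

as_surv_evaluator <- function(x) {
  if (inherits(x, "surv_fit")) {
    return(function(t) survival_at(x, t))
  }
  if (is.function(x)) return(x)
  stop("survival evaluator must be a surv_fit or a function of time",
       call. = FALSE)
}

#' One-off adverse-event burden of an arm
#'
#' Expected cost and QALY loss of grade 3-4 adverse events, each the
#' incidence-weighted sum over events; both are charged once, in the first
#' cycle, undiscounted.
#'
#' @param incidence named incidence vector (probabilities).
#' @param cost named per-event management costs, USD.
#' @param disutility named disutility decrements (negative values; the
#'   magnitude is used).
#' @return list with \code{cost} (USD) and \code{qaly_loss} (QALYs).
#' @export
ae_burden <- function(incidence, cost, disutility) {
  stopifnot(all(incidence >= 0 & incidence <= 1))
  nm <- names(incidence)
  list(cost = sum(incidence * cost[nm]),
       qaly_loss = sum(incidence * abs(disutility[nm])))
}

#' Accrue costs and effects over a cohort trace
#'
#' Cycle sums approximate the continuous integrals with the configured
#' integration rule (trapezoid by default: the average of start- and
#' end-of-cycle occupancy, discounted at the cycle midpoint; the
#' "endpoint" alternative uses end-of-cycle occupancy discounted at the
#' cycle end).  Life-years and QALYs accrue on the alive states with the
#' state utilities; drug acquisition and administration accrue on the
#' progression-free occupancy (treatment to progression) using the arm's
#' first-line schedule; follow-up accrues on all alive states; treatment
#' after progression accrues on the progressed occupancy; the adverse-event
#' burden is added once in cycle 1, undiscounted.
#'
#' @param trace cohort trace from \code{\link{build_trace}}.
#' @param arm "P" or "C".
#' @param params a \code{cea_params}.
#' @return object of class \code{arm_outcome}: discounted and undiscounted
#'   life-years and QALYs, cost components (acquisition, administration,
#'   followup, ae, subsequent) and their total, all USD.
#' @export
accrue_outcomes <- function(trace, arm, params) {
  k <- nrow(trace) - 1L
  if (k < 1L) stop("trace must contain at least one full cycle",
                   call. = FALSE)
  first <- seq_len(k)
  second <- first + 1L
  if (identical(params$integration, "trapezoid")) {
    agg <- function(x) (x[first] + x[second]) / 2
    t_disc <- (trace$time_days[first] + trace$time_days[second]) / 2
  } else {
    agg <- function(x) x[second]
    t_disc <- trace$time_days[second]
  }
  df <- discount_factor(t_disc, params$discount_rate)
  dt <- params$cycle_days / 365.25
  o_pfs <- agg(trace$pfs)
  o_pd <- agg(trace$pd)
  o_alive <- o_pfs + o_pd

  sched <- firstline_schedule(arm, params, k)
  subs <- subsequent_cycle_cost(arm, params, k)
  aeb <- ae_burden(params$ae$incidence[[arm]], params$ae$cost,
                   params$ae$disutility)

  ly_disc <- sum(o_alive * dt * df)
  ly_undisc <- sum(o_alive * dt)
  q_states_disc <- sum((o_pfs * params$utility$pfs +
                          o_pd * params$utility$pd) * dt * df)
  q_states_undisc <- sum((o_pfs * params$utility$pfs +
                            o_pd * params$utility$pd) * dt)
  comp <- c(
    acquisition = sum(o_pfs * sched$acquisition * df),
    administration = sum(o_pfs * sched$attendances * params$admin_cost * df),
    followup = sum(o_alive * params$followup_cost * df),
    ae = aeb$cost,
    subsequent = sum(o_pd * subs * df))
  structure(list(arm = arm,
                 ly = ly_disc, ly_undisc = ly_undisc,
                 qaly = q_states_disc - aeb$qaly_loss,
                 qaly_undisc = q_states_undisc - aeb$qaly_loss,
                 cost_components = comp,
                 total_cost = sum(comp)),
            class = "arm_outcome")
}

#' Summary-level arm outcome
#'
#' Constructor for an \code{arm_outcome} holding only reported totals, e.g.
#' when recomputing incremental results from a published per-arm table.
#'
#' @param total_cost total cost, USD.
#' @param ly discounted life-years.
#' @param qaly discounted QALYs.
#' @param arm optional label.
#' @return \code{arm_outcome}.
#' @export
arm_outcome <- function(total_cost, ly, qaly, arm = NA_character_) {
  structure(list(arm = arm, ly = ly, ly_undisc = NA_real_, qaly = qaly,
                 qaly_undisc = NA_real_,
                 cost_components = c(total = total_cost),
                 total_cost = total_cost),
            class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("Arm %s: cost $%.2f, %.3f LY, %.3f QALY (discounted)\n",
              x$arm, x$total_cost, x$ly, x$qaly))
  invisible(x)
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' Differences are experimental minus comparator.  When the incremental
#' cost and effect share a sign the comparison is interior and the ICER is
#' their ratio; a strategy that is cheaper and at least as effective is
#' dominant, one that is costlier and no more effective is dominated (the
#' ICER is then reported as not applicable).  A zero QALY difference with a
#' non-zero cost difference is flagged undefined rather than divided.
#' \code{icer_value} always carries the raw cost/QALY ratio whenever the
#' QALY difference is non-zero (negative for cost-saving comparisons),
#' which is what tornado and threshold analyses plot.
#'
#' @param p,c \code{arm_outcome} objects (experimental, comparator).
#' @return object of class \code{ce_result} with \code{delta_cost},
#'   \code{delta_ly}, \code{delta_qaly}, \code{icer_per_qaly},
#'   \code{icer_per_ly}, \code{icer_value}, \code{dominance}.
#' @export
icer <- function(p, c) {
  dC <- p$total_cost - c$total_cost
  dLY <- p$ly - c$ly
  dQ <- p$qaly - c$qaly
  dominance <- if (dQ >= 0 && dC <= 0 && (dQ > 0 || dC < 0)) {
    "dominant"
  } else if (dQ <= 0 && dC >= 0 && (dQ < 0 || dC > 0)) {
    "dominated"
  } else if (dQ == 0 && dC == 0) {
    "undefined"
  } else {
    "interior"
  }
  ratio <- if (dQ != 0) dC / dQ else NA_real_
  structure(list(
    delta_cost = dC, delta_ly = dLY, delta_qaly = dQ,
    icer_per_qaly = if (dominance == "interior") ratio else NA_real_,
    icer_per_ly = if (dominance == "interior" && dLY != 0) dC / dLY else
      NA_real_,
    icer_value = ratio,
    dominance = dominance), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf(paste0("Incremental: cost $%.2f, %.3f LY, %.3f QALY",
                     " (%s)\n"),
              x$delta_cost, x$delta_ly, x$delta_qaly, x$dominance))
  if (x$dominance == "interior") {
    cat(sprintf("ICER: $%.2f per QALY", x$icer_per_qaly))
    if (!is.na(x$icer_per_ly)) cat(sprintf(", $%.2f per LY", x$icer_per_ly))
    cat("\n")
  }
  invisible(x)
}

#' Run the partitioned survival model for both arms
#'
#' @param fits nested list \code{list(P = list(PFS = , OS = ), C = ...)} of
#'   \code{surv_fit} objects or evaluator functions.
#' @param params a \code{cea_params}.
#' @return list with per-arm \code{arm_outcome}s (\code{P}, \code{C}), the
#'   incremental \code{ce} result, and the two cohort \code{traces}.
#' @export
run_psm <- function(fits, params) {
  for (arm in c("P", "C")) {
    for (ep in c("PFS", "OS")) {
      if (is.null(fits[[arm]][[ep]])) {
        stop("missing survival input for arm ", arm, " endpoint ", ep,
             call. = FALSE)
      }
    }
  }
  traces <- lapply(c(P = "P", C = "C"), function(a) {
    build_trace(fits[[a]]$PFS, fits[[a]]$OS, params)
  })
  out <- lapply(c(P = "P", C = "C"), function(a) {
    accrue_outcomes(traces[[a]], a, params)
  })
  list(P = out$P, C = out$C, ce = icer(out$P, out$C), traces = traces)
}

#' Model evaluator closure over fixed survival curves
#'
#' Returns a function of a parameter set that reruns the partitioned
#' survival model on the given (fixed) curves and returns the incremental
#' result; the interface the sensitivity analyses consume.  Survival-curve
#' uncertainty is deliberately not part of the parameter set.
#'
#' @inheritParams run_psm
#' @return function: \code{cea_params} -> \code{ce_result}.
#' @export
psm_evaluator <- function(fits) {
  function(params) run_psm(fits, params)$ce
}
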