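#' Configuration for the synthetic two-arm trial generator
#'
#' Builds and validates the configuration of the synthetic trial that stands
#' in for a two-arm first-line study in dMMR/MSI-H metastatic colorectal
#' cancer.  The defaults emulate the published trial conditions: median PFS
#' of about 16.5 months in the experimental (P) arm with a pronounced
#' long-term plateau, 8.2 months in the chemotherapy (C) arm, staggered
#' accrual with long administrative follow-up (median around 44 months), and
#' a small loss-to-follow-up hazard.
#'
#' @param n_per_arm subjects per arm (>= 2).  Default 154, a typical per-arm
#'   size for a phase-3 trial of this kind.
#' @param pfs_family_P,pfs_family_C progression-free survival generators per
#'   arm: a list with elements \code{family} (one of
#'   \code{\link{surv_families}()}) and \code{params} (natural-scale
#'   parameter vector, times in days).
#' @param post_progression_rate exponential hazard of death after
#'   progression, per month.  Default \code{log(2)/24}: 24-month median
#'   post-progression survival.
#' @param accrual_months uniform accrual window, months.
#' @param admin_followup_months additional follow-up after accrual closes,
#'   months; the administrative censoring time of a subject entering at time
#'   e is \code{accrual - e + admin_followup}.  May be \code{Inf}.
#' @param dropout_rate exponential loss-to-follow-up hazard, per month.
#' @param seed integer RNG seed used by \code{\link{simulate_trial}}.
#' @return an object of class \code{trial_sim_config}.
#' @examples
#' cfg <- trial_sim_config(n_per_arm = 50, seed = 7)
#' ipd <- simulate_trial(cfg)
#' head(ipd)
#' @export
trial_sim_config <- function(n_per_arm = 154L,
                             pfs_family_P = list(
                               family = "loglogistic",
                               params = c(shape = 0.63,
                                          scale = months_to_days(16.5))),
                             pfs_family_C = list(
                               family = "lognormal",
                               params = c(meanlog = log(months_to_days(8.2)),
                                          sdlog = 1.65)),
                             post_progression_rate = log(2) / 24,
                             accrual_months = 24,
                             admin_followup_months = 33,
                             dropout_rate = 0.002,
                             seed = 1L) {
  cfg <- list(n_per_arm = as.integer(n_per_arm),
              pfs_family_P = pfs_family_P, pfs_family_C = pfs_family_C,
              post_progression_rate = post_progression_rate,
              accrual_months = accrual_months,
              admin_followup_months = admin_followup_months,
              dropout_rate = dropout_rate, seed = as.integer(seed))
  check_sim_config(cfg)
  class(cfg) <- "trial_sim_config"
  cfg
}

check_sim_config <- function(cfg) {
  if (!is.finite(cfg$n_per_arm) || cfg$n_per_arm < 2) {
    stop("n_per_arm: must be an integer >= 2", call. = FALSE)
  }
  for (fld in c("post_progression_rate", "dropout_rate", "accrual_months",
                "admin_followup_months")) {
    if (!is.numeric(cfg[[fld]]) || length(cfg[[fld]]) != 1 ||
        is.na(cfg[[fld]]) || cfg[[fld]] < 0) {
      stop(fld, ": must be a single non-negative number", call. = FALSE)
    }
  }
  for (fld in c("pfs_family_P", "pfs_family_C")) {
    fam <- cfg[[fld]]
    if (!is.list(fam) || is.null(fam$family) || is.null(fam$params)) {
      stop(fld, ": must be a list with elements 'family' and 'params'",
           call. = FALSE)
    }
    if (!fam$family %in% surv_families()) {
      stop(fld, ": unknown survival family '", fam$family, "'",
           call. = FALSE)
    }
    if (!surv_params_ok(fam$family, fam$params)) {
      stop(fld, ": invalid parameters for family '", fam$family, "'",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Simulate a two-arm trial as individual patient data
#'
#' Draws per-subject progression and death times and applies the trial's
#' censoring mechanisms.  Each subject contributes one PFS and one OS record;
#' overall survival is progression time plus an exponential post-progression
#' survival time, so the OS time of a subject is never below the PFS time.
#' Censoring is the minimum of loss to follow-up and the administrative
#' cut-off implied by staggered accrual; a record is an event iff the event
#' time does not exceed the censoring time (ties count as events).
#'
#' @param config a \code{\link{trial_sim_config}}.
#' @return an IPD table: \code{data.frame} with columns \code{subject_id},
#'   \code{arm} ("P"/"C"), \code{endpoint} ("PFS"/"OS"), \code{time_days}
#'   (> 0) and \code{event} (0/1).
#' @export
simulate_trial <- function(config) {
  check_sim_config(config)
  set.seed(config$seed)
  per_day <- function(rate_month) rate_month / 30.4375
  accrual_d <- months_to_days(config$accrual_months)
  fu_d <- months_to_days(config$admin_followup_months)

  one_arm <- function(arm, fam, id0) {
    n <- config$n_per_arm
    pfs <- surv_rand(fam$family, fam$params, n)
    pp_rate <- per_day(config$post_progression_rate)
    pp <- if (is.infinite(config$post_progression_rate)) {
      rep(0, n)
    } else if (pp_rate > 0) {
      stats::rexp(n, rate = pp_rate)
    } else {
      rep(Inf, n)
    }
    os <- pfs + pp
    entry <- if (accrual_d > 0) stats::runif(n, 0, accrual_d) else rep(0, n)
    admin <- accrual_d - entry + fu_d
    drop_rate <- per_day(config$dropout_rate)
    dropout <- if (drop_rate > 0) stats::rexp(n, rate = drop_rate) else
      rep(Inf, n)
    cens <- pmin(admin, dropout)
    ids <- id0 + seq_len(n)
    rbind(
      data.frame(subject_id = ids, arm = arm, endpoint = "PFS",
                 time_days = pmin(pfs, cens),
                 event = as.integer(pfs <= cens)),
      data.frame(subject_id = ids, arm = arm, endpoint = "OS",
                 time_days = pmin(os, cens),
                 event = as.integer(os <= cens))
    )
  }
  ipd <- rbind(one_arm("P", config$pfs_family_P, 0L),
               one_arm("C", config$pfs_family_C, config$n_per_arm))
  if (any(!is.finite(ipd$time_days))) {
    stop("simulated times are not finite; with post_progression_rate = 0 ",
         "at least one censoring mechanism must be active", call. = FALSE)
  }
  rownames(ipd) <- NULL
  ipd
}

ipd_subset <- function(ipd, arm, endpoint) {
  sub <- ipd[ipd$arm == arm & ipd$endpoint == endpoint, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no records for arm '", arm, "' endpoint '", endpoint, "'",
         call. = FALSE)
  }
  sub
}

#' Kaplan-Meier estimate as a step curve
#'
#' Product-limit estimate for one arm and endpoint of an IPD table, via
#' \code{\link[survival]{survfit}}.  Events precede censorings at tied times
#' (the standard convention).  A time-0 anchor with survival 1 and the full
#' cohort at risk is prepended.
#'
#' @param ipd IPD table as returned by \code{\link{simulate_trial}} or
#'   \code{\link{reconstruct_ipd}}.
#' @param arm,endpoint selection labels.
#' @return \code{data.frame} with columns \code{time_days}, \code{survival},
#'   \code{n_at_risk}, one row per distinct observed time plus the anchor.
#' @export
km_estimate <- function(ipd, arm, endpoint) {
  sub <- ipd_subset(ipd, arm, endpoint)
  sf <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = sub)
  data.frame(time_days = c(0, sf$time),
             survival = c(1, sf$surv),
             n_at_risk = c(sf$n, sf$n.risk))
}

#' Median of a Kaplan-Meier step curve
#'
#' First time at which the estimated survival drops to 0.5 or below
#' (NA if it never does).
#'
#' @param curve a step curve from \code{\link{km_estimate}}.
#' @return time in days.
#' @export
km_median <- function(curve) {
  i <- which(curve$survival <= 0.5)
  if (length(i) == 0) NA_real_ else curve$time_days[min(i)]
}

#' Emulate digitisation of a survival curve
#'
#' Samples a Kaplan-Meier step function on a regular time grid plus every
#' step location, optionally perturbs the read-off values with Gaussian
#' jitter (mimicking plot-extraction error), truncates to [0, 1] and restores
#' monotonicity by isotonic regression so the output satisfies the digitised
#' curve invariants (starts at (0, 1), non-increasing).
#'
#' @param curve step curve with columns \code{time_days}, \code{survival}.
#' @param grid_step grid spacing in days (> 0).
#' @param jitter_sd standard deviation of the read-off noise, on the
#'   probability scale (>= 0).
#' @param seed optional RNG seed for the jitter; the current stream is used
#'   when NULL.
#' @return \code{data.frame(time_days, survival)}.
#' @export
digitize_curve <- function(curve, grid_step, jitter_sd = 0, seed = NULL) {
  stopifnot(grid_step > 0, jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  tmax <- max(curve$time_days)
  grid <- sort(unique(c(seq(0, tmax, by = grid_step), curve$time_days)))
  idx <- findInterval(grid, curve$time_days)
  s <- curve$survival[pmax(idx, 1L)]
  if (jitter_sd > 0) {
    s <- s + stats::rnorm(length(s), 0, jitter_sd)
    s <- pmin(pmax(s, 0), 1)
    s <- -stats::isoreg(grid, -s)$yf
    s <- pmin(pmax(s, 0), 1)
  }
  s[1] <- 1
  data.frame(time_days = grid, survival = s)
}

#' Number-at-risk table for an arm and endpoint
#'
#' Counts subjects still at risk (observed time >= boundary) at 0, interval,
#' 2 interval, ...; the companion input the pseudo-IPD reconstruction needs
#' alongside a digitised curve.
#'
#' @inheritParams km_estimate
#' @param interval_days boundary spacing in days (> 0).
#' @return \code{data.frame(time_days, n_at_risk)}.
#' @export
make_risk_table <- function(ipd, arm, endpoint, interval_days) {
  stopifnot(interval_days > 0)
  sub <- ipd_subset(ipd, arm, endpoint)
  bounds <- seq(0, interval_days * ceiling(max(sub$time_days) / interval_days),
                by = interval_days)
  data.frame(time_days = bounds,
             n_at_risk = vapply(bounds,
                                function(b) sum(sub$time_days >= b), 0L))
}
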