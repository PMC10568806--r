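#' Clean a digitised survival curve
#'
#' Pre-processing applied to raw plot-extracted coordinates before
#' reconstruction: orders by time, clamps survival to [0, 1], enforces
#' monotone non-increase by isotonic (pool-adjacent-violators) regression,
#' deduplicates equal times keeping the lower survival, and anchors the
#' curve at (0, 1).  Idempotent on an already-clean curve.
#'
#' @param raw \code{data.frame} with columns \code{time_days} (>= 0) and
#'   \code{survival}; at least two distinct times.
#' @return cleaned \code{data.frame(time_days, survival)} starting at (0, 1).
#' @examples
#' raw <- data.frame(time_days = c(10, 20, 30, 40),
#'                   survival = c(1.0, 0.8, 0.85, 0.6))
#' clean_curve(raw)   # middle values pooled to 0.825
#' @export
clean_curve <- function(raw) {
  stopifnot(is.data.frame(raw), all(c("time_days", "survival") %in%
                                      names(raw)))
  keep <- stats::complete.cases(raw[, c("time_days", "survival")])
  tt <- raw$time_days[keep]
  ss <- raw$survival[keep]
  if (length(tt) < 2 || any(tt < 0)) {
    stop("need at least two points with non-negative times", call. = FALSE)
  }
  if (length(unique(tt)) == 1) {
    stop("all points share a single time; cannot form a curve",
         call. = FALSE)
  }
  o <- order(tt, -ss)
  tt <- tt[o]
  ss <- pmin(pmax(ss[o], 0), 1)
  ss <- -stats::isoreg(seq_along(tt), -ss)$yf  # PAVA, non-increasing in time
  ss <- pmin(pmax(ss, 0), 1)
  last <- !duplicated(tt, fromLast = TRUE)    # keep lower survival per time
  tt <- tt[last]
  ss <- ss[last]
  if (tt[1] > 0) {
    tt <- c(0, tt)
    ss <- c(1, ss)
  } else {
    ss[1] <- 1
  }
  data.frame(time_days = tt, survival = ss)
}

# Process the digitised points of one risk-table interval.
#
# The number censored in the interval (ncen) is fixed by the outer
# iteration; what remains free is where, within the interval, those
# censorings sit relative to the curve steps.  Under "uniform" allocation
# (the classical assumption) they sit at the interior quantile midpoints
# and leave the risk set strictly before the next later click, so events
# precede censorings at tied times.  Under "adaptive" allocation (the
# default) the count consumed before each click is chosen, near its
# uniform expectation, to minimise the gap between the running
# product-limit estimate and the input curve -- this matters in sparse
# tails, where a one-subject misplacement moves the curve by S/n.
# Either way the interval's totals, and hence the boundary risk-set
# match, are identical, and event counts follow from the running
# product-limit identity with cumulative (drift-free) rounding.
walk_interval <- function(km, nn, idx, t, S, ncen, t0, t1,
                          allocation = "adaptive") {
  d <- integer(length(idx))
  cens_t <- numeric(0)
  rem <- ncen                       # censorings not yet placed
  t_prev <- t0
  grid <- if (ncen > 0) t0 + (seq_len(ncen) - 0.5) / ncen * (t1 - t0) else
    numeric(0)
  used <- 0L
  for (k in seq_along(idx)) {
    i <- idx[k]
    # uniform expectation: censorings whose midquantile time precedes the
    # click
    c_unif <- sum(grid[seq_len(ncen) > used] < t[i])
    ck <- c_unif
    dk <- 0L
    if (km > 0 && nn > 0) {
      pick_d <- function(m) {
        if (m <= 0) return(0L)
        max(0L, min(as.integer(round(m * (1 - S[i] / km))), m))
      }
      if (allocation == "adaptive" && rem > 0) {
        best <- Inf
        for (cc in 0:rem) {
          m <- nn - cc
          dd <- pick_d(m)
          ach <- if (m > 0) km * (1 - dd / m) else km
          score <- abs(ach - S[i]) + 1e-9 * abs(cc - c_unif)
          if (score < best - 1e-15) {
            best <- score
            ck <- cc
            dk <- dd
          }
        }
      } else {
        ck <- min(c_unif, rem)
        dk <- pick_d(nn - ck)
      }
    } else {
      ck <- min(c_unif, rem)
    }
    if (ck > 0) {
      # censor times spread over the gap before this click
      cens_t <- c(cens_t, t_prev + (seq_len(ck) - 0.5) / ck *
                    (t[i] - t_prev))
      nn <- nn - ck
      rem <- rem - ck
      used <- used + ck
    }
    if (dk > 0) {
      km <- km * (1 - dk / nn)
      nn <- nn - dk
    }
    d[k] <- dk
    t_prev <- t[i]
  }
  if (rem > 0) {                    # censorings after the last click
    cens_t <- c(cens_t, t_prev + (seq_len(rem) - 0.5) / rem *
                  (t1 - t_prev))
    nn <- nn - rem
  }
  list(km = km, nn = nn, d = d, cens_t = cens_t)
}

#' Reconstruct pseudo individual patient data from a digitised curve
#'
#' Inverts the Kaplan-Meier construction: given plot-extracted survival
#' coordinates and the published number-at-risk table, recovers a
#' subject-level (time, event) dataset whose product-limit estimate tracks
#' the input curve and whose risk set matches the table at every boundary.
#' Within each risk-table interval the number censored is found iteratively
#' (censoring assumed uniform over the interval, placed at interior quantile
#' midpoints); integer event counts at the curve steps follow from the
#' running product-limit identity.  After the last click, all subjects still
#' at risk are censored at the final observed time.  The procedure is fully
#' deterministic.
#'
#' @param curve digitised curve (\code{time_days}, \code{survival});
#'   cleaned with \code{\link{clean_curve}} first (cleaning is idempotent,
#'   so passing an already-clean curve is fine).
#' @param risk number-at-risk table (\code{time_days}, \code{n_at_risk})
#'   with the first row at time 0 carrying the cohort size, counts
#'   non-increasing.  When NULL, \code{n_start} must be given and no
#'   censoring before the last follow-up time is assumed (with a warning).
#' @param total_events optional total event count; when supplied, event
#'   counts in the final interval are rescaled (cumulative re-rounding) so
#'   the reconstruction matches it.
#' @param n_start cohort size, used only when \code{risk} is NULL.
#' @param arm,endpoint labels stamped on the output records.
#' @param censoring within-interval censoring placement: \code{"adaptive"}
#'   (default) chooses, near the uniform expectation, how many of the
#'   interval's censorings precede each curve step so the reconstructed
#'   product-limit estimate hugs the input curve — the interval totals and
#'   boundary risk-set matches are unchanged; \code{"uniform"} is the
#'   classical interior-quantile-midpoint placement.
#' @return IPD table (\code{subject_id}, \code{arm}, \code{endpoint},
#'   \code{time_days}, \code{event}) with exactly \code{risk$n_at_risk[1]}
#'   rows.
#' @references The iterative inversion follows the published algorithm for
#'   recreating patient-level data from survival plots and at-risk tables.
#' @export
reconstruct_ipd <- function(curve, risk = NULL, total_events = NULL,
                            n_start = NULL, arm = NA_character_,
                            endpoint = NA_character_,
                            censoring = c("adaptive", "uniform")) {
  censoring <- match.arg(censoring)
  curve <- clean_curve(curve)
  if (is.null(risk)) {
    if (is.null(n_start)) {
      stop("supply a number-at-risk table or n_start", call. = FALSE)
    }
    warning("no number-at-risk table supplied; assuming no censoring ",
            "before the last follow-up time", call. = FALSE)
    risk <- data.frame(time_days = 0, n_at_risk = as.integer(n_start))
  }
  stopifnot(is.data.frame(risk),
            all(c("time_days", "n_at_risk") %in% names(risk)))
  risk <- risk[order(risk$time_days), , drop = FALSE]
  if (nrow(risk) == 0 || risk$time_days[1] != 0) {
    stop("risk table must start at time 0", call. = FALSE)
  }
  if (risk$n_at_risk[1] <= 0) {
    stop("risk table's first count must be positive", call. = FALSE)
  }
  if (any(diff(risk$n_at_risk) > 0)) {
    j <- which(diff(risk$n_at_risk) > 0)[1]
    stop("infeasible risk table: count increases at interval ", j,
         " (t = ", risk$time_days[j + 1], ")", call. = FALSE)
  }

  t <- curve$time_days
  S <- curve$survival
  N <- length(t)
  trisk <- risk$time_days
  nrisk <- as.integer(risk$n_at_risk)
  J <- length(trisk)
  # boundaries beyond the digitised span still constrain tail censoring;
  # they hold no clicks (sentinel index N + 1)
  lower <- vapply(trisk, function(b) {
    i <- which(t >= b)[1]
    if (is.na(i)) N + 1L else i
  }, 0L)

  km <- 1
  nn <- nrisk[1]
  ev_times <- numeric(0)
  cens_times <- numeric(0)
  last_d <- NULL      # event counts of the final interval (for total_events)
  last_idx <- NULL

  for (j in seq_len(J)) {
    i1 <- lower[j]
    i2 <- if (j < J) min(lower[j + 1] - 1L, N) else N
    idx <- if (i2 >= i1 && i1 <= N) seq(i1, i2) else integer(0)
    t_end <- if (j < J) trisk[j + 1] else max(t[N], trisk[j])
    if (j < J) {
      s_entry <- S[min(i1, N)]
      s_next <- S[min(lower[j + 1], N)]
      ncen <- if (s_entry > 0) {
        as.integer(round(nn * s_next / s_entry)) - nrisk[j + 1]
      } else 0L
      res <- NULL
      for (iter in 1:60) {
        ncen <- max(0L, min(ncen, nn))
        res <- walk_interval(km, nn, idx, t, S, ncen, trisk[j], t_end,
                             allocation = censoring)
        gap <- res$nn - nrisk[j + 1]
        if (gap == 0L) break
        new_ncen <- ncen + gap
        if (max(0L, min(new_ncen, nn)) == ncen) break
        ncen <- new_ncen
      }
      if (abs(res$nn - nrisk[j + 1]) > 1L) {
        stop("reconstruction infeasible in interval ", j,
             " (t = ", trisk[j], " to ", t_end, "): risk table implies ",
             "a negative number of censorings", call. = FALSE)
      }
    } else {
      res <- walk_interval(km, nn, idx, t, S, 0L, trisk[j], t_end,
                           allocation = censoring)
      last_d <- res$d
      last_idx <- idx
    }
    km <- res$km
    nn <- res$nn
    ev_times <- c(ev_times, rep(t[idx], res$d))
    cens_times <- c(cens_times, res$cens_t)
  }

  if (!is.null(total_events) && length(last_idx) > 0) {
    done_before <- length(ev_times) - sum(last_d)
    target_last <- max(0L, as.integer(total_events) - done_before)
    if (target_last != sum(last_d) && sum(last_d) > 0) {
      scaled <- cumsum(last_d) * target_last / sum(last_d)
      new_d <- diff(c(0L, as.integer(round(scaled))))
      avail <- nrisk[J] - sum(cens_times >= trisk[J])
      while (sum(new_d) > avail) new_d[which.max(new_d)] <-
          new_d[which.max(new_d)] - 1L
      ev_times <- c(ev_times[seq_len(done_before)],
                    rep(t[last_idx], new_d))
      nn <- avail - sum(new_d)
    }
  }

  # everyone still at risk is censored administratively at the last time
  cens_times <- c(cens_times, rep(t[N], nn))
  out <- data.frame(
    time_days = c(ev_times, cens_times),
    event = rep(c(1L, 0L), c(length(ev_times), length(cens_times))))
  out <- out[order(out$time_days, -out$event), , drop = FALSE]
  data.frame(subject_id = seq_len(nrow(out)), arm = arm,
             endpoint = endpoint, time_days = out$time_days,
             event = out$event, row.names = NULL)
}

#' Evaluate a step curve at arbitrary times
#'
#' Left-continuous step-function evaluation of a Kaplan-Meier or digitised
#' curve: the value at time t is the survival at the latest tabulated time
#' not exceeding t.
#'
#' @param curve \code{data.frame(time_days, survival)} sorted by time.
#' @param t vector of times.
#' @return vector of survival values.
#' @export
step_curve_at <- function(curve, t) {
  idx <- findInterval(t, curve$time_days)
  ifelse(idx < 1, 1, curve$survival[pmax(idx, 1L)])
}
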