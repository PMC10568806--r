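#' Cost of one administration of a regimen component
#'
#' Converts a protocol dose to milligrams using the dosing basis
#' (per square metre of body surface area, per kilogram of body weight, or
#' flat) and multiplies by the unit price.  No vial rounding is applied.
#'
#' @param component list with \code{drug}, \code{basis} (one of
#'   \code{"per_m2"}, \code{"per_kg"}, \code{"flat"}) and \code{dose}.
#' @param prices named vector of unit prices, USD per mg.
#' @param bsa body surface area, m^2.
#' @param weight body weight, kg.
#' @return cost in USD.
#' @examples
#' regimen_cost_per_admin(list(drug = "bevacizumab", basis = "per_kg",
#'                             dose = 5),
#'                        c(bevacizumab = 15), bsa = 1.8, weight = 65)
#' @export
regimen_cost_per_admin <- function(component, prices, bsa, weight) {
  if (!component$drug %in% names(prices) || is.na(prices[[component$drug]])) {
    stop("no unit price for drug '", component$drug, "'", call. = FALSE)
  }
  mg <- switch(component$basis,
    per_m2 = component$dose * bsa,
    per_kg = component$dose * weight,
    flat = component$dose,
    stop("unknown dosing basis '", component$basis, "'", call. = FALSE))
  mg * prices[[component$drug]]
}

backbone_cost <- function(components, prices, bsa, weight) {
  sum(vapply(components, regimen_cost_per_admin, 0, prices = prices,
             bsa = bsa, weight = weight))
}

folfox_components <- function(d) {
  list(list(drug = "oxaliplatin", basis = "per_m2",
            dose = d$folfox$oxaliplatin_mg_m2),
       list(drug = "leucovorin", basis = "per_m2",
            dose = d$folfox$leucovorin_mg_m2),
       list(drug = "fluorouracil", basis = "per_m2",
            dose = d$folfox$fluorouracil_mg_m2))
}

folfiri_components <- function(d) {
  list(list(drug = "irinotecan", basis = "per_m2",
            dose = d$folfiri$irinotecan_mg_m2),
       list(drug = "leucovorin", basis = "per_m2",
            dose = d$folfiri$leucovorin_mg_m2),
       list(drug = "fluorouracil", basis = "per_m2",
            dose = d$folfiri$fluorouracil_mg_m2))
}

#' Per-cycle first-line schedules of drug-acquisition and attendance costs
#'
#' Builds, for one arm, the scheduled (full-adherence) drug-acquisition cost
#' and attendance count of each model cycle, before multiplication by the
#' progression-free occupancy.  The experimental arm receives the
#' checkpoint inhibitor on its three-weekly schedule up to its maximum
#' number of administrations (the cycle containing the cap is prorated);
#' under the patient-assistance-programme scenario the acquisition cost is
#' replaced by the programme's prorated annual fee up to its lifetime cap.
#' The chemotherapy arm's cost is the mixture-weighted average over the six
#' observed regimens; the EGFR-antibody loading dose applies in cycle 1
#' only, and its weekly infusions add attendances.
#'
#' @param arm "P" or "C".
#' @param params a \code{cea_params}.
#' @param n_cycles number of cycles to schedule.
#' @return list with numeric vectors \code{acquisition} (USD per cycle) and
#'   \code{attendances} (visits per cycle).
#' @export
firstline_schedule <- function(arm, params, n_cycles) {
  d <- params$dosing
  if (arm == "P") {
    pem <- d$pembrolizumab
    if (isTRUE(params$pap$enabled)) {
      per_cycle <- params$pap$annual_cost * params$cycle_days / 365.25
      sched <- pmin(per_cycle,
                    pmax(0, params$pap$cap_total -
                           per_cycle * (seq_len(n_cycles) - 1)))
    } else {
      doses <- pmin(pem$admin_per_cycle,
                    pmax(0, pem$max_administrations -
                           pem$admin_per_cycle * (seq_len(n_cycles) - 1)))
      sched <- doses * pem$dose_mg * params$prices[["pembrolizumab"]]
    }
    att <- rep(pem$attendances_per_cycle, n_cycles)
    return(list(acquisition = sched, attendances = att))
  }
  if (arm != "C") stop("unknown arm '", arm, "'", call. = FALSE)

  pr <- params$prices
  bsa <- params$bsa
  wt <- params$weight
  w <- params$firstline_mix_C
  nadm <- d$chemo_admin_per_cycle
  folfox_cy <- nadm * backbone_cost(folfox_components(d), pr, bsa, wt)
  folfiri_cy <- nadm * backbone_cost(folfiri_components(d), pr, bsa, wt)
  bev_cy <- nadm * regimen_cost_per_admin(
    list(drug = "bevacizumab", basis = "per_kg", dose = d$bevacizumab_mg_kg),
    pr, bsa, wt)
  cet_weekly_cy <- d$cetuximab$weekly_per_cycle * regimen_cost_per_admin(
    list(drug = "cetuximab", basis = "per_m2", dose = d$cetuximab$weekly_mg_m2),
    pr, bsa, wt)
  cet_loading_extra <- regimen_cost_per_admin(
    list(drug = "cetuximab", basis = "per_m2",
         dose = d$cetuximab$loading_mg_m2 - d$cetuximab$weekly_mg_m2),
    pr, bsa, wt)

  base_cy <-
    w[["mfolfox"]] * folfox_cy +
    w[["mfolfox_bev"]] * (folfox_cy + bev_cy) +
    w[["mfolfox_cet"]] * (folfox_cy + cet_weekly_cy) +
    w[["folfiri"]] * folfiri_cy +
    w[["folfiri_bev"]] * (folfiri_cy + bev_cy) +
    w[["folfiri_cet"]] * (folfiri_cy + cet_weekly_cy)
  w_cet <- w[["mfolfox_cet"]] + w[["folfiri_cet"]]
  sched <- rep(base_cy, n_cycles)
  sched[1] <- sched[1] + w_cet * cet_loading_extra
  att <- rep(d$chemo_attendances_per_cycle +
               d$cetuximab_extra_attendances * w_cet, n_cycles)
  list(acquisition = sched, attendances = att)
}

#' Per-cycle cost of treatment after progression
#'
#' The progressed-state treatment cost is modelled as a class-weighted
#' per-cycle cost applied to the progressed occupancy (the memoryless
#' approximation a partitioned survival model admits, since time in state is
#' not tracked per patient).  Class costs use representative regimens:
#' chemotherapy is the simple average of the CAPIRI, CAPOX, FOLFOX and
#' FOLFIRI per-cycle costs; the checkpoint-inhibitor classes price the
#' three-weekly 200 mg and two-weekly 240 mg schedules and stop contributing
#' after the configured cap in cycles (treatment-duration limit, prorated in
#' the cycle containing the cap); the angiogenesis and EGFR antibody classes
#' use their standard schedules.  Best-supportive-care cost (fixed) is added
#' to every cycle.
#'
#' @inheritParams firstline_schedule
#' @return numeric vector of per-cycle costs, USD.
#' @export
subsequent_cycle_cost <- function(arm, params, n_cycles) {
  if (!arm %in% c("P", "C")) stop("unknown arm '", arm, "'", call. = FALSE)
  d <- params$dosing
  pr <- params$prices
  bsa <- params$bsa
  wt <- params$weight
  w <- params$subsequent_mix[[arm]]
  n2 <- d$subsequent_admin_per_cycle

  folfox_cy <- d$chemo_admin_per_cycle *
    backbone_cost(folfox_components(d), pr, bsa, wt)
  folfiri_cy <- d$chemo_admin_per_cycle *
    backbone_cost(folfiri_components(d), pr, bsa, wt)
  cape <- regimen_cost_per_admin(
    list(drug = "capecitabine", basis = "per_m2",
         dose = d$capecitabine_mg_m2_course), pr, bsa, wt)
  capox_cy <- n2 * (cape + regimen_cost_per_admin(
    list(drug = "oxaliplatin", basis = "per_m2",
         dose = d$capox_oxaliplatin_mg_m2), pr, bsa, wt))
  capiri_cy <- n2 * (cape + regimen_cost_per_admin(
    list(drug = "irinotecan", basis = "per_m2",
         dose = d$capiri_irinotecan_mg_m2), pr, bsa, wt))
  chemo_cy <- mean(c(capiri_cy, capox_cy, folfox_cy, folfiri_cy))

  pem <- d$pembrolizumab
  ici_pembro_cy <- pem$admin_per_cycle * pem$dose_mg * pr[["pembrolizumab"]]
  ici_other_cy <- d$nivolumab$admin_per_cycle * d$nivolumab$dose_mg *
    pr[["nivolumab"]]
  vegf_cy <- d$chemo_admin_per_cycle * regimen_cost_per_admin(
    list(drug = "bevacizumab", basis = "per_kg", dose = d$bevacizumab_mg_kg),
    pr, bsa, wt)
  egfr_cy <- d$cetuximab$weekly_per_cycle * regimen_cost_per_admin(
    list(drug = "cetuximab", basis = "per_m2",
         dose = d$cetuximab$weekly_mg_m2), pr, bsa, wt)

  if (params$ici_cap_cycles < 0) {
    stop("subsequent_ici_cap_cycles must be >= 0", call. = FALSE)
  }
  ici_frac <- pmin(1, pmax(0, params$ici_cap_cycles -
                             (seq_len(n_cycles) - 1)))
  w[["chemotherapy"]] * chemo_cy +
    w[["vegf_inhibitor"]] * vegf_cy +
    w[["egfr_inhibitor"]] * egfr_cy +
    ici_frac * (w[["pembrolizumab"]] * ici_pembro_cy +
                  w[["other_ici"]] * ici_other_cy) +
    params$bsc_cost
}
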