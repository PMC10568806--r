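# Shared fixtures, built once per test run.

# default-condition synthetic trial with base-case family binding
synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ipd <- simulate_trial(trial_sim_config(seed = 42L))
      params <- load_config(quiet = TRUE)
      fits <- list(P = list(), C = list())
      binding <- base_case_families()
      for (a in c("P", "C")) {
        for (e in c("PFS", "OS")) {
          dat <- ipd[ipd$arm == a & ipd$endpoint == e, ]
          fits[[a]][[e]] <- suppressMessages(
            fit_parametric(dat, binding[[paste(a, e, sep = "_")]]))
        }
      }
      cache <<- list(ipd = ipd, params = params, fits = fits,
                     model = psm_evaluator(fits))
    }
    cache
  }
})

# parameter set with all costs zeroed and full utilities (effect-only model)
zero_cost_params <- function(params) {
  params$prices[] <- 0
  params$admin_cost <- 0
  params$followup_cost <- 0
  params$bsc_cost <- 0
  params$ae$cost[] <- 0
  params$ae$incidence$P[] <- 0
  params$ae$incidence$C[] <- 0
  params$utility$pfs <- 1
  params$utility$pd <- 1
  params$discount_rate <- 0
  params
}

# multiply every unit cost by s (for scale-equivariance checks)
scale_costs <- function(params, s) {
  params$prices <- params$prices * s
  params$admin_cost <- params$admin_cost * s
  params$followup_cost <- params$followup_cost * s
  params$bsc_cost <- params$bsc_cost * s
  params$ae$cost <- params$ae$cost * s
  params$pap$annual_cost <- params$pap$annual_cost * s
  params$pap$cap_total <- params$pap$cap_total * s
  params
}

exp_evaluator <- function(lambda_per_day) {
  function(t) exp(-lambda_per_day * t)
}
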