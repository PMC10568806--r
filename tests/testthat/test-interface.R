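test_that("the packaged baseline loads cleanly with the published values", {
  expect_no_warning(params <- load_config(quiet = TRUE))
  expect_equal(params$utility$pfs, 0.7825)
  expect_equal(params$utility$pd, 0.64)
  expect_equal(params$prices[["pembrolizumab"]], 179.18)
  expect_equal(params$admin_cost, 310.16)
  expect_equal(params$bsc_cost, 0)
  expect_equal(params$cycle_days, 42)
  expect_equal(params$wtp, 38142.56)
  # mixtures are exact distributions after the rounding renormalisation
  expect_equal(sum(params$firstline_mix_C), 1)
  expect_equal(sum(params$subsequent_mix$P), 1)
  expect_equal(sum(params$subsequent_mix$C), 1)
  reg <- param_registry(params)
  expect_true(all(c("beta", "gamma", "fixed") %in% reg$kind))
  # prices marked fixed are not sampled
  for (dr in c("pembrolizumab", "cetuximab", "nivolumab")) {
    expect_equal(reg$kind[reg$id == paste0("prices.", dr)], "fixed")
  }
})

test_that("invalid and partial configurations are reported by field", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("utility:", "  pd: {base: 1.2}"), bad)
  expect_error(suppressWarnings(load_config(bad, quiet = TRUE)),
               "utility.pd")
  partial <- tempfile(fileext = ".yaml")
  writeLines(c("utility:", "  pfs: {base: 0.8}"), partial)
  expect_warning(params <- load_config(partial, quiet = TRUE),
                 "costs")
  expect_equal(params$utility$pfs, 0.8)
  expect_equal(params$bsc_cost, 0)        # defaulted
  expect_equal(params$utility$pd, 0.64)   # defaulted
})

test_that("parameter paths get and set through the registry ids", {
  params <- synth_fixture()$params
  p2 <- set_param(params, "prices.oxaliplatin", 5)
  expect_equal(get_param(p2, "prices.oxaliplatin"), 5)
  expect_equal(get_param(params, "prices.oxaliplatin"), 3.4)
  expect_equal(get_param(p2, "subsequent_mix.C.other_ici"),
               unname(params$subsequent_mix$C[["other_ici"]]))
})

test_that("delimited readers and writers round-trip", {
  ipd <- synth_fixture()$ipd[1:20, ]
  f <- tempfile(fileext = ".csv")
  write_ipd(ipd, f)
  back <- read_ipd(f)
  expect_equal(back$time_days, ipd$time_days)
  expect_equal(back$event, ipd$event)
  curve <- data.frame(time_days = c(0, 10), survival = c(1, 0.5))
  write_curve(curve, f)
  expect_equal(read_curve(f), curve)
  risk <- data.frame(time_days = c(0, 10), n_at_risk = c(10L, 5L))
  write_risk_table(risk, f)
  expect_equal(read_risk_table(f), risk)
  expect_error(read_ipd(f), "lacks required columns")
})

pipeline_inputs <- function(ipd) {
  curves <- risk <- list(P = list(), C = list())
  for (a in c("P", "C")) {
    for (e in c("PFS", "OS")) {
      km <- km_estimate(ipd, a, e)
      curves[[a]][[e]] <- digitize_curve(km, grid_step = 14, jitter_sd = 0)
      risk[[a]][[e]] <- make_risk_table(ipd, a, e, months_to_days(6))
    }
  }
  list(curves = curves, risk = risk)
}

test_that("the pipeline composes all stages and reproduces itself", {
  ipd <- simulate_trial(trial_sim_config(n_per_arm = 80, seed = 31))
  inputs <- pipeline_inputs(ipd)
  out_dir <- file.path(tempdir(), "psmcea-pipeline")
  res <- suppressMessages(
    run_pipeline(inputs, seed = 4, n_psa = 20, dsa = TRUE,
                 out_dir = out_dir))
  expect_equal(unname(res$manifest$families), unname(base_case_families()))
  expect_length(res$chosen, 4)
  expect_s3_class(res$base_case$ce, "ce_result")
  expect_equal(nrow(res$psa$draws), 20)
  expect_true(all(res$ceac$prob_cost_effective >= 0 &
                    res$ceac$prob_cost_effective <= 1))
  # ranking tables exist for every endpoint
  expect_true(all(vapply(res$fits,
                         function(f) !is.null(attr(f, "ranking")), TRUE)))
  # written artefacts, with unit-bearing headers
  expect_true(file.exists(file.path(out_dir, "summary.csv")))
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  expect_true(file.exists(file.path(out_dir, "tornado.csv")))
  expect_true(file.exists(file.path(out_dir, "ceac.csv")))
  sm <- utils::read.csv(file.path(out_dir, "summary.csv"))
  expect_true(any(grepl("usd", sm$quantity)))
  expect_true("time_days" %in%
                names(utils::read.csv(file.path(out_dir, "trace_P.csv"))))

  # identical rerun: same seed, byte-identical numbers
  res2 <- suppressMessages(
    run_pipeline(inputs, seed = 4, n_psa = 20, dsa = FALSE))
  expect_identical(res$base_case$ce, res2$base_case$ce)
  expect_identical(res$psa$draws, res2$psa$draws)
})

test_that("the pipeline names missing inputs", {
  ipd <- simulate_trial(trial_sim_config(n_per_arm = 40, seed = 32))
  inputs <- pipeline_inputs(ipd)
  inputs$curves$C$OS <- NULL
  expect_error(run_pipeline(inputs), "arm C endpoint OS")
  ipd_miss <- ipd[!(ipd$arm == "P" & ipd$endpoint == "OS"), ]
  expect_error(run_pipeline(list(ipd = ipd_miss)), "arm P endpoint OS")
  expect_error(run_pipeline(list()), "ipd")
})
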