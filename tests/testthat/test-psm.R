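test_that("discounting follows the annual convention on a day scale", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(1234, 0), 1)
  expect_equal(discount_factor(365.25, 0.05), 1 / 1.05)
  expect_error(discount_factor(-1, 0.05))
})

test_that("trace occupancy conserves mass and clamps crossing curves", {
  params <- synth_fixture()$params
  # PFS extrapolation above OS: progression-free clamped to OS, PD zero
  tr <- build_trace(exp_evaluator(0.001), exp_evaluator(0.002), params)
  expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-9))
  expect_true(all(tr$pd == 0))
  expect_equal(tr$pfs, 1 - tr$dead)
  # identical curves: nobody in the progressed state
  tr2 <- build_trace(exp_evaluator(0.002), exp_evaluator(0.002), params)
  expect_true(all(tr2$pd == 0))
  expect_error(build_trace(function(t) rep(1.2, length(t)),
                           exp_evaluator(0.001), params), "outside")
})

test_that("trace stops at the lifetime-horizon threshold", {
  params <- synth_fixture()$params
  lam <- log(2) / 365.25  # one-year median OS
  tr <- build_trace(exp_evaluator(lam), exp_evaluator(lam), params)
  # S(t) < 0.01 first at t = log(100)/lam ~ 6.64 years -> cycle 58
  t_star <- log(100) / lam
  expect_equal(max(tr$cycle), ceiling(t_star / params$cycle_days))
  expect_lt(min(1 - tr$dead), 0.01)
  expect_true(all((1 - tr$dead)[-nrow(tr)] >= 0.01))
  # the hard cap binds when survival never crosses the threshold
  params$horizon_cap_years <- 5
  tr2 <- build_trace(exp_evaluator(1e-6), exp_evaluator(1e-6), params)
  expect_equal(max(tr2$time_days) / 365.25, 5, tolerance = 0.05)
})

test_that("component costing matches hand arithmetic", {
  params <- synth_fixture()$params
  folfox <- list(
    list(drug = "oxaliplatin", basis = "per_m2", dose = 85),
    list(drug = "leucovorin", basis = "per_m2", dose = 400),
    list(drug = "fluorouracil", basis = "per_m2", dose = 2800))
  per_admin <- sum(vapply(folfox, regimen_cost_per_admin, 0,
                          prices = params$prices, bsa = 1.80, weight = 65))
  expect_equal(per_admin, 2161.80)
  expect_equal(regimen_cost_per_admin(
    list(drug = "bevacizumab", basis = "per_kg", dose = 5),
    params$prices, 1.80, 65), 4875.00)
  expect_equal(regimen_cost_per_admin(
    list(drug = "pembrolizumab", basis = "flat", dose = 0),
    params$prices, 1.80, 65), 0)
  expect_error(regimen_cost_per_admin(
    list(drug = "mystery", basis = "flat", dose = 1),
    params$prices, 1.80, 65), "mystery")
})

test_that("adverse-event burden is the incidence-weighted one-off sum", {
  params <- synth_fixture()$params
  aeb <- ae_burden(params$ae$incidence$P, params$ae$cost,
                   params$ae$disutility)
  expect_equal(aeb$cost, 0.06 * 392.44 + 0.05 * 724.64 + 0.01 * 157.28)
  expect_equal(aeb$qaly_loss, 0.06 * 0.09 + 0.05 * 0.085 + 0.01 * 0.08)
  zero <- ae_burden(c(a = 0, b = 0), c(a = 100, b = 50),
                    c(a = -0.1, b = -0.2))
  expect_equal(zero$cost, 0)
  expect_equal(zero$qaly_loss, 0)
})

test_that("treat-to-progression caps stop drug acquisition", {
  params <- synth_fixture()$params
  params$discount_rate <- 0
  # full progression-free occupancy: the 35-administration cap binds at
  # 17.5 cycles (full cost through cycle 17, half in cycle 18, none after)
  tr <- build_trace(function(t) rep(1, length(t)),
                    function(t) rep(1, length(t)), params)
  out <- accrue_outcomes(tr, "P", params)
  expect_equal(unname(out$cost_components["acquisition"]),
               35 * 200 * params$prices[["pembrolizumab"]])
  sched <- firstline_schedule("P", params, 20)
  expect_equal(sched$acquisition[17] / sched$acquisition[18], 2)
  expect_equal(sched$acquisition[19], 0)
})

test_that("discounted life-years match the closed-form exponential oracle", {
  params <- zero_cost_params(synth_fixture()$params)
  params$discount_rate <- 0.05
  lam <- log(2) / months_to_days(18)
  tr <- build_trace(exp_evaluator(lam), exp_evaluator(lam), params)
  out <- accrue_outcomes(tr, "P", params)
  # continuous integral of e^{-lam t} (1+r)^{-t/365.25} over the horizon
  rho <- lam + log(1.05) / 365.25
  t_end <- max(tr$time_days)
  analytic <- (1 - exp(-rho * t_end)) / (rho * 365.25)
  expect_equal(out$ly, analytic, tolerance = 0.005)
  expect_equal(out$qaly, out$ly)  # utilities 1, no adverse events
  expect_equal(out$total_cost, 0)
})

test_that("equal state utilities make QALYs proportional to life-years", {
  params <- synth_fixture()$params
  params$ae$incidence$P[] <- 0
  params$utility$pd <- params$utility$pfs
  fx <- synth_fixture()
  tr <- build_trace(fx$fits$P$PFS, fx$fits$P$OS, params)
  out <- accrue_outcomes(tr, "P", params)
  expect_equal(out$qaly, params$utility$pfs * out$ly)
})

test_that("discounting is monotone in the rate", {
  fx <- synth_fixture()
  vals <- lapply(c(0, 0.05, 0.08), function(r) {
    p <- fx$params
    p$discount_rate <- r
    run_psm(fx$fits, p)
  })
  for (arm in c("P", "C")) {
    cost <- vapply(vals, function(v) v[[arm]]$total_cost, 0)
    qaly <- vapply(vals, function(v) v[[arm]]$qaly, 0)
    expect_true(all(diff(cost) < 0))
    expect_true(all(diff(qaly) < 0))
    expect_lte(vals[[2]][[arm]]$ly, vals[[2]][[arm]]$ly_undisc)
  }
})

test_that("incremental results scale exactly with unit costs", {
  fx <- synth_fixture()
  base <- run_psm(fx$fits, fx$params)$ce
  scaled <- run_psm(fx$fits, scale_costs(fx$params, 3))$ce
  expect_equal(scaled$delta_cost, 3 * base$delta_cost)
  expect_equal(scaled$icer_value, 3 * base$icer_value)
  expect_equal(scaled$delta_qaly, base$delta_qaly)
})

test_that("tightening the horizon threshold barely changes totals", {
  fx <- synth_fixture()
  p2 <- fx$params
  p2$horizon_threshold <- 0.001
  a <- run_psm(fx$fits, fx$params)
  b <- run_psm(fx$fits, p2)
  for (arm in c("P", "C")) {
    expect_lt(abs(b[[arm]]$qaly - a[[arm]]$qaly) / a[[arm]]$qaly, 0.01)
  }
})

test_that("dominance classification follows the cost-effect quadrants", {
  a <- arm_outcome(100, 1, 1)
  expect_equal(icer(arm_outcome(99, 2, 2), a)$dominance, "dominant")
  expect_equal(icer(arm_outcome(101, 0.5, 0.5), a)$dominance, "dominated")
  ce <- icer(arm_outcome(150, 2, 2), a)
  expect_equal(ce$dominance, "interior")
  expect_equal(ce$icer_per_qaly, 50)
  expect_equal(ce$icer_per_ly, 50)
  same <- icer(a, a)
  expect_equal(same$dominance, "undefined")
  expect_true(is.na(same$icer_per_qaly))
  # zero QALY difference with a cost difference: flagged, no division
  odd <- icer(arm_outcome(200, 1, 1), a)
  expect_true(is.na(odd$icer_per_qaly))
  expect_equal(odd$dominance, "dominated")
})

test_that("the engine rejects incomplete inputs", {
  fx <- synth_fixture()
  broken <- fx$fits
  broken$C$OS <- NULL
  expect_error(run_psm(broken, fx$params), "arm C endpoint OS")
})
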