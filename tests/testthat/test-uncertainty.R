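test_that("beta moment matching solves the stated identities", {
  ab <- beta_from_moments(0.5, 0.1)
  expect_equal(unname(ab), c(12, 12))
  # round trip: moments of the resulting beta reproduce the inputs
  for (case in list(c(0.64, 0.033), c(0.1, 0.01), c(0.9, 0.02))) {
    ab <- beta_from_moments(case[1], case[2])
    m <- ab[["alpha"]] / sum(ab)
    v <- prod(ab) / (sum(ab)^2 * (sum(ab) + 1))
    expect_equal(m, case[1], tolerance = 1e-9)
    expect_equal(sqrt(v), case[2], tolerance = 1e-9)
  }
  # concentration limit: alpha + beta explodes, mean preserved
  ab <- beta_from_moments(0.3, 1e-4)
  expect_gt(sum(ab), 1e7)
  expect_equal(ab[["alpha"]] / sum(ab), 0.3)
  expect_error(beta_from_moments(0.5, 0.6), "moment condition")
  expect_error(beta_from_moments(1.2, 0.1), "mean")
})

test_that("gamma moment matching solves the stated identities", {
  sc <- gamma_from_moments(310.16, 77.54)
  expect_equal(sc[["shape"]], 16)
  expect_equal(sc[["scale"]], 19.385)
  expect_equal(unname(gamma_from_moments(5, 5)), c(1, 5))  # exponential
  for (case in list(c(3.4, 0.85), c(100, 12))) {
    sc <- gamma_from_moments(case[1], case[2])
    expect_equal(sc[["shape"]] * sc[["scale"]], case[1])
    expect_equal(sqrt(sc[["shape"]]) * sc[["scale"]], case[2])
  }
  expect_error(gamma_from_moments(-1, 1), "> 0")
})

test_that("tornado covers every ranged parameter and flags failures", {
  fx <- synth_fixture()
  reg <- param_registry(fx$params)
  dsa <- run_dsa(fx$params, fx$model, registry = reg)
  eligible <- reg$id[is.finite(reg$dsa_low) & is.finite(reg$dsa_high)]
  expect_setequal(dsa$id, c(eligible, "pap_scenario"))
  expect_true(all(diff(dsa$width[!is.na(dsa$width)]) <= 1e-9))
  # a parameter pinned to its baseline spans zero width
  reg0 <- reg
  i <- which(reg0$id == "followup_cost")
  reg0$dsa_low[i] <- reg0$dsa_high[i] <- reg0$base[i]
  d0 <- run_dsa(fx$params, fx$model, registry = reg0, include_pap = FALSE)
  expect_equal(d0$width[d0$id == "followup_cost"], 0)
})

test_that("cost-only parameters leave the effect side untouched", {
  fx <- synth_fixture()
  base <- fx$model(fx$params)
  for (v in c(25.06, 37.60)) {
    ce <- fx$model(set_param(fx$params, "followup_cost", v))
    expect_equal(ce$delta_qaly, base$delta_qaly)
    expect_false(isTRUE(all.equal(ce$delta_cost, base$delta_cost)))
  }
})

test_that("probabilistic draws are seeded, honest and renormalised", {
  fx <- synth_fixture()
  psa1 <- run_psa(fx$params, fx$model, n_iter = 30, seed = 5)
  psa2 <- run_psa(fx$params, fx$model, n_iter = 30, seed = 5)
  expect_identical(psa1, psa2)
  psa3 <- run_psa(fx$params, fx$model, n_iter = 30, seed = 6)
  expect_false(identical(psa1$draws, psa3$draws))
  # disutilities sampled as magnitudes come back negative
  expect_true(all(psa1$samples[, "ae.disutility.diarrhoea"] < 0))
  # an all-fixed registry reproduces the base case in every draw
  reg <- param_registry(fx$params)
  none <- run_psa(fx$params, fx$model, n_iter = 5, seed = 1,
                  registry = reg[reg$kind == "fixed", ])
  base <- fx$model(fx$params)
  expect_true(all(none$draws$delta_cost == base$delta_cost))
  expect_true(all(none$draws$delta_qaly == base$delta_qaly))
  # invalid distribution rejected before sampling
  bad <- reg
  bad$alpha[bad$id == "utility.pd"] <- -1
  expect_error(run_psa(fx$params, fx$model, n_iter = 2, seed = 1,
                       registry = bad), "utility.pd")
})

test_that("sampled parameter means track their distributions", {
  fx <- synth_fixture()
  reg <- param_registry(fx$params)
  r <- reg[reg$id == "utility.pd", ]
  set.seed(99)
  draws <- stats::rbeta(500, r$alpha, r$beta)
  m <- r$alpha / (r$alpha + r$beta)
  sdd <- sqrt(r$alpha * r$beta / ((r$alpha + r$beta)^2 *
                                    (r$alpha + r$beta + 1)))
  expect_lt(abs(mean(draws) - m), 3 * sdd / sqrt(500))
  expect_equal(m, 0.640, tolerance = 5e-4)
})

test_that("acceptability curve has the right limits", {
  draws <- data.frame(delta_cost = c(-10, 20, 30, 40),
                      delta_qaly = c(1, 2, -1, 4))
  cc <- ceac(draws, c(0, 1e9))
  expect_equal(cc$prob_cost_effective[1], mean(draws$delta_cost < 0))
  expect_equal(cc$prob_cost_effective[2], mean(draws$delta_qaly > 0))
  # degenerate distribution with constant ICER r: step from 0 to 1 at r
  const <- data.frame(delta_cost = rep(50, 4), delta_qaly = rep(2, 4))
  cc2 <- ceac(const, c(15, 35))
  expect_equal(cc2$prob_cost_effective, c(0, 1))
  expect_true(all(ceac(draws)$prob_cost_effective >= 0 &
                    ceac(draws)$prob_cost_effective <= 1))
  expect_error(ceac(draws, numeric(0)), "empty")
})

test_that("assistance-programme scenario reprices first-line acquisition only", {
  fx <- synth_fixture()
  p <- apply_scenario_pap(fx$params)
  expect_true(p$pap$enabled)
  p$pap$enabled <- FALSE
  expect_identical(p, fx$params)
  # annual fee prorated per cycle; lifetime cap after two years
  p2 <- apply_scenario_pap(fx$params)
  sched <- firstline_schedule("P", p2, 30)
  expect_equal(sched$acquisition[1] * 365.25 / p2$cycle_days, 11200)
  expect_equal(sum(sched$acquisition), 22400)
  # untouched elsewhere: chemotherapy arm schedule identical
  expect_identical(firstline_schedule("C", p2, 10),
                   firstline_schedule("C", fx$params, 10))
})
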