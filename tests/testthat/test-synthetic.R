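test_that("RC-time algebra and pressure reconstruction identities hold", {
  # tau = 0.42 s at PVR = 3.5 WU gives PAC = 2.0 mL/mmHg
  expect_equal(0.42 / (0.06 * 3.5), 2.0)
  # PP split 2/3 above mPAP: mPAP = dPAP + PP/3
  mpap <- 30; pp <- 21
  spap <- mpap + (2 / 3) * pp
  dpap <- mpap - (1 / 3) * pp
  expect_equal(spap, 44)
  expect_equal(dpap, 23)
  expect_equal(dpap + pp / 3, mpap)
})

test_that("derived PAC reproduces the intended PAC exactly", {
  h <- generate_hemodynamics(generator_config(n = 2000, seed = 14))
  d <- derive_hemodynamics(h$hr, h$spap, h$dpap, h$mpap, h$pawp, h$co)
  expect_lt(max(abs(d$pac - h$pac_true)), 1e-9)
  expect_true(all(d$tpg > 0))
  expect_true(all(h$dpap > 0))
  expect_gte(attr(h, "n_rejected"), 0)
})

test_that("default marginals land near their calibration targets", {
  h <- generate_hemodynamics(generator_config(n = 10000, seed = 99))
  d <- derive_hemodynamics(h$hr, h$spap, h$dpap, h$mpap, h$pawp, h$co)
  expect_lt(abs(median(d$pac) - 2.4), 0.5)
  expect_lt(abs(median(h$age) - 64), 3)
  expect_lt(abs(median(h$co) - 4.9), 0.5)
  expect_lt(abs(median(h$mpap) - 28), 4)
})

test_that("identical config and seed give a byte-identical cohort", {
  cfg <- generator_config(n = 500, seed = 77,
                          coefficients = list(list(var = "age", beta = 0.02)))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  attr(a, "n_rejected") <- attr(b, "n_rejected") <- NULL
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("survival generation respects the censoring construction", {
  cfg <- generator_config(n = 3000, seed = 8,
                          censoring = list(horizon = 10, dropout_max = 40))
  h <- generate_hemodynamics(cfg)
  s <- generate_survival(h, cfg)
  expect_true(all(s$time > 0))
  expect_true(all(s$time <= 10))
  # subjects alive at the horizon are censored exactly at the horizon
  at_horizon <- s$time == 10
  expect_gt(sum(at_horizon), 0)
  expect_true(all(s$status[at_horizon] == 0L))

  # censoring fraction is monotone nonincreasing in the horizon
  fracs <- vapply(c(3, 6, 12), function(hz) {
    cfg_h <- generator_config(n = 3000, seed = 8,
                              censoring = list(horizon = hz, dropout_max = 40))
    mean(generate_survival(h, cfg_h)$status == 0L)
  }, 0)
  expect_true(all(diff(fracs) <= 0))
})

test_that("effects orient event times and a null cohort carries no signal", {
  cfg <- generator_config(n = 1500, seed = 4,
                          coefficients = list(list(var = "mpap", beta = 0.05)))
  s <- generate_survival(generate_hemodynamics(cfg), cfg)
  ev <- s$status == 1
  expect_lt(stats::cor(s$lp_true[ev], s$time[ev], method = "kendall"), 0)

  # null cohort: any fitted model scores near chance on hold-out data
  cfg0 <- generator_config(n = 3000, seed = 15)
  s0 <- annotate_cohort(generate_survival(generate_hemodynamics(cfg0), cfg0))
  expect_true(all(s0$lp_true == 0))
  x <- pacpredict:::build_design(s0, c("age", "mpap", "pac"))
  tr <- 1:2000; te <- 2001:3000
  f <- fit_cox(x[tr, ], s0$time[tr], s0$status[tr])
  cc <- harrell_c(predict_risk(f, x[te, ]), s0$time[te], s0$status[te])
  expect_lt(abs(cc$c_index - 0.5), 0.04)
})

test_that("coefficient terms are validated and transforms supported", {
  cfg <- generator_config(n = 200, seed = 3,
                          coefficients = list(list(var = "nope", beta = 1)))
  h <- generate_hemodynamics(generator_config(n = 200, seed = 3))
  expect_error(generate_survival(h, cfg), "unknown column")

  cfg2 <- generator_config(n = 200, seed = 3, coefficients = list(
    list(var = "co", transform = "log", beta = -0.5),
    list(var = "age", transform = "below", threshold = 60, beta = 0.3)))
  s <- generate_survival(h, cfg2)
  lp <- -0.5 * (log(h$co) - mean(log(h$co))) +
    0.3 * ((h$age < 60) - mean(h$age < 60))
  expect_equal(s$lp_true, lp)
})

test_that("an infeasible configuration errors instead of spinning", {
  m <- default_marginals()
  m$pawp <- list(meanlog = log(200), sdlog = 0.05)  # TPG > 0 nearly never
  expect_error(generate_hemodynamics(generator_config(n = 100, seed = 1,
                                                      marginals = m)),
               "rejection rate")
})

test_that("the redundancy scenario couples PAC to mPAP without effect", {
  co <- make_redundancy_scenario(n = 4000, seed = 11)
  # rank correlation, PAC being hyperbolically coupled (heavy right tail)
  expect_lt(stats::cor(co$pac, co$mpap, method = "spearman"), -0.3)
  cfg <- attr(co, "config")
  expect_false(any(vapply(cfg$coefficients,
                          function(tm) tm$var == "pac", TRUE)))
})
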