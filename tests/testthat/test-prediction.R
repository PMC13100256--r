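# small cohorts and configs keep these unit tests quick; the full-size
# study design is exercised in the acceptance suite
small_config <- function(..., seed = 3) {
  mccv_config(n_sample = 800, n_train = 600, n_reps = 20, seed = seed, ...)
}

test_that("partitions are shared across variants and runs are repeatable", {
  co <- make_redundancy_scenario(n = 2500, seed = 2)
  mc1 <- run_mccv(co, small_config())
  mc2 <- run_mccv(co, small_config())
  expect_identical(mc1$c_index, mc2$c_index)
  expect_identical(mc1$partitions, mc2$partitions)
  # one partition per rep, train and test disjoint with documented sizes
  p1 <- mc1$partitions[[1]]
  expect_length(p1$train, 600)
  expect_length(p1$test, 200)
  expect_length(intersect(p1$train, p1$test), 0)
  expect_true(all(mc1$c_index >= 0 & mc1$c_index <= 1, na.rm = TRUE))
})

test_that("hold-out concordance does not exceed training concordance on average", {
  co <- make_redundancy_scenario(n = 2500, seed = 6)
  mc <- run_mccv(co, small_config(), train_c = TRUE)
  expect_gte(mean(mc$train_c[, "full"], na.rm = TRUE),
             mean(mc$c_index[, "full"], na.rm = TRUE))
})

test_that("handicapping the only informative covariate collapses to chance", {
  cfg <- generator_config(n = 2500, seed = 13, coefficients = list(
    list(var = "age", beta = 0.05)))
  co <- generate_cohort(cfg)
  mc <- run_mccv(co, small_config(
    model_covariates = c("age", "bsa", "cci"), handicaps = "age"))
  expect_lt(abs(mean(mc$c_index[, "minus_age"], na.rm = TRUE) - 0.5), 0.02)
  expect_gt(mean(mc$c_index[, "full"], na.rm = TRUE), 0.55)
})

test_that("a constant offset between distributions is reported exactly", {
  set.seed(10)
  base <- 0.70 + rnorm(40, 0, 0.01)
  cmat <- cbind(full = base, minus_x = base - 0.05)
  cmp <- compare_models(cmat)
  expect_equal(cmp$table$mean_difference, 0.05, tolerance = 1e-12)
  expect_lt(cmp$table$rope_mass, 0.01)
  expect_equal(cmp$table$pairwise_p, 0)  # constant shift: exact difference
  expect_error(compare_models(cmat[1, , drop = FALSE]), "two repetitions")
  expect_error(compare_models(cmat, full = "nope"), "no 'nope' column")
})

test_that("a redundant near-copy column has no predictive price", {
  co <- make_redundancy_scenario(n = 2500, seed = 17)
  set.seed(17)
  co$mpap_copy <- co$mpap + rnorm(nrow(co), 0, 0.1)
  mc <- run_mccv(co, small_config(
    model_covariates = c("age", "mpap", "mpap_copy"),
    handicaps = "mpap_copy"))
  d <- mc$c_index[, "full"] - mc$c_index[, "minus_mpap_copy"]
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.003)
})

test_that("ROPE mass falls as the removed variable's true effect grows", {
  masses <- vapply(c(0, 0.6, 1.2), function(b) {
    cfg <- generator_config(n = 2500, seed = 23, coefficients = c(
      list(list(var = "age", beta = 0.03)),
      if (b > 0) list(list(var = "co", transform = "log", beta = b))))
    co <- generate_cohort(cfg)
    mc <- run_mccv(co, small_config(
      model_covariates = c("age", "co", "cci"), handicaps = "co"))
    compare_models(mc)$table$rope_mass
  }, 0)
  # monotone up to quadrature resolution on the posterior grid
  expect_true(all(diff(masses) <= 0.01))
  expect_gt(masses[1], 0.9)
  expect_lt(masses[3], 0.1)
})

test_that("the Bayesian paired-difference summary behaves sensibly", {
  set.seed(33)
  d0 <- rnorm(100, 0, 0.004)
  p0 <- rope_posterior(d0)
  expect_gt(p0$rope_mass, 0.95)
  expect_true(p0$hdi[1] <= p0$mean & p0$mean <= p0$hdi[2])
  d1 <- rnorm(100, 0.05, 0.004)
  p1 <- rope_posterior(d1)
  expect_lt(p1$rope_mass, 1e-6)
  expect_lt(abs(p1$mean - 0.05), 0.002)
  # degenerate constant differences
  expect_equal(rope_posterior(rep(0.002, 10))$rope_mass, 1)
  expect_equal(rope_posterior(rep(0.2, 10))$rope_mass, 0)
})

test_that("PVR bins assign boundaries to the lower bin, open above 5", {
  b <- pvr_bins(c(1.9, 2, 2.01, 3, 3.01, 5, 5.01, NA))
  expect_equal(as.character(b),
               c("<=2", "<=2", "2-3", "2-3", "3-5", "3-5", ">5", NA))
  co <- make_redundancy_scenario(n = 1500, seed = 27)
  bb <- pvr_bins(co$pvr)
  expect_equal(sum(table(bb)) + sum(is.na(bb)), nrow(co))
})

test_that("subgroup runs shrink the sampling scheme proportionally", {
  co <- make_redundancy_scenario(n = 4000, seed = 37)
  cfg <- mccv_config(n_sample = 2000, n_train = 1500, n_reps = 4, seed = 1,
                     model_covariates = c("age", "mpap", "pac"),
                     handicaps = "pac")
  msgs <- capture_messages(
    res <- subgroup_mccv(co, cfg, stratifier = "pvr", min_stratum = 40))
  expect_true(any(grepl("shrunk", msgs)))
  for (lev in names(res)) {
    used <- res[[lev]]$config_used
    if (res[[lev]]$shrunk) {
      expect_lte(used$n_sample, floor(res[[lev]]$n_stratum * 5 / 6))
      expect_equal(used$n_sample %% 4, 0)
      expect_equal(used$n_train, used$n_sample * 3 / 4)
    }
    expect_s3_class(res[[lev]]$comparison, "mccv_comparison")
  }
  # the documented worked example: a 120-row stratum gives 100 = 75 + 25
  expect_equal((floor(120 * 5 / 6) %/% 4) * 4, 100)
})

test_that("tiny strata are skipped with a message", {
  co <- make_redundancy_scenario(n = 300, seed = 39)
  co$ph_class <- factor(rep(c("NO_PH", "PRECAP"), length.out = 300),
                        levels = ph_levels())
  co$ph_class[1:290] <- "NO_PH"
  cfg <- mccv_config(n_sample = 200, n_train = 150, n_reps = 3, seed = 1,
                     model_covariates = c("age", "mpap"), handicaps = "mpap")
  msgs <- capture_messages(
    res <- subgroup_mccv(co, cfg, stratifier = "ph", min_stratum = 40))
  expect_true(any(grepl("skipped", msgs)))
  expect_true("PRECAP" %in% attr(res, "skipped"))
  expect_false("PRECAP" %in% names(res))
})
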