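test_that("derived hemodynamics match hand arithmetic", {
  d <- derive_hemodynamics(hr = 80, spap = 48, dpap = 18, mpap = 28,
                           pawp = 13, co = 6)
  expect_equal(d$pp, 30)
  expect_equal(d$tpg, 15)
  expect_equal(d$pvr, 2.5)
  expect_equal(d$sv, 75)
  expect_equal(d$pac, 2.5)

  d2 <- derive_hemodynamics(hr = 100, spap = 40, dpap = 20, mpap = 27,
                            pawp = 12, co = 5)
  expect_equal(d2$sv, 50)
  expect_equal(d2$tpg, 15)
  expect_equal(d2$pvr, 3.0)
  expect_equal(d2$pac, 2.5)
})

test_that("nonpositive pulse pressure flags PAC undefined, keeps the rest", {
  d <- derive_hemodynamics(hr = 70, spap = 40, dpap = 40, mpap = 40,
                           pawp = 10, co = 5)
  expect_equal(d$pp, 0)
  expect_false(d$pac_defined)
  expect_true(is.na(d$pac))
  expect_equal(d$tpg, 30)   # other fields still computed
  expect_equal(d$sv, 1000 * 5 / 70)
})

test_that("nonpositive HR or CO is an invalid-input error", {
  expect_error(derive_hemodynamics(0, 40, 20, 30, 10, 5), "heart rate")
  expect_error(derive_hemodynamics(70, 40, 20, 30, 10, -1), "cardiac output")
})

test_that("derivation is deterministic and internally unit-consistent", {
  set.seed(31)
  hr <- runif(200, 40, 120); co <- runif(200, 2, 8)
  spap <- runif(200, 25, 90); dpap <- runif(200, 5, 24)
  mpap <- (spap + 2 * dpap) / 3; pawp <- runif(200, 4, 20)
  d <- derive_hemodynamics(hr, spap, dpap, mpap, pawp, co)
  expect_identical(d, derive_hemodynamics(hr, spap, dpap, mpap, pawp, co))
  expect_equal(d$pac, d$sv / d$pp)  # recomputing PAC from its own outputs
})

test_that("each QC bound is strict: the boundary passes, beyond it fails", {
  bounds <- list(
    CO_RANGE   = list(var = "co",   lo = 0.5, hi = 15),
    MPAP_RANGE = list(var = "mpap", lo = 5,   hi = 80),
    DPAP_RANGE = list(var = "dpap", lo = 0,   hi = 70),
    SPAP_RANGE = list(var = "spap", lo = 7,   hi = 130),
    PAWP_RANGE = list(var = "pawp", lo = 0,   hi = 60),
    HR_RANGE   = list(var = "hr",   lo = 10,  hi = 200),
    AGE_RANGE  = list(var = "age",  lo = 18,  hi = 90))
  for (code in names(bounds)) {
    b <- bounds[[code]]
    for (v in c(b$lo, b$hi)) {
      args <- stats::setNames(list(v), b$var)
      expect_true(do.call(check_physiologic, args)$passed,
                  info = paste(code, "boundary", v))
    }
    for (v in c(b$lo - 0.01, b$hi + 0.01)) {
      args <- stats::setNames(list(v), b$var)
      res <- do.call(check_physiologic, args)
      expect_false(res$passed, info = paste(code, "outside", v))
      expect_identical(res$reason_codes, code)
    }
  }
})

test_that("QC reports multiple reasons and never raises", {
  res <- check_physiologic(age = 17, hr = 250)
  expect_false(res$passed)
  expect_setequal(strsplit(res$reason_codes, ";")[[1]],
                  c("AGE_RANGE", "HR_RANGE"))
  expect_true(check_physiologic(co = 15)$passed)   # boundary survives
  expect_false(check_physiologic(co = 0.4)$passed)
  expect_true(check_physiologic()$passed)          # all missing: no codes
})

test_that("PH classification follows the hemodynamic rules", {
  expect_equal(as.character(classify_ph(25, 10, 1.5)), "UNDETERMINED")
  expect_equal(as.character(classify_ph(20, 10, 3.0)), "NO_PH")
  expect_equal(as.character(classify_ph(25, 18, 3.0)), "CPCPH")
  expect_equal(as.character(classify_ph(25, 18, 2.0)), "IPCPH")
  expect_equal(as.character(classify_ph(25, 15, 2.1)), "PRECAP")
  expect_error(classify_ph(NA, 10, 2), "complete")
})

test_that("PH labels partition random triples", {
  set.seed(7)
  n <- 10000
  lab <- classify_ph(runif(n, 5, 60), runif(n, 0, 40), runif(n, 0, 12))
  expect_false(anyNA(lab))
  expect_equal(sum(table(lab)), n)
})

test_that("exclusion audit counts each row once, first reason wins", {
  cohort <- data.frame(
    age = c(17, rep(50, 9)),
    co = c(5, 0.3, rep(5, 8)),
    hr = rep(70, 10), spap = rep(40, 10), dpap = rep(15, 10),
    mpap = rep(25, 10), pawp = rep(12, 10))
  res <- apply_exclusions(cohort)
  expect_equal(nrow(res$cohort), 8)
  audit <- stats::setNames(res$audit$n_excluded, res$audit$reason)
  expect_equal(unname(audit["AGE_RANGE"]), 1L)
  expect_equal(unname(audit["CO_RANGE"]), 1L)
  expect_equal(sum(audit), 2L)

  # a row failing both age and HR is counted once, under age
  cohort$hr[1] <- 250
  res2 <- apply_exclusions(cohort)
  audit2 <- stats::setNames(res2$audit$n_excluded, res2$audit$reason)
  expect_equal(unname(audit2["AGE_RANGE"]), 1L)
  expect_equal(unname(audit2["HR_RANGE"]), 0L)

  # all-pass cohort is an identity transform with an all-zero audit
  ok <- cohort[3:10, ]
  res3 <- apply_exclusions(ok)
  expect_identical(res3$cohort, ok)
  expect_true(all(res3$audit$n_excluded == 0))

  expect_error(apply_exclusions(data.frame(age = 5, co = 5)), "excluded")
})

test_that("cohort round-trips through delimited text with a column map", {
  co <- data.frame(heart_rate = c(70, 80), spap = c(40, 50),
                   dpap = c(15, 18), mpap = c(24, 30),
                   pawp = c(10, NA), co = c(5, 6))
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f, column_map = c(heart_rate = "hr"))
  expect_equal(back$hr, co$heart_rate)
  expect_true(is.na(back$pawp[2]))
  expect_error(read_cohort(f, column_map = c(nope = "hr")), "nope")
})

test_that("annotate_cohort appends derived fields, QC and PH class", {
  co <- data.frame(age = c(50, 60), hr = c(80, 100), spap = c(48, 40),
                   dpap = c(18, 20), mpap = c(28, 27), pawp = c(13, 12),
                   co = c(6, 5))
  a <- annotate_cohort(co)
  expect_equal(a$pac, c(2.5, 2.5))
  expect_equal(as.character(a$ph_class), c("PRECAP", "PRECAP"))
  expect_true(all(a$qc_pass))
  expect_equal(attr(a, "n_unclassified"), 0L)

  co$mpap[2] <- NA
  a2 <- annotate_cohort(co)
  expect_true(is.na(a2$ph_class[2]))
  expect_equal(attr(a2, "n_unclassified"), 1L)
})
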