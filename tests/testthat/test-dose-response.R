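test_that("dilution series reproduces the stated concentration bookkeeping", {
  d <- dilution_series(dilution_scheme(10000, 2, 10, transfer_dilution = 100))
  expect_equal(round(d$stock_uM[10], 2), 19.53)
  expect_equal(d$final_uM[10], 0.1953125)  # 195 nM
  d8 <- dilution_series(dilution_scheme(100, 2, 8, transfer_dilution = 1))
  expect_equal(d8$final_uM[8], 0.78125)
  # conservation: stock_i * fold^(i-1) == top for every point
  expect_equal(d$stock_uM * 2^(d$point - 1), rep(10000, 10))
})

test_that("scheme validation rejects bad inputs", {
  expect_error(dilution_scheme(-1, 2, 8))
  expect_error(dilution_scheme(100, 1, 8))
  expect_error(dilution_scheme(100, 2, 1))
})

test_that("noise-free IC50 is recovered to 1e-3", {
  conc <- dilution_series(dilution_scheme(100, 2, 8, 1))$final_uM
  d <- data.frame(conc_uM = rep(conc, each = 4),
                  activity = allokin:::ic50_model(rep(conc, each = 4),
                                                  log10(18), 1))
  f <- fit_ic50(d)
  expect_equal(f$ic50, 18, tolerance = 1e-3 / 18)
  expect_equal(f$hill, 1, tolerance = 1e-6)
  expect_true(f$converged)
  expect_false(f$censored_at_top)
})

test_that("the fitted curve passes through 50% at the fitted IC50", {
  d <- gen_dose_response(seed = 31)
  f <- fit_ic50(data.frame(conc_uM = d$conc_uM, activity = d$activity))
  expect_equal(predict(f, data.frame(conc_uM = f$ic50)), 50, tolerance = 1e-9)
})

test_that("one-sided responses give converged = FALSE", {
  conc <- dilution_series(dilution_scheme(100, 2, 8, 1))$final_uM
  f <- fit_ic50(data.frame(conc_uM = conc, activity = rep(95, 8)))
  expect_false(f$converged)
})

test_that("fit is invariant to concentration unit rescaling", {
  d <- gen_dose_response(seed = 32)
  f_uM <- fit_ic50(data.frame(conc_uM = d$conc_uM, activity = d$activity))
  f_nM <- fit_ic50(data.frame(conc_uM = d$conc_uM * 1000,
                              activity = d$activity))
  expect_equal(f_nM$ic50 / f_uM$ic50, 1000, tolerance = 1e-6)
  expect_equal(f_nM$hill, f_uM$hill, tolerance = 1e-6)
})

test_that("censoring flags IC50 at or beyond the top concentration", {
  conc <- dilution_series(dilution_scheme(100, 2, 8, 1))$final_uM
  act <- allokin:::ic50_model(rep(conc, each = 2), log10(400), 1)
  f <- fit_ic50(data.frame(conc_uM = rep(conc, each = 2), activity = act))
  expect_true(f$censored_at_top)
})

test_that("hill slopes 0.5 and 2 are recovered in the correct order", {
  f_lo <- fit_ic50(local({
    d <- gen_dose_response(seed = 33, hill = 0.5)
    data.frame(conc_uM = d$conc_uM, activity = d$activity)
  }))
  f_hi <- fit_ic50(local({
    d <- gen_dose_response(seed = 33, hill = 2)
    data.frame(conc_uM = d$conc_uM, activity = d$activity)
  }))
  expect_lt(f_lo$hill, f_hi$hill)
  expect_equal(f_lo$hill, 0.5, tolerance = 0.4)
  expect_equal(f_hi$hill, 2, tolerance = 0.4)
})

test_that("selectivity ratios reproduce the Table-1 style statements", {
  s <- selectivity_ratio(25, 100)
  expect_equal(s$fold, 4)
  expect_equal(s$direction, "IGF1R-selective")
  s2 <- selectivity_ratio(100, 10)
  expect_equal(s2$fold, 10)
  expect_equal(s2$direction, "InsR-selective")
  s3 <- selectivity_ratio(7, 7)
  expect_equal(s3$direction, "nonselective")
  expect_error(selectivity_ratio(-1, 10), "positive")
})

test_that("ic50_fit methods are coherent", {
  d <- gen_dose_response(seed = 34)
  f <- fit_ic50(data.frame(conc_uM = d$conc_uM, activity = d$activity))
  expect_named(coef(f), c("ic50", "hill"))
  expect_equal(length(residuals(f)), nrow(f$data))
  expect_equal(sum(residuals(f)^2), f$rss, tolerance = 1e-9)
  expect_output(print(f), "IC50")
})
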