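test_that("noise-free Michaelis-Menten parameters are recovered exactly", {
  S <- 519 / 2^(0:7)
  v <- 100 * S / (50 + S)
  f <- fit_michaelis_menten(S, v)
  expect_equal(f$vmax, 100, tolerance = 1e-6)
  expect_equal(f$km, 50, tolerance = 1e-6)
  # v at [S] = Km equals Vmax/2 on the fitted curve
  expect_equal(predict(f, data.frame(S = f$km)), f$vmax / 2, tolerance = 1e-9)
})

test_that("non-saturating data is flagged, not silently accepted", {
  S <- c(1, 2, 4, 8)
  v <- 100 * S / (500 + S)
  f <- fit_michaelis_menten(S, v)
  expect_true(f$non_saturating)
})

test_that("Km recovery under 5% noise is accurate in the median", {
  err <- vapply(1:100, function(s) {
    k <- gen_kinetics(seed = s, mechanism = "none", km = 130, noise_frac = 0.05)
    d <- k[k$I_uM == 0, ]
    abs(fit_michaelis_menten(d$S_uM, d$rate)$km - 130) / 130
  }, numeric(1))
  expect_lt(median(err), 0.10)
})

test_that("Lineweaver-Burk reproduces the closed-form line", {
  S <- 519 / 2^(0:7)
  v <- 100 * S / (50 + S)
  lb <- lineweaver_burk(S, v)
  expect_equal(lb$slope, 50 / 100, tolerance = 1e-9)
  expect_equal(lb$intercept, 1 / 100, tolerance = 1e-9)
  expect_equal(lb$r_squared, 1, tolerance = 1e-9)
  # doubling all rates halves slope and intercept
  lb2 <- lineweaver_burk(S, 2 * v)
  expect_equal(lb2$slope, lb$slope / 2, tolerance = 1e-9)
  expect_equal(lb2$intercept, lb$intercept / 2, tolerance = 1e-9)
  expect_error(lineweaver_burk(S, v - 10), "positive")
})

test_that("non-competitive reciprocal lines share the -1/Km root", {
  km <- 80
  S <- 519 / 2^(0:7)
  lines <- lapply(c(0, 50), function(I) {
    vmax <- 100 / (1 + I / 30)
    lineweaver_burk(S, vmax * S / (km + S))
  })
  # intersection x of the two lines: (b2 - b1) / (a1 - a2)
  x <- (lines[[2]]$intercept - lines[[1]]$intercept) /
    (lines[[1]]$slope - lines[[2]]$slope)
  expect_equal(x, -1 / km, tolerance = 1e-9)
})

test_that("classifier reproduces the three textbook mechanisms noise-free", {
  mk <- function(mech, ki = 20, I_uM = c(0, 25, 50)) {
    gen_kinetics(seed = 1, mechanism = mech, ki = ki, I_uM = I_uM,
                 noise_frac = 0)
  }
  expect_equal(classify_mechanism(mk("competitive"))$mechanism, "competitive")
  expect_equal(classify_mechanism(mk("non-competitive"))$mechanism,
               "non-competitive")
  expect_equal(classify_mechanism(mk("uncompetitive"))$mechanism,
               "uncompetitive")
  expect_equal(classify_mechanism(mk("mixed"))$mechanism, "mixed")
  expect_equal(classify_mechanism(mk("none"))$mechanism, "indeterminate")
})

test_that("at [I]=0 the apparent parameters equal the plain fit exactly", {
  k <- gen_kinetics(seed = 41, mechanism = "competitive")
  cl <- classify_mechanism(k)
  d0 <- k[k$I_uM == 0, ]
  f0 <- fit_michaelis_menten(d0$S_uM, d0$rate)
  expect_identical(cl$table$vmax[cl$table$I_uM == 0], f0$vmax)
  expect_identical(cl$table$km[cl$table$I_uM == 0], f0$km)
})

test_that("classifier input validation", {
  k <- gen_kinetics(seed = 1, noise_frac = 0)
  expect_error(classify_mechanism(k[k$I_uM == 0, ]), "2 inhibitor levels")
  expect_error(classify_mechanism(k[k$I_uM > 0, ]), "I\\] = 0")
})

test_that("substrate windowing is reported, never silent", {
  k <- gen_kinetics(seed = 42, mechanism = "non-competitive", noise_frac = 0)
  cl <- classify_mechanism(k, s_range = c(10, 600))
  expect_gt(nrow(cl$excluded_points), 0)
  expect_equal(cl$mechanism, "non-competitive")
  expect_output(print(cl), "excluded")
})

test_that("peptide molarity conversion uses the 12.5 kDa default", {
  expect_equal(peptide_conc_uM(0.2), 16)
  expect_equal(peptide_conc_uM(1), 80)
  expect_equal(peptide_conc_uM(1, mass_kda = 25), 40)
  # the paper's peptide range 0.9 - 114.3 uM maps back to mg/mL
  expect_equal(peptide_conc_uM(114.3 * 12.5 / 1000), 114.3)
})
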