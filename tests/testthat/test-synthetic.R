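test_that("all generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_library(25, seed = 2), gen_library(25, seed = 2))
  expect_identical(gen_plate(seed = 2), gen_plate(seed = 2))
  expect_identical(gen_dose_response(seed = 2), gen_dose_response(seed = 2))
  expect_identical(gen_kinetics(seed = 2), gen_kinetics(seed = 2))
  s1 <- gen_pose_scene(); s2 <- gen_pose_scene()
  expect_identical(s1$pdb_text, s2$pdb_text)
  expect_identical(lapply(s1$poses, `[[`, "conformers"),
                   lapply(s2$poses, `[[`, "conformers"))
})

test_that("generators leave the global RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_library(5, seed = 1))
  invisible(gen_plate(seed = 1))
  invisible(gen_dose_response(seed = 1))
  invisible(gen_kinetics(seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("library labels are recovered exactly by the real filters", {
  lib <- gen_library(40, seed = 51)
  mols <- parse_smiles_set(lib$smiles, ids = lib$id)
  expect_length(attr(mols, "failed"), 0)
  expect_equal(unname(vapply(mols, has_strong_donor, logical(1))), lib$donor)
  expect_equal(unname(vapply(mols, passes_feature_prereqs, logical(1))),
               lib$prereqs)
  expect_equal(unname(vapply(mols, function(m) isTRUE(match_markush(m)),
                             logical(1))), lib$markush)
})

test_that("fraction 0 gives zero downstream matches; bad specs error", {
  lib <- gen_library(20, seed = 52, frac_markush = 0)
  mols <- parse_smiles_set(lib$smiles, ids = lib$id)
  expect_false(any(vapply(mols, function(m) isTRUE(match_markush(m)),
                          logical(1))))
  expect_error(gen_library(10, frac_markush = 1.2), "spec error")
  expect_error(gen_library(0), "spec error")
})

test_that("pose scene verdicts match the planted truth", {
  sc <- gen_pose_scene()
  scr <- screen_poses(sc$pocket, sc$poses)
  expect_equal(scr$pass, sc$truth$expect_pass)
  expect_error(gen_pose_scene(margin = 0.001), "spec error")
  # margins: planted distances sit >= margin from the thresholds
  rep <- detect_interactions(sc$pocket, sc$poses$pass)
  thr <- interaction_thresholds()
  expect_lte(rep$hbond_val1063_geom[["dist"]], thr$d_hb - sc$margin + 1e-6)
  rep_f <- detect_interactions(sc$pocket, sc$poses$fail_main)
  expect_gte(rep_f$hbond_val1063_geom[["dist"]], thr$d_hb + sc$margin - 1e-6)
})

test_that("plate generator obeys its spec and errors", {
  expect_error(gen_plate(noise_frac = 0), "spec error")
  expect_error(gen_plate(percent_inhibition = 150), "spec error")
  expect_error(gen_plate(n_hits = 10000), "spec error")
  g <- gen_plate(seed = 53, n_hits = 5, percent_inhibition = 60)
  expect_equal(sum(g$truth$planted), 5)
  expect_s3_class(g$plate, "plate")
})

test_that("generated control Z' approaches its closed-form expectation", {
  zp <- vapply(1:100, function(s) plate_qc(gen_plate(seed = s)$plate)$zprime,
               numeric(1))
  sd <- 0.05 * 8000
  expected <- 1 - 3 * (sd + sd) / 8000
  expect_equal(mean(zp), expected, tolerance = 0.05)
})

test_that("dose-response generator matches its design", {
  d <- gen_dose_response(seed = 54)
  expect_equal(length(unique(d$conc_uM)), 8)
  expect_equal(max(d$conc_uM), 100)
  expect_equal(min(d$conc_uM), 0.78125)
  expect_equal(nrow(d), 32)
  expect_equal(attr(d, "true_ic50"), 25)
  d0 <- gen_dose_response(seed = 54, noise_sd = 0)
  f <- fit_ic50(data.frame(conc_uM = d0$conc_uM, activity = d0$activity))
  expect_equal(f$ic50, 25, tolerance = 1e-3 / 25)
})

test_that("kinetics generator matches the paper design and recovers truth", {
  k <- gen_kinetics(seed = 55, noise_frac = 0)
  expect_setequal(unique(k$I_uM), c(100, 50, 25, 12, 0))
  expect_equal(length(unique(k$S_uM)), 8)
  expect_equal(max(k$S_uM), 519)
  expect_equal(min(k$S_uM), 519 / 128, tolerance = 1e-9)  # ~4 uM
  d0 <- k[k$I_uM == 0, ]
  f <- fit_michaelis_menten(d0$S_uM, d0$rate)
  expect_equal(f$vmax, 100, tolerance = 1e-5)
  expect_equal(f$km, 130, tolerance = 1e-4)
  expect_equal(classify_mechanism(
    gen_kinetics(seed = 55, mechanism = "competitive",
                 noise_frac = 0))$mechanism, "competitive")
})

test_that("the full pipeline demo runs end to end and is self-consistent", {
  t0 <- Sys.time()
  r <- run_pipeline_demo(seed = 5)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 300)
  expect_equal(r$pose_screen$pass, r$pose_truth$expect_pass)
  expect_true(all(r$planted %in% r$hits$compound))
  expect_equal(r$library$markush, r$library$markush_obs)
  expect_equal(r$mechanism$mechanism, r$true_mechanism)
  expect_output(print(r), "pipeline")
})
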