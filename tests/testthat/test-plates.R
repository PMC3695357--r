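test_that("percent activity matches the printed formula", {
  expect_equal(percent_activity(500, 100, 900), 50)
  expect_equal(percent_activity(900, 100, 900), 100)
  expect_equal(percent_activity(100, 100, 900), 0)
  expect_error(percent_activity(500, 300, 300), "degenerate")
})

test_that("Z' matches the printed formula with the 0.6 QC bound", {
  z <- zprime(1000, 10, 100, 10)
  expect_equal(as.numeric(z), 1 - 60 / 900)
  expect_true(attr(z, "acceptable"))
  expect_equal(as.numeric(zprime(1000, 0, 100, 0)), 1)
  z3 <- zprime(1000, 100, 100, 50)
  expect_equal(as.numeric(z3), 0.5)
  expect_false(attr(z3, "acceptable"))
  expect_error(zprime(5, 1, 5, 1), "degenerate")
})

test_that("plate QC window and verdicts behave as stated", {
  mk <- function(neg, pos) {
    rlu <- matrix(neg, 16, 24)
    roles <- default_roles()
    rlu[roles == "pos_ctrl_no_kinase"] <- pos
    # tiny deterministic jitter so SDs are nonzero but Z' stays high
    rlu <- rlu + matrix(rep_len(c(-1, 1), 384), 16, 24)
    plate(rlu, roles)
  }
  qc <- plate_qc(mk(900, 100))
  expect_equal(qc$window, 900 / 100, tolerance = 0.05)
  expect_true(qc$pass)
  qc5 <- plate_qc(mk(500, 100))
  expect_false(qc5$pass)
  expect_warning(qc_sw <- plate_qc(mk(100, 900)), "swapped")
  expect_false(qc_sw$pass)
})

test_that("hit calling uses mean - 3 SD over sample wells only", {
  roles <- default_roles()
  sw <- which(roles == "sample")
  vals <- rep_len(c(95, 105), length(sw))  # mean 100, sd ~5.006
  rlu <- matrix(0, 16, 24)
  rlu[roles != "sample"] <- 5000  # extreme controls must not affect stats
  rlu[sw] <- vals
  ids <- matrix(NA_character_, 16, 24)
  ids[sw] <- sprintf("c%03d", seq_along(sw))
  rlu[sw[1]] <- 84
  rlu[sw[2]] <- 86
  p <- plate(rlu, roles, ids)
  h <- call_hits(p)
  m <- attr(h, "plate_mean"); s <- attr(h, "plate_sd")
  expect_equal(m, mean(rlu[sw]))
  expect_equal(s, sd(rlu[sw]))
  expect_equal(h$is_hit[h$compound == "c001"],
               84 <= m - 3 * s)
  expect_false(h$is_hit[h$compound == "c002"] && 86 > m - 3 * s)
  # sorted ascending by mean RLU
  expect_equal(h$mean_rlu, sort(h$mean_rlu))
})

test_that("hit calling is threshold-monotone (3 SD hits are 2 SD hits)", {
  p <- gen_plate(seed = 12)$plate
  h3 <- call_hits(p, k = 3)
  h2 <- call_hits(p, k = 2)
  hits3 <- h3$compound[h3$is_hit]
  hits2 <- h2$compound[h2$is_hit]
  expect_true(all(hits3 %in% hits2))
})

test_that("percent activity and hit calls are affine-invariant", {
  g <- gen_plate(seed = 13)
  p <- g$plate
  h <- call_hits(p)
  k <- 2.5; c0 <- 300
  p2 <- plate(k * p$rlu + c0, p$roles, p$ids)
  h2 <- call_hits(p2)
  expect_equal(h2$compound[h2$is_hit], h$compound[h$is_hit])
  # % activity unchanged under the affine map
  qc <- plate_qc(p); qc2 <- plate_qc(p2)
  s <- p$rlu[p$roles == "sample"][1:5]
  expect_equal(percent_activity(k * s + c0, k * qc$pos_mean + c0,
                                k * qc$neg_mean + c0),
               percent_activity(s, qc$pos_mean, qc$neg_mean))
  # Z' invariant under pure scaling
  expect_equal(zprime(k * qc$neg_mean, k * qc$neg_sd,
                      k * qc$pos_mean, k * qc$pos_sd)[1],
               zprime(qc$neg_mean, qc$neg_sd, qc$pos_mean, qc$pos_sd)[1])
})

test_that("degenerate plates raise errors", {
  roles <- default_roles()
  rlu <- matrix(100, 16, 24)
  expect_error(call_hits(plate(rlu, roles)), "zero sample")
})

test_that("plate CSV round-trips", {
  g <- gen_plate(seed = 14)
  path <- tempfile(fileext = ".csv")
  write_plate_csv(g$plate, path)
  p2 <- read_plate_csv(path)
  expect_equal(p2$rlu, g$plate$rlu, tolerance = 1e-9)
  expect_identical(p2$roles, g$plate$roles)
  expect_identical(p2$ids, g$plate$ids)
})

test_that("planted hits are fully recalled on QC-passing plates", {
  for (s in 1:20) {
    g <- gen_plate(seed = s, percent_inhibition = 40)  # 8-SD effect
    expect_true(plate_qc(g$plate)$pass)
    h <- call_hits(g$plate)
    expect_true(all(g$truth$compound[g$truth$planted] %in%
                      h$compound[h$is_hit]), info = paste("seed", s))
  }
})
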