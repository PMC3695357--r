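test_that("pocket extraction keeps residues within the radius", {
  txt <- mini_pdb(list(
    list(name = "CA", resname = "ALA", resno = 1, xyz = c(5, 0, 0)),
    list(name = "CA", resname = "GLY", resno = 2, xyz = c(9.9, 0, 0)),
    list(name = "CA", resname = "SER", resno = 3, xyz = c(10.1, 0, 0))))
  p <- read_pdb_protein(write_tmp(txt, ".pdb"))
  lig <- matrix(c(0, 0, 0), 1, 3)
  pk <- extract_pocket(p, lig, radius = 10)
  expect_setequal(pk$residues$resno, c(1, 2))
  expect_error(extract_pocket(p, lig, radius = 0), "radius")
})

test_that("pocket extraction is invariant under joint rigid rotation", {
  sc <- gen_pose_scene()
  R <- axis_rotation(c(0, 0, 0), c(2, -1, 1), 0.8)
  tv <- c(3, 4, -5)
  prot2 <- sc$protein
  xyz <- apply_rigid(as.matrix(prot2$atoms[, c("x", "y", "z")]), R, tv)
  prot2$atoms$x <- xyz[, 1]; prot2$atoms$y <- xyz[, 2]; prot2$atoms$z <- xyz[, 3]
  lig2 <- apply_rigid(sc$poses$pass$conformers[[1]], R, tv)
  pk2 <- extract_pocket(prot2, lig2)
  expect_setequal(pk2$residues$resno, sc$pocket$residues$resno)
})

test_that("hydrogen bond to Val1063 follows the distance+angle rule", {
  # ligand O-H with H 1.9 A from the Val O, angle ~165 degrees
  ang <- 165 * pi / 180
  m <- parse_smiles("CO", id = "methanol")
  o <- which(m$atoms$elem == "O")
  h <- intersect(allokin:::atom_neighbors(m, o), which(m$atoms$is_h))[1]
  c1 <- which(m$atoms$elem == "C")
  hs <- setdiff(which(m$atoms$is_h), h)
  xyz <- matrix(0, nrow(m$atoms), 3)
  xyz[o, ] <- c(0, 0, 0)
  xyz[h, ] <- c(0.97, 0, 0)
  xyz[c1, ] <- c(-0.7, 1.2, 0)
  xyz[hs, ] <- cbind(-1.4, 1.2 + 0.3 * seq_along(hs), 0.5)
  # place the acceptor so that angle O-H...A = 165 at distance 1.9 from H
  acc <- xyz[h, ] + 1.9 * c(cos(pi - ang), sin(pi - ang), 0)
  m$conformers <- list(xyz)
  txt <- mini_pdb(list(
    list(name = "O", resname = "VAL", resno = 1063, xyz = acc),
    list(name = "SD", resname = "MET", resno = 1054, xyz = c(0, 0, 50)),
    list(name = "SD", resname = "MET", resno = 1079, xyz = c(0, 0, -50)),
    list(name = "NZ", resname = "LYS", resno = 1033, xyz = c(50, 0, 0)),
    list(name = "OD1", resname = "ASP", resno = 1153, xyz = c(-50, 0, 0)),
    list(name = "OE1", resname = "GLU", resno = 1050, xyz = c(0, 50, 0)),
    list(name = "NE", resname = "ARG", resno = 1134, xyz = c(0, -50, 0))))
  p <- read_pdb_protein(write_tmp(txt, ".pdb"))
  pk <- extract_pocket(p, m$conformers[[1]], radius = 100)
  rep <- detect_interactions(pk, m)
  expect_true(rep$hbond_val1063)
  expect_lte(rep$hbond_val1063_geom[["dist"]], 3.5)
  expect_gte(rep$hbond_val1063_geom[["angle"]], 120)
})

test_that("Met stacking uses the centroid-sulfur distance", {
  m <- parse_smiles("c1ccccc1", id = "benzene")
  ring <- which(!m$atoms$is_h)
  xyz <- matrix(0, nrow(m$atoms), 3)
  ang <- seq(0, 300, by = 60) * pi / 180
  xyz[ring, ] <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  xyz[m$atoms$is_h, ] <- cbind(2.47 * cos(ang), 2.47 * sin(ang), 0)
  m$conformers <- list(xyz)
  txt <- mini_pdb(list(
    list(name = "O", resname = "VAL", resno = 1063, xyz = c(50, 0, 0)),
    list(name = "SD", resname = "MET", resno = 1054, xyz = c(0, 0, 5)),
    list(name = "SD", resname = "MET", resno = 1079, xyz = c(0, 0, -8)),
    list(name = "NZ", resname = "LYS", resno = 1033, xyz = c(50, 0, 0)),
    list(name = "OD1", resname = "ASP", resno = 1153, xyz = c(-50, 0, 0)),
    list(name = "OE1", resname = "GLU", resno = 1050, xyz = c(0, 50, 0)),
    list(name = "NE", resname = "ARG", resno = 1134, xyz = c(0, -50, 0))))
  p <- read_pdb_protein(write_tmp(txt, ".pdb"))
  pk <- extract_pocket(p, xyz, radius = 100)
  rep <- detect_interactions(pk, m)
  expect_true(rep$stack_met1054)
  expect_false(rep$stack_met1079)
  expect_equal(rep$stack_met1054_dist, 5, tolerance = 1e-6)
})

test_that("Lys1033 electrostatic rule uses acceptor/anion to NZ distance", {
  sc <- gen_pose_scene()
  rep <- detect_interactions(sc$pocket, sc$poses$pass)
  expect_true(rep$electro_lys1033)
  expect_lte(rep$electro_lys1033_dist, 5)
  rep2 <- detect_interactions(sc$pocket, sc$poses$main_only)
  expect_false(rep2$electro_lys1033)
})

test_that("allosteric verdict is main-AND plus at-least-one-secondary", {
  sc <- gen_pose_scene()
  reps <- lapply(sc$poses, function(p) detect_interactions(sc$pocket, p))
  v <- lapply(reps, apply_allosteric_filter)
  expect_true(v$pass$pass)
  expect_equal(v$pass$n_secondary, 1)
  expect_false(v$main_only$pass)       # all main true, no secondary
  expect_true(all(v$main_only$main_satisfied))
  expect_false(v$fail_main$pass)       # Val H-bond broken
  expect_false(v$fail_main$main_satisfied[["hbond_val1063"]])
})

test_that("missing filter residues raise a configuration error listing them", {
  sc <- gen_pose_scene()
  pk <- sc$pocket
  pk$atoms <- pk$atoms[pk$atoms$resno != 1033, ]
  expect_error(detect_interactions(pk, sc$poses$pass), "1033")
})

test_that("detections are invariant under a joint rigid transform", {
  sc <- gen_pose_scene()
  scr <- screen_poses(sc$pocket, sc$poses)
  R <- axis_rotation(c(0, 0, 0), c(1, 2, 3), 37 * pi / 180)
  tv <- c(5, -3, 2)
  prot2 <- sc$protein
  xyz <- apply_rigid(as.matrix(prot2$atoms[, c("x", "y", "z")]), R, tv)
  prot2$atoms$x <- xyz[, 1]; prot2$atoms$y <- xyz[, 2]; prot2$atoms$z <- xyz[, 3]
  poses2 <- lapply(sc$poses, function(p) {
    p$conformers[[1]] <- apply_rigid(p$conformers[[1]], R, tv)
    p
  })
  pk2 <- extract_pocket(prot2, poses2$pass$conformers[[1]])
  scr2 <- screen_poses(pk2, poses2)
  expect_equal(scr2$pass, scr$pass)
  expect_equal(scr2$n_secondary, scr$n_secondary)
  expect_equal(scr2$hbond_val1063_dist, scr$hbond_val1063_dist,
               tolerance = 1e-9)
})

test_that("thresholds are monotone: loosening never loses a flag", {
  sc <- gen_pose_scene()
  strict <- interaction_thresholds()
  loose <- interaction_thresholds(d_hb = 4.5, d_met = 8, d_el = 7,
                                  angle_hb = 90)
  for (p in sc$poses) {
    r1 <- detect_interactions(sc$pocket, p, strict)
    r2 <- detect_interactions(sc$pocket, p, loose)
    for (flag in c("hbond_val1063", "stack_met1054", "stack_met1079",
                   "electro_lys1033", "hbond_asp1153", "hbond_glu1050",
                   "hbond_arg1134")) {
      if (isTRUE(r1[[flag]])) expect_true(r2[[flag]], info = flag)
    }
  }
})

test_that("verdict is a pure function of the report", {
  sc <- gen_pose_scene()
  rep <- detect_interactions(sc$pocket, sc$poses$pass)
  expect_identical(apply_allosteric_filter(rep), apply_allosteric_filter(rep))
})
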