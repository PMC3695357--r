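test_that("feature perception matches the stated rules", {
  f <- perceive_features(parse_smiles("Oc1ccccc1"))
  expect_length(f$donor, 1)
  expect_gte(length(f$acceptor), 1)
  expect_length(f$aromatic_ring, 1)

  f <- perceive_features(parse_smiles("c1ccccc1"))
  expect_length(f$donor, 0)
  expect_length(f$acceptor, 0)
  expect_length(f$aromatic_ring, 1)

  f <- perceive_features(parse_smiles("C"))
  expect_length(f$donor, 0)
  expect_length(f$acceptor, 0)
  expect_length(f$aromatic_ring, 0)
})

test_that("torsion grid collapses for rigid molecules", {
  m <- generate_conformers(parse_smiles("c1ccccc1"), "torsion_grid", 30)
  expect_length(m$conformers, 1)
})

test_that("butane at 120 degrees gives at most 3 distinct conformers", {
  m <- generate_conformers(parse_smiles("CCCC"), "torsion_grid", 120)
  expect_lte(length(m$conformers), 3)
  expect_gte(length(m$conformers), 1)
})

test_that("stochastic conformers are deterministic under a fixed seed", {
  m1 <- generate_conformers(parse_smiles("OCCCN"), "stochastic", 50, seed = 9)
  m2 <- generate_conformers(parse_smiles("OCCCN"), "stochastic", 50, seed = 9)
  expect_identical(m1$conformers, m2$conformers)
})

test_that("planted rigid fixture matches the reduced two-feature model", {
  m <- planted_donor_acceptor(5.0)
  expect_true(match_pharmacophore(m, two_feature_model(5.0, 0.5))$matched)
  expect_false(match_pharmacophore(m, two_feature_model(6.0, 0))$matched)
})

test_that("matching is invariant under rigid motion", {
  m <- planted_donor_acceptor(5.0)
  model <- two_feature_model(5.0, 0.5)
  R <- axis_rotation(c(0, 0, 0), c(1, 1, 2), 1.1)
  m2 <- m
  m2$conformers[[1]] <- apply_rigid(m$conformers[[1]], R, c(-4, 2, 7))
  expect_equal(match_pharmacophore(m2, model)$matched,
               match_pharmacophore(m, model)$matched)
  # and for a non-matching distance too
  model_no <- two_feature_model(8.0, 0.5)
  expect_equal(match_pharmacophore(m2, model_no)$matched,
               match_pharmacophore(m, model_no)$matched)
})

test_that("matching is monotone in tolerance", {
  m <- planted_donor_acceptor(5.0)
  tols <- c(0.2, 0.5, 1.0, 2.0, 4.0)
  hits <- vapply(tols, function(t) {
    match_pharmacophore(m, two_feature_model(6.5, t))$matched
  }, logical(1))
  expect_true(all(diff(hits) >= 0))  # once matched, stays matched
})

test_that("forbidden volume: zero clash distance never rejects, larger never admits", {
  m <- planted_donor_acceptor(5.0)
  positions <- rbind(c(0, 0, 0), c(5, 0, 0))
  wall <- matrix(c(2.5, 0.5, 0), 1, 3)  # near the ligand chain
  verdicts <- vapply(c(0, 0.5, 2, 5, 20), function(cd) {
    model <- pharmacophore_model(c("donor", "acceptor"),
                                 matrix(c(0, 5, 5, 0), 2, 2),
                                 tolerance = 0.5, positions = positions,
                                 forbidden_atoms = wall, clash_distance = cd)
    match_pharmacophore(m, model)$matched
  }, logical(1))
  expect_true(verdicts[1])          # clash 0 never rejects
  expect_true(all(diff(verdicts) <= 0))  # raising clash never admits
})

test_that("model_from_ligand reproduces the planted distances", {
  m <- planted_donor_acceptor(5.0)
  o <- which(m$atoms$elem == "O")
  n <- which(m$atoms$elem == "N")
  model <- model_from_ligand(m, list(donor = o, acceptor = n),
                             tolerance = 0.5)
  expect_equal(model$dist[1, 2], 5.0, tolerance = 1e-9)
  expect_true(match_pharmacophore(m, model)$matched)
})

test_that("flexible matching agrees with the brute-force torsion oracle", {
  m <- allokin:::embed_molecule(parse_smiles("OCCCN", id = "flex"))
  expect_lte(length(allokin:::rotatable_bonds(m)), 3)
  for (d in c(3.0, 4.5, 8.0)) {
    model <- two_feature_model(d, 0.5)
    pkg <- match_pharmacophore(
      generate_conformers(m, "torsion_grid", 30), model)$matched
    expect_equal(pkg, oracle_torsion_match(m, model, 30), info = paste(d))
  }
})

test_that("missing feature kind gives not-matched, missing conformer errors", {
  m <- parse_smiles("CCCC")  # no donor/acceptor
  m$conformers <- list(matrix(0, nrow(m$atoms), 3))
  expect_false(match_pharmacophore(m, two_feature_model(5, 1))$matched)
  m2 <- parse_smiles("OCCN")
  expect_error(match_pharmacophore(m2, two_feature_model(5, 1)), "conformer")
})
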