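# Independent oracles used by the property and acceptance tests.  These are
# deliberate re-implementations from the rule statements (hand-coded graph
# walks / brute-force grids), not calls into the package logic they check.

# ---- strong-donor oracle ---------------------------------------------------

# is heavy atom j a carbonyl/sulfonyl-type center, i.e. a 3- or 4-coordinate
# C or S double-bonded to an O?
oracle_is_cs_oxo <- function(mol, j) {
  if (!(mol$atoms$elem[j] %in% c("C", "S"))) return(FALSE)
  b <- mol$bonds
  any((b$a1 == j & b$order == "2" & mol$atoms$elem[b$a2] == "O") |
        (b$a2 == j & b$order == "2" & mol$atoms$elem[b$a1] == "O"))
}

oracle_neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# the paper's strong-donor rule, evaluated by brute-force graph walks:
#  (a) any aliphatic amine: a non-aromatic nitrogen with only single bonds
#      and no carbonyl/sulfonyl neighbor (any substitution level), OR
#  (b) the printed SMARTS environment: an N-H nitrogen with exactly one
#      hydrogen and two further neighbors, neither of which is a
#      carbonyl/sulfonyl center
oracle_strong_donor <- function(mol) {
  for (i in which(mol$atoms$elem == "N" & !mol$atoms$is_h)) {
    nb <- oracle_neighbors(mol, i)
    nb_heavy <- nb[!mol$atoms$is_h[nb]]
    n_h <- sum(mol$atoms$is_h[nb])
    orders <- mol$bonds$order[mol$bonds$a1 == i | mol$bonds$a2 == i]
    oxo_nb <- any(vapply(nb_heavy, function(j) oracle_is_cs_oxo(mol, j),
                         logical(1)))
    if (!mol$atoms$aromatic[i] && all(orders %in% c("1", "am")) && !oxo_nb) {
      return(TRUE)
    }
    if (n_h == 1L && length(nb_heavy) == 2L && !oxo_nb) return(TRUE)
  }
  FALSE
}

# 50-molecule panel spanning the nitrogen environments the rule talks about
donor_panel <- c(
  "CCN(CC)CC", "CN", "CNC", "CN(C)C", "NC1CCCCC1", "C1CCNCC1",
  "C1CN(C)CCN1C", "C1COCCN1", "NCCO", "NCCN",
  "Nc1ccccc1", "CNc1ccccc1", "c1ccccc1Nc1ccccc1", "CN(C)c1ccccc1",
  "Nc1ccc(O)cc1", "Nc1ccccn1", "Cc1ccc(N)cc1",
  "CNC(C)=O", "CC(=O)Nc1ccccc1", "NC(=O)c1ccccc1", "CNC(=O)NC",
  "CNC(=O)OC", "O=C1CCCN1", "CC(=O)N(C)C",
  "CS(=O)(=O)NC", "CS(=O)(=O)Nc1ccccc1", "O=S(=O)(N)c1ccccc1",
  "c1ccncc1", "c1ccc2ncccc2c1", "c1cc[nH]c1", "c1cc2[nH]ccc2cc1",
  "c1cnc[nH]1", "Cn1cccc1", "c1ccc2[nH]cnc2c1",
  "N#Cc1ccccc1", "CC#N", "O=[N+]([O-])c1ccccc1", "C[N+](C)(C)C",
  "NN", "NO", "CC(=O)NN", "NC(=N)N",
  "OC(=O)CN", "NCC(=O)O", "CNCC(=O)NC",
  "Clc1ccccc1N", "COc1ccc(CN)cc1", "O=C(c1ccccc1)N1CCCCC1",
  "CC(C)(C)NC(=O)C", "c1ccc(CNCc2ccccc2)cc1"
)

# ---- torsion-grid oracle ---------------------------------------------------

# Rodrigues rotation of points about the axis p1 -> p2 (own implementation)
oracle_rotate <- function(xyz, idx, p1, p2, angle) {
  k <- p2 - p1
  k <- k / sqrt(sum(k^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, p1) %*% t(R),
                      2, p1, `+`)
  xyz
}

# atoms on the b-side of bond (a, b) after cutting it
oracle_moving_side <- function(mol, a, b) {
  g <- igraph::make_empty_graph(nrow(mol$atoms), directed = FALSE)
  g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  el <- igraph::as_edgelist(g)
  hit <- which((el[, 1] == a & el[, 2] == b) | (el[, 1] == b & el[, 2] == a))[1]
  g <- igraph::delete_edges(g, hit)
  comp <- igraph::components(g)$membership
  which(comp == comp[b])
}

# does any assignment of one feature per model kind satisfy all pairwise
# distance constraints in coordinate set xyz?
oracle_assignment_ok <- function(mol, xyz, model) {
  feats <- perceive_features(mol)
  cand <- lapply(model$kinds, function(k) {
    f <- feats[[k]]
    if (k == "aromatic_ring") f else as.list(f)
  })
  if (any(vapply(cand, length, 0L) == 0L)) return(FALSE)
  combos <- expand.grid(lapply(cand, seq_along))
  nk <- length(model$kinds)
  for (r in seq_len(nrow(combos))) {
    sel <- as.integer(combos[r, ])
    anchors <- lapply(seq_len(nk), function(j) cand[[j]][[sel[j]]])
    keys <- vapply(anchors, function(a) paste(sort(a), collapse = ","), "")
    if (anyDuplicated(keys)) next
    centers <- t(vapply(anchors,
                        function(a) colMeans(xyz[a, , drop = FALSE]),
                        numeric(3)))
    dmat <- as.matrix(stats::dist(centers))
    if (all(abs(dmat - model$dist) <= model$tolerance + 1e-9)) return(TRUE)
  }
  FALSE
}

# brute-force exhaustive torsion grid: rotate every rotatable bond through
# the full grid (no deduplication) and report whether any combination of
# dihedrals admits a satisfying feature assignment
oracle_torsion_match <- function(mol, model, step_deg) {
  stopifnot(length(mol$conformers) >= 1L)
  seed_xyz <- mol$conformers[[1L]]
  rb <- allokin:::rotatable_bonds(mol)
  angles <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  if (length(rb) == 0L) {
    return(oracle_assignment_ok(mol, seed_xyz, model))
  }
  grids <- expand.grid(rep(list(angles), length(rb)))
  for (r in seq_len(nrow(grids))) {
    xyz <- seed_xyz
    for (j in seq_along(rb)) {
      a <- mol$bonds$a1[rb[j]]
      b <- mol$bonds$a2[rb[j]]
      mov <- setdiff(oracle_moving_side(mol, a, b), b)
      xyz <- oracle_rotate(xyz, mov, xyz[b, ], xyz[a, ],
                           as.numeric(grids[r, j]))
    }
    if (oracle_assignment_ok(mol, xyz, model)) return(TRUE)
  }
  FALSE
}

# ---- shared fixtures -------------------------------------------------------

# rigid planted fixture: a parsed molecule whose single conformer puts the
# hydroxyl O at the origin and the amine N on the x-axis at `dist` Angstrom
planted_donor_acceptor <- function(dist = 5.0) {
  m <- parse_smiles("OCCCCN", id = "planted")
  n <- nrow(m$atoms)
  xyz <- matrix(0, n, 3)
  o <- which(m$atoms$elem == "O")
  nn <- which(m$atoms$elem == "N")
  others <- setdiff(seq_len(n), c(o, nn))
  xyz[o, ] <- c(0, 0, 0)
  xyz[nn, ] <- c(dist, 0, 0)
  # spread the remaining atoms off-axis so no two coincide
  xyz[others, ] <- cbind(seq_along(others), 3, seq_along(others) %% 2)
  m$conformers <- list(xyz)
  m
}

# reduced two-feature model at a stated donor-acceptor distance
two_feature_model <- function(dist, tolerance) {
  pharmacophore_model(c("donor", "acceptor"),
                      matrix(c(0, dist, dist, 0), 2, 2),
                      tolerance = tolerance)
}

# minimal PDB text with one atom per listed residue (name, resname, resno,
# xyz), for pocket-extraction fixtures
mini_pdb <- function(residues) {
  lines <- vapply(seq_along(residues), function(k) {
    r <- residues[[k]]
    allokin:::pdb_atom_line(k, r$name, r$resname, r$resno,
                            r$xyz[1], r$xyz[2], r$xyz[3],
                            substr(r$name, 1, 1))
  }, character(1))
  paste(c(lines, "END", ""), collapse = "\n")
}

write_tmp <- function(text, ext) {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}
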