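#' Four-feature pharmacophore model and matching
#'
#' The binder model is an abstract arrangement of a hydrogen-bond donor, a
#' hydrogen-bond acceptor, an aromatic (5/6-membered) ring and one further
#' heavy-atom group, held together by pairwise center-to-center distance
#' constraints, plus an optional forbidden-volume rule that rejects poses
#' clashing with protein atoms.  The numeric interfeature distances are
#' configuration data, typically derived from a posed reference ligand with
#' [model_from_ligand()].
#'
#' @name pharmacophore
NULL

FEATURE_KINDS <- c("donor", "acceptor", "aromatic_ring", "any_heavy")

#' Perceive pharmacophore features of a molecule
#'
#' Donors are N/O with at least one hydrogen plus protonatable aliphatic
#' amines; acceptors are N/O with an available lone pair (shared definitions
#' with the stage-1 filters); aromatic rings are 5/6-membered rings of
#' aromatic atoms; every heavy atom is a candidate anchor for the `any_heavy`
#' feature.
#'
#' @param mol a `molecule`.
#' @return list with components `donor`, `acceptor` (atom indices),
#'   `aromatic_ring` (list of atom-index vectors) and `any_heavy`.
#' @export
perceive_features <- function(mol) {
  list(
    donor = donor_atoms(mol),
    acceptor = acceptor_atoms(mol),
    aromatic_ring = aromatic_rings(mol),
    any_heavy = heavy_atoms(mol)
  )
}

#' Construct a pharmacophore model
#'
#' @param kinds character vector of feature kinds (subset of donor, acceptor,
#'   aromatic_ring, any_heavy; one instance each).
#' @param dist symmetric matrix of target center-to-center distances
#'   (Angstrom) between features, in the order of `kinds`.
#' @param tolerance allowed deviation per pair (Angstrom), scalar or matrix.
#'   Default 1.0.
#' @param positions optional k x 3 matrix of model-frame feature coordinates
#'   (required for the forbidden-volume check).
#' @param forbidden_atoms optional m x 3 matrix of protein atom coordinates
#'   defining the forbidden volume, in the same frame as `positions`.
#' @param clash_distance minimum allowed ligand-protein atom distance
#'   (Angstrom, default 1.5).
#' @return object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(kinds, dist, tolerance = 1.0,
                                positions = NULL, forbidden_atoms = NULL,
                                clash_distance = 1.5) {
  stopifnot(all(kinds %in% FEATURE_KINDS), !anyDuplicated(kinds))
  dist <- as.matrix(dist)
  k <- length(kinds)
  stopifnot(nrow(dist) == k, ncol(dist) == k,
            isTRUE(all.equal(dist, t(dist))),
            all(dist[upper.tri(dist)] > 0),
            all(tolerance >= 0), clash_distance >= 0)
  if (is.matrix(tolerance)) {
    stopifnot(nrow(tolerance) == k, ncol(tolerance) == k)
  } else {
    tolerance <- matrix(tolerance, k, k)
  }
  if (!is.null(positions)) {
    positions <- matrix(positions, ncol = 3L)
    stopifnot(nrow(positions) == k)
  }
  if (!is.null(forbidden_atoms)) {
    forbidden_atoms <- matrix(forbidden_atoms, ncol = 3L)
  }
  structure(list(kinds = kinds, dist = dist, tolerance = tolerance,
                 positions = positions, forbidden_atoms = forbidden_atoms,
                 clash_distance = clash_distance),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat(sprintf("<pharmacophore_model: %s; tol %.2f A; %s forbidden volume>\n",
              paste(x$kinds, collapse = "+"), max(x$tolerance),
              if (is.null(x$forbidden_atoms)) "no" else
                sprintf("%d-atom", nrow(x$forbidden_atoms))))
  invisible(x)
}

#' Derive a pharmacophore model from a posed reference ligand
#'
#' Reproduces the procedure of building the model from a ligand's orientation
#' in the crystal structure: feature centers are measured on the given
#' conformer and converted into a pairwise distance matrix (and model-frame
#' positions for the forbidden-volume rule).
#'
#' @param mol posed reference ligand (`molecule` with a conformer).
#' @param anchors named list mapping each feature kind to an atom-index
#'   vector (a ring's atoms for `aromatic_ring`).
#' @param conformer conformer index (default 1).
#' @param tolerance,forbidden_atoms,clash_distance passed to
#'   [pharmacophore_model()].
#' @return a `pharmacophore_model`.
#' @export
model_from_ligand <- function(mol, anchors, conformer = 1L, tolerance = 1.0,
                              forbidden_atoms = NULL, clash_distance = 1.5) {
  stopifnot(length(mol$conformers) >= conformer)
  xyz <- mol$conformers[[conformer]]
  kinds <- names(anchors)
  centers <- t(vapply(anchors, function(idx) {
    colMeans(xyz[idx, , drop = FALSE])
  }, numeric(3)))
  pharmacophore_model(kinds, cross_dist(centers, centers),
                      tolerance = tolerance, positions = centers,
                      forbidden_atoms = forbidden_atoms,
                      clash_distance = clash_distance)
}

# deterministic 3-D embedding of a molecule (distance-geometry ETKDG with a
# fixed random seed, run through the bundled helper script; atom order is
# preserved through the mol-block round trip)
embed_molecule <- function(mol, seed = 42L) {
  script <- system.file("python", "embed_conformer.py", package = "allokin")
  if (!nzchar(script)) {
    stop("embed_conformer.py not found; is the package installed?",
         call. = FALSE)
  }
  fin <- tempfile(fileext = ".mol")
  fout <- tempfile(fileext = ".mol")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(mol_to_sdf(mol), fin)
  status <- suppressWarnings(system2("python", c(shQuote(script), seed),
                                     stdin = fin, stdout = fout,
                                     stderr = FALSE))
  if (status != 0L || !file.exists(fout)) {
    stop(sprintf("3-D embedding failed for molecule '%s'", mol$id),
         call. = FALSE)
  }
  ln <- readLines(fout, warn = FALSE)
  natoms <- as.integer(substr(ln[4L], 1L, 3L))
  if (is.na(natoms) || natoms != nrow(mol$atoms)) {
    stop(sprintf("3-D embedding failed for molecule '%s'", mol$id),
         call. = FALSE)
  }
  xyz <- t(vapply(ln[4L + seq_len(natoms)], function(l) {
    c(as.numeric(substr(l, 1L, 10L)), as.numeric(substr(l, 11L, 20L)),
      as.numeric(substr(l, 21L, 30L)))
  }, numeric(3)))
  dimnames(xyz) <- NULL
  mol$conformers <- list(xyz)
  mol
}

# atoms moved when rotating bond k (the side containing a2)
moving_side <- function(mol, k) {
  g <- mol_graph(mol)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
    g, c(as.character(mol$bonds$a1[k]), as.character(mol$bonds$a2[k]))))
  comp <- igraph::components(g2)$membership
  which(comp == comp[mol$bonds$a2[k]])
}

#' Enumerate conformers by torsion driving
#'
#' Starting from one deterministically embedded seed geometry, either
#' enumerates all rotatable-bond dihedrals on a regular angular grid
#' (`torsion_grid`) or draws the requested number of random dihedral vectors
#' from a fixed seed (`stochastic`).  Conformers are deduplicated by
#' best-fit heavy-atom RMSD below `dedup_rmsd`.
#'
#' @param mol a `molecule` (a conformer is embedded if absent).
#' @param mode `"torsion_grid"` or `"stochastic"`.
#' @param step_or_count grid step in degrees (torsion_grid) or number of
#'   samples (stochastic).
#' @param seed RNG seed for stochastic mode (default 1).
#' @param dedup_rmsd deduplication threshold in Angstrom (default 0.25).
#' @return the molecule with its `conformers` list populated.
#' @export
generate_conformers <- function(mol, mode = c("torsion_grid", "stochastic"),
                                step_or_count = 30, seed = 1L,
                                dedup_rmsd = 0.25) {
  mode <- match.arg(mode)
  if (length(mol$conformers) == 0L) mol <- embed_molecule(mol)
  seed_xyz <- mol$conformers[[1L]]
  rb <- rotatable_bonds(mol)
  if (length(rb) == 0L) {
    mol$conformers <- list(seed_xyz)
    return(mol)
  }
  sides <- lapply(rb, function(k) moving_side(mol, k))
  angle_sets <- if (mode == "torsion_grid") {
    step <- step_or_count
    stopifnot(step > 0, step <= 360)
    as.matrix(expand.grid(rep(list(seq(0, 360 - step, by = step)),
                              length(rb))))
  } else {
    n <- step_or_count
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    m <- matrix(stats::runif(n * length(rb), 0, 360), nrow = n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    m
  }
  heavy <- heavy_atoms(mol)
  kept <- list()
  for (r in seq_len(nrow(angle_sets))) {
    xyz <- seed_xyz
    for (j in seq_along(rb)) {
      k <- rb[j]
      xyz <- rotate_about_bond(xyz, sides[[j]],
                               xyz[mol$bonds$a1[k], ], xyz[mol$bonds$a2[k], ],
                               angle_sets[r, j])
    }
    dup <- FALSE
    for (kc in kept) {
      if (rmsd_fit(xyz[heavy, , drop = FALSE],
                   kc[heavy, , drop = FALSE]) < dedup_rmsd) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- xyz
  }
  mol$conformers <- kept
  mol
}

# heavy-graph bond distances between atoms (for the "distanced group" rule)
graph_distances <- function(mol) {
  g <- mol_graph(mol)
  igraph::distances(g)
}

#' Match a molecule against a pharmacophore model
#'
#' For every conformer, searches exhaustively over assignments of one
#' perceived feature per model kind; a conformer matches when all pairwise
#' feature-center distances lie within tolerance of the model distances.  The
#' `any_heavy` anchor must be a group distanced from the other assigned
#' features (at least 2 bonds in the graph).  When the model carries
#' `forbidden_atoms`, the conformer is rigidly superposed by its assigned
#' feature centers onto the model-frame positions and rejected if any ligand
#' atom comes closer than `clash_distance` to a protein atom.
#'
#' @param mol a `molecule` with at least one conformer.
#' @param model a `pharmacophore_model`.
#' @return list of class `match_result`: `matched` (logical), and when
#'   matched, `conformer` (index) and `assignment` (named list of anchors).
#' @export
match_pharmacophore <- function(mol, model) {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (length(mol$conformers) == 0L) {
    stop(sprintf("molecule '%s' has no conformers", mol$id), call. = FALSE)
  }
  feats <- perceive_features(mol)
  cand <- lapply(model$kinds, function(k) {
    f <- feats[[k]]
    if (k == "aromatic_ring") f else as.list(f)
  })
  if (any(vapply(cand, length, 0L) == 0L)) {
    return(structure(list(matched = FALSE), class = "match_result"))
  }
  gd <- if ("any_heavy" %in% model$kinds) graph_distances(mol) else NULL
  combos <- expand.grid(lapply(cand, seq_along))
  nk <- length(model$kinds)
  use_fv <- !is.null(model$forbidden_atoms) && !is.null(model$positions) &&
    model$clash_distance > 0
  for (ci in seq_along(mol$conformers)) {
    xyz <- mol$conformers[[ci]]
    centers_by_kind <- lapply(cand, function(anchors) {
      t(vapply(anchors, function(idx) colMeans(xyz[idx, , drop = FALSE]),
               numeric(3)))
    })
    for (r in seq_len(nrow(combos))) {
      sel <- as.integer(combos[r, ])
      anchors <- lapply(seq_len(nk), function(j) cand[[j]][[sel[j]]])
      # distinct anchors: no feature may reuse exactly the same atom set
      keys <- vapply(anchors, function(a) paste(sort(a), collapse = ","), "")
      if (anyDuplicated(keys)) next
      if (!is.null(gd)) {
        ah <- which(model$kinds == "any_heavy")
        others <- unlist(anchors[-ah])
        if (min(gd[anchors[[ah]], others]) < 2) next
      }
      centers <- t(vapply(seq_len(nk),
                          function(j) centers_by_kind[[j]][sel[j], ],
                          numeric(3)))
      dmat <- cross_dist(centers, centers)
      if (any(abs(dmat - model$dist) > model$tolerance + 1e-9)) next
      if (use_fv) {
        fit <- kabsch(centers, model$positions)
        lig <- apply_rigid(xyz[!mol$atoms$is_h, , drop = FALSE], fit$R, fit$t)
        if (min_pair_dist(lig, model$forbidden_atoms) <
              model$clash_distance) next
      }
      names(anchors) <- model$kinds
      return(structure(list(matched = TRUE, conformer = ci,
                            assignment = anchors),
                       class = "match_result"))
    }
  }
  structure(list(matched = FALSE), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("<match_result: matched (conformer %d)>\n", x$conformer))
  } else {
    cat("<match_result: not matched>\n")
  }
  invisible(x)
}
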