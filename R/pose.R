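#' Binding-site extraction and post-docking interaction filters
#'
#' Poses arrive pre-docked (ligand coordinates in the protein frame); the
#' functions here extract the pocket around a reference ligand, measure the
#' key protein-ligand interaction geometries and apply the allosteric
#' selection rule: all main filters (hydrogen bond to Val1063, sulfur-aromatic
#' stacking with Met1054 and Met1079) plus at least one secondary filter
#' (electrostatics with Lys1033, or a hydrogen bond with Asp1153, Glu1050 or
#' Arg1134).
#'
#' @name pose_interactions
NULL

#' Default interaction geometry thresholds
#'
#' @param d_hb maximum donor-heavy-atom to acceptor distance for a hydrogen
#'   bond (Angstrom, default 3.5).
#' @param angle_hb minimum donor-H...acceptor angle (degrees, default 120).
#' @param d_met maximum aromatic-ring-centroid to methionine-sulfur distance
#'   for sulfur-aromatic stacking (Angstrom, default 6.0).
#' @param d_el maximum anion/acceptor to lysine side-chain-N distance for an
#'   electrostatic contact (Angstrom, default 5.0).
#' @param residues named list of residue numbers used by the filters;
#'   override when a structure uses different numbering.
#' @param secondary which secondary rules participate in the verdict
#'   (default: Lys1033 electrostatics and Asp1153/Glu1050/Arg1134 hydrogen
#'   bonds; His1133/Asp1154 contacts are reported as extras either way).
#' @return list of class `interaction_thresholds`.
#' @export
interaction_thresholds <- function(d_hb = 3.5, angle_hb = 120,
                                   d_met = 6.0, d_el = 5.0,
                                   residues = list(
                                     val_hb = 1063L, met_stack = c(1054L, 1079L),
                                     lys_el = 1033L, asp_hb = 1153L,
                                     glu_hb = 1050L, arg_hb = 1134L,
                                     extras = c(1133L, 1154L)),
                                   secondary = c("electro_lys1033",
                                                 "hbond_asp1153",
                                                 "hbond_glu1050",
                                                 "hbond_arg1134")) {
  stopifnot(d_hb > 0, d_met > 0, d_el > 0, angle_hb >= 0, angle_hb <= 180)
  structure(list(d_hb = d_hb, angle_hb = angle_hb, d_met = d_met, d_el = d_el,
                 residues = residues, secondary = secondary),
            class = "interaction_thresholds")
}

#' Extract the binding-site model around a reference ligand
#'
#' A residue is retained iff at least one of its atoms lies within `radius`
#' of some ligand atom (the radius defaults to 10 Angstrom = 1.0 nm).
#'
#' @param protein a `protein_structure`.
#' @param ligand_coords n x 3 matrix of reference-ligand coordinates
#'   (Angstrom, protein frame).
#' @param radius inclusion radius in Angstrom (default 10).
#' @return object of class `pocket_model` with the retained residue atoms.
#' @export
extract_pocket <- function(protein, ligand_coords, radius = 10) {
  stopifnot(inherits(protein, "protein_structure"))
  if (nrow(protein$atoms) == 0L) stop("empty protein", call. = FALSE)
  ligand_coords <- matrix(ligand_coords, ncol = 3L)
  if (nrow(ligand_coords) == 0L) stop("ligand has no atoms", call. = FALSE)
  if (!is.numeric(radius) || radius <= 0) {
    stop("radius must be positive", call. = FALSE)
  }
  a <- protein$atoms
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]), ligand_coords)
  mind <- apply(d, 1L, min)
  key <- paste(a$chain, a$resno)
  keep_res <- unique(key[mind <= radius])
  atoms <- a[key %in% keep_res, , drop = FALSE]
  structure(list(atoms = atoms, radius = radius,
                 source_ligand = ligand_coords,
                 residues = unique(atoms[, c("chain", "resno", "resname")])),
            class = "pocket_model")
}

#' @export
print.pocket_model <- function(x, ...) {
  cat(sprintf("<pocket_model: %d residues within %.1f A>\n",
              nrow(x$residues), x$radius))
  invisible(x)
}

pocket_res_atoms <- function(pocket, resno, names = NULL) {
  a <- pocket$atoms[pocket$atoms$resno == resno, , drop = FALSE]
  if (!is.null(names)) a <- a[a$name %in% names, , drop = FALSE]
  a
}

pocket_res_xyz <- function(pocket, resno, names = NULL) {
  as.matrix(pocket_res_atoms(pocket, resno, names)[, c("x", "y", "z")])
}

# best ligand-donor -> protein-acceptor hydrogen bond geometry:
# distance is donor-heavy to acceptor; angle is donor-H...acceptor
best_hbond_to_acceptor <- function(pose, xyz, acceptor_xyz, thr) {
  don <- donor_atoms(pose)
  best <- list(found = FALSE, dist = NA_real_, angle = NA_real_)
  if (!length(don) || nrow(acceptor_xyz) == 0L) return(best)
  for (d in don) {
    hs <- atom_neighbors(pose, d)
    hs <- hs[pose$atoms$is_h[hs]]
    for (ai in seq_len(nrow(acceptor_xyz))) {
      acc <- acceptor_xyz[ai, ]
      dist <- vec_norm(xyz[d, ] - acc)
      ang <- if (length(hs)) {
        max(vapply(hs, function(h) angle_deg(xyz[d, ], xyz[h, ], acc),
                   numeric(1)))
      } else {
        NA_real_
      }
      ok <- dist <= thr$d_hb && (!is.na(ang) && ang >= thr$angle_hb)
      if (ok) return(list(found = TRUE, dist = dist, angle = ang))
      if (is.na(best$dist) || dist < best$dist) {
        best <- list(found = FALSE, dist = dist, angle = ang)
      }
    }
  }
  best
}

# protein-donor -> ligand-acceptor contact (distance-only: crystallographic
# protein records carry no hydrogens)
best_hbond_from_donor <- function(pose, xyz, donor_xyz, thr) {
  acc <- acceptor_atoms(pose)
  if (!length(acc) || nrow(donor_xyz) == 0L) {
    return(list(found = FALSE, dist = NA_real_))
  }
  d <- cross_dist(xyz[acc, , drop = FALSE], donor_xyz)
  list(found = min(d) <= thr$d_hb, dist = min(d))
}

#' Measure the post-docking interaction geometries of one pose
#'
#' Hydrogen bonds use a donor-heavy-to-acceptor distance plus a
#' donor-H...acceptor angle criterion; the Val1063 acceptor is its backbone
#' carbonyl oxygen (valine has no side-chain carboxyl).  Methionine
#' "stacking" is measured as the aromatic-ring-centroid to sulfur distance.
#' The electrostatic rule accepts a ligand anion or acceptor atom near the
#' Lys1033 side-chain nitrogen.  All raw geometries are reported so
#' borderline calls can be audited or re-scored.
#'
#' @param pocket a `pocket_model` containing the filter residues.
#' @param pose a `molecule` with one conformer in the protein frame
#'   (explicit hydrogens; added automatically by [read_sdf()]).
#' @param thr an `interaction_thresholds` object.
#' @return list of class `interaction_report` with per-rule flags and
#'   geometry values.
#' @export
detect_interactions <- function(pocket, pose, thr = interaction_thresholds()) {
  stopifnot(inherits(pocket, "pocket_model"), inherits(pose, "molecule"))
  if (length(pose$conformers) == 0L) {
    stop("pose has no coordinates", call. = FALSE)
  }
  res <- thr$residues
  need <- c(res$val_hb, res$met_stack, res$lys_el, res$asp_hb, res$glu_hb,
            res$arg_hb)
  missing <- setdiff(need, pocket$atoms$resno)
  if (length(missing)) {
    stop(sprintf("filter residues missing from pocket: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  xyz <- pose$conformers[[1L]]

  # main 1: H-bond to the Val backbone carbonyl O
  val_acc <- pocket_res_xyz(pocket, res$val_hb, names = c("O", "OXT"))
  hb_val <- best_hbond_to_acceptor(pose, xyz, val_acc, thr)

  # main 2+3: ring-centroid to Met S distances
  rings <- aromatic_rings(pose)
  centroids <- if (length(rings)) {
    t(vapply(rings, function(r) colMeans(xyz[r, , drop = FALSE]), numeric(3)))
  } else {
    matrix(numeric(), 0L, 3L)
  }
  met <- lapply(res$met_stack, function(rn) {
    s <- pocket_res_xyz(pocket, rn, names = "SD")
    if (nrow(s) == 0L || nrow(centroids) == 0L) {
      list(found = FALSE, dist = NA_real_)
    } else {
      d <- min(cross_dist(centroids, s))
      list(found = d <= thr$d_met, dist = d)
    }
  })

  # secondary: Lys NZ electrostatics against ligand anions/acceptors
  nz <- pocket_res_xyz(pocket, res$lys_el, names = "NZ")
  el_atoms <- union(acceptor_atoms(pose), which(pose$atoms$charge < 0L))
  el <- if (nrow(nz) && length(el_atoms)) {
    d <- min(cross_dist(xyz[el_atoms, , drop = FALSE], nz))
    list(found = d <= thr$d_el, dist = d)
  } else {
    list(found = FALSE, dist = NA_real_)
  }

  # secondary H-bonds: ligand donors to Asp/Glu side-chain carboxylates;
  # Arg guanidinium (protein donor) to ligand acceptors
  hb_asp <- best_hbond_to_acceptor(
    pose, xyz, pocket_res_xyz(pocket, res$asp_hb, c("OD1", "OD2")), thr)
  hb_glu <- best_hbond_to_acceptor(
    pose, xyz, pocket_res_xyz(pocket, res$glu_hb, c("OE1", "OE2")), thr)
  hb_arg <- best_hbond_from_donor(
    pose, xyz, pocket_res_xyz(pocket, res$arg_hb, c("NE", "NH1", "NH2")), thr)

  # optional extra contacts (His1133 / Asp1154 etc.): nearest-atom distances
  extras <- lapply(res$extras, function(rn) {
    p <- pocket_res_xyz(pocket, rn)
    if (nrow(p) == 0L) return(NULL)
    hv <- heavy_atoms(pose)
    list(resno = rn, min_dist = min(cross_dist(xyz[hv, , drop = FALSE], p)))
  })
  extras <- Filter(Negate(is.null), extras)

  structure(list(
    hbond_val1063 = hb_val$found,
    hbond_val1063_geom = c(dist = hb_val$dist, angle = hb_val$angle),
    stack_met1054 = met[[1]]$found,
    stack_met1054_dist = met[[1]]$dist,
    stack_met1079 = met[[2]]$found,
    stack_met1079_dist = met[[2]]$dist,
    electro_lys1033 = el$found,
    electro_lys1033_dist = el$dist,
    hbond_asp1153 = hb_asp$found,
    hbond_asp1153_geom = c(dist = hb_asp$dist, angle = hb_asp$angle),
    hbond_glu1050 = hb_glu$found,
    hbond_glu1050_geom = c(dist = hb_glu$dist, angle = hb_glu$angle),
    hbond_arg1134 = hb_arg$found,
    hbond_arg1134_dist = hb_arg$dist,
    extras = extras,
    secondary_rules = thr$secondary
  ), class = "interaction_report")
}

#' Apply the allosteric selection rule to an interaction report
#'
#' Pass iff all three main filters hold (Val1063 hydrogen bond, Met1054 and
#' Met1079 stacking) and at least one configured secondary filter holds.
#'
#' @param report an `interaction_report`.
#' @return list of class `filter_verdict`: `pass`, `main_satisfied` (named
#'   logical) and `n_secondary`.
#' @export
apply_allosteric_filter <- function(report) {
  stopifnot(inherits(report, "interaction_report"))
  main <- c(hbond_val1063 = isTRUE(report$hbond_val1063),
            stack_met1054 = isTRUE(report$stack_met1054),
            stack_met1079 = isTRUE(report$stack_met1079))
  sec <- vapply(report$secondary_rules, function(r) isTRUE(report[[r]]),
                logical(1))
  structure(list(pass = all(main) && sum(sec) >= 1L,
                 main_satisfied = main, n_secondary = sum(sec)),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat(sprintf("<filter_verdict: %s (main %d/3, secondary %d)>\n",
              if (x$pass) "PASS" else "FAIL", sum(x$main_satisfied),
              x$n_secondary))
  invisible(x)
}

#' Screen a set of docked poses through the allosteric filter
#'
#' @param pocket a `pocket_model`.
#' @param poses list of posed `molecule`s (e.g. from [read_sdf()]).
#' @param thr an `interaction_thresholds` object.
#' @return data frame with one row per pose: id, every flag, the raw
#'   geometry values and the verdict.
#' @export
screen_poses <- function(pocket, poses, thr = interaction_thresholds()) {
  rows <- lapply(poses, function(p) {
    rep <- detect_interactions(pocket, p, thr)
    v <- apply_allosteric_filter(rep)
    data.frame(
      id = p$id,
      hbond_val1063 = rep$hbond_val1063,
      hbond_val1063_dist = rep$hbond_val1063_geom[["dist"]],
      stack_met1054 = rep$stack_met1054,
      stack_met1054_dist = rep$stack_met1054_dist,
      stack_met1079 = rep$stack_met1079,
      stack_met1079_dist = rep$stack_met1079_dist,
      electro_lys1033 = rep$electro_lys1033,
      hbond_asp1153 = rep$hbond_asp1153,
      hbond_glu1050 = rep$hbond_glu1050,
      hbond_arg1134 = rep$hbond_arg1134,
      n_secondary = v$n_secondary,
      pass = v$pass,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
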