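#' Seeded generators for every pipeline input
#'
#' Each generator emulates one class of input the screening pipeline
#' consumes — compound libraries, pocket/pose geometry, raw plates,
#' dose-response tables and kinetics tables — with the ground truth known by
#' construction, so every downstream stage can be validated without external
#' data.  All generators are deterministic under a fixed seed and leave the
#' global random-number state untouched.
#'
#' @name synthetic_data
NULL

# run expr under a private RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# ---- compound libraries ----------------------------------------------------

# label-neutral alkyl decorations grafted into the %s slot of each template
LIB_ALKYLS <- c("C", "CC", "CCC", "C(C)C", "CCCC")

# curated templates; labels are true by construction:
#   donor   = carries a strong hydrogen-bond donor (aliphatic/anilino amine)
#   markush = two linked aromatic rings with a meta/para acceptor substituent
#   prereqs = has >= 1 aromatic ring and >= 1 acceptor
LIB_TEMPLATES <- list(
  markush_donor = list(
    templates = c("Oc1ccc(CNc2ccc(%s)cc2)cc1",
                  "Oc1cccc(CNc2ccc(%s)cc2)c1",
                  "Nc1ccc(COc2ccc(%s)cc2)cc1"),
    donor = TRUE, markush = TRUE, prereqs = TRUE),
  markush_nodonor = list(
    templates = c("COc1ccc(COc2ccc(%s)cc2)cc1",
                  "COc1cccc(CCc2ccc(%s)cc2)c1"),
    donor = FALSE, markush = TRUE, prereqs = TRUE),
  plain_donor = list(
    templates = c("Nc1ccc(%s)cc1",
                  "NC1CCC(%s)CC1"),
    donor = TRUE, markush = FALSE,
    prereqs = c(TRUE, FALSE)),  # the cyclohexylamine has no aromatic ring
  plain_nodonor = list(
    templates = c("COc1ccc(%s)cc1",
                  "c1ccc(-c2ccc(%s)cc2)cc1",
                  "CCOC(=O)C%s"),
    donor = FALSE, markush = FALSE,
    prereqs = c(TRUE, FALSE, FALSE))  # biphenyl/ester lack an acceptor/ring
)

#' Generate a compound library with by-construction labels
#'
#' Molecules are assembled by grafting label-neutral alkyl fragments into
#' curated SMILES templates, so the emitted `donor` / `prereqs` / `markush`
#' labels are ground truth for the corresponding filters rather than the
#' output of any checker.
#'
#' @param n number of molecules.
#' @param seed integer seed; identical arguments give identical output.
#' @param frac_markush fraction of Markush-compliant molecules, in [0, 1].
#' @param frac_donor fraction of strong-donor-bearing molecules, in [0, 1]
#'   (drawn independently of `frac_markush`, except that all Markush
#'   templates with a donor keep it).
#' @return data frame with columns `id`, `smiles`, `donor`, `prereqs`,
#'   `markush`.
#' @export
gen_library <- function(n, seed = 1L, frac_markush = 0.3, frac_donor = 0.5) {
  if (n < 1L) stop("spec error: n must be at least 1", call. = FALSE)
  if (frac_markush < 0 || frac_markush > 1 || frac_donor < 0 ||
      frac_donor > 1) {
    stop("spec error: planted fractions must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    markush <- stats::runif(n) < frac_markush
    donor <- stats::runif(n) < frac_donor
    rows <- lapply(seq_len(n), function(i) {
      cat_name <- paste0(if (markush[i]) "markush" else "plain",
                         if (donor[i]) "_donor" else "_nodonor")
      cat <- LIB_TEMPLATES[[cat_name]]
      k <- sample.int(length(cat$templates), 1L)
      smi <- sprintf(cat$templates[k], sample(LIB_ALKYLS, 1L))
      prereqs <- rep_len(cat$prereqs, length(cat$templates))[k]
      data.frame(id = sprintf("syn_%04d", i), smiles = smi,
                 donor = donor[i], prereqs = prereqs, markush = markush[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# ---- pocket / pose scenes --------------------------------------------------

pdb_atom_line <- function(serial, name, resname, resno, x, y, z, elem) {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, resname, resno, x, y, z, elem)
}

# hexagonal aromatic ring in the xy-plane, centroid at the origin
scene_ring_xyz <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
}

# ligand: 4-aminophenol (with_phenol) or aniline, built with explicit donor
# hydrogens and a single conformer already in the protein frame
scene_ligand <- function(id, with_phenol = TRUE, shift = c(0, 0, 0)) {
  xyz <- rbind(
    scene_ring_xyz(),
    c(2.83, 0, 0),        # 7  N (anilino donor)
    c(3.83, 0, 0),        # 8  H on N, pointing at the Val carbonyl
    c(2.48, 0.95, 0))     # 9  H on N
  elem <- c(rep("C", 6), "N", "H", "H")
  arom <- c(rep(TRUE, 6), FALSE, FALSE, FALSE)
  bonds <- data.frame(
    a1 = c(1:6, 1L, 7L, 7L),
    a2 = c(2:6, 1L, 7L, 8L, 9L),
    order = c(rep("ar", 6), "1", "1", "1"),
    stringsAsFactors = FALSE)
  if (with_phenol) {
    xyz <- rbind(xyz,
                 c(-2.75, 0, 0),   # 10 O (phenol)
                 c(-3.30, 0.85, 0))  # 11 H on O
    elem <- c(elem, "O", "H")
    arom <- c(arom, FALSE, FALSE)
    bonds <- rbind(bonds,
                   data.frame(a1 = c(4L, 10L), a2 = c(10L, 11L),
                              order = "1", stringsAsFactors = FALSE))
  }
  xyz <- sweep(xyz, 2L, shift, "+")
  atoms <- data.frame(elem = elem, is_h = elem == "H", aromatic = arom,
                      charge = 0L, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  new_molecule(id, atoms, bonds, conformers = list(unname(xyz)))
}

scene_pdb_text <- function(d_val) {
  res <- list(
    # Val1063: backbone carbonyl O on the ligand N-H axis, d_val from the N
    list("VAL", 1063, list(O = c(2.83 + d_val, 0, 0), C = c(3.9 + d_val, 0.9, 0),
                           CA = c(5.2 + d_val, 0.7, 0.3), N = c(5.8 + d_val, 1.9, 0.5))),
    # Met1054/1079: SD above/below the ring plane (stacking distances 4.0/4.53)
    list("MET", 1054, list(SD = c(0, 0, 4.0), CG = c(0, 0.8, 5.2),
                           CB = c(0, 1.9, 6.0), CE = c(1.6, 0, 4.6))),
    list("MET", 1079, list(SD = c(0.5, 0, -4.5), CG = c(0.5, 0.8, -5.7),
                           CB = c(0.5, 1.9, -6.5), CE = c(2.1, 0, -5.1))),
    # Lys1033: NZ 4.0 A from the phenol oxygen
    list("LYS", 1033, list(NZ = c(-2.75, 4.0, 0), CE = c(-2.75, 5.5, 0),
                           CD = c(-2.75, 6.8, 0.8))),
    # remaining filter residues: present in the pocket but out of range
    list("GLU", 1050, list(OE1 = c(4, -7, 3), OE2 = c(4.8, -7.6, 3.4),
                           CD = c(4.3, -8.2, 2.6))),
    list("HIS", 1133, list(NE2 = c(6, -5, -4), CE1 = c(6.8, -5.6, -4.5))),
    list("ARG", 1134, list(NE = c(-4, 7, -3), NH1 = c(-4.8, 8.2, -3.2),
                           NH2 = c(-3.4, 8.0, -4.0), CZ = c(-4.1, 8.4, -3.5))),
    list("ASP", 1153, list(OD1 = c(0, -8, 0), OD2 = c(0.6, -8.6, 0.9),
                           CG = c(0.2, -8.9, -0.2))),
    list("ASP", 1154, list(OD1 = c(-6, -5, 3), OD2 = c(-6.7, -5.6, 3.4),
                           CG = c(-6.4, -5.9, 2.5)))
  )
  lines <- character()
  serial <- 0L
  for (r in res) {
    for (nm in names(r[[3]])) {
      serial <- serial + 1L
      p <- r[[3]][[nm]]
      lines <- c(lines, pdb_atom_line(serial, nm, r[[1]], r[[2]],
                                      p[1], p[2], p[3], substr(nm, 1, 1)))
    }
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

#' Generate a pocket/pose scene with planted interaction geometry
#'
#' Builds a minimal binding-site model (residues Lys1033, Glu1050, Met1054,
#' Val1063, Met1079, His1133, Arg1134, Asp1153, Asp1154 at fixed
#' coordinates) and three ligand poses whose interaction distances sit
#' strictly inside or outside the filter thresholds by at least `margin`
#' Angstrom: a full pass case (all main filters plus the Lys1033
#' electrostatic contact), a main-only case (all main filters, no
#' secondary) and a broken-main case (Val1063 hydrogen bond out of range).
#'
#' @param margin planted distance margin in Angstrom, between 0.01 (the
#'   coordinate precision) and 1.
#' @param thr an `interaction_thresholds` object (defaults used for the
#'   planted geometry).
#' @return list with `protein` (a `protein_structure`), `pocket` (a
#'   `pocket_model` around the pass pose), `poses` (named list of
#'   `molecule`s), `truth` (data frame of expected verdicts), `pdb_text`
#'   and `sdf_text`.
#' @export
gen_pose_scene <- function(margin = 0.5, thr = interaction_thresholds()) {
  if (!is.numeric(margin) || margin < 0.01 || margin > 1) {
    stop("spec error: margin must lie in [0.01, 1] Angstrom", call. = FALSE)
  }
  d_val <- thr$d_hb - margin
  txt <- scene_pdb_text(d_val)
  pdb_path <- tempfile(fileext = ".pdb")
  writeLines(txt, pdb_path)
  protein <- read_pdb_protein(pdb_path)
  unlink(pdb_path)

  poses <- list(
    pass = scene_ligand("pose_pass", with_phenol = TRUE),
    main_only = scene_ligand("pose_main_only", with_phenol = FALSE),
    fail_main = scene_ligand("pose_fail_main", with_phenol = TRUE,
                             shift = c(-2 * margin, 0, 0))
  )
  truth <- data.frame(
    pose = names(poses),
    expect_pass = c(TRUE, FALSE, FALSE),
    description = c(
      "all three main filters + Lys1033 electrostatics",
      "main filters hold but no secondary contact",
      sprintf("Val1063 H-bond stretched to %.2f A (> %.1f)",
              d_val + 2 * margin, thr$d_hb)),
    stringsAsFactors = FALSE)
  pocket <- extract_pocket(protein, poses$pass$conformers[[1]])
  list(protein = protein, pocket = pocket, poses = poses, truth = truth,
       pdb_text = txt,
       sdf_text = paste(vapply(poses, mol_to_sdf, character(1)),
                        collapse = ""),
       margin = margin)
}

# ---- plates ----------------------------------------------------------------

#' Generate a 384-well plate with planted inhibitors
#'
#' Control columns follow the standard layout; every well is drawn from a
#' normal distribution whose standard deviation is `noise_frac` of the
#' control separation.  Planted compounds have their mean shifted down by
#' the stated percent inhibition.
#'
#' @param seed integer seed.
#' @param n_hits number of planted inhibitors (default 8).
#' @param percent_inhibition planted effect size in percent of the control
#'   window (default 50).
#' @param neg_mean,pos_mean no-inhibition and no-kinase control means in RLU.
#' @param noise_frac Gaussian noise SD as a fraction of the control
#'   separation (must be > 0; default 0.05).
#' @return list with `plate` (a `plate`) and `truth` (data frame: compound,
#'   planted, true_inhibition).
#' @export
gen_plate <- function(seed = 1L, n_hits = 8L, percent_inhibition = 50,
                      neg_mean = 9000, pos_mean = 1000, noise_frac = 0.05) {
  if (noise_frac <= 0) {
    stop("spec error: noise_frac must be positive", call. = FALSE)
  }
  if (percent_inhibition < 0 || percent_inhibition > 100) {
    stop("spec error: percent_inhibition must lie in [0, 100]", call. = FALSE)
  }
  stopifnot(neg_mean > pos_mean)
  roles <- default_roles()
  n_samples <- sum(roles == "sample")
  if (n_hits < 0L || n_hits > n_samples) {
    stop(sprintf("spec error: n_hits must lie in [0, %d]", n_samples),
         call. = FALSE)
  }
  sd <- noise_frac * (neg_mean - pos_mean)
  with_seed(seed, {
    rlu <- matrix(0, PLATE_ROWS, PLATE_COLS)
    rlu[roles == "pos_ctrl_no_kinase"] <-
      stats::rnorm(sum(roles == "pos_ctrl_no_kinase"), pos_mean, sd)
    rlu[roles == "neg_ctrl_no_inhibition"] <-
      stats::rnorm(sum(roles == "neg_ctrl_no_inhibition"), neg_mean, sd)
    sw <- which(roles == "sample")
    means <- rep(neg_mean, n_samples)
    planted <- sample(n_samples, n_hits)
    means[planted] <- neg_mean - percent_inhibition / 100 *
      (neg_mean - pos_mean)
    rlu[sw] <- stats::rnorm(n_samples, means, sd)
    rlu[rlu < 0] <- 0
    ids <- matrix(NA_character_, PLATE_ROWS, PLATE_COLS)
    ids[sw] <- sprintf("cmpd_%03d", seq_len(n_samples))
    p <- plate(rlu, roles, ids)
    truth <- data.frame(
      compound = ids[sw],
      planted = seq_len(n_samples) %in% planted,
      true_inhibition = ifelse(seq_len(n_samples) %in% planted,
                               percent_inhibition, 0),
      stringsAsFactors = FALSE)
    list(plate = p, truth = truth)
  })
}

# ---- dose-response ---------------------------------------------------------

#' Generate a dose-response dataset with known IC50 and Hill slope
#'
#' An 8-point 1:2 dilution series from a stated top concentration, measured
#' in quadruplicate, with Gaussian noise added to the percent-activity
#' values.
#'
#' @param seed integer seed.
#' @param ic50 true IC50 in micromolar (default 25).
#' @param hill true Hill slope (default 1).
#' @param top_uM top assay concentration (default 100).
#' @param n_points,fold dilution design (defaults 8 points, 1:2).
#' @param replicates replicate count per point (default 4).
#' @param noise_sd Gaussian noise SD in percent-activity points (default 5;
#'   0 gives noise-free data).
#' @return data frame with columns `conc_uM`, `replicate`, `activity` and
#'   attributes `true_ic50`, `true_hill`.
#' @export
gen_dose_response <- function(seed = 1L, ic50 = 25, hill = 1, top_uM = 100,
                              n_points = 8L, fold = 2, replicates = 4L,
                              noise_sd = 5) {
  stopifnot(ic50 > 0, hill > 0, noise_sd >= 0, replicates >= 1)
  conc <- dilution_series(dilution_scheme(top_uM, fold, n_points,
                                          transfer_dilution = 1))$final_uM
  with_seed(seed, {
    d <- expand.grid(replicate = seq_len(replicates), conc_uM = conc)
    d <- d[, c("conc_uM", "replicate")]
    mu <- ic50_model(d$conc_uM, log10(ic50), hill)
    d$activity <- mu + stats::rnorm(nrow(d), 0, noise_sd)
    rownames(d) <- NULL
    structure(d, true_ic50 = ic50, true_hill = hill)
  })
}

# ---- kinetics --------------------------------------------------------------

KINETIC_MECHANISMS <- c("competitive", "non-competitive", "uncompetitive",
                        "mixed", "none")

# apparent (Vmax, Km) under the textbook inhibition laws
apparent_params <- function(mechanism, vmax, km, I, ki, ki_prime) {
  a <- 1 + I / ki
  ap <- 1 + I / ki_prime
  switch(mechanism,
         competitive = list(vmax = vmax, km = km * a),
         `non-competitive` = list(vmax = vmax / a, km = km),
         uncompetitive = list(vmax = vmax / a, km = km / a),
         mixed = list(vmax = vmax / ap, km = km * a / ap),
         none = list(vmax = vmax, km = km))
}

#' Generate a Michaelis-Menten kinetics dataset with known mechanism
#'
#' Rates follow the stated mechanism's apparent-parameter laws at each
#' inhibitor level (default design: eight 1:2 substrate concentrations from
#' 519 uM and inhibitor at 100, 50, 25, 12 and 0 uM) with multiplicative
#' Gaussian noise, in quadruplicate.
#'
#' @param seed integer seed.
#' @param mechanism one of `"competitive"`, `"non-competitive"`,
#'   `"uncompetitive"`, `"mixed"`, `"none"`.
#' @param vmax,km uninhibited parameters (defaults 100, 130 uM).
#' @param ki inhibition constant in uM (default 30).
#' @param ki_prime second inhibition constant of the mixed mechanism
#'   (default `3 * ki`; ignored otherwise).
#' @param I_uM inhibitor concentrations (must include 0).
#' @param S_top,n_S,fold substrate design (defaults: 8 points, 1:2 from
#'   519 uM, i.e. down to ~4 uM).
#' @param replicates replicate count (default 4).
#' @param noise_frac multiplicative Gaussian noise SD as a fraction of each
#'   true rate (default 0.05; 0 gives noise-free data).
#' @return data frame with columns `S_uM`, `I_uM`, `replicate`, `rate` and
#'   attributes `true_mechanism`, `true_vmax`, `true_km`, `true_ki`.
#' @export
gen_kinetics <- function(seed = 1L, mechanism = "non-competitive",
                         vmax = 100, km = 130, ki = 30, ki_prime = 3 * ki,
                         I_uM = c(100, 50, 25, 12, 0), S_top = 519,
                         n_S = 8L, fold = 2, replicates = 4L,
                         noise_frac = 0.05) {
  mechanism <- match.arg(mechanism, KINETIC_MECHANISMS)
  stopifnot(vmax > 0, km > 0, ki > 0, ki_prime > 0, noise_frac >= 0,
            replicates >= 1, 0 %in% I_uM)
  S <- S_top / fold^(seq_len(n_S) - 1L)
  with_seed(seed, {
    rows <- lapply(I_uM, function(I) {
      p <- apparent_params(mechanism, vmax, km, I, ki, ki_prime)
      d <- expand.grid(replicate = seq_len(replicates), S_uM = S)
      mu <- p$vmax * d$S_uM / (p$km + d$S_uM)
      data.frame(S_uM = d$S_uM, I_uM = I, replicate = d$replicate,
                 rate = mu * (1 + stats::rnorm(nrow(d), 0, noise_frac)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, true_mechanism = mechanism, true_vmax = vmax,
              true_km = km, true_ki = ki)
  })
}

# ---- end-to-end demo -------------------------------------------------------

#' Run the whole pipeline on synthetic inputs
#'
#' Generates a small library, pose scene, plate, dose-response curve and
#' kinetics dataset from one seed, pushes each through the corresponding
#' pipeline stage and returns a run report.
#'
#' @param seed integer seed.
#' @param n_molecules library size (default 12; kept small because the
#'   library filters call out to the chemistry toolkit per molecule).
#' @return list of class `pipeline_report`.
#' @export
run_pipeline_demo <- function(seed = 1L, n_molecules = 12L) {
  lib <- gen_library(n_molecules, seed = seed)
  mols <- parse_smiles_set(lib$smiles, ids = lib$id)
  filt <- filter_library(mols)
  markush <- vapply(mols, function(m) isTRUE(match_markush(m)), logical(1))

  scene <- gen_pose_scene()
  screen <- screen_poses(scene$pocket, scene$poses)

  pl <- gen_plate(seed = seed)
  qc <- plate_qc(pl$plate)
  hits <- call_hits(pl$plate)

  dr <- gen_dose_response(seed = seed)
  ic <- fit_ic50(data.frame(conc_uM = dr$conc_uM, activity = dr$activity))

  kin <- gen_kinetics(seed = seed)
  mech <- classify_mechanism(kin)

  structure(list(
    library = merge(lib, data.frame(id = names(markush), markush_obs = markush),
                    by = "id"),
    filter_results = filt,
    pose_screen = screen,
    pose_truth = scene$truth,
    plate_qc = qc,
    hits = hits[hits$is_hit, , drop = FALSE],
    planted = pl$truth$compound[pl$truth$planted],
    ic50 = ic,
    true_ic50 = attr(dr, "true_ic50"),
    mechanism = mech,
    true_mechanism = attr(kin, "true_mechanism"),
    seed = seed
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Synthetic screening pipeline run (seed %d)\n", x$seed))
  cat(sprintf("  library: %d molecules, %d pass all filters, %d Markush hits\n",
              nrow(x$library), sum(x$filter_results$verdict),
              sum(x$library$markush_obs)))
  cat(sprintf("  poses:   %d/%d verdicts as planted\n",
              sum(x$pose_screen$pass == x$pose_truth$expect_pass),
              nrow(x$pose_truth)))
  cat(sprintf("  plate:   Z' %.3f, %d/%d planted inhibitors recovered\n",
              x$plate_qc$zprime,
              sum(x$hits$compound %in% x$planted), length(x$planted)))
  cat(sprintf("  IC50:    %.2f uM fitted vs %.2f true\n",
              x$ic50$ic50, x$true_ic50))
  cat(sprintf("  kinetics: %s (true: %s)\n",
              x$mechanism$mechanism, x$true_mechanism))
  invisible(x)
}
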