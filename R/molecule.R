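#' @title Molecular graph container and standard-format I/O
#' @description The `molecule` S3 class is the carrier for all compound-level
#'   computation in the package: a chemical graph with OpenBabel-perceived
#'   aromaticity, explicit hydrogens, formal charges and optional 3-D
#'   conformers (coordinates in Angstrom).
#' @name molecule
NULL

new_molecule <- function(id, atoms, bonds, conformers = list()) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  if (nrow(bonds)) {
    stopifnot(all(bonds$a1 >= 1L), all(bonds$a2 >= 1L),
              all(bonds$a1 <= nrow(atoms)), all(bonds$a2 <= nrow(atoms)),
              all(bonds$a1 != bonds$a2))
  }
  bonds$ring <- ring_bond_flags(atoms, bonds)
  atoms$hcount <- explicit_h_counts(atoms, bonds)
  structure(
    list(id = id, atoms = atoms, bonds = bonds, conformers = conformers),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  nh <- sum(!x$atoms$is_h)
  cat(sprintf("<molecule %s: %d heavy atoms, %d bonds, %d ring bond(s), %d conformer(s)>\n",
              x$id, nh, nrow(x$bonds), sum(x$bonds$ring), length(x$conformers)))
  invisible(x)
}

# number of atoms / heavy atoms
n_atoms <- function(mol) nrow(mol$atoms)
heavy_atoms <- function(mol) which(!mol$atoms$is_h)

# igraph view of the molecular graph (optionally heavy atoms only, keeping
# original atom indices as vertex names)
mol_graph <- function(mol, heavy_only = FALSE) {
  n <- nrow(mol$atoms)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  }
  if (heavy_only) {
    g <- igraph::induced_subgraph(g, which(!mol$atoms$is_h))
  }
  g
}

# ring membership of bonds: a bond is in a ring iff it is not a bridge
ring_bond_flags <- function(atoms, bonds) {
  if (!nrow(bonds)) return(logical(0))
  g <- igraph::make_empty_graph(nrow(atoms), directed = FALSE)
  g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  flags <- rep(TRUE, nrow(bonds))
  flags[igraph::bridges(g)] <- FALSE
  flags
}

ring_atom_flags <- function(mol) {
  fl <- logical(nrow(mol$atoms))
  rb <- which(mol$bonds$ring)
  fl[mol$bonds$a1[rb]] <- TRUE
  fl[mol$bonds$a2[rb]] <- TRUE
  fl
}

explicit_h_counts <- function(atoms, bonds) {
  h <- integer(nrow(atoms))
  if (!nrow(bonds)) return(h)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    if (atoms$is_h[j]) h[i] <- h[i] + 1L
    if (atoms$is_h[i]) h[j] <- h[j] + 1L
  }
  h
}

# neighbors of atom i (indices into mol$atoms)
atom_neighbors <- function(mol, i) {
  c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
}

# enumerate rings of the given sizes among aromatic atoms: for every aromatic
# bond, close the shortest cycle through it and keep 5/6-membered results
aromatic_rings <- function(mol, sizes = c(5L, 6L)) {
  ab <- which(mol$bonds$ring &
                mol$atoms$aromatic[mol$bonds$a1] &
                mol$atoms$aromatic[mol$bonds$a2])
  if (!length(ab)) return(list())
  arom_atoms <- which(mol$atoms$aromatic)
  g <- mol_graph(mol)
  g <- igraph::induced_subgraph(g, arom_atoms)
  rings <- list()
  for (k in ab) {
    u <- as.character(mol$bonds$a1[k]); v <- as.character(mol$bonds$a2[k])
    if (!(u %in% igraph::V(g)$name) || !(v %in% igraph::V(g)$name)) next
    eid <- tryCatch(igraph::get_edge_ids(g, c(u, v)), error = function(e) 0L)
    if (is.na(eid) || eid == 0L) next
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v))
    path <- sp$vpath[[1]]
    if (length(path) %in% sizes) {
      ring <- sort(as.integer(igraph::V(g)$name[as.integer(path)]))
      key <- paste(ring, collapse = "-")
      rings[[key]] <- ring
    }
  }
  unname(rings)
}

# --- SMILES ----------------------------------------------------------------

#' Parse a SMILES string into a molecule
#'
#' Sanitizes and perceives aromaticity with the OpenBabel toolkit (the single
#' aromaticity model used throughout the package) and stores explicit
#' hydrogens so that hydrogen-dependent rules (donor SMARTS, hydrogen-bond
#' geometry) see the full valence picture.
#'
#' @param text a single SMILES string.
#' @param id identifier for the molecule; defaults to the input string.
#' @return an object of class `molecule`.
#' @examples
#' m <- parse_smiles("c1ccccc1")
#' sum(m$atoms$aromatic)
#' @export
parse_smiles <- function(text, id = text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  mols <- parse_smiles_set(text, id)
  if (length(mols) == 0L) {
    stop(sprintf("unparsable SMILES: '%s'", text), call. = FALSE)
  }
  mols[[1L]]
}

#' Parse a set of SMILES strings in one batched toolkit call
#'
#' @param smiles character vector of SMILES.
#' @param ids identifiers (defaults to the SMILES strings themselves).
#' @return named list of `molecule` objects; inputs that fail to parse are
#'   omitted and reported in the `"failed"` attribute.
#' @export
parse_smiles_set <- function(smiles, ids = smiles) {
  stopifnot(length(smiles) == length(ids), !anyDuplicated(ids))
  internal <- sprintf("ak%06d", seq_along(smiles))
  recs <- ob_parse_smiles_set(smiles, internal, addh = TRUE)
  got <- vapply(recs, `[[`, "", "id")
  out <- list()
  for (k in seq_along(recs)) {
    pos <- match(recs[[k]]$id, internal)
    if (is.na(pos)) next
    a <- recs[[k]]$atoms
    if (nrow(a) == 0L) next
    out[[ids[pos]]] <- new_molecule(ids[pos], a[, c("elem", "sybyl", "aromatic",
                                                    "charge", "is_h")],
                                    recs[[k]]$bonds)
  }
  failed <- setdiff(ids, names(out))
  attr(out, "failed") <- failed
  out
}

# serialize a molecule (one conformer) to MOL2 text; the universal exchange
# form used for SMARTS matching and format conversion
mol_to_mol2 <- function(mol, conformer = if (length(mol$conformers)) 1L else 0L) {
  xyz <- if (conformer > 0L) {
    mol$conformers[[conformer]]
  } else {
    matrix(0, nrow(mol$atoms), 3L)
  }
  n <- nrow(mol$atoms)
  hdr <- c("@<TRIPOS>MOLECULE", mol$id,
           sprintf(" %d %d 0 0 0", n, nrow(mol$bonds)),
           "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM")
  at <- sprintf("%7d %-4s %10.4f %10.4f %10.4f %-6s %3d  UNL1 %10.4f",
                seq_len(n), mol$atoms$elem, xyz[, 1], xyz[, 2], xyz[, 3],
                mol$atoms$sybyl, 1L, 0)
  bd <- if (nrow(mol$bonds)) {
    sprintf("%6d %5d %5d %4s", seq_len(nrow(mol$bonds)),
            mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  } else character()
  paste(c(hdr, at, "@<TRIPOS>BOND", bd, ""), collapse = "\n")
}

#' Write a molecule as canonical SMILES
#'
#' @param mol a `molecule`.
#' @return a single canonical SMILES string.
#' @export
write_smiles <- function(mol) {
  out <- ob_run(mol_to_sdf(mol), "sdf", "can")
  smi <- strsplit(trimws(out), "[[:space:]]+")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) {
    stop(sprintf("could not write SMILES for molecule '%s'", mol$id),
         call. = FALSE)
  }
  smi
}

# serialize a molecule (one conformer) to an SDF V2000 record; formal charges
# travel in M CHG lines, aromatic bonds as type 4 (re-perceived on read)
mol_to_sdf <- function(mol, conformer = if (length(mol$conformers)) 1L else 0L) {
  xyz <- if (conformer > 0L) {
    mol$conformers[[conformer]]
  } else {
    matrix(0, nrow(mol$atoms), 3L)
  }
  n <- nrow(mol$atoms)
  nb <- nrow(mol$bonds)
  order_num <- c(`1` = 1L, `2` = 2L, `3` = 3L, ar = 4L, am = 1L)
  lines <- c(
    mol$id, "  allokin", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$elem),
    if (nb) sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1, mol$bonds$a2,
                    order_num[mol$bonds$order]) else character()
  )
  chg <- which(mol$atoms$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste(sprintf("%4d%4d", grp,
                                             mol$atoms$charge[grp]),
                                     collapse = "")))
    }
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}

# count of matches of a SMARTS pattern against a molecule (explicit-H form,
# formal charges preserved)
smarts_count <- function(mol, smarts) {
  obm <- ChemmineOB::forEachMol("SDF", mol_to_sdf(mol), identity)
  as.integer(ChemmineOB::smartsSearch_OB(obm, smarts))
}

smarts_matches <- function(mol, smarts) smarts_count(mol, smarts) > 0L

# OpenBabel descriptor block (logP, MW, canonical SMILES, ...) for a molecule
ob_descriptors <- function(mol) {
  obm <- ChemmineOB::forEachMol("SDF", mol_to_sdf(mol), identity)
  ChemmineOB::prop_OB(obm)
}

# --- SDF -------------------------------------------------------------------

#' Read molecules from an SDF file
#'
#' Order-preserving; records that fail sanitization are skipped with a warning
#' and counted in the `"skipped"` attribute.  When a record carries a 3-D (or
#' 2-D) coordinate block the coordinates are attached as conformer 1.
#'
#' @param path SDF file (V2000/V3000).
#' @param addh add explicit hydrogens (with generated positions when the
#'   record is 3-D).  Default `TRUE`.
#' @return list of `molecule` objects with a `"skipped"` attribute.
#' @export
read_sdf <- function(path, addh = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(raw))) {
    stop(sprintf("empty SDF file: %s", path), call. = FALSE)
  }
  recs <- strsplit(raw, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  out <- list()
  skipped <- 0L
  opts <- if (addh) "-h" else character()
  for (k in seq_along(recs)) {
    rec <- paste0(recs[[k]], "\n$$$$")
    m2 <- tryCatch(ob_run(rec, "sdf", "mol2", opts), error = function(e) "")
    parsed <- parse_mol2(m2)
    if (length(parsed) != 1L || nrow(parsed[[1]]$atoms) == 0L) {
      warning(sprintf("skipping unparsable SDF record %d in %s", k, path),
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    p <- parsed[[1]]
    chg <- parse_sdf_charges(rec)
    charge <- integer(nrow(p$atoms))
    if (length(chg) == 1L && !is.null(chg[[1]])) {
      nc <- min(chg[[1]]$natoms, nrow(p$atoms))
      charge[seq_len(nc)] <- chg[[1]]$charge[seq_len(nc)]
    }
    p$atoms$charge <- charge
    id <- if (nzchar(p$id) && p$id != "*****") p$id else sprintf("record_%d", k)
    xyz <- as.matrix(p$atoms[, c("x", "y", "z")])
    conf <- if (any(xyz != 0)) list(unname(xyz)) else list()
    out[[length(out) + 1L]] <- new_molecule(
      id, p$atoms[, c("elem", "sybyl", "aromatic", "charge", "is_h")],
      p$bonds, conformers = conf)
  }
  if (length(out) == 0L) {
    stop(sprintf("no parsable records in SDF file: %s", path), call. = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write molecules to an SDF file
#'
#' Each molecule's first conformer (or a zero-coordinate block) is written via
#' an OpenBabel MOL2-to-SDF conversion, so bond orders are kekulized the same
#' way they were perceived.
#'
#' @param mols a `molecule` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  m2 <- paste(vapply(mols, mol_to_mol2, ""), collapse = "\n")
  out <- ob_run(m2, "mol2", "sdf")
  writeLines(out, path)
  invisible(path)
}

# --- PDB -------------------------------------------------------------------

#' Read a protein structure from a PDB file
#'
#' Residue numbering is taken verbatim from the file (the interaction filters
#' name residues by the crystal structure's own numbering); heteroatoms and
#' waters are excluded by default.
#'
#' @param path PDB file.
#' @param keep_hetatm keep HETATM records (default `FALSE`).
#' @return object of class `protein_structure` with an `atoms` data frame
#'   (elem, name, resname, resno, chain, x, y, z).
#' @export
read_pdb_protein <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  a <- pdb$atom
  if (!keep_hetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[!(a$resid %in% c("HOH", "WAT", "H2O")), , drop = FALSE]
  if (nrow(a) == 0L) {
    stop(sprintf("no ATOM records in PDB file: %s", path), call. = FALSE)
  }
  atoms <- data.frame(
    elem = a$elesy, name = a$elety, resname = a$resid,
    resno = as.integer(a$resno), chain = a$chain,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, source = path), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure: %d atoms, %d residues>\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

# atoms of one residue (by number, optionally chain / atom names)
residue_atoms <- function(protein, resno, chain = NULL, names = NULL) {
  a <- protein$atoms
  sel <- a$resno == resno
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!is.null(names)) sel <- sel & a$name %in% names
  a[sel, , drop = FALSE]
}
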