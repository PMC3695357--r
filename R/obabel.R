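# Internal plumbing around the OpenBabel command-line tool.  All format
# interconversion (SMILES/SDF/MOL2) and 3-D embedding go through one obabel
# invocation per *set* of molecules so library-scale calls stay cheap.

ob_binary <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) {
    stop("OpenBabel 'obabel' executable not found on PATH", call. = FALSE)
  }
  bin
}

# Run obabel on `input` text, returning output text.  `opts` are extra
# command-line flags (e.g. "-h", "--gen3d", "fastest").  stderr is captured and
# returned as an attribute so callers can count skipped records without the
# console filling with OpenBabel warnings.
ob_run <- function(input, in_format, out_format, opts = character()) {
  fin <- tempfile(fileext = paste0(".", in_format))
  fout <- tempfile(fileext = paste0(".", out_format))
  ferr <- tempfile(fileext = ".err")
  on.exit(unlink(c(fin, fout, ferr)), add = TRUE)
  writeLines(input, fin)
  status <- suppressWarnings(system2(
    ob_binary(),
    c(shQuote(fin), paste0("-i", in_format), paste0("-o", out_format),
      "-O", shQuote(fout), opts),
    stdout = FALSE, stderr = ferr
  ))
  err <- if (file.exists(ferr)) readLines(ferr, warn = FALSE) else character()
  out <- if (file.exists(fout)) readLines(fout, warn = FALSE) else character()
  structure(paste(out, collapse = "\n"), stderr = err, status = status)
}

# --- MOL2 parsing ----------------------------------------------------------

# Split multi-record MOL2 text into per-molecule blocks and parse each into
# list(id, atoms, bonds).  Atom fields: elem, sybyl, aromatic, x, y, z, is_h.
parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0L) return(list())
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    id <- trimws(blk[2L])
    a0 <- grep("^@<TRIPOS>ATOM", blk)[1L]
    b0 <- grep("^@<TRIPOS>BOND", blk)[1L]
    sec_ends <- grep("^@<TRIPOS>", blk)
    a1 <- min(c(sec_ends[sec_ends > a0], length(blk) + 1L)) - 1L
    b1 <- min(c(sec_ends[sec_ends > b0], length(blk) + 1L)) - 1L
    atom_lines <- blk[(a0 + 1L):a1]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    af <- strsplit(trimws(atom_lines), "[[:space:]]+")
    sybyl <- vapply(af, `[`, "", 6L)
    elem <- vapply(strsplit(sybyl, ".", fixed = TRUE), `[`, "", 1L)
    atoms <- data.frame(
      elem = elem,
      sybyl = sybyl,
      x = as.numeric(vapply(af, `[`, "", 3L)),
      y = as.numeric(vapply(af, `[`, "", 4L)),
      z = as.numeric(vapply(af, `[`, "", 5L)),
      stringsAsFactors = FALSE
    )
    atoms$is_h <- atoms$elem == "H"
    bonds <- if (!is.na(b0) && b0 + 1L <= b1) {
      bond_lines <- blk[(b0 + 1L):b1]
      bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
      bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
      data.frame(
        a1 = as.integer(vapply(bf, `[`, "", 2L)),
        a2 = as.integer(vapply(bf, `[`, "", 3L)),
        order = vapply(bf, `[`, "", 4L),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(a1 = integer(), a2 = integer(), order = character(),
                 stringsAsFactors = FALSE)
    }
    # atom is aromatic if typed .ar or on any aromatic bond
    arom <- grepl("\\.ar$", atoms$sybyl)
    if (nrow(bonds)) {
      ab <- bonds$order == "ar"
      arom[bonds$a1[ab]] <- TRUE
      arom[bonds$a2[ab]] <- TRUE
    }
    atoms$aromatic <- arom
    list(id = id, atoms = atoms, bonds = bonds)
  })
}

# --- SDF (V2000) parsing ---------------------------------------------------

# Minimal V2000 reader used for formal charges and for record bookkeeping.
# Returns list(id, natoms, charge) per record; charge is an integer vector.
parse_sdf_charges <- function(text) {
  recs <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  lapply(recs, function(r) {
    ln <- strsplit(r, "\n", fixed = TRUE)[[1]]
    if (length(ln) < 4L) return(NULL)
    id <- trimws(ln[1L])
    natoms <- suppressWarnings(as.integer(substr(ln[4L], 1L, 3L)))
    if (is.na(natoms)) return(NULL)
    charge <- integer(natoms)
    code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
    for (i in seq_len(natoms)) {
      f <- strsplit(trimws(ln[4L + i]), "[[:space:]]+")[[1]]
      code <- f[6L]
      if (!is.na(code) && code %in% names(code_map)) {
        charge[i] <- code_map[[code]]
      }
    }
    for (m in grep("^M  CHG", ln, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", m)),
                               "[[:space:]]+")[[1]])
      n <- f[1L]
      for (j in seq_len(n)) {
        charge[f[2L * j]] <- f[2L * j + 1L]
      }
    }
    list(id = id, natoms = natoms, charge = charge)
  })
}

# Convert a vector of SMILES (with internal ids) to parsed mol2 records plus
# per-atom formal charges, in two batched obabel calls.  Records that fail to
# parse are absent from the result; callers match by id.
ob_parse_smiles_set <- function(smiles, ids, addh = TRUE, gen3d = FALSE) {
  stopifnot(length(smiles) == length(ids))
  smi_text <- paste(smiles, ids, sep = "\t")
  opts <- character()
  if (addh) opts <- c(opts, "-h")
  if (gen3d) opts <- c(opts, "--gen3d", "fastest")
  m2 <- ob_run(smi_text, "smi", "mol2", opts)
  sd <- ob_run(smi_text, "smi", "sdf", opts)
  mols <- parse_mol2(m2)
  chgs <- Filter(Negate(is.null), parse_sdf_charges(sd))
  chg_by_id <- stats::setNames(chgs, vapply(chgs, `[[`, "", "id"))
  for (k in seq_along(mols)) {
    ch <- chg_by_id[[mols[[k]]$id]]
    mols[[k]]$atoms$charge <-
      if (!is.null(ch) && ch$natoms == nrow(mols[[k]]$atoms)) {
        ch$charge
      } else {
        integer(nrow(mols[[k]]$atoms))
      }
  }
  mols
}
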