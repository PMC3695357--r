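#' Ligand-arm Markush selection and SAR series annotation
#'
#' The ligand-based selection keeps molecules containing at least two 5- or
#' 6-membered aromatic systems joined by a 1-3 atom non-ring linker, with a
#' hydrogen-bond-accepting substituent (O, N, F, or a fluorinated carbon) at
#' the meta and/or para position of a linked ring.  Confirmed actives fall
#' into potency-ordered structural series (catechols > salicylic acid
#' derivatives > benzodioxoles) annotated by [annotate_series()].
#'
#' @name markush_select
NULL

#' Build a Markush query
#'
#' @param ring_sizes allowed aromatic ring sizes (default 5 and 6).
#' @param linker_lengths allowed numbers of non-ring linker atoms (subset of
#'   1:3).
#' @param positions ring positions (relative to the linker attachment atom,
#'   which is position 1) where the acceptor substituent may sit; default
#'   `c(3, 4)` i.e. meta/para, both ring directions accepted.
#' @return list of class `markush_query`.
#' @export
markush_query <- function(ring_sizes = c(5L, 6L), linker_lengths = 1:3,
                          positions = c(3L, 4L)) {
  stopifnot(all(linker_lengths %in% 1:3), all(positions %in% 2:6),
            all(ring_sizes %in% c(5L, 6L)))
  structure(list(ring_sizes = as.integer(ring_sizes),
                 linker_lengths = as.integer(linker_lengths),
                 positions = as.integer(positions)),
            class = "markush_query")
}

# order the atoms of a ring along its cycle, starting from `start`
ring_cycle_order <- function(mol, ring, start) {
  ordered <- start
  prev <- -1L
  cur <- start
  repeat {
    nb <- intersect(atom_neighbors(mol, cur), ring)
    nxt <- setdiff(nb, c(prev, ordered))
    if (!length(nxt)) break
    prev <- cur
    cur <- nxt[1L]
    ordered <- c(ordered, cur)
    if (length(ordered) == length(ring)) break
  }
  ordered
}

# is atom s an acceptor-class substituent first atom: O, N, F, or a carbon
# bearing at least one fluorine?
is_acceptor_substituent <- function(mol, s) {
  e <- mol$atoms$elem[s]
  if (e %in% c("O", "N", "F")) return(TRUE)
  if (e == "C") {
    nb <- atom_neighbors(mol, s)
    return(any(mol$atoms$elem[nb] == "F"))
  }
  FALSE
}

# does `ring` carry an acceptor substituent at an allowed position relative
# to attachment atom `att`?  Returns the substituent atom index or NA.
ring_position_substituent <- function(mol, ring, att, positions) {
  cyc <- ring_cycle_order(mol, ring, att)
  n <- length(cyc)
  for (pos in positions) {
    # position p is graph distance p-1 around the ring, both directions
    offs <- unique(c(pos - 1L, n - (pos - 1L)))
    for (o in offs) {
      if (o < 1L || o >= n) next
      atom <- cyc[1L + o]
      subs <- setdiff(atom_neighbors(mol, atom), ring)
      subs <- subs[!mol$atoms$is_h[subs]]
      for (s in subs) {
        if (is_acceptor_substituent(mol, s)) return(s)
      }
    }
  }
  NA_integer_
}

#' Match a molecule against the Markush rule
#'
#' True iff two distinct aromatic rings of allowed size are connected by a
#' simple path of 1-3 non-ring heavy atoms (all path bonds non-ring) and at
#' least one of the two rings carries an acceptor-class substituent (first
#' atom O, N, F, or a fluorine-bearing carbon) at an allowed meta/para
#' position relative to its linker attachment.  Either ring may carry the
#' substituent; the witness records which.
#'
#' @param mol a `molecule`.
#' @param q a `markush_query`.
#' @return logical scalar; when TRUE the `"witness"` attribute lists the two
#'   rings, the linker path and the substituent atom.
#' @export
match_markush <- function(mol, q = markush_query()) {
  rings <- aromatic_rings(mol, sizes = q$ring_sizes)
  if (length(rings) < 2L) return(FALSE)
  ring_flag <- ring_atom_flags(mol)
  bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ring_bond_keys <- bond_key(mol$bonds$a1[mol$bonds$ring],
                             mol$bonds$a2[mol$bonds$ring])
  g <- mol_graph(mol, heavy_only = TRUE)
  vnames <- as.integer(igraph::V(g)$name)
  max_len <- max(q$linker_lengths) + 1L

  for (i in seq_along(rings)) {
    for (j in seq_along(rings)) {
      if (i == j) next
      ra <- rings[[i]]; rb <- rings[[j]]
      if (length(intersect(ra, rb))) next  # fused systems have no linker
      for (u in ra) {
        paths <- igraph::all_simple_paths(
          g, from = as.character(u), to = as.character(rb), cutoff = max_len)
        for (p in paths) {
          pa <- vnames[as.integer(p)]
          if (!(pa[length(pa)] %in% rb)) next
          interior <- pa[-c(1L, length(pa))]
          n_link <- length(interior)
          if (!(n_link %in% q$linker_lengths)) next
          if (any(ring_flag[interior])) next
          # all path bonds must be non-ring
          keys <- bond_key(pa[-length(pa)], pa[-1L])
          if (any(keys %in% ring_bond_keys)) next
          # acceptor substituent on either ring, relative to its attachment
          sub_a <- ring_position_substituent(mol, ra, pa[1L], q$positions)
          sub_b <- ring_position_substituent(mol, rb, pa[length(pa)],
                                             q$positions)
          if (!is.na(sub_a) || !is.na(sub_b)) {
            wit <- list(ring_a = ra, ring_b = rb, linker = interior,
                        substituent = if (!is.na(sub_a)) sub_a else sub_b,
                        substituent_ring = if (!is.na(sub_a)) "a" else "b")
            return(structure(TRUE, witness = wit))
          }
        }
      }
    }
  }
  FALSE
}

SERIES_SMARTS <- c(
  catechol    = "[OX2H1]c1ccccc1[OX2H1]",
  salicylate  = "[OX2H1]c1ccccc1[CX3](=O)[OX2,OX1]",
  benzodioxole = "[CX4]1Oc2ccccc2O1"
)

#' Annotate the SAR series of a molecule
#'
#' Assigns the first matching label in the potency-ordered priority
#' catechol > salicylate > benzodioxole; `"other"` when none matches.
#'
#' @param mol a `molecule`.
#' @return character scalar label.
#' @export
annotate_series <- function(mol) {
  for (lab in names(SERIES_SMARTS)) {
    if (smarts_count(mol, SERIES_SMARTS[[lab]]) > 0L) return(lab)
  }
  "other"
}
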