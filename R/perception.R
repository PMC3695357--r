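# Atom-level chemical perception rules shared by the stage-1 library filters
# and the pharmacophore module.  One set of definitions is used everywhere so
# the two stages cannot disagree about what counts as a donor or acceptor.

# does atom j sit on a carbonyl/sulfonyl-like center, i.e. is it a C or S
# (3- or 4-connected to heavy atoms + H) double-bonded to O?
is_carbonyl_center <- function(mol, j) {
  if (!(mol$atoms$elem[j] %in% c("C", "S"))) return(FALSE)
  b <- mol$bonds
  dbl <- (b$a1 == j & b$order == "2" & mol$atoms$elem[b$a2] == "O") |
         (b$a2 == j & b$order == "2" & mol$atoms$elem[b$a1] == "O")
  any(dbl)
}

# aliphatic amine per the triage rule: nitrogen that is non-aromatic, carries
# no double/triple bond, and has no carbonyl/sulfonyl neighbor (so amide and
# sulfonamide nitrogens are excluded).  Tertiary amines qualify -- they can
# become donors upon protonation.
is_aliphatic_amine <- function(mol, i) {
  a <- mol$atoms
  if (a$elem[i] != "N" || a$aromatic[i]) return(FALSE)
  b <- mol$bonds
  inc <- b$a1 == i | b$a2 == i
  if (any(!b$order[inc] %in% c("1", "am"))) return(FALSE)
  nb <- atom_neighbors(mol, i)
  nb <- nb[!mol$atoms$is_h[nb]]
  !any(vapply(nb, function(j) is_carbonyl_center(mol, j), logical(1)))
}

aliphatic_amine_atoms <- function(mol) {
  idx <- which(mol$atoms$elem == "N" & !mol$atoms$is_h)
  idx[vapply(idx, function(i) is_aliphatic_amine(mol, i), logical(1))]
}

# hydrogen-bond donor atoms: N/O bearing at least one hydrogen, plus
# protonatable aliphatic amines (consistent with the stage-1 donor rule)
donor_atoms <- function(mol) {
  a <- mol$atoms
  nh <- which(a$elem %in% c("N", "O") & !a$is_h & a$hcount >= 1L)
  sort(unique(c(nh, aliphatic_amine_atoms(mol))))
}

# hydrogen-bond acceptor atoms: N or O with an available lone pair.
#   O: any neutral or anionic oxygen.
#   N: excluded when positively charged, pyrrole-like (aromatic with an H or
#      three heavy neighbors), amide/sulfonamide-delocalized, or part of a
#      nitro group; pyridine-type aromatic N (two ring neighbors) accepts.
acceptor_atoms <- function(mol) {
  a <- mol$atoms
  out <- integer()
  for (i in which(!a$is_h & a$elem %in% c("N", "O"))) {
    if (a$charge[i] > 0L) next
    if (a$elem[i] == "O") {
      out <- c(out, i)
      next
    }
    nb_heavy <- setdiff(atom_neighbors(mol, i), which(a$is_h))
    if (a$aromatic[i]) {
      if (a$hcount[i] == 0L && length(nb_heavy) == 2L) out <- c(out, i)
      next
    }
    if (any(vapply(nb_heavy, function(j) is_carbonyl_center(mol, j),
                   logical(1)))) next
    if (is_carbonyl_center_n(mol, i)) next
    out <- c(out, i)
  }
  out
}

# nitro-like N (itself double-bonded to O)
is_carbonyl_center_n <- function(mol, i) {
  b <- mol$bonds
  any((b$a1 == i & b$order == "2" & mol$atoms$elem[b$a2] == "O") |
      (b$a2 == i & b$order == "2" & mol$atoms$elem[b$a1] == "O"))
}

# rotatable bonds: acyclic single (non-amide) bonds between two heavy atoms
# that each have at least one further heavy neighbor
rotatable_bonds <- function(mol) {
  b <- mol$bonds
  a <- mol$atoms
  heavy_deg <- integer(nrow(a))
  hb <- b[!a$is_h[b$a1] & !a$is_h[b$a2], , drop = FALSE]
  for (k in seq_len(nrow(hb))) {
    heavy_deg[hb$a1[k]] <- heavy_deg[hb$a1[k]] + 1L
    heavy_deg[hb$a2[k]] <- heavy_deg[hb$a2[k]] + 1L
  }
  which(b$order == "1" & !b$ring &
          !a$is_h[b$a1] & !a$is_h[b$a2] &
          heavy_deg[b$a1] >= 2L & heavy_deg[b$a2] >= 2L)
}

n_rotatable_bonds <- function(mol) length(rotatable_bonds(mol))

# aromatic proportion: aromatic heavy atoms / heavy atoms (ESOL descriptor)
aromatic_proportion <- function(mol) {
  h <- heavy_atoms(mol)
  if (!length(h)) return(0)
  mean(mol$atoms$aromatic[h])
}
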