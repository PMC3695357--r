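#' Stage-1 library triage filters
#'
#' The target-arm triage keeps compounds that (i) carry a strong hydrogen-bond
#' donor, (ii) have at least one aromatic ring and one hydrogen-bond acceptor,
#' (iii) contain no toxicophoric/reactive fragment from a configurable
#' blacklist, and (iv) satisfy logP/logS property cutoffs.
#'
#' @name library_filters
NULL

# the published strong-donor SMARTS: a secondary N-H whose two heavy
# neighbors are neither carbonyl nor sulfonyl centers
DONOR_SMARTS_DEFAULT <-
  "[#1][#7;H1]([!$([#6,#16;X3,X4]=[O])])[!$([#6,#16;X3,X4]=[O])]"

default_blacklist <- function() {
  c(
    acyl_halide      = "[CX3](=O)[F,Cl,Br,I]",
    sulfonyl_halide  = "[SX4](=O)(=O)[F,Cl,Br,I]",
    aldehyde         = "[CX3H1](=O)[#6]",
    michael_acceptor = "[CX3]=[CX3][CX3]=[OX1]",
    alkyl_halide     = "[CX4][Cl,Br,I]",
    nitroaromatic    = "[c][$([NX3](=O)=O),$([NX3+](=O)[O-])]",
    anhydride        = "[CX3](=O)[OX2][CX3](=O)",
    epoxide          = "[OX2]1[CX4][CX4]1",
    isocyanate       = "[NX2]=[CX2]=[OX1]",
    peroxide         = "[OX2][OX2]"
  )
}

#' Build a filter configuration
#'
#' @param donor_smarts donor SMARTS pattern (default: the published pattern
#'   for non-amide, non-sulfonamide N-H groups).
#' @param blacklist named character vector of toxicophore/reactive-fragment
#'   SMARTS.  The default set (acyl/sulfonyl halides, aldehydes, Michael
#'   acceptors, alkyl halides, nitroaromatics, anhydrides, epoxides,
#'   isocyanates, peroxides) is representative, not canonical, and fully
#'   editable.
#' @param logp_max maximum accepted logP (unitless, default 5).
#' @param logs_min minimum accepted estimated log10 aqueous solubility in
#'   mol/L (default -5).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(donor_smarts = DONOR_SMARTS_DEFAULT,
                          blacklist = default_blacklist(),
                          logp_max = 5, logs_min = -5) {
  stopifnot(is.character(donor_smarts), length(donor_smarts) == 1L,
            is.character(blacklist), !is.null(names(blacklist)) || length(blacklist) == 0L,
            is.numeric(logp_max), is.numeric(logs_min))
  structure(list(donor_smarts = donor_smarts, blacklist = blacklist,
                 logp_max = logp_max, logs_min = logs_min,
                 logp_method = "openbabel atom-contribution logP",
                 logs_method = "ESOL regression (logP, MW, RB, aromatic proportion)",
                 aromaticity_model = "openbabel"),
            class = "filter_config")
}

#' Strong hydrogen-bond donor test
#'
#' True iff the molecule contains an aliphatic (non-aromatic, non-amide,
#' non-sulfonamide) amine nitrogen of any substitution level, or matches the
#' configured donor SMARTS after explicit-hydrogen addition.
#'
#' @param mol a `molecule`.
#' @param cfg a `filter_config`.
#' @return logical scalar.
#' @export
has_strong_donor <- function(mol, cfg = filter_config()) {
  if (length(aliphatic_amine_atoms(mol)) > 0L) return(TRUE)
  n <- tryCatch(smarts_count(mol, cfg$donor_smarts), error = function(e) {
    stop(sprintf("invalid donor SMARTS in config: %s", cfg$donor_smarts),
         call. = FALSE)
  })
  n > 0L
}

#' Aromatic-ring and hydrogen-acceptor prerequisite test
#'
#' True iff the molecule has at least one 5/6-membered aromatic ring and at
#' least one hydrogen-bond acceptor atom (acceptor definition shared with the
#' pharmacophore module).
#'
#' @param mol a `molecule`.
#' @return logical scalar.
#' @export
passes_feature_prereqs <- function(mol) {
  length(aromatic_rings(mol)) >= 1L && length(acceptor_atoms(mol)) >= 1L
}

#' Medicinal-chemistry blacklist filter
#'
#' Fails iff any blacklist SMARTS matches; the report names every matched
#' rule so borderline compounds can be audited.
#'
#' @param mol a `molecule`.
#' @param cfg a `filter_config`.
#' @return list with elements `pass` (logical), `rules` (named logical: TRUE
#'   means the rule matched) and `matched` (names of matched rules).
#' @export
medchem_filter <- function(mol, cfg = filter_config()) {
  rules <- vapply(cfg$blacklist, function(s) smarts_count(mol, s) > 0L,
                  logical(1))
  list(pass = !any(rules), rules = rules, matched = names(rules)[rules])
}

# ESOL estimated log10 solubility (mol/L) from logP, molecular weight,
# rotatable-bond count and aromatic proportion
esol_logs <- function(logp, mw, rotatable, aromatic_prop) {
  0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * rotatable - 0.74 * aromatic_prop
}

#' logP / logS property filter
#'
#' Accepts a molecule iff computed logP is at most `logp_max` and estimated
#' logS (log10 mol/L, ESOL regression) is at least `logs_min`.  The logS
#' cutoff is a magnitude cap on (negative) log-solubility: a literal
#' "logS < 5" excludes nothing, so the accepted reading is logS >= -5.
#'
#' @param mol a `molecule`.
#' @param cfg a `filter_config`.
#' @return logical scalar with `"logp"` and `"logs"` attributes carrying the
#'   computed values.
#' @export
property_filter <- function(mol, cfg = filter_config()) {
  d <- tryCatch(ob_descriptors(mol), error = function(e) NULL)
  if (is.null(d) || !is.finite(d$logP) || !is.finite(d$MW)) {
    stop(sprintf("descriptor computation failed for molecule '%s'", mol$id),
         call. = FALSE)
  }
  logs <- esol_logs(d$logP, d$MW, n_rotatable_bonds(mol),
                    aromatic_proportion(mol))
  structure(d$logP <= cfg$logp_max && logs >= cfg$logs_min,
            logp = d$logP, logs = logs)
}

#' Apply all four stage-1 filters to a set of molecules
#'
#' @param mols list of `molecule` objects (e.g. from [parse_smiles_set()]).
#' @param cfg a `filter_config`.
#' @return data frame (one row per molecule) with columns `id`, `donor`,
#'   `prereqs`, `medchem`, `properties`, `verdict` (the conjunction), plus
#'   `logp`, `logs` and `medchem_matched`.
#' @export
filter_library <- function(mols, cfg = filter_config()) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  rows <- lapply(mols, function(m) {
    mc <- medchem_filter(m, cfg)
    pf <- property_filter(m, cfg)
    data.frame(
      id = m$id,
      donor = has_strong_donor(m, cfg),
      prereqs = passes_feature_prereqs(m),
      medchem = mc$pass,
      properties = as.logical(pf),
      logp = attr(pf, "logp"),
      logs = attr(pf, "logs"),
      medchem_matched = paste(mc$matched, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$verdict <- out$donor & out$prereqs & out$medchem & out$properties
  rownames(out) <- NULL
  out
}
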