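# SMILES-derived ligand descriptors: 2-D compositional and topological
# features in the spirit of fragment/count descriptor sets (NssNH, NssO,
# NaaO, ... naming follows the common atom-type fragment convention:
# s = single bond, a = aromatic bond, a leading N = "number of").

# SMARTS patterns counted over all matches
.fragment_smarts <- c(
  NsNH2   = "[NX3;H2;!$(N=*)]",                  # primary amine -NH2
  NssNH   = "[NX3;H1;!$(N=*)]",                  # secondary amine -NH-
  NsssN   = "[NX3;H0;!$(N=*)]",                  # tertiary amine N
  NaaN    = "[n]",                               # aromatic N
  NsOH    = "[OX2;H1]",                          # hydroxyl -OH
  NssO    = "[OX2;H0]",                          # ether/ester -O-
  NaaO    = "[o]",                               # aromatic O
  NdO     = "[OX1]",                             # double-bonded O
  nCOOH   = "[CX3](=O)[OX2H1]",                  # carboxylic acid
  nCdO    = "[CX3]=[OX1]",                       # carbonyl C
  nSH     = "[SX2;H1]",                          # thiol
  nRingAtoms = "[R]",                            # atoms in any ring
  nAromAtoms = "[a]"                             # aromatic atoms
)

# SMARTS patterns counted over symmetry-unique matches (ring counts)
.ring_smarts <- c(
  nAromRings6 = "[a]1[a][a][a][a][a]1",          # six-membered aromatic rings
  nAromRings5 = "[a]1[a][a][a][a]1",             # five-membered aromatic rings
  nRings6 = "[R]1[R][R][R][R][R]1",
  nRings5 = "[R]1[R][R][R][R]1"
)

# element counts from a molecular formula string like "C6H8N2O2"
.formula_counts <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  syms <- sub("[0-9]*$", "", toks)
  cnts <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  cnts[is.na(cnts)] <- 1
  setNames(cnts, syms)
}

#' Compute 2-D ligand descriptors from SMILES
#'
#' Generates compositional and topological molecular descriptors for each
#' ligand: molecular properties (molecular weight, logP, topological polar
#' surface area, molar refractivity, hydrogen-bond donor/acceptor counts),
#' element counts, ring counts, and fragment-count descriptors obtained by
#' SMARTS matching (e.g. `NssNH` = number of secondary-amine -NH- fragments,
#' `NssO` = number of ether-type -O- fragments).  All features are computed
#' from the molecular graph; no 3-D geometry is used.  When `ligand_charge`
#' is supplied it is appended as the `molecular_charge` column (the
#' molecular charge of the ligand in aqueous solution is itself a
#' descriptor).
#'
#' @param smiles Character vector of valid SMILES strings (one per ligand).
#' @param ligand_charge Optional numeric vector of molecular charges in
#'   aqueous solution, recycled to `length(smiles)` if scalar.
#' @return A tibble with the `smiles` identifier column followed by numeric
#'   descriptor columns, one row per input ligand.  Descriptor values that
#'   could not be computed are `NA` (later removed by [drop_degenerate()]).
#' @examples
#' ligand_descriptors(c("C", "c1ccccc1"))
#' @export
ligand_descriptors <- function(smiles, ligand_charge = NULL) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    abort(paste0("unparsable SMILES: ",
                 paste(unique(smiles[is.na(can)]), collapse = ", ")))
  }
  rows <- ChemmineOB::forEachMol(
    "SMILES", paste(smiles, collapse = "\n"),
    function(mol) {
      tryCatch({
        p <- ChemmineOB::prop_OB(mol)
        frag <- vapply(.fragment_smarts, function(pat) {
          as.numeric(ChemmineOB::smartsSearch_OB(list(mol), pat,
                                                 uniqueMatches = FALSE)[[1]])
        }, numeric(1))
        ring <- vapply(.ring_smarts, function(pat) {
          as.numeric(ChemmineOB::smartsSearch_OB(list(mol), pat,
                                                 uniqueMatches = TRUE)[[1]])
        }, numeric(1))
        ec <- .formula_counts(p$formula)
        cnt <- function(sym) if (sym %in% names(ec)) ec[[sym]] else 0
        c(MW = p$MW, logP = p$logP, TPSA = p$TPSA, MR = p$MR,
          nHBA = p$HBA1, nHBD = p$HBD,
          nHeavy = sum(ec[names(ec) != "H"]),
          nC = cnt("C"), nN = cnt("N"), nO = cnt("O"),
          nS = cnt("S"), nP = cnt("P"),
          nHal = cnt("F") + cnt("Cl") + cnt("Br") + cnt("I"),
          frag, ring)
      }, error = function(cnd) NULL)
    })
  width <- max(vapply(rows, length, integer(1)), 0)
  proto <- rows[[which(vapply(rows, length, integer(1)) == width)[1]]]
  mat <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r)) setNames(rep(NA_real_, width), names(proto)) else r
  }))
  out <- dplyr::bind_cols(tibble(smiles = smiles),
                          as_tibble(as.data.frame(mat)))
  if (!is.null(ligand_charge)) {
    out$molecular_charge <- as.numeric(rep(ligand_charge, length.out = length(smiles)))
  }
  out
}
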