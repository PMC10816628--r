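# Physicochemical descriptors for drug-likeness triage.
#
# Definitions follow the rule-of-five conventions: HBA is the N+O count, HBD
# the count of N-H and O-H hydrogens. LogP is a coarse atom-contribution
# (Crippen-style) estimate; the method is recorded in the output so results
# from alternative estimators are comparable.

# reduced atom-contribution table for logP: values are averages over the
# classic Crippen atom classes falling in each bucket
.logp_contrib <- function(mol) {
  at <- mol$atoms
  nb <- .neighbors(mol)
  contrib <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    e <- at$element[i]
    het_nbr <- any(at$element[nb[[i]]$nbr] %in% c("N", "O", "S", "P"))
    contrib[i] <- switch(e,
      C = if (at$aromatic[i]) {
            if (het_nbr) 0.14 else 0.29
          } else if (het_nbr) -0.10 else 0.14,
      N = if (at$charge[i] > 0) -1.00 else if (at$aromatic[i]) -0.35 else -0.60,
      O = if (at$charge[i] < 0) -1.00 else if (at$aromatic[i]) 0.11 else -0.25,
      S = 0.45, P = 0.0, F = 0.30, Cl = 0.65, Br = 0.86, I = 1.10, B = 0.0,
      0.0)
    # hydrogens: on carbon slightly positive, on heteroatoms negative
    hval <- if (e == "C") 0.12 else -0.22
    contrib[i] <- contrib[i] + hval * at$nH[i]
  }
  sum(contrib)
}

#' Compute the drug-likeness descriptor set for a compound
#'
#' Returns molecular weight, hydrogen-bond donors/acceptors (rule-of-five
#' conventions: HBD = N-H plus O-H hydrogens, HBA = N plus O count), an
#' atom-contribution LogP estimate, rotatable bonds (non-ring single bonds
#' between non-terminal heavy atoms), heavy atom count, and the number of
#' Lipinski violations.
#'
#' @param x a SMILES string, a `molecule`, or a `compound` (see
#'   [read_smiles_file()]).
#' @return a one-row data.frame with columns `mw`, `hbd`, `hba`, `logp`,
#'   `rotatable_bonds`, `heavy_atoms`, `lipinski_violations` and an attribute
#'   `logp_method`.
#' @examples
#' compute_descriptors("CC(=O)Oc1ccccc1C(=O)O")  # aspirin: mw 180.16, hbd 1
#' @export
compute_descriptors <- function(x) {
  mol <- as_molecule(x)
  at <- mol$atoms
  mw <- sum(.atomic_mass[at$element]) + sum(at$nH) * .atomic_mass[["H"]]
  hbd <- sum(at$nH[at$element %in% c("N", "O")])
  hba <- sum(at$element %in% c("N", "O"))
  logp <- .logp_contrib(mol)
  rot <- 0L
  if (nrow(mol$bonds) > 0) {
    deg <- at$degree
    rot <- sum(!mol$bonds$in_ring & mol$bonds$order == 1 &
               deg[mol$bonds$a1] >= 2 & deg[mol$bonds$a2] >= 2)
  }
  d <- data.frame(mw = unname(mw), hbd = hbd, hba = hba,
                  logp = round(logp, 3), rotatable_bonds = as.integer(rot),
                  heavy_atoms = nrow(at),
                  lipinski_violations = NA_integer_)
  d$lipinski_violations <- lipinski_violations(d)
  attr(d, "logp_method") <- "atom-contribution (reduced Crippen-style)"
  d
}

#' Count Lipinski rule-of-five violations
#'
#' One violation for each of: MW > 500 g/mol, LogP > 5, HBD > 5, HBA > 10.
#'
#' @param d a data.frame with columns `mw`, `logp`, `hbd`, `hba` (one or more
#'   rows).
#' @return integer vector in `[0, 4]`, one value per row.
#' @export
lipinski_violations <- function(d) {
  stopifnot(all(c("mw", "logp", "hbd", "hba") %in% names(d)))
  as.integer((d$mw > 500) + (d$logp > 5) + (d$hbd > 5) + (d$hba > 10))
}

#' Coerce to a molecule
#' @param x SMILES string, `molecule`, or `compound`.
#' @return a `molecule`.
#' @export
as_molecule <- function(x) {
  if (inherits(x, "molecule")) return(x)
  if (inherits(x, "compound")) return(parse_smiles(x$smiles))
  if (is.character(x) && length(x) == 1) return(parse_smiles(x))
  stop("cannot interpret input as a molecule")
}
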