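# Murcko scaffold decomposition: ring systems plus the linkers connecting
# them, terminal side chains stripped. Exocyclic multiple bonds onto the
# retained frame (e.g. the amide oxygen of a linker) are kept.

#' Murcko scaffold of a compound
#'
#' Iteratively removes terminal atoms until only rings and inter-ring linkers
#' remain, then restores atoms multiply bonded to the retained frame. Acyclic
#' molecules have an empty scaffold (returned as `""`); such compounds are
#' grouped into a dedicated no-scaffold cluster downstream.
#'
#' @param x SMILES string, `molecule`, or `compound`.
#' @return the canonical SMILES of the scaffold (`""` if the molecule has no
#'   ring system). Idempotent: the scaffold of a scaffold is itself.
#' @examples
#' murcko_scaffold("Cc1ccccc1")   # toluene -> benzene
#' murcko_scaffold("CCC")         # acyclic -> ""
#' @export
murcko_scaffold <- function(x) {
  mol <- as_molecule(x)
  if (!any(mol$atoms$in_ring)) return("")
  n <- nrow(mol$atoms)
  keep <- rep(TRUE, n)
  # iteratively strip terminal atoms (plain degree-1 pruning leaves exactly
  # rings + linkers)
  repeat {
    deg <- integer(n)
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      if (keep[a] && keep[b]) { deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L }
    }
    drop <- keep & deg <= 1L & !mol$atoms$in_ring
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # restore atoms attached to the frame by a double/triple bond
  repeat {
    added <- FALSE
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      if (mol$bonds$order[k] >= 2 && xor(keep[a], keep[b])) {
        keep[a] <- keep[b] <- TRUE
        added <- TRUE
      }
    }
    if (!added) break
  }
  write_smiles(.subset_molecule(mol, which(keep)))
}

# sub-molecule on an atom subset; hydrogens are credited for severed bonds
.subset_molecule <- function(mol, atoms_keep) {
  remap <- match(seq_len(nrow(mol$atoms)), atoms_keep)
  at <- mol$atoms[atoms_keep, , drop = FALSE]
  bsel <- mol$bonds$a1 %in% atoms_keep & mol$bonds$a2 %in% atoms_keep
  lost <- mol$bonds[!bsel, , drop = FALSE]
  for (k in seq_len(nrow(lost))) {
    for (a in c(lost$a1[k], lost$a2[k])) {
      j <- remap[a]
      if (!is.na(j)) at$nH[j] <- at$nH[j] + as.integer(round(lost$order[k]))
    }
  }
  bb <- mol$bonds[bsel, , drop = FALSE]
  bb$a1 <- remap[bb$a1]; bb$a2 <- remap[bb$a2]
  rownames(at) <- NULL; rownames(bb) <- NULL
  .annotate_graph(structure(list(atoms = at, bonds = bb), class = "molecule"))
}
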