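# Circular (Morgan/ECFP-style) fingerprints and Tanimoto similarity.
#
# Atom environments are hashed from graph invariants only, so any SMILES
# spelling of a molecule yields the same bit vector. The default radius 2 with
# 1024 bits corresponds to the common ECFP4 setting.

# deterministic 31-bit integer hash of an integer vector (doubles stay exact:
# all intermediates < 2^53)
.ihash <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

#' Morgan (circular) fingerprint
#'
#' @param x SMILES string, `molecule`, or `compound`.
#' @param radius circular-environment radius (default 2, the ECFP4 setting).
#' @param nbits fingerprint length (default 1024).
#' @return an object of class `fingerprint`: an integer 0/1 vector of length
#'   `nbits` with attributes `radius` and `nbits`.
#' @examples
#' fp <- morgan_fingerprint("c1ccccc1")
#' sum(fp)  # popcount > 0
#' @export
morgan_fingerprint <- function(x, radius = 2L, nbits = 1024L) {
  mol <- as_molecule(x)
  at <- mol$atoms
  nb <- .neighbors(mol)
  n <- nrow(at)
  elem_code <- match(at$element, names(.default_valence))
  inv <- vapply(seq_len(n), function(i) {
    .ihash(c(elem_code[i], at$degree[i], at$nH[i], at$charge[i] + 10L,
             as.integer(at$aromatic[i]), as.integer(at$in_ring[i])))
  }, numeric(1))
  features <- inv
  for (r in seq_len(radius)) {
    inv_new <- vapply(seq_len(n), function(i) {
      if (length(nb[[i]]$nbr) == 0) return(.ihash(c(inv[i], 0)))
      pairs <- cbind(round(nb[[i]]$order * 10), inv[nb[[i]]$nbr])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      .ihash(c(inv[i], as.numeric(t(pairs))))
    }, numeric(1))
    inv <- inv_new
    features <- c(features, inv)
  }
  bits <- integer(nbits)
  bits[(features %% nbits) + 1L] <- 1L
  structure(bits, radius = as.integer(radius), nbits = as.integer(nbits),
            class = "fingerprint")
}

#' Tanimoto similarity between two fingerprints
#'
#' Defined as |A intersect B| / |A union B| over set bits. Two all-zero
#' fingerprints compare as 1.0, preserving the identity invariant
#' `tanimoto(x, x) == 1`.
#'
#' @param a,b fingerprints (equal length 0/1 vectors).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch: ",
                                   length(a), " vs ", length(b))
  ab <- sum(a & b)
  un <- sum(a | b)
  if (un == 0) return(1.0)
  ab / un
}

#' Fingerprint matrix for a set of compounds
#' @param smiles character vector of SMILES.
#' @param radius,nbits passed to [morgan_fingerprint()].
#' @return a matrix (length(smiles) x nbits) of 0/1 integers.
#' @export
fingerprint_matrix <- function(smiles, radius = 2L, nbits = 1024L) {
  m <- t(vapply(smiles, function(s) as.integer(morgan_fingerprint(s, radius, nbits)),
                integer(nbits)))
  rownames(m) <- names(smiles)
  m
}
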