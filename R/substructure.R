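# Substructure matching (subgraph monomorphism, VF2-style backtracking) and
# the PAINS flagging built on it.
#
# Patterns are written as SMILES fragments, not full SMARTS: each pattern atom
# must match element and aromaticity (and charge when non-zero), and each
# pattern bond must match order, with aromatic bonds matching aromatic bonds.
# This restricted language covers the assay-interference motifs shipped with
# the package; full SMARTS logic (wildcards, recursive environments) is out of
# scope and documented as such.

#' Test whether a pattern occurs as a substructure of a molecule
#'
#' @param target SMILES/`molecule`/`compound` searched in.
#' @param pattern SMILES/`molecule` searched for (connected fragment).
#' @return TRUE if at least one embedding exists.
#' @examples
#' has_substructure("Cc1ccccc1", "c1ccccc1")  # TRUE
#' has_substructure("C1CCCCC1", "c1ccccc1")   # FALSE (aromaticity mismatch)
#' @export
has_substructure <- function(target, pattern) {
  t <- as_molecule(target)
  p <- as_molecule(pattern)
  np <- nrow(p$atoms); nt <- nrow(t$atoms)
  if (np > nt) return(FALSE)
  tnb <- .neighbors(t)
  pnb <- .neighbors(p)

  atom_ok <- function(pa, ta) {
    p$atoms$element[pa] == t$atoms$element[ta] &&
      p$atoms$aromatic[pa] == t$atoms$aromatic[ta] &&
      (p$atoms$charge[pa] == 0L || p$atoms$charge[pa] == t$atoms$charge[ta]) &&
      p$atoms$degree[pa] <= t$atoms$degree[ta]
  }
  bond_ok <- function(po, to) isTRUE(all.equal(po, to))

  # order pattern atoms so each one (after the first) touches an earlier one
  ord <- integer(0)
  seen <- rep(FALSE, np)
  queue <- 1L
  while (length(queue) > 0) {
    a <- queue[1]; queue <- queue[-1]
    if (seen[a]) next
    seen[a] <- TRUE
    ord <- c(ord, a)
    queue <- c(queue, pnb[[a]]$nbr[!seen[pnb[[a]]$nbr]])
  }
  if (length(ord) < np) ord <- c(ord, which(!seen))  # disconnected pattern

  map <- rep(NA_integer_, np)
  used <- rep(FALSE, nt)

  match_from <- function(step) {
    if (step > np) return(TRUE)
    pa <- ord[step]
    # candidate targets: either neighbours of an already-mapped pattern
    # neighbour, or (first atom) everything
    mapped_nbrs <- pnb[[pa]]$nbr[!is.na(map[pnb[[pa]]$nbr])]
    cands <- if (length(mapped_nbrs) > 0) {
      first <- mapped_nbrs[1]
      tnb[[map[first]]]$nbr
    } else seq_len(nt)
    for (ta in cands) {
      if (used[ta] || !atom_ok(pa, ta)) next
      ok <- TRUE
      for (k in seq_along(pnb[[pa]]$nbr)) {
        qa <- pnb[[pa]]$nbr[k]
        if (is.na(map[qa])) next
        hit <- which(tnb[[ta]]$nbr == map[qa])
        if (length(hit) == 0 ||
            !bond_ok(pnb[[pa]]$order[k], tnb[[ta]]$order[hit[1]])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      map[pa] <<- ta; used[ta] <<- TRUE
      if (match_from(step + 1L)) return(TRUE)
      map[pa] <<- NA_integer_; used[ta] <<- FALSE
    }
    FALSE
  }
  match_from(1L)
}

#' Load a substructure pattern set
#'
#' Plain-text file with one pattern per line: `id<TAB or comma>smiles`.
#' Lines starting with `#` are ignored. Malformed patterns abort with the
#' offending id, so a broken pattern file fails at startup rather than
#' silently weakening the filter.
#'
#' @param path file path; default is the packaged assay-interference set.
#' @return data.frame with columns `id`, `smiles` and a `molecule` list-column.
#' @export
load_patterns <- function(path = system.file("extdata", "pains_patterns.tsv",
                                             package = "xpftriage")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t,]")
  df <- data.frame(id = vapply(parts, `[`, "", 1),
                   smiles = vapply(parts, `[`, "", 2))
  df$molecule <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_smiles(df$smiles[i]),
             error = function(e) stop("malformed pattern '", df$id[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  df
}

#' Partition compounds into PAINS-free and PAINS-flagged sets
#'
#' Pan-assay interference compounds (PAINS) carry substructures prone to
#' producing assay artefacts; they are removed before acquisition. The
#' partition is exhaustive and disjoint; each flagged record carries the id of
#' the first matching pattern.
#'
#' @param compounds a compound table (data.frame with `id`, `smiles`).
#' @param patterns a pattern set from [load_patterns()] (default: packaged set).
#' @return list with elements `kept` and `flagged` (the latter with an extra
#'   `pattern_id` column).
#' @export
pains_filter <- function(compounds, patterns = load_patterns()) {
  if (is.null(compounds) || nrow(compounds) == 0) {
    empty <- compounds[0, , drop = FALSE]
    flagged <- cbind(empty, pattern_id = character(0))
    return(list(kept = empty, flagged = flagged))
  }
  hit <- rep(NA_character_, nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    mol <- parse_smiles(compounds$smiles[i])
    for (j in seq_len(nrow(patterns))) {
      if (has_substructure(mol, patterns$molecule[[j]])) {
        hit[i] <- patterns$id[j]
        break
      }
    }
  }
  flagged <- compounds[!is.na(hit), , drop = FALSE]
  if (nrow(flagged) > 0) flagged$pattern_id <- hit[!is.na(hit)]
  else flagged$pattern_id <- character(0)
  list(kept = compounds[is.na(hit), , drop = FALSE], flagged = flagged)
}
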