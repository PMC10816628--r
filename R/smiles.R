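# Minimal-but-correct SMILES machinery for 2D triage work.
#
# The molecular graph is the only chemistry container the package needs:
# descriptors, fingerprints, scaffolds and substructure matching are all pure
# graph functions, so two SMILES spellings of one molecule give identical
# results without any canonicalisation step in between.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")

# default valences used to infer implicit hydrogens; charge-adjusted below
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

.atomic_mass <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.453,
                  Br = 79.904, I = 126.904)

.valence_for <- function(element, charge) {
  v <- unname(.default_valence[element])
  if (is.na(v)) return(NA_real_)
  if (element %in% c("N", "P", "B")) v <- v + charge
  if (element %in% c("O", "S")) v <- v + charge
  if (element == "C" && charge != 0) v <- v - abs(charge)
  max(v, 0)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset plus bracket atoms (charge, explicit H count,
#' isotopes ignored), aromatic lowercase atoms, branches, ring-closure digits
#' (including `%nn`), bond symbols `- = # :`, directional bonds `/` `\\`
#' (read as single), and dot-separated components. Stereochemistry is ignored:
#' the triage operates on 2D constitution only.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `molecule`: a list with `atoms`
#'   (data.frame: element, aromatic, charge, nH, degree, in_ring) and `bonds`
#'   (data.frame: a1, a2, order, aromatic, in_ring). Bond order is 1, 2, 3 or
#'   1.5 for aromatic bonds.
#' @examples
#' m <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")  # aspirin
#' nrow(m$atoms)
#' @export
parse_smiles <- function(smiles) {
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("SMILES must be a single non-empty string")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  el <- character(0); arom <- logical(0); chg <- integer(0)
  nH <- integer(0); nH_explicit <- logical(0)
  b1 <- integer(0); b2 <- integer(0); bord <- numeric(0); barom <- logical(0)

  stack <- integer(0)          # open-branch anchors
  prev <- 0L                   # previous atom index (0 = none)
  pending_bond <- NA_character_
  ring_open <- list()          # closure label -> list(atom, bond)

  add_atom <- function(element, aromatic, charge, hcount, h_explicit) {
    el[length(el) + 1L] <<- element
    arom[length(arom) + 1L] <<- aromatic
    chg[length(chg) + 1L] <<- charge
    nH[length(nH) + 1L] <<- hcount
    nH_explicit[length(nH_explicit) + 1L] <<- h_explicit
    length(el)
  }
  bond_order <- function(sym, a, b) {
    if (!is.na(sym)) {
      switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1,
             stop("unknown bond symbol: ", sym))
    } else if (arom[a] && arom[b]) 1.5 else 1
  }
  add_bond <- function(a, b, sym) {
    o <- bond_order(sym, a, b)
    b1[length(b1) + 1L] <<- a
    b2[length(b2) + 1L] <<- b
    bord[length(bord) + 1L] <<- o
    barom[length(barom) + 1L] <<- (o == 1.5)
  }
  connect <- function(idx) {
    force(idx)  # atom must be materialised before any vector is read
    if (prev > 0L) add_bond(prev, idx, pending_bond)
    pending_bond <<- NA_character_
    prev <<- idx
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in SMILES: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      # [isotope?][element][@..?][H count?][charge?][:map?]
      mm <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9+-]*)?(:[0-9]+)?$",
        body))[[1]]
      if (length(mm) == 0L) stop("cannot parse bracket atom [", body, "]")
      raw_el <- mm[3]
      aromatic <- raw_el %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      element <- if (aromatic) {
        paste0(toupper(substr(raw_el, 1, 1)), substr(raw_el, 2, nchar(raw_el)))
      } else raw_el
      htok <- mm[5]
      hcount <- if (is.na(htok) || !nzchar(htok)) 0L
        else if (htok == "H") 1L else as.integer(substr(htok, 2, nchar(htok)))
      ctok <- mm[6]
      charge <- 0L
      if (!is.na(ctok) && nzchar(ctok)) {
        if (grepl("^[+-][0-9]+$", ctok)) {
          charge <- as.integer(ctok)
        } else {
          charge <- sum(strsplit(ctok, "")[[1]] == "+") -
                    sum(strsplit(ctok, "")[[1]] == "-")
        }
      }
      connect(add_atom(element, aromatic, charge, hcount, TRUE))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      connect(add_atom(paste0(ch, chars[i + 1L]), FALSE, 0L, 0L, FALSE))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      connect(add_atom(ch, FALSE, 0L, 0L, FALSE))
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      connect(add_atom(toupper(ch), TRUE, 0L, 0L, FALSE))
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L
      pending_bond <- NA_character_
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("truncated %nn ring closure")
        lab <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        lab <- ch
        i <- i + 1L
      }
      if (prev == 0L) stop("ring closure before any atom")
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        sym <- if (!is.na(pending_bond)) pending_bond else op$bond
        add_bond(op$atom, prev, sym)
        ring_open[[lab]] <- NULL
        pending_bond <- NA_character_
      } else {
        ring_open[[lab]] <- list(atom = prev, bond = pending_bond)
        pending_bond <- NA_character_
      }
    } else if (ch == "@" || ch == "*") {
      i <- i + 1L  # chirality / wildcard markers: ignored
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smiles)
    }
  }
  if (length(ring_open) > 0L)
    stop("unclosed ring bond(s) in SMILES: ", smiles)
  if (length(stack) > 0L)
    stop("unbalanced '(' in SMILES: ", smiles)
  if (length(el) == 0L) stop("SMILES contains no atoms: ", smiles)

  bad <- !(el %in% names(.default_valence)) & el != "H"
  if (any(bad)) stop("unsupported element(s): ", paste(unique(el[bad]), collapse = ", "))

  # implicit hydrogens for organic-subset atoms
  bsum <- numeric(length(el))
  for (k in seq_along(b1)) {
    bsum[b1[k]] <- bsum[b1[k]] + bord[k]
    bsum[b2[k]] <- bsum[b2[k]] + bord[k]
  }
  for (a in seq_along(el)) {
    if (!nH_explicit[a]) {
      v <- .valence_for(el[a], chg[a])
      nH[a] <- max(0L, as.integer(v - ceiling(bsum[a] - 1e-9)))
    }
  }

  atoms <- data.frame(element = el, aromatic = arom, charge = chg, nH = nH,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = b1, a2 = b2, order = bord, aromatic = barom)
  if (nrow(bonds) > 0 &&
      anyDuplicated(t(apply(cbind(b1, b2), 1, sort))) > 0)
    stop("duplicate bond in SMILES: ", smiles)
  mol <- structure(list(atoms = atoms, bonds = bonds), class = "molecule")
  mol <- .fold_explicit_h(mol)
  mol <- .annotate_graph(mol)
  .perceive_aromaticity(mol)
}

# explicit [H] atoms become implicit H counts on their heavy partner, so the
# two spellings give identical graphs
.fold_explicit_h <- function(mol) {
  hs <- which(mol$atoms$element == "H")
  if (length(hs) == 0) return(mol)
  for (h in hs) {
    k <- which(mol$bonds$a1 == h | mol$bonds$a2 == h)
    if (length(k) == 1) {
      partner <- setdiff(c(mol$bonds$a1[k], mol$bonds$a2[k]), h)
      mol$atoms$nH[partner] <- mol$atoms$nH[partner] + 1L
    }
  }
  keep <- setdiff(seq_len(nrow(mol$atoms)), hs)
  remap <- match(seq_len(nrow(mol$atoms)), keep)
  bkeep <- !(mol$bonds$a1 %in% hs | mol$bonds$a2 %in% hs)
  mol$bonds <- mol$bonds[bkeep, , drop = FALSE]
  mol$bonds$a1 <- remap[mol$bonds$a1]
  mol$bonds$a2 <- remap[mol$bonds$a2]
  mol$atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  rownames(mol$bonds) <- NULL
  mol
}

# smallest ring through each ring bond (via shortest alternative path)
.rings <- function(mol, max_size = 7L) {
  rb <- which(mol$bonds$in_ring)
  if (length(rb) == 0) return(list())
  na <- nrow(mol$atoms)
  g <- igraph::graph_from_edgelist(
    as.matrix(mol$bonds[rb, c("a1", "a2")]), directed = FALSE)
  if (igraph::vcount(g) < na) g <- igraph::add_vertices(g, na - igraph::vcount(g))
  rings <- list()
  seen <- character(0)
  for (k in seq_along(rb)) {
    u <- mol$bonds$a1[rb[k]]; v <- mol$bonds$a2[rb[k]]
    eid <- igraph::get_edge_ids(g, c(u, v))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v)$vpath[[1]])
    if (length(sp) == 0 || length(sp) > max_size) next
    cyc <- sort(as.integer(sp))
    key <- paste(cyc, collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- as.integer(sp)
    }
  }
  rings
}

# pragmatic Hueckel-style aromatisation of kekulised input rings: a 5-7 ring
# is aromatic when every member is sp2 (endocyclic/fused double bond) or a
# lone-pair heteroatom, and the pi-electron count is 4n+2
.perceive_aromaticity <- function(mol) {
  if (nrow(mol$bonds) == 0 || all(!mol$bonds$in_ring)) return(mol)
  rings <- .rings(mol)
  if (length(rings) == 0) return(mol)
  ring_atom <- mol$atoms$in_ring
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    nb <- .neighbors(mol)
    for (ring in rings) {
      if (length(ring) < 5 || all(mol$atoms$aromatic[ring])) next
      pi_e <- 0L; ok <- TRUE
      for (a in ring) {
        dbl_in_ring <- any(nb[[a]]$order == 2 & ring_atom[nb[[a]]$nbr])
        dbl_any <- any(nb[[a]]$order >= 2 & nb[[a]]$order < 1.5 + 1)  # 2 or 3
        e <- mol$atoms$element[a]
        if (mol$atoms$aromatic[a] || dbl_in_ring) pi_e <- pi_e + 1L
        else if (!dbl_any && e %in% c("N", "O", "S")) pi_e <- pi_e + 2L
        else if (!dbl_any && e == "C" && mol$atoms$charge[a] == -1L) pi_e <- pi_e + 2L
        else { ok <- FALSE; break }
      }
      if (ok && pi_e %% 4L == 2L) {
        mol$atoms$aromatic[ring] <- TRUE
        bsel <- mol$bonds$a1 %in% ring & mol$bonds$a2 %in% ring & mol$bonds$in_ring
        mol$bonds$order[bsel] <- 1.5
        mol$bonds$aromatic[bsel] <- TRUE
        changed <- TRUE
      }
    }
  }
  mol
}

# degree + ring membership (a bond is in a ring iff it is not a bridge)
.annotate_graph <- function(mol) {
  na <- nrow(mol$atoms)
  deg <- integer(na)
  if (nrow(mol$bonds) > 0) {
    tab <- table(factor(c(mol$bonds$a1, mol$bonds$a2), levels = seq_len(na)))
    deg <- as.integer(tab)
  }
  mol$atoms$degree <- deg
  if (nrow(mol$bonds) > 0) {
    g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("a1", "a2")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < na) g <- igraph::add_vertices(g, na - igraph::vcount(g))
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(nrow(mol$bonds)) %in% as.integer(br))
    mol$bonds$in_ring <- in_ring_bond
    ring_atoms <- unique(c(mol$bonds$a1[in_ring_bond], mol$bonds$a2[in_ring_bond]))
    mol$atoms$in_ring <- seq_len(na) %in% ring_atoms
  } else {
    mol$bonds$in_ring <- logical(0)
    mol$atoms$in_ring <- rep(FALSE, na)
  }
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds, formula %s>\n",
              nrow(x$atoms), nrow(x$bonds), molecular_formula(x)))
  invisible(x)
}

#' Molecular formula (Hill order)
#' @param mol a `molecule`.
#' @return a string such as "C9H8O4".
#' @export
molecular_formula <- function(mol) {
  counts <- as.list(table(mol$atoms$element))
  h <- sum(mol$atoms$nH) + (if (is.null(counts[["H"]])) 0 else counts[["H"]])
  counts[["H"]] <- NULL
  if (h > 0) counts[["H"]] <- h
  els <- names(counts)
  ord <- if ("C" %in% els) {
    c("C", intersect("H", els), sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  paste(vapply(ord, function(e) {
    paste0(e, if (counts[[e]] > 1) counts[[e]] else "")
  }, character(1)), collapse = "")
}

# adjacency list: for atom i, data.frame(nbr, order, aromatic, bond)
.neighbors <- function(mol) {
  na <- nrow(mol$atoms)
  out <- vector("list", na)
  for (i in seq_len(na)) out[[i]] <- list(nbr = integer(0), order = numeric(0),
                                          bond = integer(0))
  bb <- mol$bonds
  for (k in seq_len(nrow(bb))) {
    a <- bb$a1[k]; b <- bb$a2[k]
    out[[a]]$nbr <- c(out[[a]]$nbr, b)
    out[[a]]$order <- c(out[[a]]$order, bb$order[k])
    out[[a]]$bond <- c(out[[a]]$bond, k)
    out[[b]]$nbr <- c(out[[b]]$nbr, a)
    out[[b]]$order <- c(out[[b]]$order, bb$order[k])
    out[[b]]$bond <- c(out[[b]]$bond, k)
  }
  out
}

# Deterministic canonical atom ranks by iterative neighbourhood refinement
# (Morgan-style), with lexicographic tie-breaking.
.refine_ranks <- function(rank, nb) {
  n <- length(rank)
  repeat {
    refined <- vapply(seq_len(n), function(i) {
      nbr_sig <- sort(paste0(sprintf("%.1f", nb[[i]]$order), ":",
                             sprintf("%06d", rank[nb[[i]]$nbr])))
      paste0(sprintf("%06d", rank[i]), "(", paste(nbr_sig, collapse = ","), ")")
    }, character(1))
    new_rank <- as.integer(factor(refined, levels = sort(unique(refined)))) - 1L
    if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
    rank <- new_rank
  }
}

.canonical_ranks <- function(mol) {
  na <- nrow(mol$atoms)
  at <- mol$atoms
  key <- paste(at$element, as.integer(at$aromatic), at$charge, at$nH, at$degree,
               sep = "|")
  rank <- as.integer(factor(key, levels = sort(unique(key)))) - 1L
  nb <- .neighbors(mol)
  rank <- .refine_ranks(rank, nb)
  # symmetry-equivalent atoms remain tied: break the lowest tie class by
  # promoting its lowest-index member, then re-refine (deterministic)
  while (length(unique(rank)) < na) {
    dup <- as.integer(names(which(table(rank) > 1)))
    tied <- which(rank == min(dup))
    promote <- tied[1]
    rank <- rank * 2L + 1L
    rank[promote] <- rank[promote] - 1L
    rank <- as.integer(factor(rank, levels = sort(unique(rank)))) - 1L
    rank <- .refine_ranks(rank, nb)
  }
  rank
}

#' Write a molecule as a canonical SMILES string
#'
#' The canonical form is deterministic for a given molecular graph (it uses
#' Morgan-style rank refinement), so any two SMILES spellings of a molecule
#' serialise identically. Aromatic atoms are written lowercase; hydrogens on
#' heteroatoms that the reader would not re-infer are written in brackets.
#'
#' @param mol a `molecule`.
#' @return a SMILES string ("" for a molecule with no atoms).
#' @export
write_smiles <- function(mol) {
  na <- nrow(mol$atoms)
  if (na == 0L) return("")
  rank <- .canonical_ranks(mol)
  nb <- .neighbors(mol)
  at <- mol$atoms

  comp <- integer(na)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("a1", "a2")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < na) g <- igraph::add_vertices(g, na - igraph::vcount(g))
    comp <- igraph::components(g)$membership
  } else comp <- seq_len(na)

  atom_token <- function(i) {
    e <- at$element[i]; aromatic <- at$aromatic[i]
    sym <- if (aromatic) tolower(e) else e
    need_bracket <- at$charge[i] != 0L || !(e %in% ORGANIC_SUBSET) ||
      (aromatic && !(e %in% AROMATIC_OK))
    if (!need_bracket) {
      # would the reader re-infer the right H count?
      v <- .valence_for(e, 0L)
      bsum <- sum(nb[[i]]$order)
      inferred <- max(0L, as.integer(v - ceiling(bsum - 1e-9)))
      if (inferred != at$nH[i]) need_bracket <- TRUE
    }
    if (!need_bracket) return(sym)
    h <- at$nH[i]
    htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ch <- at$charge[i]
    ctok <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
      else sprintf("%+d", ch)
    paste0("[", sym, htok, ctok, "]")
  }
  bond_token <- function(o, arom_bond) {
    if (arom_bond || o == 1) "" else if (o == 2) "=" else if (o == 3) "#" else ""
  }

  # --- pass 1: DFS to classify every bond as tree edge or ring closure ------
  visited <- rep(FALSE, na)
  bond_done <- rep(FALSE, max(nrow(mol$bonds), 1L))
  tree_children <- vector("list", na)
  tree_bond <- vector("list", na)
  closure_at <- vector("list", na)   # atom -> character tokens (bondsym+label)
  ring_num <- 0L
  roots <- integer(0)

  dfs <- function(i) {
    visited[i] <<- TRUE
    ord <- order(rank[nb[[i]]$nbr], nb[[i]]$nbr)
    nbrs <- nb[[i]]$nbr[ord]; bonds <- nb[[i]]$bond[ord]; orders <- nb[[i]]$order[ord]
    for (k in seq_along(nbrs)) {
      bk <- bonds[k]
      if (bond_done[bk]) next
      if (visited[nbrs[k]]) {
        # back edge: ring closure, label written at both ends
        bond_done[bk] <<- TRUE
        ring_num <<- ring_num + 1L
        lab <- if (ring_num < 10) as.character(ring_num)
               else paste0("%", sprintf("%02d", ring_num))
        tok <- paste0(bond_token(orders[k], mol$bonds$aromatic[bk]), lab)
        closure_at[[i]] <<- c(closure_at[[i]], tok)
        closure_at[[nbrs[k]]] <<- c(closure_at[[nbrs[k]]], tok)
      } else {
        bond_done[bk] <<- TRUE
        tree_children[[i]] <<- c(tree_children[[i]], nbrs[k])
        tree_bond[[i]] <<- c(tree_bond[[i]], bk)
        dfs(nbrs[k])
      }
    }
  }
  for (cmp in sort(unique(comp))) {
    members <- which(comp == cmp)
    root <- members[which.min(rank[members])]
    roots <- c(roots, root)
    dfs(root)
  }

  # --- pass 2: emit ---------------------------------------------------------
  emit <- function(i) {
    out <- paste0(atom_token(i), paste(closure_at[[i]], collapse = ""))
    kids <- tree_children[[i]]; kb <- tree_bond[[i]]
    if (length(kids) > 0) {
      branches <- vapply(seq_along(kids), function(k) {
        paste0(bond_token(mol$bonds$order[kb[k]], mol$bonds$aromatic[kb[k]]),
               emit(kids[k]))
      }, character(1))
      if (length(branches) > 1)
        out <- paste0(out, paste0("(", branches[-length(branches)], ")",
                                  collapse = ""))
      out <- paste0(out, branches[length(branches)])
    }
    out
  }
  paste(vapply(roots, emit, character(1)), collapse = ".")
}

#' Canonicalise a SMILES string
#' @param smiles a SMILES string.
#' @return the canonical SMILES of the same molecule.
#' @export
canonical_smiles <- function(smiles) write_smiles(parse_smiles(smiles))
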