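# Structural stage: PDB-subset I/O, rigid superposition, pocket definition,
# buried interface area, and rule-based protein-ligand interaction typing.
#
# Residue identity is (chain, PDB residue number, insertion code), 1-based as
# deposited. Geometric interaction rules follow widely used profiler defaults
# and are configurable through `interaction_thresholds()`.

#' Parse a PDB file (ATOM/HETATM/TER subset)
#'
#' @param path path to a PDB-format file.
#' @return a `pdb_structure`: list with `atoms` (data.frame: record, serial,
#'   name, resname, chain, resnum, icode, x, y, z, element) and `source`.
#'   HETATM records (ligands, waters) are kept and separable via `record`.
#' @export
parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path)
  lines <- lines[sel]
  f <- function(l, a, b) substr(l, a, b)
  rows <- lapply(seq_along(lines), function(i) {
    l <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(f(l, 31, 38), f(l, 39, 46), f(l, 47, 54))))
    if (anyNA(xyz)) {
      warning("malformed coordinates on line ", i, ", record skipped")
      return(NULL)
    }
    el <- trimws(f(l, 77, 78))
    nm <- trimws(f(l, 13, 16))
    if (!nzchar(el)) el <- substr(gsub("[0-9]", "", nm), 1, 1)
    data.frame(record = trimws(f(l, 1, 6)),
               serial = suppressWarnings(as.integer(f(l, 7, 11))),
               name = nm,
               resname = trimws(f(l, 18, 20)),
               chain = trimws(f(l, 22, 22)),
               resnum = suppressWarnings(as.integer(f(l, 23, 26))),
               icode = trimws(f(l, 27, 27)),
               x = xyz[1], y = xyz[2], z = xyz[3],
               element = toupper(el))
  })
  atoms <- do.call(rbind, rows)
  if (is.null(atoms) || nrow(atoms) == 0) stop("no parseable atoms in ", path)
  structure(list(atoms = atoms, source = path), class = "pdb_structure")
}

#' Write a structure (or atom table) in PDB format
#' @param s a `pdb_structure` or its `atoms` data.frame.
#' @param path output path.
#' @export
write_pdb <- function(s, path) {
  at <- if (inherits(s, "pdb_structure")) s$atoms else s
  lines <- vapply(seq_len(nrow(at)), function(i) {
    sprintf("%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            at$record[i], at$serial[i],
            if (nchar(at$name[i]) < 4) paste0(" ", at$name[i]) else at$name[i],
            at$resname[i], at$chain[i], at$resnum[i],
            ifelse(is.na(at$icode[i]) | at$icode[i] == "", " ", at$icode[i]),
            at$x[i], at$y[i], at$z[i], 1.00, 0.00, at$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
}

#' @export
print.pdb_structure <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("<pdb_structure: %d atoms, %d chains, %d residues>\n",
              nrow(at), length(unique(at$chain)),
              length(unique(paste(at$chain, at$resnum, at$icode)))))
  invisible(x)
}

.res_ids <- function(atoms) paste0(atoms$chain, ":", atoms$resnum, atoms$icode)

#' Residues of a structure
#' @param s a `pdb_structure`.
#' @param polymer_only drop HETATM records (waters, ligands).
#' @return data.frame (chain, resname, resnum, icode), one row per residue.
#' @export
structure_residues <- function(s, polymer_only = TRUE) {
  at <- s$atoms
  if (polymer_only) at <- at[at$record == "ATOM", , drop = FALSE]
  key <- .res_ids(at)
  at <- at[!duplicated(key), c("chain", "resname", "resnum", "icode")]
  rownames(at) <- NULL
  at
}

# --- superposition ----------------------------------------------------------

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares superposes moving points `a` onto fixed points `b`; the
#' rotation is constrained to be proper (no reflection).
#'
#' @param a,b numeric n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear).
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `a %*% rotation + translation` superposes onto `b`, and `rmsd` in
#'   Angstroms.
#' @export
superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3)
    stop("selections must be equal-sized n x 3 matrices")
  if (nrow(a) < 3) stop("need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (qr(a0)$rank < 2) stop("degenerate (collinear) geometry")
  h <- t(a0) %*% b0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  moved <- a0 %*% rot
  rmsd <- sqrt(mean(rowSums((moved - b0)^2)))
  list(rotation = rot, translation = cb - as.numeric(ca %*% rot), rmsd = rmsd)
}

#' Paired C-alpha coordinates of common residues in two chains
#' @param s1,s2 `pdb_structure`s.
#' @param chain1,chain2 chain identifiers.
#' @return list of two n x 3 matrices over residues present in both chains.
#' @export
ca_pairing <- function(s1, chain1, s2, chain2) {
  pick <- function(s, ch) {
    at <- s$atoms
    at <- at[at$record == "ATOM" & at$chain == ch & at$name == "CA", ]
    at[order(at$resnum), ]
  }
  a <- pick(s1, chain1); b <- pick(s2, chain2)
  common <- intersect(a$resnum, b$resnum)
  if (length(common) < 3) stop("fewer than 3 shared CA positions")
  a <- a[match(common, a$resnum), ]; b <- b[match(common, b$resnum), ]
  list(a = as.matrix(a[, c("x", "y", "z")]), b = as.matrix(b[, c("x", "y", "z")]))
}

# --- pocket -----------------------------------------------------------------

.parse_residue_spec <- function(spec) {
  if (is.list(spec)) return(spec)
  m <- regmatches(spec, regexec("^([A-Za-z0-9]):([0-9]+)([A-Za-z]?)$", spec))[[1]]
  if (length(m) == 0) stop("residue spec must be 'chain:resnum', got ", spec)
  list(chain = m[2], resnum = as.integer(m[3]), icode = m[4])
}

#' Define a binding pocket around a centre residue
#'
#' The pocket membership rule: a residue belongs to the pocket when at least
#' one of its atoms lies within `radius` Angstroms of any atom of the centre
#' residue. Membership is monotone in the radius and the centre residue is
#' always a member.
#'
#' @param s a `pdb_structure`.
#' @param center residue spec: `"chain:resnum"` or
#'   `list(chain=, resnum=, icode=)`.
#' @param radius pocket radius in Angstroms (default 15, the docking-site
#'   radius used around the anchoring residues).
#' @return a `pocket` object: list(center, radius, members) where members is a
#'   data.frame (chain, resname, resnum, icode).
#' @export
define_pocket <- function(s, center, radius = 15) {
  spec <- .parse_residue_spec(center)
  at <- s$atoms[s$atoms$record == "ATOM", , drop = FALSE]
  csel <- at$chain == spec$chain & at$resnum == spec$resnum
  if (!is.null(spec$icode) && nzchar(spec$icode %||% ""))
    csel <- csel & at$icode == spec$icode
  if (!any(csel)) stop("centre residue ", spec$chain, ":", spec$resnum,
                       " not present in structure")
  cx <- as.matrix(at[csel, c("x", "y", "z")])
  d2 <- .min_dist2_to_set(as.matrix(at[, c("x", "y", "z")]), cx)
  at$near <- d2 <= radius^2 + 1e-12
  key <- .res_ids(at)
  member_keys <- unique(key[at$near])
  members <- at[!duplicated(key) & key %in% member_keys,
                c("chain", "resname", "resnum", "icode")]
  members <- members[order(members$chain, members$resnum), ]
  rownames(members) <- NULL
  structure(list(center = spec, radius = radius, members = members),
            class = "pocket")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# squared distance from each row of `pts` to nearest row of `ref`
.min_dist2_to_set <- function(pts, ref) {
  apply(pts, 1, function(p) min(colSums((t(ref) - p)^2)))
}

# --- solvent-accessible and buried surface area -----------------------------

.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

.sphere_points <- function(n) {
  # golden-spiral points on the unit sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley sphere sampling)
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`.
#' @param probe probe radius in Angstroms (default 1.4, a water molecule).
#' @param n_points sample points per atom (default 960).
#' @return total SASA in square Angstroms.
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  n <- nrow(atoms)
  el <- toupper(atoms$element)
  r <- .vdw_radii[el]
  r[is.na(r)] <- 1.70
  r <- unname(r) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  sp <- .sphere_points(n_points)
  total <- 0
  for (i in seq_len(n)) {
    pts <- sweep(sp * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij2 <- sum((xyz[i, ] - xyz[j, ])^2)
      if (dij2 >= (r[i] + r[j])^2) next
      d2 <- colSums((t(pts) - xyz[j, ])^2)
      acc <- acc & d2 > r[j]^2
      if (!any(acc)) break
    }
    total <- total + 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  total
}

#' Buried contact surface area between two chains
#'
#' Computed as `(SASA(a alone) + SASA(b alone) - SASA(complex)) / 2`, the
#' conventional per-partner buried area.
#'
#' @param s a `pdb_structure`.
#' @param chain_a,chain_b chain identifiers.
#' @param probe probe radius (default 1.4).
#' @param n_points sphere-sampling density per atom.
#' @return buried area in square Angstroms.
#' @export
contact_surface_area <- function(s, chain_a, chain_b, probe = 1.4,
                                 n_points = 960L) {
  at <- s$atoms[s$atoms$record == "ATOM", , drop = FALSE]
  a <- at[at$chain == chain_a, , drop = FALSE]
  b <- at[at$chain == chain_b, , drop = FALSE]
  if (nrow(a) == 0) stop("chain ", chain_a, " absent from structure")
  if (nrow(b) == 0) stop("chain ", chain_b, " absent from structure")
  (sasa(a, probe, n_points) + sasa(b, probe, n_points) -
     sasa(rbind(a, b), probe, n_points)) / 2
}

# --- interaction typing -----------------------------------------------------

#' Geometric thresholds for typed protein-ligand contacts
#'
#' Defaults follow published interaction-profiler conventions: hydrogen bond
#' donor-acceptor distance <= 4.1 A (donor angle >= 100 deg when hydrogens are
#' present; waived and flagged otherwise), hydrophobic C...C <= 4.0 A between
#' apolar carbons, pi-stacking centroid distance <= 5.5 A with plane-angle
#' windows (< 30 deg parallel, 60-90 deg T-shaped), pi-cation <= 6.0 A,
#' salt bridge <= 5.5 A between charged-group centroids, halogen bond
#' X...acceptor <= 4.0 A, water bridge legs <= 4.1 A.
#'
#' @param ... named overrides of the defaults.
#' @return named list of thresholds.
#' @export
interaction_thresholds <- function(...) {
  th <- list(hbond_dist = 4.1, hbond_angle = 100,
             hydrophobic_dist = 4.0,
             pistack_dist = 5.5, pistack_parallel = 30,
             pistack_tshape_lo = 60, pistack_tshape_hi = 90,
             pication_dist = 6.0,
             saltbridge_dist = 5.5,
             halogen_dist = 4.0,
             waterbridge_dist = 4.1)
  over <- list(...)
  bad <- setdiff(names(over), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(over)] <- over
  th
}

# protein side-chain carbons excluded from the apolar set because they are
# bonded to N/O/S by residue topology
.polar_adjacent_carbons <- list(
  SER = "CB", THR = "CB", CYS = "CB", ASP = "CG", GLU = "CD", ASN = "CG",
  GLN = "CD", ARG = c("CZ", "CD"), LYS = "CE", HIS = c("CG", "CD2", "CE1"),
  MET = c("CG", "CE"), TRP = c("CD1", "CE2"), TYR = "CZ", PRO = c("CD"))

.protein_aromatic_rings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

.protein_cation_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "CZ"))
.protein_anion_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.protein_donor_names <- c("N", "NZ", "NE", "NH1", "NH2", "ND1", "NE2", "ND2",
                          "NE1", "OG", "OG1", "OH", "SG")

.angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

.ring_normal <- function(coords) {
  c0 <- colMeans(coords)
  sv <- svd(sweep(coords, 2, c0))
  sv$v[, 3]
}

#' Detect typed protein-ligand interactions
#'
#' Applies pure geometric rules (see [interaction_thresholds()]) between a
#' ligand pose and the protein residues of a pocket. Hydrogen-bond angle
#' checks run only when the ligand provides hydrogen positions (rows with
#' element "H" and a `parent` column); otherwise detection is distance-only
#' and the record is flagged `angle_waived`.
#'
#' @param s a `pdb_structure` (the receptor).
#' @param ligand data.frame of ligand atoms: `element`, `x`, `y`, `z`,
#'   optional `charge`, optional `nH` (donor capability), optional `parent`
#'   for explicit hydrogens. Aromatic rings may be supplied as
#'   `attr(ligand, "rings")`, a list of atom-index vectors.
#' @param pocket a `pocket` restricting the protein residues considered.
#' @param compound_id identifier recorded on each interaction.
#' @param thresholds from [interaction_thresholds()].
#' @return data.frame of interaction records: compound_id, chain, resname,
#'   resnum, type, distance, angle, angle_waived.
#' @export
detect_interactions <- function(s, ligand, pocket, compound_id = "LIG",
                                thresholds = interaction_thresholds()) {
  th <- thresholds
  at <- s$atoms[s$atoms$record == "ATOM", , drop = FALSE]
  keys <- .res_ids(at)
  pocket_keys <- paste0(pocket$members$chain, ":", pocket$members$resnum,
                        pocket$members$icode)
  at <- at[keys %in% pocket_keys, , drop = FALSE]
  if (nrow(at) == 0 || nrow(ligand) == 0)
    return(.empty_interactions())

  if (is.null(ligand$charge)) ligand$charge <- 0
  if (is.null(ligand$nH)) ligand$nH <- NA_integer_
  unknown <- !(toupper(ligand$element) %in% c(names(.vdw_radii), ""))
  if (any(unknown)) {
    warning("unknown ligand element(s) ignored for typed roles: ",
            paste(unique(ligand$element[unknown]), collapse = ", "))
  }
  lig_h <- which(ligand$element == "H")
  heavy <- setdiff(seq_len(nrow(ligand)), lig_h)
  lxyz <- as.matrix(ligand[, c("x", "y", "z")])
  pxyz <- as.matrix(at[, c("x", "y", "z")])

  recs <- list()
  add <- function(row_at, type, dist, angle = NA_real_, waived = FALSE) {
    recs[[length(recs) + 1L]] <<- data.frame(
      compound_id = compound_id, chain = at$chain[row_at],
      resname = at$resname[row_at], resnum = at$resnum[row_at],
      type = type, distance = dist, angle = angle, angle_waived = waived)
  }

  have_h <- length(lig_h) > 0 && !is.null(ligand$parent)

  # hydrogen bonds (ligand donor -> protein acceptor, and the reverse)
  lig_polar <- heavy[ligand$element[heavy] %in% c("N", "O")]
  prot_polar <- which(at$element %in% c("N", "O"))
  for (i in lig_polar) {
    for (j in prot_polar) {
      d <- sqrt(sum((lxyz[i, ] - pxyz[j, ])^2))
      if (d > th$hbond_dist || d < 1e-6) next
      lig_is_donor <- isTRUE(ligand$nH[i] > 0) ||
        (have_h && any(ligand$parent[lig_h] == i))
      prot_is_donor <- at$name[j] %in% .protein_donor_names
      if (!lig_is_donor && !prot_is_donor) next
      if (lig_is_donor && have_h && any(ligand$parent[lig_h] == i)) {
        hs <- lig_h[ligand$parent[lig_h] == i]
        angs <- vapply(hs, function(h) .angle_deg(lxyz[i, ], lxyz[h, ], pxyz[j, ]),
                       numeric(1))
        ang <- max(angs)
        if (ang < th$hbond_angle) next
        add(j, "HBOND", d, ang, FALSE)
      } else {
        add(j, "HBOND", d, NA_real_, TRUE)
      }
    }
  }

  # hydrophobic contacts between apolar carbons
  lig_apolar <- if (!is.null(ligand$apolar)) which(ligand$apolar)
    else heavy[ligand$element[heavy] == "C"]
  excl <- mapply(function(rn, nm) {
    nm %in% c("C", .polar_adjacent_carbons[[rn]] %||% character(0))
  }, at$resname, at$name)
  prot_apolar <- which(at$element == "C" & !excl)
  for (i in lig_apolar) {
    d2 <- colSums((t(pxyz[prot_apolar, , drop = FALSE]) - lxyz[i, ])^2)
    hits <- which(d2 <= th$hydrophobic_dist^2)
    for (h in hits) add(prot_apolar[h], "HYDROPHOBIC", sqrt(d2[h]))
  }

  # ring-based interactions need ligand ring definitions
  rings <- attr(ligand, "rings")
  res_split <- split(seq_len(nrow(at)), .res_ids(at))
  for (rkey in names(res_split)) {
    rows <- res_split[[rkey]]
    rn <- at$resname[rows[1]]
    # protein cation vs ligand ring (pi-cation), and protein ring vs both
    cat_names <- .protein_cation_atoms[[rn]]
    if (!is.null(cat_names)) {
      cat_rows <- rows[at$name[rows] %in% cat_names]
      if (length(cat_rows) > 0 && !is.null(rings)) {
        cat_xyz <- colMeans(pxyz[cat_rows, , drop = FALSE])
        for (ring in rings) {
          cen <- colMeans(lxyz[ring, , drop = FALSE])
          d <- sqrt(sum((cen - cat_xyz)^2))
          if (d <= th$pication_dist)
            add(cat_rows[1], "PI_CATION", d)
        }
      }
    }
    ring_names <- .protein_aromatic_rings[[rn]]
    if (!is.null(ring_names)) {
      ring_rows <- rows[at$name[rows] %in% ring_names]
      if (length(ring_rows) >= 5) {
        pcen <- colMeans(pxyz[ring_rows, , drop = FALSE])
        pnorm <- .ring_normal(pxyz[ring_rows, , drop = FALSE])
        # ligand cation vs protein ring
        lig_cat <- heavy[ligand$charge[heavy] > 0]
        for (i in lig_cat) {
          d <- sqrt(sum((lxyz[i, ] - pcen)^2))
          if (d <= th$pication_dist) add(ring_rows[1], "PI_CATION", d)
        }
        # pi stacking
        if (!is.null(rings)) {
          for (ring in rings) {
            cen <- colMeans(lxyz[ring, , drop = FALSE])
            d <- sqrt(sum((cen - pcen)^2))
            if (d > th$pistack_dist) next
            lnorm <- .ring_normal(lxyz[ring, , drop = FALSE])
            ang <- acos(pmin(abs(sum(lnorm * pnorm)), 1)) * 180 / pi
            if (ang < th$pistack_parallel ||
                (ang >= th$pistack_tshape_lo && ang <= th$pistack_tshape_hi))
              add(ring_rows[1], "PI_STACK", d, ang)
          }
        }
      }
    }
    # salt bridges: ligand charge vs protein charged-group centroid
    for (sgn in c(1, -1)) {
      grp <- if (sgn > 0) .protein_anion_atoms[[rn]] else .protein_cation_atoms[[rn]]
      if (is.null(grp)) next
      grows <- rows[at$name[rows] %in% grp]
      if (length(grows) == 0) next
      gcen <- colMeans(pxyz[grows, , drop = FALSE])
      for (i in heavy[sign(ligand$charge[heavy]) == sgn]) {
        d <- sqrt(sum((lxyz[i, ] - gcen)^2))
        if (d <= th$saltbridge_dist) add(grows[1], "SALT_BRIDGE", d)
      }
    }
  }

  # halogen bonds: ligand X ... protein O/N
  lig_hal <- heavy[ligand$element[heavy] %in% c("F", "Cl", "Br", "I")]
  for (i in lig_hal) {
    for (j in prot_polar) {
      d <- sqrt(sum((lxyz[i, ] - pxyz[j, ])^2))
      if (d <= th$halogen_dist) add(j, "HALOGEN", d)
    }
  }

  # water bridges: ligand polar - water O - protein polar
  wat <- s$atoms[s$atoms$record == "HETATM" &
                 s$atoms$resname %in% c("HOH", "WAT") &
                 s$atoms$element == "O", , drop = FALSE]
  if (nrow(wat) > 0) {
    wxyz <- as.matrix(wat[, c("x", "y", "z")])
    for (w in seq_len(nrow(wat))) {
      near_lig <- any(sqrt(colSums((t(lxyz[lig_polar, , drop = FALSE]) -
                                      wxyz[w, ])^2)) <= th$waterbridge_dist)
      if (!near_lig) next
      for (j in prot_polar) {
        d <- sqrt(sum((wxyz[w, ] - pxyz[j, ])^2))
        if (d <= th$waterbridge_dist) add(j, "WATER_BRIDGE", d)
      }
    }
  }

  if (length(recs) == 0) return(.empty_interactions())
  out <- do.call(rbind, recs)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

.empty_interactions <- function() {
  data.frame(compound_id = character(0), chain = character(0),
             resname = character(0), resnum = integer(0), type = character(0),
             distance = numeric(0), angle = numeric(0),
             angle_waived = logical(0))
}

#' Residues-by-compounds interaction matrix
#'
#' Mirrors the gray-square heatmap view: one row per residue, one column per
#' compound, cells holding the (comma-joined) set of interaction types.
#'
#' @param records data.frame of interaction records from
#'   [detect_interactions()] (possibly several compounds concatenated).
#' @return list with `matrix` (character matrix of type sets, "" when none),
#'   `counts` (numeric matrix of record counts), and `residue_marginal`
#'   (named vector: number of distinct compounds contacting each residue,
#'   sorted decreasing).
#' @export
build_interaction_matrix <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    m <- matrix(character(0), 0, 0)
    return(list(matrix = m, counts = matrix(numeric(0), 0, 0),
                residue_marginal = numeric(0)))
  }
  res <- paste0(records$resname, records$resnum, "(", records$chain, ")")
  cmp <- records$compound_id
  rl <- sort(unique(res)); cl <- sort(unique(cmp))
  m <- matrix("", length(rl), length(cl), dimnames = list(rl, cl))
  cnt <- matrix(0, length(rl), length(cl), dimnames = list(rl, cl))
  for (k in seq_len(nrow(records))) {
    i <- match(res[k], rl); j <- match(cmp[k], cl)
    types <- unique(c(strsplit(m[i, j], ",")[[1]], records$type[k]))
    types <- types[nzchar(types)]
    m[i, j] <- paste(sort(types), collapse = ",")
    cnt[i, j] <- cnt[i, j] + 1
  }
  marginal <- apply(m, 1, function(r) sum(nzchar(r)))
  list(matrix = m, counts = cnt,
       residue_marginal = sort(marginal, decreasing = TRUE))
}
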