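# Synthetic-data generators: everything the commercial docking engine and the
# wet lab would otherwise provide, as pure functions of (spec, seed).
#
# The generated world states the conditions of the study it emulates: an
# "active" compound stratum matching the descriptor profile of known
# inhibitors (MW 200-400 g/mol, 2-3 H-bond donors, >= 4 acceptors, LogP 1-3,
# no Lipinski violations), viability plates where 1 uM cisplatin leaves
# 85-90% of cells viable with ~5 pp replicate noise, and a fixture encoding
# the printed per-stage compound bookkeeping.

# fragment grammar for the active stratum: diaryl amides/sulfonamides with
# polar decorations; inactives are greasy or tiny molecules outside the box
.active_templates <- c(
  "Oc1ccc(cc1)C(=O)Nc1ccc(%s)cc1",
  "Oc1ccc(cc1)C(=O)Nc1ccc(%s)c(C)c1",
  "Oc1ccc(cc1)S(=O)(=O)Nc1ccc(%s)cc1",
  "OCc1ccc(cc1)C(=O)Nc1ccc(%s)cc1",
  "Oc1ccc(cc1)C(=O)Nc1ccc(%s)nc1",
  "Oc1ccc(cc1)NC(=O)c1ccc(%s)nc1",
  "Oc1ccc(cc1)C(=O)NCc1ccc(%s)cc1")
.active_subs <- c("OC", "OCC", "C(=O)OC", "F", "Cl", "C#N", "OC(F)F",
                  "C(=O)N(C)C", "OCCO")
.inactive_templates <- c(
  "CCCCCCCCCC", "CCCCCCCCCCCC", "CCCCCCc1ccccc1", "CCCCCCCCc1ccccc1",
  "c1ccc(cc1)c1ccccc1", "CCCCCCCCCCCCCC", "CC(C)CC(C)(C)C", "CCCCOCCCC",
  "Clc1ccc(Cl)c(Cl)c1", "CCCCCCCCCCCCCCCC", "CCCCCCCCCCC(C)C",
  "CCCCSCCCC")

#' Library specification for the synthetic compound generator
#' @param n_active,n_inactive stratum sizes.
#' @param seed integer seed.
#' @param mw_range,logp_range active-stratum descriptor box.
#' @param hbd_set allowed donor counts for actives.
#' @param hba_min minimum acceptor count for actives.
#' @param max_attempts bounded rejection-sampling attempts per record.
#' @return named list.
#' @export
library_spec <- function(n_active = 100, n_inactive = 400, seed = 1,
                         mw_range = c(200, 400), logp_range = c(1, 3),
                         hbd_set = c(2, 3), hba_min = 4,
                         max_attempts = 200L) {
  list(n_active = n_active, n_inactive = n_inactive, seed = seed,
       mw_range = mw_range, logp_range = logp_range, hbd_set = hbd_set,
       hba_min = hba_min, max_attempts = max_attempts)
}

#' Generate a synthetic compound library
#'
#' Actives are assembled from a diaryl amide/sulfonamide fragment grammar and
#' rejection-sampled against the active descriptor box (all returned actives
#' satisfy it); inactives are drawn from templates outside the box. The
#' result is a pure function of the spec (including its seed).
#'
#' @param spec a [library_spec()].
#' @return data.frame: id, smiles, source ("SYNTHETIC"), stratum
#'   (ACTIVE/INACTIVE), plus descriptor columns.
#' @export
gen_library <- function(spec = library_spec()) {
  set.seed(spec$seed)
  in_box <- function(d) {
    d$mw >= spec$mw_range[1] && d$mw <= spec$mw_range[2] &&
      d$hbd %in% spec$hbd_set && d$hba >= spec$hba_min &&
      d$logp >= spec$logp_range[1] && d$logp <= spec$logp_range[2] &&
      d$lipinski_violations == 0
  }
  actives <- character(0)
  attempts <- 0L
  while (length(actives) < spec$n_active) {
    attempts <- attempts + 1L
    if (attempts > spec$max_attempts * max(spec$n_active, 1))
      stop("active descriptor targets infeasible after ", attempts, " attempts")
    tpl <- sample(.active_templates, 1)
    sub <- sample(.active_subs, 1)
    smi <- sprintf(tpl, sub)
    d <- compute_descriptors(smi)
    if (in_box(d)) actives <- c(actives, smi)
  }
  inactives <- if (spec$n_inactive > 0)
    sample(.inactive_templates, spec$n_inactive, replace = TRUE)
  else character(0)

  smiles <- c(actives, inactives)
  stratum <- c(rep("ACTIVE", length(actives)), rep("INACTIVE", length(inactives)))
  ids <- sprintf("SYN%04d", seq_along(smiles))
  desc <- do.call(rbind, lapply(smiles, compute_descriptors))
  cbind(data.frame(id = ids, compound_id = ids, smiles = smiles,
                   source = "SYNTHETIC", stratum = stratum),
        desc)
}

#' Generate docking-score tables correlated with the activity stratum
#'
#' Scores are ChemPLP-like (dimensionless, higher is better). The
#' active-stratum shift is calibrated internally (deterministic bisection on
#' the generated noise) so that the rank correlation between stratum and score
#' approximates the requested value.
#'
#' @param library a compound table from [gen_library()] (needs `compound_id`,
#'   `stratum`, `heavy_atoms`).
#' @param correlation requested stratum/score rank correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @return data.frame: compound_id, score, ligand_efficiency.
#' @export
gen_scores <- function(library, correlation = 0.8, seed = 1) {
  stopifnot(abs(correlation) <= 1)
  set.seed(seed)
  n <- nrow(library)
  active <- as.numeric(library$stratum == "ACTIVE")
  eps <- stats::rnorm(n)
  score_for <- function(delta) 70 + 10 * eps + delta * active
  achieved <- function(delta) {
    if (stats::sd(active) == 0) return(0)
    suppressWarnings(stats::cor(active, score_for(delta), method = "spearman"))
  }
  if (correlation == 0 || stats::sd(active) == 0) {
    delta <- 0
  } else {
    sgn <- sign(correlation)
    lo <- 0; hi <- 200
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (abs(achieved(sgn * mid)) < abs(correlation)) lo <- mid else hi <- mid
    }
    delta <- sgn * (lo + hi) / 2
  }
  score <- score_for(delta)
  data.frame(compound_id = library$compound_id, score = score,
             ligand_efficiency = ligand_efficiency(score, library$heavy_atoms))
}

#' Plate specification for the viability simulator
#' @param cisplatin_viability percent viability under 1 uM cisplatin
#'   (default 87.5, the midpoint of the stated 85-90% band).
#' @param replicate_sd replicate noise, percentage points (default 5).
#' @param replicates wells per condition per experiment (default 3).
#' @param experiments independent experiments (default 2).
#' @param vehicle_od mean vehicle optical density (default 1.0).
#' @param seed integer seed.
#' @return named list.
#' @export
plate_spec <- function(cisplatin_viability = 87.5, replicate_sd = 5,
                       replicates = 3, experiments = 2, vehicle_od = 1.0,
                       seed = 1) {
  list(cisplatin_viability = cisplatin_viability, replicate_sd = replicate_sd,
       replicates = replicates, experiments = experiments,
       vehicle_od = vehicle_od, seed = seed)
}

#' Simulate viability plates from per-compound true viabilities
#'
#' Well ODs are `vehicle_od * viability/100 * (1 + N(0, replicate_sd/100))`;
#' each experiment includes vehicle and cisplatin wells. With zero noise,
#' [normalize_viability()] recovers the truth exactly.
#'
#' @param truth data.frame: compound_id, v_alone, v_combo, optionally
#'   v_alone_10, v_combo_10 (percent viabilities; NA skips the condition).
#' @param spec a [plate_spec()].
#' @return a plate table accepted by [normalize_viability()].
#' @export
gen_plates <- function(truth, spec = plate_spec()) {
  if (any(unlist(truth[, -1]) < 0, na.rm = TRUE))
    stop("negative target viability")
  set.seed(spec$seed)
  rows <- list()
  well <- function(experiment, replicate, compound_id, condition, conc, viab) {
    od <- spec$vehicle_od * viab / 100 *
      (1 + stats::rnorm(1, 0, spec$replicate_sd / 100))
    data.frame(experiment = experiment, replicate = replicate,
               compound_id = compound_id, condition = condition,
               concentration_uM = conc, od = max(od, 0))
  }
  for (e in seq_len(spec$experiments)) {
    for (r in seq_len(spec$replicates)) {
      rows[[length(rows) + 1L]] <- well(e, r, "CONTROL", "VEHICLE", 0, 100)
      rows[[length(rows) + 1L]] <- well(e, r, "CISPLATIN", "CISPLATIN_1uM", 1,
                                        spec$cisplatin_viability)
      for (i in seq_len(nrow(truth))) {
        id <- truth$compound_id[i]
        rows[[length(rows) + 1L]] <-
          well(e, r, id, "COMPOUND_ALONE", 50, truth$v_alone[i])
        rows[[length(rows) + 1L]] <-
          well(e, r, id, "COMBINATION", 50, truth$v_combo[i])
        if (!is.null(truth$v_alone_10) && !is.na(truth$v_alone_10[i])) {
          rows[[length(rows) + 1L]] <-
            well(e, r, id, "COMPOUND_ALONE_10uM", 10, truth$v_alone_10[i])
          rows[[length(rows) + 1L]] <-
            well(e, r, id, "COMBINATION_10uM", 10, truth$v_combo_10[i])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cisplatin concentration-response experiment
#'
#' Emulates the crystal-violet assay setup: concentrations spanning 1-30 uM,
#' six replicates, true 4PL parameters with IC50 3.0 uM, and replicate noise
#' in percentage points.
#'
#' @param seed integer seed.
#' @param ic50,hill,top,bottom true 4PL parameters.
#' @param conc concentration grid (uM).
#' @param replicates wells per concentration.
#' @param noise_sd additive viability noise (pp, default 5).
#' @return data.frame: conc, viability (one row per well); the truth is
#'   attached as attributes `ic50` etc.
#' @export
gen_cisplatin_curve <- function(seed = 1, ic50 = 3.0, hill = 1.3, top = 100,
                                bottom = 0,
                                conc = c(1, 2, 3, 5, 7.5, 10, 15, 20, 30),
                                replicates = 6, noise_sd = 5) {
  set.seed(seed)
  cc <- rep(conc, each = replicates)
  mu <- bottom + (top - bottom) / (1 + (cc / ic50)^hill)
  v <- mu + stats::rnorm(length(cc), 0, noise_sd)
  out <- data.frame(conc = cc, viability = v)
  attr(out, "ic50") <- ic50; attr(out, "hill") <- hill
  attr(out, "top") <- top; attr(out, "bottom") <- bottom
  out
}

#' Synthetic qPCR Ct table for the NSCLC cell-line panel
#'
#' Encodes the reported expression ordering: H1299 has the highest ERCC1
#' expression (smallest delta-Ct), followed by A549; ERCC4 shows no marked
#' differences between lines.
#'
#' @param seed integer seed.
#' @param collections number of independent RNA collections (default 3).
#' @return data.frame: cell_line, gene, collection, ct.
#' @export
gen_ct_table <- function(seed = 1, collections = 3) {
  set.seed(seed)
  lines <- c("H1299", "A549", "H1993", "H661", "H1975", "HCC827")
  dct_ercc1 <- c(H1299 = 3.0, A549 = 4.2, H1993 = 6.0, H661 = 5.5,
                 H1975 = 6.3, HCC827 = 6.2)
  dct_ercc4 <- stats::setNames(rep(6.5, 6), lines)
  rows <- list()
  for (co in seq_len(collections)) {
    for (cl in lines) {
      ct_act <- 18 + stats::rnorm(1, 0, 0.2)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cl, gene = "ACTB", collection = co, ct = ct_act)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cl, gene = "ERCC1", collection = co,
        ct = ct_act + dct_ercc1[[cl]] + stats::rnorm(1, 0, 0.15))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cl, gene = "ERCC4", collection = co,
        ct = ct_act + dct_ercc4[[cl]] + stats::rnorm(1, 0, 0.15))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- toy protein-ligand complexes ------------------------------------------

# minimal receptor: anchor LYS at the origin, the eight pocket neighbours on
# a 10 A circle (beyond every interaction cutoff from a ligand at the anchor)
.toy_receptor <- function() {
  resdefs <- list(
    list(num = 833, name = "TYR"), list(num = 834, name = "ASN"),
    list(num = 837, name = "PRO"), list(num = 840, name = "PHE"),
    list(num = 841, name = "LEU"), list(num = 856, name = "MET"),
    list(num = 859, name = "VAL"), list(num = 862, name = "ILE"))
  rows <- list(); serial <- 0L
  add <- function(name, resname, resnum, x, y, z, element) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      record = "ATOM", serial = serial, name = name, resname = resname,
      chain = "X", resnum = resnum, icode = "", x = x, y = y, z = z,
      element = element)
  }
  # anchor LYS860
  add("N", "LYS", 860, 0.0, 1.4, 1.0, "N")
  add("CA", "LYS", 860, 0.0, 0.0, 0.0, "C")
  add("C", "LYS", 860, 1.4, -0.5, 0.5, "C")
  add("O", "LYS", 860, 2.4, 0.2, 0.5, "O")
  add("CB", "LYS", 860, -1.0, -0.8, -0.7, "C")
  add("NZ", "LYS", 860, -3.0, -2.0, -1.5, "N")
  for (k in seq_along(resdefs)) {
    rd <- resdefs[[k]]
    ang <- 2 * pi * (k - 1) / 8
    ox <- 10 * cos(ang); oy <- 10 * sin(ang)
    add("N", rd$name, rd$num, ox, oy, 0.0, "N")
    add("CA", rd$name, rd$num, ox + 1.46, oy, 0.0, "C")
    add("C", rd$name, rd$num, ox + 2.0, oy + 1.4, 0.0, "C")
    add("O", rd$name, rd$num, ox + 3.2, oy + 1.6, 0.0, "O")
    add("CB", rd$name, rd$num, ox + 1.9, oy - 1.0, 1.0, "C")
  }
  structure(list(atoms = do.call(rbind, rows), source = "toy"),
            class = "pdb_structure")
}

#' Generate a toy protein-ligand complex exercising one interaction rule
#'
#' The emitted geometry sits inside the corresponding detection threshold by
#' exactly `margin` Angstroms (outside every cutoff by at least `margin` for
#' motif "NONE"), making threshold-crossing behaviour directly testable.
#'
#' @param motif one of "HBOND", "PI_CATION", "HYDROPHOBIC", "NONE".
#' @param margin distance margin in Angstroms (> 0).
#' @param thresholds the threshold set the geometry is constructed against.
#' @return list: `structure` (a toy receptor), `ligand` (atom table, with a
#'   ring attribute for PI_CATION), `pocket` (15 A pocket around the anchor),
#'   `motif`, `margin`.
#' @export
gen_toy_complex <- function(motif = c("HBOND", "PI_CATION", "HYDROPHOBIC",
                                      "NONE"),
                            margin = 0.5,
                            thresholds = interaction_thresholds()) {
  motif <- match.arg(motif)
  if (margin <= 0) stop("margin must be > 0")
  s <- .toy_receptor()
  th <- thresholds
  # motif geometry points out of the receptor plane (the neighbour residues
  # all sit at z = 0, 10 A away) so exactly one typed contact can fire
  axis <- NULL
  lig <- switch(motif,
    HBOND = {
      d <- th$hbond_dist - margin
      acceptor <- c(2.4, 0.2, 0.5)  # LYS860 backbone O
      axis <- c(1, 0, 1) / sqrt(2)
      opos <- acceptor + d * axis
      l <- data.frame(element = c("O", "H"),
                      x = c(opos[1], opos[1] - axis[1]),
                      y = c(opos[2], opos[2] - axis[2]),
                      z = c(opos[3], opos[3] - axis[3]),
                      charge = 0, nH = c(1L, 0L), parent = c(NA, 1L))
      l
    },
    HYDROPHOBIC = {
      d <- th$hydrophobic_dist - margin
      cb <- c(-1.0, -0.8, -0.7)
      axis <- c(0, 0, -1)
      p <- cb + d * axis
      data.frame(element = "C", x = p[1], y = p[2], z = p[3],
                 charge = 0, nH = NA_integer_, parent = NA_integer_)
    },
    PI_CATION = {
      d <- th$pication_dist - margin
      nz <- c(-3.0, -2.0, -1.5)
      axis <- c(0, 0, -1)
      cen <- nz + d * axis
      ang <- 2 * pi * (0:5) / 6
      l <- data.frame(element = rep("C", 6),
                      x = cen[1] + 1.39 * cos(ang),
                      y = cen[2] + 1.39 * sin(ang),
                      z = cen[3] + 0 * ang,
                      charge = 0, nH = NA_integer_, parent = NA_integer_)
      attr(l, "rings") <- list(1:6)
      l
    },
    NONE = {
      axis <- c(1, 1, 1) / sqrt(3)
      data.frame(element = "C", x = 50, y = 50, z = 50 + margin,
                 charge = 0, nH = NA_integer_, parent = NA_integer_)
    })
  pocket <- define_pocket(s, "X:860", 15)
  list(structure = s, ligand = lig, pocket = pocket, motif = motif,
       margin = margin, axis = axis)
}
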