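# Cell-based stage: viability normalisation against vehicle controls, the
# three-step decision cascade with the 10 uM rescue branch, 4PL dose-response
# fitting, and relative gene-expression (2^-dCt) ranking.
#
# The cascade thresholds are strict inequalities as stated for the wet-lab
# protocol: relative-to-cisplatin viability must be < 85% to pass stage 1,
# compound-alone viability < 30% routes a compound to the 10 uM branch, and
# an inhibitor effect > 10 percentage points is required for BEST.

#' Default cascade thresholds
#' @param stage1 relative-to-cisplatin viability cut (%, strict `<`).
#' @param cytotox compound-alone viability cut (%, strict `<`).
#' @param effect inhibitor-effect cut (percentage points, strict `>`).
#' @param retest_death cell-death cut at the 10 uM retest (%, strict `>`).
#' @return named list.
#' @export
cascade_thresholds <- function(stage1 = 85, cytotox = 30, effect = 10,
                               retest_death = 50) {
  list(stage1 = stage1, cytotox = cytotox, effect = effect,
       retest_death = retest_death)
}

#' Normalize plate optical densities to percent viability
#'
#' Within each experiment, the mean OD of the vehicle wells defines 100%
#' viability; condition viabilities are per-experiment percentages averaged
#' across experiments. If an `od_ref` column is present (reference-wavelength
#' absorbance), it is subtracted from `od` before normalisation.
#'
#' @param records plate table: data.frame with columns `experiment`,
#'   `replicate`, `compound_id`, `condition` (VEHICLE, CISPLATIN_1uM,
#'   COMPOUND_ALONE, COMBINATION, COMPOUND_ALONE_10uM, COMBINATION_10uM),
#'   `concentration_uM`, `od`, optional `od_ref`.
#' @return data.frame of assay summaries, one row per compound: `compound_id`,
#'   `v_cis`, `v_alone`, `v_combo`, `v_alone_10`, `v_combo_10`,
#'   `n_experiments`.
#' @export
normalize_viability <- function(records) {
  req <- c("experiment", "compound_id", "condition", "od")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("plate table missing column(s): ",
                         paste(miss, collapse = ", "))
  od <- records$od
  if (!is.null(records$od_ref)) od <- od - records$od_ref
  if (any(!is.finite(od))) stop("non-finite OD values in plate table")
  records$net_od <- od

  exps <- unique(records$experiment)
  per_exp <- lapply(exps, function(e) {
    re <- records[records$experiment == e, , drop = FALSE]
    veh <- re$net_od[re$condition == "VEHICLE"]
    if (length(veh) == 0) stop("experiment ", e, " has no VEHICLE records")
    vmean <- mean(veh)
    if (vmean <= 0) stop("experiment ", e, " has non-positive vehicle OD")
    agg <- stats::aggregate(net_od ~ compound_id + condition, data = re, FUN = mean)
    agg$viability <- 100 * agg$net_od / vmean
    agg$experiment <- e
    agg
  })
  long <- do.call(rbind, per_exp)

  cis <- long[long$condition == "CISPLATIN_1uM", , drop = FALSE]
  v_cis_global <- if (nrow(cis) > 0) mean(cis$viability) else NA_real_

  ids <- setdiff(unique(long$compound_id), c("CONTROL", "CISPLATIN"))
  out <- do.call(rbind, lapply(ids, function(id) {
    li <- long[long$compound_id == id, , drop = FALSE]
    mv <- function(cond) {
      v <- li$viability[li$condition == cond]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    data.frame(compound_id = id,
               v_cis = v_cis_global,
               v_alone = mv("COMPOUND_ALONE"),
               v_combo = mv("COMBINATION"),
               v_alone_10 = mv("COMPOUND_ALONE_10uM"),
               v_combo_10 = mv("COMBINATION_10uM"),
               n_experiments = length(unique(li$experiment)))
  }))
  rownames(out) <- NULL
  out
}

#' Combination viability relative to cisplatin alone
#' @param v_combo combination viability (%).
#' @param v_cis cisplatin-alone viability (%); must be > 0.
#' @return `100 * v_combo / v_cis` (%).
#' @export
relative_to_cisplatin <- function(v_combo, v_cis) {
  if (any(!is.finite(v_cis)) || any(v_cis <= 0))
    stop("degenerate cisplatin control (v_cis <= 0)")
  100 * v_combo / v_cis
}

#' Inhibitor effect in percentage points
#'
#' Compound-alone viability minus combination viability; positive values mean
#' the combination kills more cells than the compound alone does, i.e. the
#' compound enhances cisplatin. This subtraction direction is the only one
#' under which the `> 10` acceptance cut selects enhancers.
#'
#' @param v_alone compound-alone viability (%).
#' @param v_combo combination viability (%).
#' @return effect in percentage points.
#' @export
inhibitor_effect <- function(v_alone, v_combo) v_alone - v_combo

#' Run the three-stage enhancement decision cascade
#'
#' Stage 1: combination viability relative to cisplatin must be < `stage1`
#' (default 85%), otherwise NO_ENHANCEMENT. Stage 2: compounds whose 50 uM
#' compound-alone viability is < `cytotox` (default 30%) are routed to the
#' reduced-concentration (10 uM) branch: there, more than `retest_death`
#' (default 50%) cell death in either 10 uM condition gives CYTOTOXIC_10uM;
#' everything else in the branch is NO_ENHANCEMENT_10uM (an `enhanced_at_10uM`
#' audit flag records the rare compound that would qualify on the 10 uM
#' numbers). Stage 3: inhibitor effect > `effect` (default 10 pp) gives BEST,
#' otherwise LOW_EFFECT. Routed compounds missing 10 uM data are UNRESOLVED,
#' never silently dropped.
#'
#' @param summaries assay summaries from [normalize_viability()] (or the
#'   packaged fixture).
#' @param thresholds from [cascade_thresholds()].
#' @return data.frame of decisions: compound_id, stage1_rel_viab, stage1_pass,
#'   cytotoxic_flag, retested, effect, enhanced_at_10uM, category.
#' @export
run_cascade <- function(summaries, thresholds = cascade_thresholds()) {
  th <- thresholds
  n <- nrow(summaries)
  out <- data.frame(compound_id = summaries$compound_id,
                    stage1_rel_viab = NA_real_, stage1_pass = FALSE,
                    cytotoxic_flag = FALSE, retested = FALSE,
                    effect = NA_real_, enhanced_at_10uM = FALSE,
                    category = NA_character_)
  for (i in seq_len(n)) {
    s <- summaries[i, ]
    rel <- relative_to_cisplatin(s$v_combo, s$v_cis)
    out$stage1_rel_viab[i] <- rel
    if (!(rel < th$stage1)) {
      out$category[i] <- "NO_ENHANCEMENT"
      next
    }
    out$stage1_pass[i] <- TRUE
    if (s$v_alone < th$cytotox) {
      out$cytotoxic_flag[i] <- TRUE
      if (is.na(s$v_alone_10) || is.na(s$v_combo_10)) {
        out$category[i] <- "UNRESOLVED"
        warning("compound ", s$compound_id,
                " routed to 10 uM branch but lacks 10 uM data")
        next
      }
      out$retested[i] <- TRUE
      death <- 100 - min(s$v_alone_10, s$v_combo_10)
      if (death > th$retest_death) {
        out$category[i] <- "CYTOTOXIC_10uM"
      } else {
        rel10 <- relative_to_cisplatin(s$v_combo_10, s$v_cis)
        eff10 <- inhibitor_effect(s$v_alone_10, s$v_combo_10)
        out$enhanced_at_10uM[i] <- (rel10 < th$stage1) && (eff10 > th$effect)
        out$category[i] <- "NO_ENHANCEMENT_10uM"
      }
      next
    }
    eff <- inhibitor_effect(s$v_alone, s$v_combo)
    out$effect[i] <- eff
    out$category[i] <- if (eff > th$effect) "BEST" else "LOW_EFFECT"
  }
  out
}

#' Tabulate cascade categories
#' @param decisions output of [run_cascade()].
#' @return named integer vector of category counts.
#' @export
cascade_counts <- function(decisions) {
  lv <- c("NO_ENHANCEMENT", "CYTOTOXIC_10uM", "NO_ENHANCEMENT_10uM",
          "BEST", "LOW_EFFECT", "UNRESOLVED")
  table(factor(decisions$category, levels = lv))
}

# --- dose-response ----------------------------------------------------------

#' Fit a four-parameter logistic concentration-response curve
#'
#' Model: `V(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`, fitted by
#' least squares on log-concentration with `bottom` constrained >= 0 and `top`
#' initialised at the vehicle level (100%). Because viabilities are
#' vehicle-normalised, the top plateau is additionally bounded by
#' `top_range` (default 50-105%: the response cannot exceed the vehicle by
#' more than assay noise), which keeps the IC50 identifiable when the assay
#' range starts above the upper plateau. By construction the predicted
#' viability at the fitted IC50 is `(top + bottom) / 2`.
#'
#' @param conc concentrations (uM, > 0).
#' @param viability percent viabilities.
#' @param top_range allowed range for the upper plateau (percent).
#' @return a `dose_response` object: list(top, bottom, ic50, hill, rss,
#'   fitted, data).
#' @export
fit_dose_response <- function(conc, viability, top_range = c(50, 105)) {
  ok <- is.finite(conc) & is.finite(viability) & conc > 0
  conc <- conc[ok]; viability <- viability[ok]
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations")
  if (stats::sd(viability) < 1e-8)
    stop("flat response: IC50 unidentifiable")
  lc <- log(conc)
  model <- function(p) {
    top <- p[1]; bottom <- p[2]; lic50 <- p[3]; hill <- p[4]
    bottom + (top - bottom) / (1 + exp(hill * (lc - lic50)))
  }
  obj <- function(p) sum((viability - model(p))^2)
  start <- c(top = min(max(max(viability), 100), top_range[2]),
             bottom = max(min(viability), 0),
             lic50 = stats::median(lc), hill = 1)
  start[2] <- min(start[2], 100)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(top_range[1], 0, min(lc) - 5, 0.1),
                      upper = c(top_range[2], 100, max(lc) + 5, 10),
                      control = list(maxit = 500))
  if (fit$convergence != 0)
    stop("4PL fit did not converge: ", fit$message)
  p <- fit$par
  structure(list(top = unname(p[1]), bottom = unname(p[2]),
                 ic50 = exp(unname(p[3])), hill = unname(p[4]),
                 rss = fit$value, fitted = model(p),
                 data = data.frame(conc = conc, viability = viability)),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("4PL fit: top %.1f%%, bottom %.1f%%, IC50 %.3g uM, hill %.2f (RSS %.1f)\n",
              x$top, x$bottom, x$ic50, x$hill, x$rss))
  invisible(x)
}

#' Predict viability from a 4PL fit
#' @param object a `dose_response`.
#' @param newdata concentrations (uM).
#' @param ... unused.
#' @export
predict.dose_response <- function(object, newdata, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (newdata / object$ic50)^object$hill)
}

# --- gene expression --------------------------------------------------------

#' Relative gene expression by the 2^-dCt method
#'
#' For each (cell line, collection), `dCt = mean Ct(gene) - mean Ct(reference)`
#' and `rel_expr = 2^-dCt`. Cell lines are ranked by mean relative expression
#' across collections.
#'
#' @param ct_table data.frame with columns `cell_line`, `gene`, `collection`,
#'   `ct`.
#' @param reference_gene reference gene symbol (default "ACTB").
#' @return list with `records` (per cell line/gene/collection rel_expr) and
#'   `ranking` (per gene: cell lines ordered by decreasing mean rel_expr).
#' @export
relative_expression <- function(ct_table, reference_gene = "ACTB") {
  req <- c("cell_line", "gene", "collection", "ct")
  miss <- setdiff(req, names(ct_table))
  if (length(miss)) stop("Ct table missing column(s): ",
                         paste(miss, collapse = ", "))
  genes <- setdiff(unique(ct_table$gene), reference_gene)
  combos <- unique(ct_table[, c("cell_line", "collection")])
  recs <- list()
  for (k in seq_len(nrow(combos))) {
    cl <- combos$cell_line[k]; co <- combos$collection[k]
    sub <- ct_table[ct_table$cell_line == cl & ct_table$collection == co, ]
    ref <- sub$ct[sub$gene == reference_gene]
    if (length(ref) == 0)
      stop("missing reference gene ", reference_gene, " for ", cl,
           " collection ", co)
    for (g in genes) {
      ct_g <- sub$ct[sub$gene == g]
      if (length(ct_g) == 0) next
      dct <- mean(ct_g) - mean(ref)
      recs[[length(recs) + 1L]] <- data.frame(
        cell_line = cl, gene = g, collection = co, dct = dct,
        rel_expr = 2^(-dct))
    }
  }
  records <- do.call(rbind, recs)
  ranking <- lapply(genes, function(g) {
    rg <- records[records$gene == g, ]
    agg <- stats::aggregate(rel_expr ~ cell_line, data = rg, FUN = mean)
    agg <- agg[order(-agg$rel_expr), ]
    rownames(agg) <- NULL
    agg
  })
  names(ranking) <- genes
  list(records = records, ranking = ranking)
}
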