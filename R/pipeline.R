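# Top-level orchestration: one configuration object, one entry point that
# chains triage -> interaction profiling -> hit calling, with per-stage
# manifests (flow conservation: in = kept + rejected at every stage) and
# byte-reproducible outputs for a fixed config and seed.

#' Pipeline run configuration
#'
#' Flat configuration; every threshold the protocol states is a named key
#' with the protocol's value as default: stage-1 cut 85%, cytotoxicity cut
#' 30%, effect cut 10 pp, 10 uM death cut 50%, score cut 90 (75 for approved
#' drugs), top-N 5000, pocket radius 15 A, 1024 fingerprint bits.
#'
#' @param scores path to a docking-score CSV, or NULL to simulate.
#' @param library path to a SMILES file, or NULL to simulate.
#' @param plates path to a plate CSV, or NULL to use the packaged fixture
#'   summaries.
#' @param out output directory (created if missing).
#' @param seed master seed; all stage seeds derive from it.
#' @param n_active,n_inactive synthetic library sizes when simulating.
#' @param top_n,score_min,max_lipinski_violations,similarity_threshold triage
#'   settings (see [triage_config()]).
#' @param stage1,cytotox,effect,retest_death cascade thresholds (see
#'   [cascade_thresholds()]).
#' @param pocket_radius pocket radius in Angstroms.
#' @param nbits fingerprint length.
#' @param run_tsne embed the chemical space (skipped when too few compounds).
#' @return a `run_config` list.
#' @export
run_config <- function(scores = NULL, library = NULL, plates = NULL,
                       out = tempfile("xpftriage_run_"), seed = 7,
                       n_active = 60, n_inactive = 240,
                       top_n = 5000, score_min = 90,
                       max_lipinski_violations = 0,
                       similarity_threshold = 0.6,
                       stage1 = 85, cytotox = 30, effect = 10,
                       retest_death = 50,
                       pocket_radius = 15, nbits = 1024L, run_tsne = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full triage + hit-calling pipeline
#'
#' Stages: (1) load or simulate the compound library and docking scores;
#' (2) rank/threshold; (3) drug-likeness and PAINS filters; (4) scaffold
#' clustering (and optional chemical-space embedding); (5) hit-calling
#' cascade on plate data or the packaged fixture. Writes TSV outputs plus a
#' JSON run report with per-stage manifests, and re-running from the same
#' config and seed reproduces the outputs byte for byte.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly also written to
#'   `<out>/report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  for (p in c(cfg$scores, cfg$library, cfg$plates))
    if (!is.null(p) && !file.exists(p))
      stop("input does not exist: ", p)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, stages = list())
  manifest <- function(stage, n_in, n_kept, n_rejected, note = "") {
    stopifnot(n_in == n_kept + n_rejected)
    report$stages[[stage]] <<- list(n_in = n_in, n_kept = n_kept,
                                    n_rejected = n_rejected, note = note)
  }

  # stage 0: library
  lib <- if (!is.null(cfg$library)) {
    l <- read_smiles_file(cfg$library)
    cbind(l, do.call(rbind, lapply(l$smiles, compute_descriptors)))
  } else {
    gen_library(library_spec(n_active = cfg$n_active,
                             n_inactive = cfg$n_inactive, seed = cfg$seed))
  }
  if (is.null(lib$stratum)) lib$stratum <- NA_character_

  scores <- if (!is.null(cfg$scores)) read_scores_csv(cfg$scores)
    else gen_scores(lib, correlation = 0.8, seed = cfg$seed + 1L)

  tcfg <- triage_config(top_n = cfg$top_n, score_min = cfg$score_min,
                        max_lipinski_violations = cfg$max_lipinski_violations,
                        similarity_threshold = cfg$similarity_threshold)

  ranked <- rank_and_cut(scores, tcfg)
  manifest("rank_and_cut", nrow(scores), nrow(ranked),
           nrow(scores) - nrow(ranked),
           sprintf("top_n=%d score_min=%g", cfg$top_n, cfg$score_min))

  pf <- apply_property_filters(ranked, lib, tcfg)
  manifest("property_filters", nrow(ranked), nrow(pf$kept), nrow(pf$rejected))
  if (nrow(pf$rejected) > 0)
    write_tsv(pf$rejected, file.path(cfg$out, "rejected.tsv"))

  shortlist <- pf$kept
  shortlist$smiles <- lib$smiles[match(shortlist$compound_id, lib$compound_id)]
  write_tsv(shortlist, file.path(cfg$out, "shortlist.tsv"))

  if (nrow(shortlist) > 0) {
    cl <- cluster_compounds(shortlist, cfg$similarity_threshold)
    write_tsv(cl, file.path(cfg$out, "clusters.tsv"))
    report$n_clusters <- max(cl$cluster_id)
  }
  if (isTRUE(cfg$run_tsne) && nrow(shortlist) >= 16) {
    fps <- fingerprint_matrix(stats::setNames(shortlist$smiles,
                                              shortlist$compound_id),
                              nbits = cfg$nbits)
    emb <- project_chemical_space(fps, seed = cfg$seed + 2L,
                                  perplexity = max(2, min(30, (nrow(fps) - 1) %/% 3)),
                                  stratum = lib$stratum[match(shortlist$compound_id,
                                                              lib$compound_id)])
    write_tsv(emb, file.path(cfg$out, "chemical_space.tsv"))
  }

  # hit calling
  summaries <- if (!is.null(cfg$plates)) {
    normalize_viability(read_plates_csv(cfg$plates))
  } else {
    build_reported_fixture()$summaries
  }
  dec <- run_cascade(summaries,
                     cascade_thresholds(cfg$stage1, cfg$cytotox, cfg$effect,
                                        cfg$retest_death))
  write_tsv(dec, file.path(cfg$out, "decisions.tsv"))
  counts <- cascade_counts(dec)
  manifest("cascade", nrow(summaries), sum(counts), 0)
  report$cascade <- as.list(counts)
  report$best_ids <- sort(dec$compound_id[dec$category == "BEST"])
  report$n_best <- length(report$best_ids)

  cfg_out <- cfg; class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out[!vapply(cfg_out, is.null, logical(1))],
                       file.path(cfg$out, "config.json"), auto_unbox = TRUE)
  jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
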