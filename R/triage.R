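# Virtual-screening post-processing: rank/threshold docking scores, property
# and PAINS filters, the anchor-residue contact requirement, two-level
# scaffold clustering, and a 2-D chemical-space projection.

#' Triage configuration
#'
#' @param top_n keep at most this many top-scoring compounds (default 5000).
#' @param score_min retain only scores strictly greater than this (default 90;
#'   75 is the convention for approved-drug collections).
#' @param max_lipinski_violations drug-likeness cut (default 0).
#' @param similarity_threshold Tanimoto threshold for merging scaffold groups
#'   (default 0.6).
#' @param contact_residue anchor residue spec for the pose filter
#'   (default Lys860 on the XPF chain, "X:860").
#' @param adjacent_residues residue numbers accepted as the anchor's
#'   neighbourhood.
#' @return named list used across the triage operations.
#' @export
triage_config <- function(top_n = 5000, score_min = 90,
                          max_lipinski_violations = 0,
                          similarity_threshold = 0.6,
                          contact_residue = "X:860",
                          adjacent_residues = c(833, 834, 837, 840, 841,
                                                856, 859, 862)) {
  stopifnot(top_n >= 1, is.finite(score_min))
  list(top_n = top_n, score_min = score_min,
       max_lipinski_violations = max_lipinski_violations,
       similarity_threshold = similarity_threshold,
       contact_residue = contact_residue,
       adjacent_residues = adjacent_residues)
}

#' Ligand efficiency of a docking score
#' @param score docking score (higher is better).
#' @param heavy_atoms heavy-atom count (>= 1).
#' @return score per heavy atom.
#' @export
ligand_efficiency <- function(score, heavy_atoms) {
  stopifnot(all(heavy_atoms >= 1))
  score / heavy_atoms
}

#' Rank docking records and apply the top-N / score cuts
#'
#' The top-N cut is applied first, then the score threshold (strictly
#' greater), matching the screening protocol's order. Records with NaN/NA
#' scores are rejected with a warning. Ties in score are broken by compound id
#' for a stable, reproducible order.
#'
#' @param records data.frame with `compound_id`, `score`.
#' @param cfg a [triage_config()].
#' @return the surviving records, sorted by decreasing score.
#' @export
rank_and_cut <- function(records, cfg = triage_config()) {
  if (is.null(records) || nrow(records) == 0) return(records)
  bad <- !is.finite(records$score)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-finite score rejected: ",
            paste(utils::head(records$compound_id[bad], 5), collapse = ", "))
    records <- records[!bad, , drop = FALSE]
  }
  records <- records[order(-records$score, records$compound_id), , drop = FALSE]
  records <- utils::head(records, cfg$top_n)
  records <- records[records$score > cfg$score_min, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Apply drug-likeness and PAINS filters to score survivors
#'
#' Each rejected compound is labelled with the first failed rule
#' (`LIPINSKI:<n>` or `PAINS:<pattern-id>`); kept plus rejected partitions the
#' input exactly.
#'
#' @param survivors data.frame with `compound_id` (and optionally `score`).
#' @param descriptors data.frame keyed by `compound_id` with descriptor
#'   columns including `lipinski_violations` and `smiles`.
#' @param cfg a [triage_config()].
#' @param patterns PAINS pattern set (default: packaged).
#' @return list(kept, rejected) where rejected carries a `reason` column.
#' @export
apply_property_filters <- function(survivors, descriptors,
                                   cfg = triage_config(),
                                   patterns = load_patterns()) {
  if (is.null(survivors) || nrow(survivors) == 0) {
    rej <- survivors
    if (!is.null(rej)) rej$reason <- character(0)
    return(list(kept = survivors, rejected = rej))
  }
  idx <- match(survivors$compound_id, descriptors$compound_id)
  if (anyNA(idx))
    stop("missing descriptors for compound(s): ",
         paste(survivors$compound_id[is.na(idx)], collapse = ", "))
  de <- descriptors[idx, , drop = FALSE]
  reason <- rep(NA_character_, nrow(survivors))
  over <- de$lipinski_violations > cfg$max_lipinski_violations
  reason[over] <- paste0("LIPINSKI:", de$lipinski_violations[over])
  todo <- which(is.na(reason))
  if (length(todo) > 0) {
    pf <- pains_filter(data.frame(id = survivors$compound_id[todo],
                                  smiles = de$smiles[todo]), patterns)
    if (nrow(pf$flagged) > 0) {
      hit <- match(pf$flagged$id, survivors$compound_id)
      reason[hit] <- paste0("PAINS:", pf$flagged$pattern_id)
    }
  }
  rejected <- survivors[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  kept <- survivors[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL; rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Keep compounds whose pose contacts the anchor residue or its neighbours
#'
#' A compound passes when it has at least one typed interaction (any type)
#' with the anchor residue or a residue in the adjacency set.
#'
#' @param poses named list: compound_id -> ligand atom table (see
#'   [detect_interactions()]).
#' @param s the receptor `pdb_structure`.
#' @param pocket a `pocket`.
#' @param cfg a [triage_config()] providing the anchor spec and adjacency set.
#' @param thresholds interaction thresholds.
#' @return character vector of compound ids kept.
#' @export
require_contact <- function(poses, s, pocket, cfg = triage_config(),
                            thresholds = interaction_thresholds()) {
  if (length(poses) == 0) return(character(0))
  anchor <- .parse_residue_spec(cfg$contact_residue)
  at <- s$atoms[s$atoms$record == "ATOM", , drop = FALSE]
  if (!any(at$chain == anchor$chain & at$resnum == anchor$resnum))
    stop("anchor residue ", cfg$contact_residue, " absent from structure")
  accept_nums <- c(anchor$resnum, cfg$adjacent_residues)
  kept <- character(0)
  for (id in names(poses)) {
    recs <- detect_interactions(s, poses[[id]], pocket, id, thresholds)
    if (nrow(recs) > 0 &&
        any(recs$chain == anchor$chain & recs$resnum %in% accept_nums))
      kept <- c(kept, id)
  }
  kept
}

#' Cluster compounds by Murcko scaffold, then merge similar scaffold groups
#'
#' Two-level scheme: compounds sharing an identical scaffold always share a
#' cluster; scaffold groups whose representative fingerprints reach the
#' Tanimoto threshold are then merged by single linkage. Acyclic molecules
#' (empty scaffold) form a dedicated no-scaffold cluster that never merges.
#' Clusters are numbered densely from 1, largest first.
#'
#' @param compounds data.frame with `id` (or `compound_id`) and `smiles`.
#' @param similarity_threshold Tanimoto merge threshold (default 0.6);
#'   at 1.0 only identical-scaffold groups remain together.
#' @return data.frame: compound_id, cluster_id, scaffold.
#' @export
cluster_compounds <- function(compounds, similarity_threshold = 0.6) {
  id_col <- if ("compound_id" %in% names(compounds)) "compound_id" else "id"
  ids <- compounds[[id_col]]
  scaff <- vapply(compounds$smiles, murcko_scaffold, character(1),
                  USE.NAMES = FALSE)
  uniq <- unique(scaff)
  grp <- match(scaff, uniq)

  # single-linkage merge of non-empty scaffold groups on scaffold fingerprints
  nonempty <- which(nzchar(uniq))
  parent <- seq_along(uniq)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(nonempty) > 1 && similarity_threshold < 1) {
    fps <- lapply(uniq[nonempty], morgan_fingerprint)
    for (i in seq_along(nonempty)) {
      for (j in seq_len(i - 1L)) {
        if (tanimoto(fps[[i]], fps[[j]]) >= similarity_threshold) {
          ri <- find(nonempty[i]); rj <- find(nonempty[j])
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(grp, find, integer(1))
  # dense ids, largest cluster first; ties broken by first scaffold string
  sizes <- table(root)
  ord <- order(-as.integer(sizes), uniq[as.integer(names(sizes))])
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- data.frame(compound_id = ids,
                    cluster_id = as.integer(relabel[as.character(root)]),
                    scaffold = scaff)
  out[order(out$cluster_id, out$compound_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Project fingerprints to 2-D chemical space (exact t-SNE)
#'
#' A compact exact t-SNE (perplexity-calibrated Gaussian affinities, gradient
#' descent with momentum and early exaggeration) suitable for the library
#' sizes this pipeline handles (hundreds of compounds). Deterministic for a
#' fixed seed and input order.
#'
#' @param fps fingerprint matrix (compounds x bits), e.g. from
#'   [fingerprint_matrix()].
#' @param seed integer seed for the embedding initialisation.
#' @param perplexity t-SNE perplexity (default 30, lowered automatically is
#'   NOT done: fewer than `3 * perplexity + 1` points is an error instructing
#'   to lower it).
#' @param n_iter gradient-descent iterations (default 400).
#' @param stratum optional per-compound labels carried through to the output.
#' @return data.frame: compound_id, x, y, stratum.
#' @export
project_chemical_space <- function(fps, seed, perplexity = 30, n_iter = 400,
                                   stratum = NULL) {
  n <- nrow(fps)
  if (n < 5) stop("need at least 5 compounds to embed")
  if (n - 1 < 3 * perplexity)
    stop("too few points for perplexity ", perplexity,
         "; lower the perplexity (need n > 3*perplexity)")
  ids <- rownames(fps)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # pairwise Jaccard distances on bits
  m <- as.matrix(fps)
  inter <- tcrossprod(m)
  pop <- rowSums(m)
  un <- outer(pop, pop, `+`) - inter
  d2 <- (1 - ifelse(un > 0, inter / un, 1))^2

  # binary-search per-point precisions to the target perplexity
  p <- matrix(0, n, n)
  logu <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-12) { h <- 0 } else {
        pr <- w / sw
        h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      if (abs(h - logu) < 1e-5) break
      if (h > logu) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    p[i, -i] <- if (sum(w) > 1e-12) w / sum(w) else 1 / (n - 1)
  }
  P <- (p + t(p)) / (2 * n)
  P <- pmax(P, 1e-12)

  # deterministic MDS initialisation (plus seeded jitter to break exact
  # degeneracies): duplicates start coincident and stay together
  set.seed(seed)
  y0 <- suppressWarnings(stats::cmdscale(stats::as.dist(sqrt(d2)), k = 2))
  if (is.null(dim(y0)) || ncol(y0) < 2)
    y0 <- matrix(0, n, 2)
  sc <- stats::sd(as.numeric(y0))
  if (sc > 0) y0 <- y0 / sc
  y <- y0 * 1e-4 + matrix(stats::rnorm(n * 2, sd = 1e-6), n, 2)
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  momentum <- 0.5; eta <- 50
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100) 4 else 1
    sumy <- rowSums(y^2)
    num <- 1 / (1 + outer(sumy, sumy, `+`) - 2 * tcrossprod(y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - eta * gain * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
    if (iter == 200) momentum <- 0.8
  }
  data.frame(compound_id = ids, x = y[, 1], y = y[, 2],
             stratum = if (is.null(stratum)) NA_character_ else stratum)
}
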