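test_that("rank_and_cut matches a brute-force oracle and handles edge cases", {
  set.seed(11)
  rec <- data.frame(compound_id = sprintf("C%03d", 1:100),
                    score = round(stats::runif(100, 50, 120), 3))
  cfg <- triage_config(top_n = 50, score_min = unname(stats::quantile(rec$score, 0.6)))
  got <- rank_and_cut(rec, cfg)
  # independent oracle: plain sort + filter
  oracle <- rec[order(-rec$score, rec$compound_id), ]
  oracle <- head(oracle, 50)
  oracle <- oracle[oracle$score > cfg$score_min, ]
  expect_identical(got$compound_id, oracle$compound_id)
  expect_equal(nrow(got), 40)

  # top-n then threshold, simple cases
  r10 <- data.frame(compound_id = letters[1:10], score = 1:10)
  expect_equal(rank_and_cut(r10, triage_config(top_n = 5, score_min = 0))$score,
               c(10, 9, 8, 7, 6))
  expect_equal(nrow(rank_and_cut(r10, triage_config(top_n = 10, score_min = 99))), 0)
  # NaN rejection with warning
  r10$score[3] <- NaN
  expect_warning(out <- rank_and_cut(r10, triage_config(top_n = 10, score_min = 0)),
                 "non-finite")
  expect_equal(nrow(out), 9)
  # stable tie order by id
  ties <- data.frame(compound_id = c("b", "a", "c"), score = c(5, 5, 5))
  expect_identical(rank_and_cut(ties, triage_config(top_n = 3, score_min = 0))$compound_id,
                   c("a", "b", "c"))
})

test_that("tightening thresholds never grows the surviving set", {
  set.seed(12)
  rec <- data.frame(compound_id = sprintf("C%03d", 1:200),
                    score = stats::rnorm(200, 90, 15))
  n_prev <- Inf
  for (smin in c(70, 80, 90, 100)) {
    n <- nrow(rank_and_cut(rec, triage_config(top_n = 150, score_min = smin)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (tn in c(200, 100, 50, 10)) {
    n <- nrow(rank_and_cut(rec, triage_config(top_n = tn, score_min = 80)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("property filters partition input and give machine-readable reasons", {
  desc <- rbind(
    cbind(compound_id = "good", smiles = "CC(=O)Nc1ccc(O)cc1",
          compute_descriptors("CC(=O)Nc1ccc(O)cc1")),
    cbind(compound_id = "fat", smiles = "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",
          compute_descriptors("CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC")),
    cbind(compound_id = "pains", smiles = "O=C1C=CC(=O)C=C1",
          compute_descriptors("O=C1C=CC(=O)C=C1")))
  surv <- data.frame(compound_id = c("good", "fat", "pains"),
                     score = c(95, 96, 97))
  res <- apply_property_filters(surv, desc, triage_config())
  expect_setequal(c(res$kept$compound_id, res$rejected$compound_id),
                  surv$compound_id)
  expect_identical(res$kept$compound_id, "good")
  expect_match(res$rejected$reason[res$rejected$compound_id == "fat"],
               "^LIPINSKI:")
  expect_match(res$rejected$reason[res$rejected$compound_id == "pains"],
               "^PAINS:quinone_para$")
  expect_error(apply_property_filters(
    data.frame(compound_id = "ghost", score = 1), desc), "ghost")
  res0 <- apply_property_filters(surv[0, ], desc)
  expect_equal(nrow(res0$kept), 0)
  expect_equal(nrow(res0$rejected), 0)
})

test_that("scaffold clustering groups identical scaffolds, largest first", {
  five <- data.frame(id = sprintf("m%d", 1:5),
                     smiles = rep("Cc1ccccc1", 5))
  cl <- cluster_compounds(five)
  expect_equal(unique(cl$cluster_id), 1L)
  expect_equal(nrow(cl), 5)

  # toluene + ethylbenzene share the benzene scaffold; cyclohexane is apart
  trio <- data.frame(id = c("tol", "eb", "chx"),
                     smiles = c("Cc1ccccc1", "CCc1ccccc1", "CC1CCCCC1"))
  cl <- cluster_compounds(trio, similarity_threshold = 1)
  expect_equal(cl$cluster_id[cl$compound_id == "tol"],
               cl$cluster_id[cl$compound_id == "eb"])
  expect_false(cl$cluster_id[cl$compound_id == "chx"] ==
                 cl$cluster_id[cl$compound_id == "tol"])
  # cluster 1 is the most populated
  expect_equal(sum(cl$cluster_id == 1), 2)
  # all-distinct scaffolds at threshold 1 -> singletons
  distinct <- data.frame(id = c("a", "b", "c"),
                         smiles = c("c1ccccc1", "c1ccncc1", "C1CCCC1"))
  cld <- cluster_compounds(distinct, similarity_threshold = 1)
  expect_equal(sort(table(cld$cluster_id)), sort(table(1:3)), ignore_attr = TRUE)
  # acyclic molecules share the dedicated no-scaffold cluster
  mix <- data.frame(id = c("a", "b", "r"),
                    smiles = c("CCC", "CCO", "c1ccccc1"))
  clm <- cluster_compounds(mix)
  expect_equal(clm$cluster_id[clm$compound_id == "a"],
               clm$cluster_id[clm$compound_id == "b"])
})

test_that("chemical-space projection is deterministic and separates strata", {
  # two strata on disjoint bit blocks
  set.seed(5)
  n <- 40
  fps <- matrix(0L, n, 64)
  for (i in 1:n) {
    block <- if (i <= n / 2) 1:24 else 41:64
    fps[i, sample(block, 12)] <- 1L
  }
  rownames(fps) <- sprintf("c%02d", 1:n)
  e1 <- project_chemical_space(fps, seed = 9, perplexity = 8, n_iter = 300)
  e2 <- project_chemical_space(fps, seed = 9, perplexity = 8, n_iter = 300)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), n)

  xy <- as.matrix(e1[, c("x", "y")])
  d <- as.matrix(dist(xy))
  within <- c(d[1:20, 1:20][upper.tri(diag(20))],
              d[21:40, 21:40][upper.tri(diag(20))])
  between <- d[1:20, 21:40]
  expect_gt(mean(between), mean(within))

  # duplicated compounds land (essentially) on top of each other
  fps2 <- rbind(fps, fps[1, , drop = FALSE])
  rownames(fps2) <- c(rownames(fps), "dup")
  e3 <- project_chemical_space(fps2, seed = 9, perplexity = 8, n_iter = 300)
  ddup <- sqrt(sum((e3[e3$compound_id == "dup", c("x", "y")] -
                    e3[e3$compound_id == "c01", c("x", "y")])^2))
  alld <- as.matrix(dist(as.matrix(e3[, c("x", "y")])))
  expect_lt(ddup, stats::quantile(alld[alld > 0], 0.01))

  expect_error(project_chemical_space(fps[1:10, ], seed = 1, perplexity = 30),
               "perplexity")
})

test_that("require_contact keeps anchored poses and drops distant ones", {
  near <- gen_toy_complex("HBOND", margin = 0.5)
  far <- gen_toy_complex("NONE", margin = 0.5)
  kept <- require_contact(list(hit = near$ligand, miss = far$ligand),
                          near$structure, near$pocket)
  expect_identical(kept, "hit")
  expect_identical(require_contact(list(), near$structure, near$pocket),
                   character(0))
  expect_error(require_contact(list(a = near$ligand), near$structure,
                               near$pocket,
                               triage_config(contact_residue = "Z:999")),
               "absent")
})

test_that("ligand efficiency is score per heavy atom", {
  expect_equal(ligand_efficiency(90, 30), 3)
  expect_error(ligand_efficiency(90, 0))
})
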