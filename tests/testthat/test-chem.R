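test_that("descriptors match hand-derived values", {
  # benzene: 6 C (12.011) + 6 H (1.008) = 78.114 g/mol, no heteroatoms
  b <- compute_descriptors("c1ccccc1")
  expect_equal(b$mw, 78.114, tolerance = 1e-6)
  expect_equal(b$heavy_atoms, 6)
  expect_equal(b$hbd, 0)
  expect_equal(b$hba, 0)
  expect_equal(b$rotatable_bonds, 0)
  # aspirin: C9H8O4 = 9*12.011 + 8*1.008 + 4*15.999 = 180.159; one O-H donor
  a <- compute_descriptors("CC(=O)Oc1ccccc1C(=O)O")
  expect_equal(a$mw, 180.159, tolerance = 1e-6)
  expect_equal(a$hbd, 1)
  expect_equal(a$hba, 4)   # N+O count
  expect_equal(a$heavy_atoms, 13)
})

test_that("descriptors are deterministic across SMILES spellings", {
  pairs <- list(c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"),
                c("c1ccccc1", "C1=CC=CC=C1"),
                c("CCO", "OCC"))
  for (p in pairs) {
    d1 <- compute_descriptors(p[1]); d2 <- compute_descriptors(p[2])
    expect_equal(d1, d2, ignore_attr = TRUE)
    expect_identical(as.integer(morgan_fingerprint(p[1])),
                     as.integer(morgan_fingerprint(p[2])))
  }
})

test_that("lipinski violation counting covers all breach combinations", {
  d <- data.frame(mw = c(300, 600, 501, 500), logp = c(2, 6, 5.01, 5),
                  hbd = c(2, 2, 6, 5), hba = c(5, 5, 11, 10))
  expect_identical(lipinski_violations(d), c(0L, 2L, 4L, 0L))
  # monotone: worsening any one property never decreases the count
  base <- data.frame(mw = 400, logp = 4, hbd = 4, hba = 8)
  v0 <- lipinski_violations(base)
  for (col in names(base)) {
    worse <- base
    worse[[col]] <- worse[[col]] * 2
    expect_gte(lipinski_violations(worse), v0)
  }
})

test_that("fingerprints are non-empty and radius-sensitive", {
  fp <- morgan_fingerprint("CCO")
  expect_s3_class(fp, "fingerprint")
  expect_length(fp, 1024)
  expect_gt(sum(fp), 0)
  fp0 <- morgan_fingerprint("CCCCO", radius = 0)
  fp2 <- morgan_fingerprint("CCCCO", radius = 2)
  expect_gt(sum(fp2), sum(fp0))
})

test_that("tanimoto obeys its contract", {
  mk <- function(idx, n = 8) { v <- integer(n); v[idx] <- 1L; v }
  # {1,2,3} vs {3,4}: 1 shared of 4 in the union
  expect_equal(tanimoto(mk(1:3), mk(3:4)), 0.25)
  expect_equal(tanimoto(mk(1:3), mk(1:3)), 1.0)
  expect_equal(tanimoto(mk(integer(0)), mk(integer(0))), 1.0)
  expect_error(tanimoto(mk(1, 8), mk(1, 16)), "mismatch")
  # symmetry + bounds on random pairs
  set.seed(42)
  for (i in 1:20) {
    x <- sample(0:1, 64, replace = TRUE)
    y <- sample(0:1, 64, replace = TRUE)
    t1 <- tanimoto(x, y)
    expect_identical(t1, tanimoto(y, x))
    expect_gte(t1, 0); expect_lte(t1, 1)
  }
})

test_that("murcko scaffolds strip side chains and are idempotent", {
  benzene <- canonical_smiles("c1ccccc1")
  expect_identical(murcko_scaffold("c1ccccc1"), benzene)
  expect_identical(murcko_scaffold("Cc1ccccc1"), benzene)      # toluene
  expect_identical(murcko_scaffold("CCc1ccccc1"), benzene)     # ethylbenzene
  expect_identical(murcko_scaffold("CCC"), "")                 # acyclic
  # idempotence on a variety of molecules
  for (s in c("CC(=O)Oc1ccccc1C(=O)O", "O=C(Nc1ccccc1)c1ccccc1",
              "c1ccc2ccccc2c1", "OCC1CCCCC1")) {
    sc <- murcko_scaffold(s)
    expect_identical(murcko_scaffold(sc), sc, label = s)
  }
  # linker carbonyls survive, terminal acyls do not
  expect_identical(murcko_scaffold("CC(=O)c1ccccc1"), benzene)
  expect_true(grepl("=O", murcko_scaffold("O=C(Nc1ccccc1)c1ccccc1")))
})

test_that("pains_filter partitions exhaustively and labels patterns", {
  pats <- load_patterns()
  cmp <- data.frame(
    id = c("quinone", "clean1", "catechol", "clean2"),
    smiles = c("O=C1C=CC(=O)C=C1", "c1ccccc1", "Oc1ccccc1O",
               "CC(=O)Nc1ccc(O)cc1"))
  res <- pains_filter(cmp, pats)
  expect_setequal(c(res$kept$id, res$flagged$id), cmp$id)
  expect_length(intersect(res$kept$id, res$flagged$id), 0)
  expect_setequal(res$flagged$id, c("quinone", "catechol"))
  expect_identical(res$flagged$pattern_id[res$flagged$id == "quinone"],
                   "quinone_para")
  # empty input
  res0 <- pains_filter(cmp[0, ], pats)
  expect_equal(nrow(res0$kept), 0)
  expect_equal(nrow(res0$flagged), 0)
})

test_that("malformed pattern files fail at load with the pattern id", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("ok\tc1ccccc1", "broken\tC1CC"), tf)
  expect_error(load_patterns(tf), "broken")
})

test_that("substructure matching respects aromaticity and bond order", {
  expect_true(has_substructure("Cc1ccccc1", "c1ccccc1"))
  expect_false(has_substructure("C1CCCCC1", "c1ccccc1"))
  expect_true(has_substructure("CC(=O)OC", "C=O"))
  expect_false(has_substructure("CCOC", "C=O"))
})
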