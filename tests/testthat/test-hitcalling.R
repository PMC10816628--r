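make_plate <- function(...) do.call(rbind, list(...))
well <- function(exp, rep, id, cond, od, conc = 50) {
  data.frame(experiment = exp, replicate = rep, compound_id = id,
             condition = cond, concentration_uM = conc, od = od)
}

test_that("viability normalisation uses per-experiment vehicle means", {
  plate <- make_plate(
    well(1, 1, "CONTROL", "VEHICLE", 1.0),
    well(1, 2, "CONTROL", "VEHICLE", 1.0),
    well(1, 1, "CISPLATIN", "CISPLATIN_1uM", 0.875, 1),
    well(1, 1, "cpd", "COMPOUND_ALONE", 0.8),
    well(1, 2, "cpd", "COMPOUND_ALONE", 0.9),
    well(1, 3, "cpd", "COMPOUND_ALONE", 1.0),
    well(1, 1, "cpd", "COMBINATION", 0.45))
  s <- normalize_viability(plate)
  expect_equal(s$v_alone, 90)          # (0.8+0.9+1.0)/3 over vehicle 1.0
  expect_equal(s$v_combo, 45)
  expect_equal(s$v_cis, 87.5)
  # od equal to vehicle -> 100%; zero od -> 0%
  p2 <- make_plate(well(1, 1, "CONTROL", "VEHICLE", 0.8),
                   well(1, 1, "x", "COMPOUND_ALONE", 0.8),
                   well(1, 1, "y", "COMPOUND_ALONE", 0))
  s2 <- normalize_viability(p2)
  expect_equal(s2$v_alone[s2$compound_id == "x"], 100)
  expect_equal(s2$v_alone[s2$compound_id == "y"], 0)
})

test_that("normalisation is scale-invariant and needs vehicles", {
  plate <- make_plate(well(1, 1, "CONTROL", "VEHICLE", 1.1),
                      well(1, 1, "cpd", "COMPOUND_ALONE", 0.7),
                      well(2, 1, "CONTROL", "VEHICLE", 0.9),
                      well(2, 1, "cpd", "COMPOUND_ALONE", 0.6))
  s1 <- normalize_viability(plate)
  plate2 <- plate
  plate2$od[plate2$experiment == 2] <- plate2$od[plate2$experiment == 2] * 3.7
  s2 <- normalize_viability(plate2)
  expect_equal(s1$v_alone, s2$v_alone)

  no_veh <- plate[plate$condition != "VEHICLE", ]
  expect_error(normalize_viability(no_veh), "VEHICLE")
  # reference wavelength subtracted when present
  plate$od_ref <- 0.05
  s3 <- normalize_viability(plate)
  expect_equal(s3$v_alone, mean(c(100 * 0.65 / 1.05, 100 * 0.55 / 0.85)))
})

test_that("stage-1 and effect arithmetic match the worked examples", {
  expect_equal(relative_to_cisplatin(70, 88), 100 * 70 / 88)  # 79.5 -> pass
  expect_lt(relative_to_cisplatin(70, 88), 85)
  expect_gt(relative_to_cisplatin(75, 88), 85)                # 85.2 -> fail
  expect_error(relative_to_cisplatin(50, 0), "degenerate")
  expect_equal(inhibitor_effect(75, 60), 15)
  expect_equal(inhibitor_effect(60, 60), 0)
  expect_equal(inhibitor_effect(55, 45), 10)  # boundary: strict > means fail
})

test_that("the cascade assigns exactly one category per compound", {
  mk <- function(id, v_alone, v_combo, v10a = NA, v10c = NA)
    data.frame(compound_id = id, v_cis = 87.5, v_alone = v_alone,
               v_combo = v_combo, v_alone_10 = v10a, v_combo_10 = v10c,
               n_experiments = 2)
  sums <- rbind(
    mk("noenh", 85, 87.5),        # rel 100
    mk("best", 70, 45),           # rel 51, effect 25
    mk("low", 68, 65),            # effect 3
    mk("cyto", 20, 15, 25, 20),   # 10 uM death 80 > 50
    mk("routed", 20, 15, 80, 80), # 10 uM survives, no enhancement
    mk("lost", 20, 15))           # routed but no 10 uM data
  expect_warning(dec <- run_cascade(sums), "lacks 10 uM")
  expect_identical(dec$category,
                   c("NO_ENHANCEMENT", "BEST", "LOW_EFFECT", "CYTOTOXIC_10uM",
                     "NO_ENHANCEMENT_10uM", "UNRESOLVED"))
  expect_equal(sum(cascade_counts(dec)), nrow(sums))
  # boundary: rel exactly 85 fails stage 1 (strict <)
  b <- mk("edge", 70, 0.85 * 87.5)
  expect_identical(run_cascade(b)$category, "NO_ENHANCEMENT")
  # all-identical with v_combo = v_cis -> all NO_ENHANCEMENT
  same <- do.call(rbind, lapply(1:5, function(i) mk(paste0("s", i), 90, 87.5)))
  expect_true(all(run_cascade(same)$category == "NO_ENHANCEMENT"))
})

test_that("threshold monotonicity holds across the cascade", {
  fx <- fixture_summaries()
  n_s1 <- function(th) sum(run_cascade(fx, cascade_thresholds(stage1 = th))$stage1_pass)
  expect_lte(n_s1(85), n_s1(90))
  n_best <- function(eff) sum(run_cascade(fx, cascade_thresholds(effect = eff))$category == "BEST")
  expect_gte(n_best(10), n_best(20))
})

test_that("4PL fitting recovers noiseless parameters exactly", {
  conc <- c(0.3, 1, 2, 5, 10, 20, 50, 100)
  v <- 0 + (100 - 0) / (1 + (conc / 5)^1)
  fit <- fit_dose_response(conc, v)
  expect_equal(fit$ic50, 5, tolerance = 1e-5)
  expect_equal(fit$top, 100, tolerance = 1e-4)
  expect_equal(fit$bottom, 0, tolerance = 1e-3)
  # algebraic identity: predicted viability at IC50 is the midpoint
  expect_equal(predict(fit, fit$ic50), (fit$top + fit$bottom) / 2,
               tolerance = 1e-6)
  expect_error(fit_dose_response(c(1, 2, 3), c(90, 50, 10)), "4 distinct")
  expect_error(fit_dose_response(conc, rep(50, 8)), "flat")
})

test_that("4PL recovery from the plate simulator stays within 15%", {
  curve <- gen_cisplatin_curve(seed = 77)
  fit <- fit_dose_response(curve$conc, curve$viability)
  expect_lt(abs(fit$ic50 - attr(curve, "ic50")) / attr(curve, "ic50"), 0.15)
})

test_that("relative expression follows 2^-dCt and ranks H1299 first for ERCC1", {
  ct <- data.frame(cell_line = rep("L1", 3), gene = c("ACTB", "G1", "G2"),
                   collection = 1, ct = c(20, 20, 23))
  res <- relative_expression(ct)
  expect_equal(res$records$rel_expr[res$records$gene == "G1"], 1.0)
  expect_equal(res$records$rel_expr[res$records$gene == "G2"], 0.125)
  expect_error(relative_expression(ct[ct$gene != "ACTB", ]), "reference")

  panel <- gen_ct_table(seed = 4)
  rr <- relative_expression(panel)
  expect_identical(rr$ranking$ERCC1$cell_line[1], "H1299")
  expect_identical(rr$ranking$ERCC1$cell_line[2], "A549")
})
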