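# xpftriage

Virtual-screening triage and cisplatin-enhancement hit calling for
ERCC1–XPF inhibitor discovery.

## The scientific problem

The ERCC1–XPF endonuclease excises cisplatin–DNA adducts in nucleotide
excision repair; NSCLC tumours that overexpress *ERCC1* resist platinum
therapy. Inhibitors that block the ERCC1–XPF dimerisation pocket (the
hydrophobic XPF cavity that receives Phe293 of ERCC1) should re-sensitise
such tumours to cisplatin. Finding them means (a) triaging millions of
docked compounds down to an acquisition shortlist and (b) triaging the
acquired compounds through combination-viability assays into a defensible
list of cisplatin enhancers. `xpftriage` implements both layers as tested R
code, with synthetic generators standing in for the docking engine and the
wet lab.

At its core are a handful of standard statistics and rules:

* **Triage:** top-*N* and score cuts on ChemPLP-like docking scores; ligand
  efficiency `LE = score / heavy atoms`; Lipinski's rule of five; PAINS
  substructure flags; Murcko scaffold clustering merged by Tanimoto
  similarity `T(A,B) = |A∩B| / |A∪B|` over 1024-bit Morgan fingerprints;
  t-SNE chemical-space maps.
* **Structure:** Kabsch superposition; pocket membership within 15 Å of a
  centre residue; buried interface area
  `(SASA_a + SASA_b − SASA_ab)/2` by Shrake–Rupley sampling; geometric
  interaction typing (H-bond ≤ 4.1 Å, hydrophobic ≤ 4.0 Å, π-cation ≤ 6.0 Å,
  π-stacking ≤ 5.5 Å, salt bridge ≤ 5.5 Å, halogen ≤ 4.0 Å).
* **Hit calling:** vehicle-normalised viability; a three-stage cascade
  (relative-to-cisplatin < 85% → compound-alone < 30% routes to a 10 µM
  retest → inhibitor effect `v_alone − v_combo` > 10 pp ⇒ BEST); 4PL
  dose–response `V(c) = bottom + (top−bottom)/(1+(c/IC50)^hill)`; qPCR
  `2^−ΔCt` expression ranking.

See `vignettes/triage-methods.Rmd` for the full methods account.

## Worked example

Run the packaged acquisition-and-cascade fixture through the decision
cascade:

```r
library(xpftriage)
fx  <- build_reported_fixture()       # 106 acquired, 4 excluded, 102 evaluated
dec <- run_cascade(fx$summaries)   # thresholds: 85% / 30% / 10 pp / 50%
cascade_counts(dec)
#>      NO_ENHANCEMENT      CYTOTOXIC_10uM NO_ENHANCEMENT_10uM                BEST
#>                  46                   5                  18                  22
#>          LOW_EFFECT          UNRESOLVED
#>                  11                   0
sort(dec$compound_id[dec$category == "BEST"])
#> CB1, CB18, CB23, CB25, CB27, CB36, CB39, CB40, CB47, CB48, CB50, CB53,
#> CB57, CB60, CB64, DB7, NCI11, NCI12, NCI18, NCI27, NCI31, NCI33
```

Reading: of 102 evaluated compounds, 46 fail the enhancement screen, 23 are
routed to the reduced-concentration branch (5 stay cytotoxic at 10 µM,
18 show no enhancement there), and of the 33 reaching the inhibitor-effect
decision, 22 are BEST cisplatin enhancers.

Dose–response fitting on the packaged cisplatin simulation (true IC50
3.0 µM, 1–30 µM, 6 replicates, 5 pp noise):

```r
curve <- gen_cisplatin_curve(seed = 42)
fit_dose_response(curve$conc, curve$viability)
#> 4PL fit: top 97.0%, bottom 3.5%, IC50 3.01 uM, hill 1.60 (RSS 1573.2)
```

A small end-to-end computational triage on synthetic data:

```r
lib  <- gen_library(library_spec(n_active = 20, n_inactive = 60, seed = 7))
sc   <- gen_scores(lib, correlation = 0.8, seed = 8)
surv <- rank_and_cut(sc, triage_config(top_n = 50, score_min = 75))
pf   <- apply_property_filters(surv, lib, triage_config(score_min = 75))
#> 41 ranked survivors -> 37 kept, 4 rejected (each with a LIPINSKI:/PAINS: reason)
```

Or the whole pipeline in one call (`run_pipeline(run_config(...))`), which
writes `shortlist.tsv`, `clusters.tsv`, `decisions.tsv`, per-stage manifests
and a JSON report. A thin CLI wraps the same calls:
`Rscript inst/cli/xpftriage.R run-all --seed 7 --out outdir/`.

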