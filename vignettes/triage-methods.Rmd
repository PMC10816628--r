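---
title: "Methods: virtual-screening triage and cisplatin-enhancement hit calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-screening triage and cisplatin-enhancement hit calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpftriage)
```

## The problem this package addresses

The ERCC1–XPF heterodimer is the structure-specific endonuclease of
nucleotide excision repair (NER), the pathway that removes bulky DNA adducts
such as cisplatin lesions. Tumours that overexpress ERCC1 repair
cisplatin-induced damage efficiently and respond poorly to platinum therapy,
which makes the ERCC1–XPF protein–protein interface — anchored by the
insertion of ERCC1's Phe293 into a hydrophobic XPF pocket — an attractive
drug target: block the dimerisation pocket and cisplatin becomes more
effective.

Discovering such inhibitors by structure-based virtual screening produces
very long ranked lists (millions of docked compounds) that must be triaged
down to an affordable acquisition set, and the acquired compounds must then
be triaged again through cell-based assays into a defensible hit list. This
package implements both triage layers as tested, reproducible code, with
synthetic-data generators standing in for the two components that cannot be
re-run offline: the commercial docking engine and the wet-lab plates.

## The computational triage

**Score cuts.** Docking scores (ChemPLP-like, higher is better) are first cut
to the top 5,000 per database and then thresholded at score > 90 (75 for
approved-drug collections, whose members are smaller and score lower), in
that order. Ties are broken by compound id so output order is reproducible.
Ligand efficiency (score per heavy atom) de-biases the size advantage of
large molecules.

**Drug-likeness and PAINS.** Surviving compounds need descriptors inside the
drug-like box (0 Lipinski violations by default) and no assay-interference
(PAINS) substructure. Each rejection carries the first failed rule
(`LIPINSKI:<n>` or `PAINS:<pattern-id>`), so the audit trail always satisfies
`in = kept + rejected`. The shipped pattern file covers the classic
interference motifs (quinones, catechol, aryl-azo, rhodanine,
phenol-hydrazone, thiourea, isothiazolone, 2-aminophenol) expressed as plain
substructure fragments; full SMARTS logic (wildcards, recursive environments)
is deliberately out of scope, and the pattern file format keeps patterns
reviewable one per line.

**Anchor-residue contact.** A pose is only acquirable if it forms at least
one typed interaction with Lys860 of XPF or its pocket neighbourhood
(default adjacency set: Tyr833, Asn834, Pro837, Phe840, Leu841, Met856,
Val859, Ile862 — the residues that line the Phe293 pocket). The adjacency
set is configurable because "adjacent" is not defined more precisely by the
protocol this reproduces.

**Scaffold clustering.** The protocol combines Murcko scaffold identity with
Tanimoto similarity without naming an algorithm. We use a deterministic
two-level scheme: compounds sharing an identical Murcko scaffold always share
a cluster; scaffold groups whose representative Morgan fingerprints reach a
Tanimoto threshold (default 0.6) are then merged by single linkage. Clusters
are renumbered densely, largest first, so "cluster 1" is always the most
populated. Acyclic molecules have an empty scaffold and form a dedicated
no-scaffold cluster that never merges.

**Chemical-space map.** Compound diversity is visualised by embedding the
1024-bit fingerprints into 2-D with an exact t-SNE (no approximate tree
code): per-point Gaussian affinities calibrated to the target perplexity by
binary search, early exaggeration for 100 iterations, adaptive gains, and a
learning rate of 50 — small enough to be stable at the library sizes this
package handles (tens to hundreds of compounds). Initialisation is classical
MDS of the Jaccard distances plus a seeded jitter of 1e-6, which makes the
embedding deterministic for a fixed seed and keeps duplicated compounds
coincident.

## The chemistry core

There is no cheminformatics toolkit in the supported R environment, so the
2D machinery is implemented natively and kept deliberately small:

* **SMILES** — organic subset plus bracket atoms (charge, explicit H),
  aromatic lowercase, ring closures, dot-separated components.
  Stereochemistry is parsed and discarded: every operation here is a function
  of 2D constitution. Kekulé-written rings are aromatised by a pragmatic
  Hückel rule (5–7-membered rings, all members sp² or lone-pair heteroatoms,
  4n+2 π electrons), so `C1=CC=CC=C1` and `c1ccccc1` yield the same graph.
* **Descriptors** — rule-of-five conventions: HBA is the N+O count, HBD the
  N–H/O–H hydrogen count. LogP is a reduced atom-contribution (Crippen-style)
  estimate; the protocol's own descriptor sources don't state their LogP
  conventions either, so small numeric drift against published histograms is
  expected and the method is recorded in the output metadata.
* **Fingerprints** — circular (Morgan/ECFP-style) environments hashed from
  graph invariants, radius 2 and 1024 bits by default (the common ECFP4
  setting; the radius is not stated by the protocol, the bit count is).
  Because hashing starts from graph invariants, any SMILES spelling of a
  molecule gives the same bits. Tanimoto of two all-zero fingerprints is
  defined as 1.0 to preserve the identity invariant.
* **Murcko scaffolds** — iterative terminal-atom pruning leaves rings plus
  linkers; atoms multiply bonded to the retained frame (amide oxygens of
  linkers) are restored. The scaffold of a scaffold is itself.

## The cell-based decision cascade

Viability plates are normalised per experiment against vehicle wells
(vehicle = 100% by construction), then averaged across experiments. The
cascade applies three strict inequalities, exactly as the wet-lab protocol
states them — boundary values fail:

1. **Enhancement screen.** Combination viability relative to cisplatin alone
   must be < 85%. At 1 µM, cisplatin alone leaves ~85–90% of H1299 cells
   viable, so this threshold demands at least ~15% extra kill from the
   combination. Failures are `NO_ENHANCEMENT`.
2. **Cytotoxicity routing.** Compounds that alone (50 µM) leave < 30%
   viability are too toxic to interpret; they are not discarded but retested
   at 10 µM. There, > 50% cell death in either condition gives
   `CYTOTOXIC_10uM`; everything else in the branch is `NO_ENHANCEMENT_10uM`
   (an `enhanced_at_10uM` audit flag records the hypothetical compound that
   would qualify on its 10 µM numbers; none does in the packaged fixture).
   Routed compounds missing 10 µM data become `UNRESOLVED`, never silently
   dropped.
3. **Inhibitor effect.** Compound-alone minus combination viability must be
   > 10 percentage points for `BEST`, else `LOW_EFFECT`. The subtraction
   direction (alone − combination, positive = enhancement) is the only
   reading under which a "greater than 10%" cut selects enhancers; the
   source sentence is grammatically ambiguous, so the convention is stated
   here rather than assumed silently.

Stage 1 gates on pooled means, not per-replicate tests: the protocol's
analysis-of-variance annotations are display-level, and the decision rules it
states are purely arithmetic.

**Dose-response.** IC50s come from a least-squares 4PL fit on
log-concentration, `V(c) = bottom + (top − bottom)/(1 + (c/IC50)^hill)`, with
`bottom ≥ 0` and the top plateau bounded to 50–105%. The bound is the
normalized-response convention: viabilities are scaled so vehicle ≡ 100%, so
the upper plateau cannot exceed 100% by more than assay noise. It matters
here because the assay range (1–30 µM against an IC50 near 3 µM) never
samples the upper plateau; with a fully free top the IC50 is weakly
identified (median recovery error just over 10% in simulation), with the
bound it recovers to ~9.5% median error at 5 pp replicate noise.

**Gene expression.** Cell-line choice is driven by `2^-ΔCt` relative
expression with ΔCt = mean Ct(gene) − mean Ct(β-actin), ranked across
independent RNA collections.

## What the synthetic generators emulate — and what they do not

* `gen_library()` assembles diaryl amide/sulfonamide compounds whose active
  stratum is rejection-sampled into the descriptor box reported for known
  inhibitors (MW 200–400 g/mol, 2–3 HBD, ≥ 4 HBA, LogP 1–3, 0 Lipinski
  violations). It emulates the *descriptor profile* of that reference set,
  not its actual chemistry: the fragment grammar is narrow, so the library's
  scaffold diversity is far below a real vendor catalogue. A green test on
  this library establishes bookkeeping and invariants, not enrichment on real
  chemistry.
* `gen_scores()` draws ChemPLP-like scores whose stratum/score rank
  correlation is calibrated by deterministic bisection to the requested value
  — it stands in for the docking engine's output distribution, not for
  docking physics.
* `gen_plates()` writes well ODs as
  `vehicle_od · viability/100 · (1 + N(0, sd))` with 5 pp replicate noise,
  3 replicates × 2 experiments, and cisplatin wells at 87.5% viability (the
  midpoint of the stated 85–90% band).
* `gen_toy_complex()` builds a minimal receptor (the anchor lysine at the
  origin, the eight pocket neighbours 10 Å away, beyond every cutoff) and
  places ligand geometry exactly `margin` Å inside the requested interaction
  threshold, making rule flips at the documented cutoffs directly testable.
* `build_reported_fixture()` encodes the published bookkeeping: 106 acquired
  compounds, 4 exclusions, and per-compound viabilities synthesised with
  ≥ 5 pp margins from every threshold so the cascade reproduces each printed
  aggregate (46 discarded, 23 routed, 33 remaining, 22 BEST with the printed
  id list, 5 cytotoxic at 10 µM). Individual viabilities for unnamed
  compounds are *not* public — they exist only as bar charts — so unnamed
  compounds are assigned to categories deterministically in natural id order
  within their database's printed aggregate. The fixture is bookkeeping
  ground truth, not biological ground truth.

## Structural analysis

PDB parsing covers the ATOM/HETATM/TER subset with residue identity
(chain, number, insertion code) preserved as deposited. Superposition is the
Kabsch algorithm (SVD with reflection correction), tested to 1e-8 against an
independent quaternion-method oracle. Pockets are defined by an
any-atom-within-radius rule around a centre residue (default 15 Å, the
docking-site radius). Buried interface area is
`(SASA(a) + SASA(b) − SASA(ab))/2` with Shrake–Rupley sphere sampling
(golden-spiral points, 960/atom default, standard van der Waals radii);
sampling error against the closed-form two-sphere result is under 2% at the
default density.

Interaction typing is a pure function of geometry with profiler-conventional
cutoffs: H-bond donor–acceptor ≤ 4.1 Å (donor angle ≥ 100° when hydrogens
are present, distance-only and flagged `angle_waived` otherwise), hydrophobic
C···C ≤ 4.0 Å between apolar carbons, π-stacking centroid ≤ 5.5 Å with
parallel (< 30°) and T-shaped (60–90°) windows, π-cation ≤ 6.0 Å,
salt bridge ≤ 5.5 Å between charged-group centroids, halogen ≤ 4.0 Å,
water-bridge legs ≤ 4.1 Å. All are configurable through
`interaction_thresholds()` and logged with the records. Protein apolar
carbons are identified by a per-residue exclusion table (side-chain carbons
bonded to N/O/S by topology are excluded) since the receptor graph is not
re-derived from coordinates.

## Numerical and degenerate-input choices

* Strict inequalities at every cascade threshold; fixture viabilities keep
  ≥ 5 pp margins so float noise cannot flip a category.
* Tanimoto(∅, ∅) = 1; fingerprint length mismatches are errors, not
  recycling.
* `rank_and_cut` rejects NaN scores with a warning; empty inputs flow
  through every stage as empty outputs.
* Clustering ties (equal cluster sizes) break on the scaffold string;
  cluster ids are dense from 1.
* t-SNE refuses to run with fewer than `3 × perplexity + 1` points and tells
  the caller to lower the perplexity instead of silently adjusting it.
* Degenerate superposition inputs (collinear points, size mismatch) and
  missing pocket centres are errors with the offending selection named.
* A missing vehicle well, a zero cisplatin control, or a routed compound
  without 10 µM data each produce a named error/flag rather than a silent
  number.

## Known limitations

* The SMILES dialect covers the organic subset + brackets; exotic elements,
  isotope-specific logic and stereochemistry are out of scope (stereo is
  discarded by design — everything downstream is 2D).
* Aromaticity perception handles common 5–7-ring systems; unusual
  kekulisations of fused polycycles may stay in Kekulé form (both spellings
  of every molecule the package generates or ships are covered by tests).
* The PAINS set is a curated subset in a restricted pattern language, not the
  full published catalogue.
* LogP is a coarse estimator; descriptor-box membership is therefore
  internally consistent (the generator and the filter share the estimator)
  but not comparable to MOE/FAF-Drugs values at high precision.
* The structural stage profiles *given* poses; it does not dock, minimise, or
  predict protonation states.
* The optional external benchmark (pocket membership and ~280 Å² interface
  area on the deposited 1Z00 structure) needs a network download and is not
  part of the offline test suite; the geometric machinery it would exercise
  is covered by in-repo oracles instead.
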