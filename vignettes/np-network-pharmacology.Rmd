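---
title: "Profiling natural-product libraries and their drug-target networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling natural-product libraries and their drug-target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npnet)
```

`npnet` turns a common but usually ad-hoc workflow — profile a compound
library, map its chemical space, build its drug–target network, predict
indications — into one tested pipeline. This vignette is the package's own
account of the models it implements, the parameters that matter, what the
synthetic generators do and do not emulate, and the design decisions taken
where conventions genuinely diverge.

## Structures, keys and normalization

Molecules enter as SMILES (one record per line) or V2000 SDF and are
immediately canonicalized through Open Babel. Two normalization steps
mirror standard library curation:

* **Largest fragment.** Salts and adducts are reduced to the connected
  component with the most heavy atoms; ties go to the larger molecular
  weight, then to the lexicographically smallest canonical string, so the
  outcome never depends on input order.
* **Deduplication.** The structure key is the *canonical isomeric SMILES*.
  A stereo-aware InChIKey would serve equally well, but the Open Babel
  InChI path discards SMILES tetrahedral annotations (both alanine
  enantiomers collapse onto one key), while its canonical SMILES keeps
  them. Since the only requirement on the key is that it be canonical and
  collision-safe — dedup must merge rewritings of one structure and keep
  enantiomers apart — the canonical SMILES is used. The first record in
  input order wins, making curation reproducible.

## The descriptor panel

Eight descriptors form the profiling and chemical-space panel, in fixed
order: AlogP, molecular weight, rotatable bonds, rings, aromatic rings,
hydrogen-bond acceptors, donors, and fractional polar surface area
(`DESCRIPTOR_COLS`). Conventions, chosen once and documented so that
differences from commercial descriptor engines are expected rather than
bugs:

* **HBA / HBD** use Lipinski's original counts — acceptors are all N and O
  atoms, donors are all hydrogens on N or O — because the panel feeds a
  Rule-of-Five filter and that rule was calibrated on these counts.
  Pharmacophore-style definitions (which, e.g., discount ester oxygens)
  give systematically lower counts.
* **AlogP** is the additive atom-contribution (Wildman–Crippen) estimate
  as implemented in Open Babel. Fixture tests assert agreement with
  measured logP within one log unit on hand-checked molecules, not
  bit-parity with any particular engine.
* **Rotatable bonds**: non-ring single bonds between non-terminal heavy
  atoms, excluding amide C–N bonds. Ring membership is decided by a bridge
  test on the heavy-atom graph.
* **Rings** is the SSSR count, computed exactly as the cyclomatic number
  (bonds − atoms + components) of the heavy-atom graph; **aromatic rings**
  is the same quantity on the subgraph of aromatic bonds, with aromaticity
  as perceived by Open Babel. Acyclic "aromatic-typed" bonds (carboxylate
  resonance) contribute nothing by construction.
* **FPSA** divides the topological polar surface area by a topological
  estimate of total surface area: TPSA plus a flat 21 Å² per apolar heavy
  atom. This is deliberately crude — FPSA is only a PCA input, never an
  acceptance surface, and any monotone surface proxy preserves what the
  PCA needs.
* **F-chirality** is the number of *assigned* tetrahedral carbon
  stereocenters divided by total carbons. Unassigned centers are not
  guessed: curated libraries are expected to carry explicit
  stereochemistry, and counting potential centers would inflate the
  fraction for poorly annotated entries. Carbon-free molecules return
  `NA` with a warning, the fraction being undefined.

## Rule-of-Five profiling

All four comparisons are strict (`<`), so a molecule at exactly 500 Da
fails the weight criterion. `library_summary()` reports the conventional
category table: `all_satisfied`, four `except_X` categories (the other
three criteria satisfied, X ignored — hence every `except_X` is at least
`all_satisfied`), and `at_least_three`.

## Chemical space

`fit_pca()` performs mean-centered covariance PCA **without scaling** by
default, the convention for descriptor-space maps of compound libraries.
The consequence is worth stating plainly: molecular weight, whose variance
(≈ 266² Da²) dwarfs every other column, dominates PC1, and on synthetic
data with independent marginals PC1 carries > 99 % of the variance. Real,
strongly correlated descriptor tables spread variance more evenly, which
is why published three-component maps report far less extreme fractions.
A `scale = TRUE` switch is provided; with it a constant column is an
error. Each component's sign is fixed so its largest-magnitude loading is
positive, making output stable across eigensolvers. Two libraries can be
fit jointly or separately; the package defaults to separate models (each
library summarized in its own frame) with `pca_project()` available to put
one library into the other's space.

Overlap between two score clouds is the fraction of each cloud inside the
axis-aligned 1st–99th-percentile bounding box of the other. A convex hull
was considered and rejected: in three dimensions with heavy-tailed
descriptor distributions the hull is controlled by a handful of outliers,
while the percentile box is robust and has a transparent self-overlap
baseline (≈ 94–98 % of a cloud lies inside its own trimmed box).

## Drug-target networks

Interaction tables carry positive, higher-is-better scores (a pKd-like
scale for experimental data; docking engines whose energies are negative
must be sign-flipped upstream — the admissibility cutoffs below only make
sense on a positive scale). Duplicate (compound, target) rows are
collapsed to their best score before anything else.

**Admissibility.** For docking data an edge enters the network only if its
score strictly exceeds (i) the chosen cutoff and (ii) the docking score of
the target's own co-crystallized reference ligand. The double rule
embodies the screening logic that a hit should both bind well in absolute
terms and out-dock the ligand the structure was solved with. The package
uses 7 as the permissive screening cutoff (hit-rate reporting) and 9 as
the stringent network-building cutoff.

**Topology and centrality.** Degree, normalized Brandes betweenness
(divisor `(N−1)(N−2)/2`, computed on the full graph so disconnected pairs
contribute zero), connected components with a deterministic tie-break
(equal-sized components ordered by their smallest node id), mean shortest
path over *connected* pairs only (published tables report finite values
for fragmented networks), and density by the general-graph convention
`2E/(N(N−1))` over both partitions — the bipartite-specific `E/(n_c n_t)`
does **not** reproduce published density values, while the general formula
does, which settles the convention. The identity `density = mean degree /
(N−1)` and the edge-count identity `targets-per-compound × n_compounds =
hits-per-target × n_targets` are exposed as `implied_density()` /
`implied_hits_per_target()` and verified against the published summary
table bundled as `dtn_reference_stats`.

**Scale-free fit.** `fit_power_law()` regresses log10 frequency on log10
degree over degrees with nonzero frequency, returning `a = 10^intercept`,
the signed exponent, and the Pearson correlation of the log–log points.
This histogram-OLS estimator is what network-pharmacology papers
conventionally report (maximum-likelihood estimators give different
numbers); it needs at least three distinct degrees. By default callers
choose which degrees to fit; the analysis drivers fit compound degrees,
where the generator's truth lives, and the acceptance script fits all
nodes of the synthetic network.

**Hubs and bottlenecks** are compounds ranked by degree (ties broken by
betweenness, then id) and by betweenness (ties by degree, then id),
respectively.

## Indication prediction

The docking-score-weighted model scores a (compound, disease) pair as the
sum of the compound's admissible docking scores over the disease's
targets:

$$C(c,d) = \sum_{t \in T(d)} s(c,t)\,\big[\,s(c,t) > \theta \;\wedge\;
s(c,t) > r_t\,\big]$$

This functional form is a **reconstruction**: published applications of
docking-score-weighted indication ranking report only coefficients, not
the formula. The plain sum is adopted because it is the simplest model
that is (a) docking-score-weighted, (b) additive over disjoint target
sets, (c) monotone under added admissible edges, and (d) of the right
magnitude — published coefficients around 50–60 match roughly six
supporting targets at scores near 9–10 each, exactly what an unnormalized
sum produces. Normalizing by target count or adding disease priors would
break (d). Zero-coefficient pairs are omitted; ties order by compound id,
then disease.

## The synthetic generators

The generators produce inputs with the statistical structure the analysis
assumes, so every stage runs and is testable without external databases.
All are pure functions of a `generator_config()`: each draws from
`withr::with_seed()` on a fixed offset of the config seed, so outputs are
byte-identical across calls and the caller's RNG state is untouched.

* **Descriptor tables** draw each column independently from a
  moment-matched marginal at the published natural-product (or
  approved-drug) means and SDs: normal for AlogP (it spans negative
  values), log-normal for molecular weight (positive, right-skewed),
  negative binomial for counts (published SDs exceed the means — Poisson
  is substituted automatically in the one drug-column case where they do
  not), and a beta for FPSA (bounded). Moment matching makes the
  "sample mean within 3 standard errors" property exact rather than
  approximate. What is *not* emulated: the strong covariance among real
  descriptors. Joint statistics (Rule-of-Five compliance above all) are
  therefore conservative — independent marginals give ≈ 25 % full
  compliance where correlated real data give ≈ 50 % — and tests assert
  marginal, not joint, behavior.
* **Interaction networks** draw compound degrees from a truncated discrete
  power law with exponent 1.125 on 1..`degree_max` and attach each
  compound to that many distinct targets with Zipf-weighted preferential
  sampling (`target_weight_exponent = 1`), which produces target-side hubs
  without parallel edges. `degree_max = 8` puts the mean at ≈ 2.7 targets
  per compound, matching the published multi-target breadth (2.1–2.7);
  the truncation also keeps every histogram bin well populated, which is
  what lets the log–log OLS fit recover the exponent within ±0.15 at
  2000 compounds. Because attachment is sampling without replacement, no
  degree sequence is infeasible once `degree_max ≤ n_targets`, which the
  config enforces.
* **Docking scores** give each compound `pairs_per_compound = 5`
  background scores (truncated normal, mean 5, sd 1.5 — a sparse
  per-compound score report) and plant one strong binder
  (uniform on 9–11) for a 10 % fraction of compounds. Reference-ligand
  scores are normal (mean 7, sd 1) capped at 8.8, i.e. strictly below the
  planted range, so planted binders are admissible at the stringent
  cutoff *by construction* and recovery is a real end-to-end test, not a
  coin flip. Consequences worth knowing: the stringent hit rate lands
  1–2 points above the planted fraction (background scores occasionally
  clear both bars), and the stringent network is an archipelago of
  planted singleton links rather than the richly connected giant
  component a real campaign yields.
* **Disease maps** link each disease to 1–8 targets and give one
  designated compound planted admissible edges to *all* targets of one
  designated disease (forced to hold at least three). Its coefficient,
  ≈ 10 per supporting target, dominates every background association,
  which is what makes "planted indication ranks first" a sharp
  recovery criterion.
* **Molecule fixtures** pair named natural products (staurosporine,
  quercetin, genistein) with standard controls and normalization cases;
  truth values are hand-counted from the published structures.

## Numerical choices and degenerate inputs

* Empty libraries, empty edge tables, carbon-free molecules, constant
  columns under scaling, fewer than three distinct degrees, and missing
  reference scores are all hard errors with named offenders — never
  silent coercions.
* Betweenness on graphs with fewer than three nodes is defined as zero
  (the normalization divisor vanishes).
* Tie-breaks are deterministic everywhere randomness could leak in:
  fragment choice, duplicate retention, component ordering, hub and
  prediction rankings.
* Tables are written with headers, stable column order and six
  significant digits.

## Scale of the shipped analyses

The analysis drivers and test suite run the generators at the study's
native scale where it matters (2884 × 243 docking campaigns, 10 000-row
descriptor tables, ten-seed recovery sweeps) and at toy scale where only
logic is exercised; the full suite completes in well under a minute.
Exact betweenness is cross-checked against a walk-count oracle on graphs
of up to 12 nodes, where exhaustive enumeration is trivially correct.

## Known limitations

* Descriptor values depend on Open Babel's perception (aromaticity,
  protonation as written); they match standard conventions, not any
  commercial engine bit-for-bit.
* 3D structure generation, conformer energies and actual docking are out
  of scope; the pipeline consumes score tables.
* The indication model's functional form is a documented reconstruction
  (see above), and the synthetic generators emulate marginal statistics,
  not the full joint structure of real libraries — passing tests certify
  the pipeline's correctness, not distributional realism of every joint
  feature.
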