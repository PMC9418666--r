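---
title: "From docking poses to pharmacology: methods behind aifp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From docking poses to pharmacology: methods behind aifp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aifp)
```

## The problem

Ligands of the beta-2 adrenoceptor (a Gs-coupled GPCR) divide into agonists,
which activate the receptor, and antagonists (including inverse agonists),
which occupy the orthosteric pocket without activating it. Both classes bind
the same pocket, and most share the beta-hydroxy-amine scaffold, so simple
physicochemical descriptors separate them poorly. The hypothesis this
package operationalises is that pharmacology is encoded in *which atomic
contacts* a ligand makes: docking a large ligand set into the receptor,
typing every receptor-atom/ligand-atom contact, and learning which typed
contacts discriminate the classes yields both a classifier and an
interpretable map of agonist- and antagonist-associated interaction hot
spots.

The pipeline has six stages, each its own module: structure ingestion and
atom-role annotation, geometric contact typing (the atomic interaction
fingerprint, AIF), anchor-based pose filtering, binary matrix encoding,
correlation- and tree-ensemble-based classification with a disciplined
evaluation protocol, and Shapley attribution of the fitted models.

## Contact typing

Every receptor-ligand heavy-atom pair within a 5.0 Å neighbour cutoff is
assigned at most one of fifteen interaction subtypes. Rules combine the
chemical roles of the two atoms (donor, acceptor, cation, anion, aromatic,
hydrophobe, halogen, carbonyl carbon/oxygen), the interatomic distance, and
angle criteria where the literature demands them. The full default table
lives in one editable object:

```{r}
str(unclass(geometry_rules()), give.attr = FALSE)
```

All thresholds are overridable (`geometry_rules(hydrogen_bond_max = 3.2)`,
or from YAML via `read_geometry_rules()`). Defaults follow the conventions
of published structural-interaction-fingerprint tools: hydrogen bonds at
donor-acceptor ≤ 3.5 Å with a D-H···A angle ≥ 120°, ionic contacts at
≤ 4.0 Å between opposite formal charges, halogen bonds at ≤ 4.0 Å with
C-X···A ≥ 140°, aromatic contacts between ring atoms whose ring centroids
lie within 5.0 Å, hydrophobic carbon-carbon contacts at ≤ 4.5 Å, and
clash/covalent/van-der-Waals bands derived from element radii.

Three choices deserve explanation:

* **One type per pair.** Types are tested in a fixed most-specific-first
  precedence (clash > covalent > vdw_clash > ionic > hydrogen_bond >
  halogen_bond > weak_hydrogen_bond > metal_complex > aromatic > carbonyl >
  polar > weak_polar > hydrophobic > vdw > proximal) and the first match
  wins. This keeps the downstream binary matrix unambiguous: a pair is never
  simultaneously "ionic" and "polar".
* **Polar is role-based, not orientation-based.** A pair of polar atoms
  (each a donor or acceptor) within 3.5 Å that does not qualify as a
  hydrogen bond — wrong geometry, or a non-complementary acceptor-acceptor
  pair — is recorded as polar, and as weak_polar out to 4.0 Å. This mirrors
  the taxonomy of the fingerprint tools this package emulates and makes
  every subtype reachable by a deterministic geometric construction, which
  the synthetic module exploits.
* **Hydrogens are optional.** Docking outputs frequently omit hydrogens, so
  every angle criterion has a heavy-atom surrogate (bonded-neighbour-D-A
  ≥ 90° for hydrogen bonds); when even the surrogate geometry is missing the
  rule degrades to its distance criterion and the fingerprint computation
  warns once. The enumeration radius also caps every per-type distance, so
  shrinking `neighbor_cutoff` below a type's maximum simply truncates that
  rule.

Records are deduplicated on (residue number, receptor atom name, ligand
element, type), keeping the shortest distance: the ligand atom is identified
by its element only, which is what makes fingerprints comparable across
ligands of different scaffolds.

## Pose filtering

Nearly all beta-2 adrenoceptor ligands anchor their protonated amine to
D113 and their amine/beta-hydroxyl to the side-chain oxygen of N312; these
contacts appear in every crystallographic complex. `filter_criteria()`
therefore demands (1) an ionic, polar or hydrogen-bond contact between
residue 113 (OD1 or OD2) and a ligand nitrogen, and (2) a hydrogen-bond or
polar contact between residue 312 OD1 and a ligand nitrogen or oxygen.
Poses lacking either anchor are discarded as docking artefacts. Two
deliberately open points are exposed as configuration rather than decided
silently: whether the D113 contact must be strictly ionic (the default
accepts polar and hydrogen bond too, the inclusive reading of the source
conventions), and whether ND2 of N312 may substitute for OD1 (not by
default — "the oxygen" is read literally — but `anchor2_atoms` accepts
both).

## Matrix, frequency filter, splits

`build_matrix()` encodes fingerprints as a binary pose × feature matrix
with feature keys `"<residue>/<receptorAtom>—<ligandElement> <type>"`.
Absent contacts are zeros (never missing), clash / vdw_clash / proximal
contacts are excluded (they are abundant but carry essentially no
pharmacological information), and every pose row inherits its ligand's
label. `frequency_filter()` keeps features present in at least 10% of poses
— rare contacts cannot support stable statistics at this dataset scale.

`split_holdout()` reserves a stratified 20% hold-out that no training or
tuning step ever touches. The default split unit is the *ligand*: poses of
one compound are near-duplicates, and letting them straddle the split
boundary would leak information and flatter every score. A pose-level mode
is retained for fidelity with protocols that split rows directly; the
package default is the leakage-safe one.

## The correlation arm

`pointwise_correlation()` computes the Pearson correlation r between each
binary feature column and the binary label, with antagonist as the positive
class; for two binary variables this is exactly the phi coefficient of the
2×2 table, and the suite verifies that identity exhaustively on all small
tables. Zero-variance features are reported as undefined (NA), never as a
fabricated zero.

The correlation *classifier* scores a pose as the sum of training r values
over its present features and thresholds the score. How per-feature
correlations become a per-pose decision is genuinely under-determined in
this family of methods; the sum-of-r score is the simplest linear reading
and is stated here prominently as a package decision (a mean-score variant
would only rescale the cutoff grid). The cutoff is chosen on training data
only, scanning midpoints between adjacent sorted unique scores and
maximising training MCC, ties toward the smaller cutoff. An alternative
reading — that the reference cutoff applies to |r| for feature *inclusion*
rather than to the score — cannot be excluded; neither interpretation is
asserted as the original one, and the scanned-cutoff classifier is the one
evaluated throughout.

## Evaluation protocol

The Matthews correlation coefficient is the headline metric because the
classes are imbalanced (~75% agonists): MCC weights both classes equally
and only rewards genuinely informative predictions. The implementation
evaluates the closed formula exactly, returning 0 when a denominator factor
vanishes (the undefined-correlation convention; the formula's limit is not
defined there and 0 is the standard neutral choice).

`repeated_stratified_kfold()` runs k-fold cross-validation (default k = 10,
configurable — the fold count is a protocol choice, not a derived quantity)
with class-stratified folds, repeated (default 13 repeats) to average out
partition noise; with ligand grouping the fold unit is again the ligand.
`bootstrap_ci()` wraps percentile bootstrap intervals over the fold scores
(default 99% level); resampling fold scores rather than samples is the
package's reading of an unstated choice, recorded here. The number of
repeats needed for a target precision follows n = ⌈z²σ²/δ²⌉ with z the
two-sided normal quantile — at σ = 0.02, δ = 0.01 and 99% confidence,
n = 27:

```{r}
estimate_repeats(sigma = 0.02, delta = 0.01, confidence = 0.99)
```

Two tree-ensemble families are built in, with defaults equal to the
reference configurations: a random forest (Gini criterion, 2000 trees,
depth 5, 5 features per split; fitted with ranger, whose
`num.trees`/`max.depth`/`mtry`/`splitrule` map those settings directly) for
the anchor-filtered arm, and gradient-boosted trees (gamma 0.2458, max
delta step 7, max depth 8, min child weight 1.246, 1150 rounds, subsample
0.7532; xgboost) for the full arm. The boosted-tree table records both
"eta 0.4306" and "learning rate 0.05873" although they alias the same
xgboost parameter; this package stores both verbatim and honours the
learning-rate entry when fitting (the name the scikit-learn-style API
resolves), an ambiguity flagged rather than hidden.
`hyperparameter_search()` optimises mean CV MCC over a bounded space using
a Latin-hypercube design — at the budgets practical here a space-filling
sampler is an honest stand-in for Bayesian optimisation with an identical
objective and selection contract; the family defaults are always evaluated
first so the search can never return something worse than them on its own
objective.

## Shapley attribution

Two independent routes compute Shapley values, and their agreement is a
standing test:

* `exact_shapley()` enumerates every feature subset and applies the
  defining weighted-marginal sum; cost 2^M, capped at 15 features. Absent
  features are marginalised *interventionally*: the value of a coalition S
  is the mean model output over hybrids taking the sample's values on S and
  a background row's values elsewhere. The efficiency, symmetry and dummy
  axioms hold by construction and are asserted on constructed games.
* `tree_shapley()` computes the same quantity in polynomial time from the
  tree structure. For one (sample, background) pair, each leaf is reached
  exactly when the coalition contains all features where only the sample
  satisfies the path (the set A) and none where only the background does
  (the set D); that indicator game has closed-form Shapley values
  ((|A|−1)!|D|!/(|A|+|D|)! for members of A, minus |A|!(|D|−1)!/(|A|+|D|)!
  for members of D), so a single recursive descent per tree accumulates
  exact attributions, averaged over the background. The kernel is in C++;
  trees are extracted from xgboost dumps and ranger `treeInfo()`.

Because the two routes share nothing beyond the fitted model, their
agreement (max |difference| below 1e-6 on 12-feature models in the suite)
validates both. Attribution units follow the model family: log-odds margin
for boosted trees, positive-class probability for random forests, recorded
in the result object. Boosted-tree predictions accumulate in single
precision, so local-accuracy comparisons against the model's own margin are
asserted at 1e-5 rather than machine tolerance. The background set is a
package decision (the method family leaves it unstated): a seeded subsample
of the training matrix, size ~10-20 — with binary features a modest
background already averages over the relevant off-coalition patterns.
`global_importance()` ranks features by mean |φ| and summarises whether a
feature's *presence* pushes toward antagonist or agonist.

## What the synthetic data emulates — and what it does not

Real inputs (receptor PDB, multi-pose SDF, label CSV) are expensive to
produce, so the package generates both layers of its own test bed.

**Toy complexes** (`generate_toy_complex()`): a sparse open shell of twelve
probe residues (Asp113, Asn312, Ser203/207, Gln301, Asn293, Gly315 backbone,
Phe193 backbone, Val114/118, Met82, Phe290 and Trp286 rings) on icosahedral
directions 8 Å from a central ligand scaffold. Planting an interaction
places the matching ligand partner (ammonium nitrogen, hydroxyl or carbonyl
oxygen, chlorine, alkyl carbon, benzene ring) radially inward of its probe
at a distance drawn from the window in which the rule table yields exactly
the requested type; all supporting atoms sit behind their probes, so no
unplanned pair enters the 5 Å cutoff — a property the generator re-verifies
on every call and enforces with an error. This makes the typer's ground
truth analytic: the suite demands *exact* recovery, and pushes each planted
pair 0.2 Å past its threshold to confirm removal or retyping. The geometry
is deliberately not a folded protein — bond lengths to the scaffold are
unphysical and residues are disconnected — because only local probe-partner
geometry reaches the typer. Consequences of this simplification: the toys
cannot exercise crowded-pocket effects (competing partners inside one
cutoff sphere), solvent, or conformational strain, so passing the toy suite
shows rule-table correctness, not docking realism.

**Planted-signal matrices** (`generate_matrix()`): the study conditions are
the defaults — 500 ligands × 10 poses, 75% agonists, 5 signal + 95 noise
features, and a correct-pose fraction of 0.1, reflecting that only about
one docking solution in ten corresponds to the experimentally observed
binding mode. Signal features appear with probability 0.9 in correct poses
of their associated class and 0.05 elsewhere; noise features have per-
feature base rates drawn once from \[0.05, 0.40\], independent of class.
The two presence probabilities are package choices (chosen once as a
strong-but-noisy contrast a docking study could plausibly deliver);
everything else restates the study's stated structure. What this generator
does *not* emulate: feature correlations (real contacts co-occur
geometrically), pose-to-pose similarity within a ligand, and label noise —
so measured performance on it is an upper bound on real-data behaviour, and
the suite treats it as a recovery benchmark, not a performance claim.

Under the default conditions the pose-level class signal is intentionally
dilute: nine of ten poses are uninformative, which caps pose-level
classification near MCC ≈ 0.2 no matter the model. The correlation
*ranking* still recovers the planted features there (signal |r| ≈ 0.1-0.15
against noise |r| ≈ 0.015). The classifier and Shapley benchmarks therefore
run on the correct-pose variant (`correct_pose_fraction = 1`, all 95 noise
features retained) — precisely the population the anchor filter is designed
to deliver, and the regime in which a high-MCC bound is a meaningful test
of the learning machinery rather than of the dilution arithmetic.

**Anchor-fingerprint sets** (`simulate_anchor_aifs()`) provide thousands of
lightweight fingerprints with a controlled motif fraction for filter
statistics, and `generate_toy_dataset()` writes a complete small study
(shared receptor PDB, multi-record SDF, labels CSV) through the real file
writers so the pipeline is exercised end to end from disk.

## Numerical choices and degenerate inputs

* Tie-breaks: threshold-classifier cutoff ties resolve toward the smaller
  cutoff; ligand-level majority votes at exactly half resolve toward the
  positive (antagonist) class; feature rankings break |r| and mean-|φ| ties
  alphabetically by key for determinism.
* Degenerate inputs error loudly rather than guess: empty confusion
  matrices, single-class training data, classes smaller than k, constant
  scores (flagged `degenerate`), unknown residue templates (warn + element
  fallback), missing labels (error listing ligand ids).
* All randomness flows through per-call integer seeds; every generator is
  byte-reproducible under a fixed seed, and fitted models are deterministic
  given (data, spec, seed) with single-threaded fitting.
* Problem sizes in the shipped suite are chosen for desk-scale runtimes:
  the exhaustive MCC sweep covers all confusion matrices with ≤ 20 samples,
  the phi sweep all 2×2 tables with margins ≤ 12, the typer suite 100
  seeded complexes, the filter benchmark 2000 fingerprints, the recovery
  benchmark the full 500 × 10 default study, and the permutation null 199
  (correlation) / 40 (boosted-tree) label shuffles on a 150-ligand study.

## Known limitations

* The fifteen-subtype taxonomy names follow the conventional fingerprint
  vocabulary; the upstream method never enumerates its subtypes by name, so
  exact numerical replication of any specific tool's output is a non-goal.
* Metal complexes and covalent contacts are typed but not plantable in the
  toy generator (a toy receptor carries no metals; covalent geometries
  would violate its clash-free construction); their rules are covered by
  direct unit tests instead.
* Receptor-side weak hydrogen bonds require explicit hydrogens; without
  them the C-H donor rule simply never fires rather than guessing
  protonation.
* The pipeline analyses one receptor structure per run; multi-receptor
  studies concatenate matrices upstream of the statistics, and no
  cross-receptor calibration is attempted.
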