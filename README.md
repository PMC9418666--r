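# aifp — atomic interaction fingerprints and ligand pharmacology

`aifp` turns 3D receptor–ligand docking poses into typed atomic-contact
fingerprints and uses them to classify — and explain — ligand pharmacology
(agonist vs antagonist) at the β2-adrenoceptor and receptors like it.

**Who it is for.** Computational chemists and structural bioinformaticians
who have a receptor structure (PDB), a set of docked ligand poses
(multi-record SDF, one record per pose titled `ligandID_poseNumber`), and a
ligand label table, and who want to know *which atomic interactions drive
activity*, not just a black-box prediction.

## The method

1. **Fingerprinting.** Every receptor-atom/ligand-atom pair within 5 Å is
   classified into one of 15 interaction subtypes (ionic, hydrogen bond,
   halogen bond, aromatic, hydrophobic, polar, …) by distance and angle
   rules over chemically annotated atoms. The set of typed contacts of one
   pose is its atomic interaction fingerprint (AIF).
2. **Pose filtering.** Poses lacking the β-hydroxy-amine anchor contacts —
   D113(OD1/OD2)···N⁺ (ionic/polar/H-bond) and N312(OD1)···N/O
   (H-bond/polar) — are discarded as docking artefacts, giving the
   "filtered" arm of the analysis; the unfiltered "full" arm is kept for
   comparison.
3. **Matrix encoding.** Fingerprints become a binary pose × feature matrix
   with keys `residue/atom—element type` (e.g. `301/O—N polar`); clash,
   vdw-clash and proximal contacts are excluded, features rarer than 10%
   of poses are dropped, and each pose inherits its ligand's label.
4. **Statistics and learning.** Each feature's association with
   pharmacology is its Pearson/phi correlation *r* with the label
   (antagonist positive); a sum-of-*r* threshold classifier provides the
   transparent baseline. Random-forest and gradient-boosted-tree
   classifiers provide the performance ceiling, evaluated by Matthews
   correlation coefficient

   MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

   under repeated stratified k-fold cross-validation with 99% bootstrap
   confidence intervals, a ligand-grouped 20% hold-out, and the repeats
   rule n = ⌈z²σ²/δ²⌉.
5. **Attribution.** Shapley values, φᵢ = Σ_S |S|!(M−|S|−1)!/M! · (f(S∪i) −
   f(S)), are computed two independent ways — exact subset enumeration
   through the model, and a polynomial-time interventional tree-structure
   algorithm (Rcpp) — and ranked by mean |φ| to name the interactions that
   push predictions toward agonism or antagonism.

A synthetic-data module generates toy binding pockets with analytically
known contacts and planted-signal fingerprint matrices under the study's
conditions (75% agonists, ≤10 poses per ligand, one correct pose in ten),
so the entire pipeline is testable without docking runs or downloads.

## Worked example

A self-contained run on generated fixtures — real PDB/SDF/CSV files written
and re-read through the standard parsers:

```r
library(aifp)
study <- generate_toy_dataset("fixtures", n_ligands = 24, poses_per_ligand = 3,
                              agonist_fraction = 0.65, seed = 11)
receptor <- assign_atom_roles(read_receptor(study$receptor_path))
poses <- lapply(read_poses(study$poses_path), assign_atom_roles)

compute_aif(receptor, poses[[1]])
#> <aifp_aif> toy 001_01: 6 records
#>   residue_number receptor_atom ligand_element ligand_atom_index          type
#> 1            113           OD2              N                 2         ionic
#> 2            118           CG2              O                 7      proximal
#> 3            193             O             CL                 6  halogen_bond
#> 4            203            OG              O                 4 hydrogen_bond
#> 5            301           OE1              O                 5         polar
#> 6            312           OD1              O                 3 hydrogen_bond
```

This pose carries the D113 ionic and N312 hydrogen-bond anchors, so it
survives the filter; across the study:

```r
aifs <- lapply(poses, function(p) compute_aif(receptor, p))
flt <- filter_dataset(aifs)
#> retained 41 of 72 poses (removed fraction 0.43)

m <- frequency_filter(build_matrix(flt$retained,
                                   read_labels(study$labels_path)), 0.05)
m
#> <aifp_matrix> 41 poses x 14 features; labels: agonist=30 antagonist=11 binder=0

spl <- split_holdout(m, 0.20, seed = 11)
rank_features(pointwise_correlation(spl$cv), 3)[, c("feature_key", "r", "direction")]
#>              feature_key  r  direction
#> 1 203/OG—O hydrogen_bond -1    agonist
#> 2     286/CD2—C aromatic  1 antagonist
#> 3     286/CE2—C aromatic  1 antagonist
```

The serine-203 hydrogen bond marks agonists and the tryptophan-286 aromatic
stack marks antagonists — exactly the contacts the generator planted per
class. The learned model agrees and generalises to the untouched hold-out:

```r
model <- train_model(spl$cv, model_spec("random_forest", estimators = 300),
                     seed = 11)
cm <- confusion_counts(spl$holdout$label,
                       predict_model(model, spl$holdout, "class"))
mcc(cm["tp"], cm["tn"], cm["fp"], cm["fn"])
#> hold-out MCC 1.00

shap <- tree_shapley(model, spl$cv, matrix_rows(spl$cv, 1:10))
head(global_importance(shap), 3)[, c("feature_key", "mean_abs_phi", "presence_direction")]
#>          feature_key mean_abs_phi presence_direction
#> 1 286/CD2—C aromatic   0.05442857         antagonist
#> 2 286/CZ3—C aromatic   0.05257143         antagonist
#> 3 286/CH2—C aromatic   0.05147619         antagonist
```

`run_pipeline(pipeline_config(...))` chains all stages over both the full
and filtered arms and writes every artifact (fingerprints, filter report,
matrices, correlation reports, evaluation JSON, Shapley summaries, resolved
config) to an output directory; `inst/scripts/aifp.R` wraps it for the
shell. The methods vignette
(`vignettes/interaction-fingerprint-pharmacology.Rmd`) documents the rule
table, the evaluation protocol, the Shapley machinery and the synthetic
generators in detail.

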