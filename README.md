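# pocketmolr

Structure-guided induction of sparse binding-pocket models
("pocketmols") for ligand affinity and pose prediction.

## The problem

In lead optimization one often has a series of ligands with measured
activities (Ki/IC50) and a handful of crystal structures of the target
with *other* ligands bound. Docking into those structures ranks poses
poorly across chemotypes (the cross-docking problem), and ligand-only
3D-QSAR models extrapolate badly beyond the training series.
`pocketmolr` implements a middle path: it induces a *pocketmol* — a
sparse set of typed interaction probes (steric, H-bond donor, H-bond
acceptor) acting as a surrogate binding site — such that the *docked
score* of each training ligand against the pocketmol matches its
measured pKi (−log10 Ki in molar; 9.0 ≡ 1 nM). New molecules are
flexibly fit into the pocketmol; the fitted score **is** the predicted
pKi, and the fitted pose is the predicted binding mode.

Two ideas carry the method:

* **Multiple-instance learning.** Every ligand is represented by an
  ensemble of candidate poses; its score is the *maximum* pose score,
  so model induction selects poses and probes jointly. Induction
  alternates greedy probe-subset selection (minimizing
  Σ(score − pKi)² + λ·|probes|), probe position/direction refinement,
  and ligand pose refinement, at three probe densities; the final model
  is chosen by *parsimony* — the mean 3D pose similarity of training
  pairs with similar activities.
* **Structure guidance.** Aligned pocket structures (selected by
  k-means from a larger pool) guide the seed alignment via
  multi-structure docking plus 3D similarity to the cognate
  crystallographic ligands, and filter the candidate probe pool: a
  steric probe survives only within 1.0 Å of a hydrophobic protein
  atom, a polar probe within 2.0 Å of a same-polarity atom, in any
  pocket variant.

Scoring is an empirical atom–probe function in pKd units
(piecewise-linear hydrophobic contact term, squared-cosine directional
polar term, quadratic interpenetration penalty); 3D similarity is
Gaussian-overlap shape plus same-type polar overlap. See the methods
vignette (`vignettes/pocketmol-methods.Rmd`) for formulas, defaults,
and design rationale.

## Worked example

The package ships a seeded synthetic benchmark generator (bead-ligand
congeneric and diverse series inside a jittered pocket ensemble, with
activities generated from a known ground-truth pocketmol), so the full
pipeline runs out of the box:

```r
library(pocketmolr)

bm <- make_benchmark(1, benchmark_config(noise_sd = 0))
mols <- lapply(bm$train, function(e) e$mol)
pki  <- setNames(vapply(bm$train, `[[`, numeric(1), "pki"),
                 vapply(bm$train, function(e) e$mol$id, character(1)))

fit <- build_pocketmol_model(mols, pki, pockets = bm$pockets,
                             mode = "structure_guided", seed = 1,
                             verbose = TRUE)
#> structure_guided hypothesis objective: 15.548
#> tessellated 15 actives -> 747 probes
#> structure filter: 747 -> 229 probes
#> models: [25] RMSE 0.65 par 0.83 [50] RMSE 0.09 par 0.81
#>   [100] RMSE 0.09 par 0.81; selected density 50
#>   (parsimony 0.806, RMSE 0.094)

test <- lapply(seq_along(bm$congeneric_test), function(i)
  generate_conformers(bm$congeneric_test[[i]]$mol, 5, 901 + i))
obs  <- vapply(bm$congeneric_test, `[[`, numeric(1), "pki")
res  <- predict_batch(fit$best, test, seed = 51)
pred <- vapply(res, `[[`, numeric(1), "pki_pred")

mean_abs_error(pred, obs)
#> [1] 0.572
kendall_tau(pred, obs, n_perm = 999, seed = 1)$tau
#> [1] 0.726
```

Interpretation: on 20 held-out congeneric ligands the induced 50-probe
model reproduces the training activities to 0.09 RMS log units and
predicts held-out activity with a mean error of ~0.57 log units and a
rank correlation of ~0.73 — the model has recovered the generating
pocket to within the noise of its own pose search. Each prediction
also carries a pose and a confidence in [0, 1] (similarity of the
predicted pose to the nearest final training pose), and
`stratify_by_confidence()` produces the confidence-stratified error
table (thresholds 0.7 / 0.5 / all).

A file-driven interface mirrors the R API: `cmd_induce()` runs the
whole pipeline from a flat YAML setup file (ligand SDF, activity CSV,
pocket PDBs with cognate-ligand SDFs) and writes a model bundle;
`cmd_predict()` and `cmd_eval()` score new molecules and emit the
stratified evaluation report; `make_fixture()` writes a complete
synthetic benchmark to disk. `inst/cli/pocketmolr` is a thin Rscript
wrapper over these commands.

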