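---
title: "StackScreen: methods and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{StackScreen: methods and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

StackScreen implements a stacked ligand- and structure-based virtual
screening pipeline for kinase-inhibitor repurposing. This vignette
documents the model and procedure of each stage, the numerical
conventions chosen where a formula admits more than one dialect, what
the synthetic generators emulate (and what they deliberately do not),
and the limits of validity.

# Activity-library ingestion

An activity table (compound id, SMILES, IC50 with an optional relation
qualifier) is read, the SMILES are converted to OpenBabel canonical
form, and duplicate molecules — identical canonical SMILES — are
merged:

- **Potency scale.** pIC50 = 9 − log10(IC50 in nM), so 1000 nM is
  exactly pIC50 6 and 316 nM is about 6.5. Conversions are performed
  only for exact potencies; relational ("censored", e.g. `> 10000`)
  and missing potencies never acquire a pIC50.
- **Duplicate merging.** Exact IC50 values of duplicates are averaged
  arithmetically *in concentration space* before the log transform
  (averaging pIC50 values instead would compute a geometric mean of the
  concentrations). A merged record is exact only if every source row is
  exact; any censored source row makes the merged record censored.
- **Activity labels.** Exact records are active when pIC50 ≥ 6
  (IC50 ≤ 1000 nM). Censored and missing potencies are labelled
  inactive under the default policy (they may alternatively be
  dropped). The threshold is a parameter (`threshold_pic50`) because
  published summaries of this design quote both 6 and 7.

```{r}
library(StackScreen)
lib <- loadActivityLibrary("activity.csv", unit = "nM")
lab <- assignActivityLabels(lib, threshold_pic50 = 6)
```

# Scaffold statistics

Inhibitors are grouped by their **most central ring (MCR)** system.
Reference MCR implementations are proprietary, so StackScreen uses a
documented stand-in: fused/spiro ring systems (bonds on cycles,
perceived via graph bridges) are the nodes of a reduced graph whose
inter-node distances are shortest bond paths; the system with minimum
eccentricity wins, with ties broken by fewer atoms and then by the
lexicographically smaller canonical key. Under these tie-breaks a
two-ring molecule such as biphenyl reduces to a single benzene key.
External assignment tables are accepted and override extraction.

Per analysed scaffold group (≥ 2 members after an optional bioisostere
merge map) the package reports:

- a **Mann–Whitney U test** of the group's pIC50 distribution against
  all other analysed groups pooled. The p value is exact by full
  enumeration of rank splits when the smaller sample has at most 8
  observations and there are no ties; otherwise a normal approximation
  with tie and continuity corrections is used.
- the **standardized residual** (O − E)/√E of the group's potent cell
  in the groups × {potent, weak} chi-square table, with potent defined
  as pIC50 ≥ 6.5 and ±1.96 as the 95 % significance cutoff.
- the **enrichment factor**
  EF = (n potent in scaffold / N potent) / (n scaffold / N).

A scaffold is **relevant** when EF > 1 *and* either route is
significant with the group more potent (Mann–Whitney p < 0.05 with a
higher in-group mean, or standardized residual > 1.96). Relevant
scaffolds become one-hot indicator bits for the meta-model.

# Descriptor QSAR

Descriptors combine OpenBabel property descriptors (molecular weight,
logP, molar refractivity, TPSA, hydrogen-bond donor/acceptor counts)
with graph and constitutional descriptors computed from the molecular
graph (ring counts, rotatable bonds, Wiener and Zagreb indices, graph
diameter/radius, …) — about 27 columns. Feature selection is
three-staged: variance filter (< 0.01 dropped), greedy correlation
pruning (while any |r| > 0.85, drop the member of the worst pair with
the larger mean absolute correlation), and random-forest recursive
feature elimination down to 10 descriptors.

Five regression families are compared with library-default
hyperparameters — multiple linear regression, partial least squares
(2 components), RBF support-vector regression, random forest, and
gradient boosting (100 rounds, learning rate 0.1, depth 3) — on one
seeded 80/20 split stratified by response quantile, with five-fold
out-of-fold Q² on the training fold deciding the winner. Scalers are
always fitted on the training rows (or in-fold rows) only.

The **applicability domain** combines three checks in the selected
descriptor space: leverage h = x(X′X)⁻¹x′ *with an intercept column*
against the Williams warning leverage h\* = 3p/n (p = number of fitted
parameters including the intercept — hence the test identity
Σh = p), studentized residuals for the Williams plot, projection onto
the first two principal components, and a per-descriptor training
[min, max] range check. A query is in-domain iff h ≤ h\* and every
descriptor is in range.

# Pharmacophore fingerprint classification

Exported pharmacophore fingerprints are treated as opaque token
multisets: one line per compound (`id<TAB>tok;tok;…`) parsed into a
pattern-count matrix with the vocabulary ordered by first appearance.
The pipeline is variance filter (< 0.01) → standardization → PCA to 20
components, every step fitted on training rows only. Five classifier
families (logistic regression, probability SVM, random forest,
gradient boosting, 5-nearest-neighbours) are evaluated over 10
stratified 80/20 split seeds with five-fold cross-validation (pooled
out-of-fold probabilities); mean CV ROC AUC picks the winner (mean CV
MCC breaks ties), which is refit on all data. Balanced accuracy is the
mean of sensitivity and specificity; MCC uses the standard four-cell
formula with a zero denominator defined as 0.

# Stacked meta-model

The meta-model stacks the QSAR-predicted pIC50 and the classifier
probability — each min-max scaled to [−1, 1] with *training* bounds
and clipped outside them — plus the relevant-scaffold one-hot bits
(already 0/1, left unscaled). The combiner is ridge-penalised logistic
regression at fixed λ = 1/n, which reproduces the sum-loss
"C = 1" convention of common penalised-logistic implementations
(those minimise Σloss + ‖w‖²/(2C); on glmnet's mean-loss scale that is
λ = 1/(Cn)). The gate passes probability strictly above 0.5.

# Docking post-analysis

Interaction reports (ligand, residue, interaction type over the seven
types hydrophobic/hbond/salt_bridge/pi_stack/pi_cation/halogen/
water_bridge) become binary interaction fingerprints with feature keys
`residue:type` sorted by residue number then type. Conventions:

- **Ranking score** is the negated binding energy (kcal/mol; more
  negative binds stronger), so larger score = better.
- **ROC AUC** is the Mann–Whitney rank statistic with ties counting
  one half.
- **logAUC** places FPR on a log10 axis clipped to [1e-3, 1],
  linearly interpolates TPR at the lower bound, integrates by
  trapezoid over log10(FPR), and normalises by the 3 decades: a
  perfect ranker scores 1 and the chance diagonal
  (1 − 1e-3)/(3 ln 10) ≈ 0.1446.
- **EF@α** takes the top ⌈αN⌉ compounds; EF at 1 % is reported as
  missing when N < 100.
- **Consensus interaction selection** intersects the top-10 features
  by chi-square statistic (presence vs activity) with the top-10 by
  seeded random-forest importance, ordered by chi-square rank; an
  empty intersection falls back to the union with a provenance flag.

The **MLP rescorer** has the fixed architecture input → 32 (ReLU) →
dropout → 16 (ReLU) → dropout → 1 (sigmoid), trained with Adam on
weighted binary cross-entropy (positive-class weight = n_neg/n_pos)
with Gaussian noise (sd 0.01) injected into the standardized energy
input during training only. The hyperparameter grid is exhaustive:
learning rate {0.001, 0.01, 0.05, 0.1} × batch {8, 16, 32, 64} ×
dropout {0.1, 0.2, 0.3, 0.4} = 64 combinations, each scored by
stratified 10-fold CV AUC on pooled out-of-fold probabilities. The
implementation is a small compiled network driven by R's RNG, so
`set.seed()` makes training reproducible; inference is deterministic
(no dropout, no noise). Input importance is the mean absolute
first-layer weight, which ranks the energy input first whenever energy
dominates the planted signal.

# Screening cascade

`runScreening()` applies the trained stages in order:

1. QSAR applicability domain (leverage + range);
2. fingerprint similarity: maximum generalized Tanimoto
   (Σmin/Σmax) to any training compound, strict > cutoff (default 0.8);
3. meta-model probability strictly > 0.5;
4. when docking results exist, MLP probability ≥ 0.95 for the final
   candidate list, ranked by probability then energy.

Compounds passing the meta gate without docking rows are reported as
`awaiting_docking`. Stage survivor counts are monotone non-increasing,
and reports (CSV + JSON with thresholds, seed, package version and a
configuration hash) contain no timestamps, so fixed seeds give
byte-identical output.

# Synthetic study conditions

Seeded generators emulate every pipeline input so all stages are
testable offline: activity libraries drawn from an embedded panel of
drug-like SMILES with a planted potency shift (+1.5 pIC50) on the
quinazoline family; descriptor datasets with flagged informative vs
noise columns; fingerprint strings whose informative token rates are
multiplied by exp(±effect) in actives; docking energies with a planted
active/inactive gap and planted over-represented interactions.

Two deliberate departures from real data matter for interpretation:

- The SMILES panel is finite (38 molecules), so large simulated
  libraries contain structural duplicates; generated compound records
  have unique ids and are treated as distinct measurements.
- Fingerprint token counts are drawn independently per compound, so
  absolute inter-compound similarities are low (≈ 0.3–0.5 even within
  a class) — unlike real congeneric series, which exceed the 0.8
  production gate. Cascade demonstrations on synthetic data therefore
  use a permissive similarity cutoff of 0.3; the production default
  remains 0.8.

# Worked example

```{r}
sp <- syntheticSpec(seed = 1, n_compounds = 192,
                    pattern_class_effect = 1.5, energy_gap = 2)
lib <- genActivityLibrary(sp)
rec <- libraryRecords(lib)
lab <- libraryRecords(assignActivityLabels(lib, 6))$label
fl <- genFlexophoreStrings(nrow(rec), sp, labels = lab,
                           ids = rec$compound_id)
models <- trainRepurposingModels(
  lib, fl$lines,
  scaffold_assignments = data.frame(compound_id = rec$compound_id,
                                    scaffold_id = rec$scaffold_family),
  seed = 1)
models$scaffold$summary        # per-scaffold statistics incl. EF
models$qsar$evals              # five regressors, R2 / RMSE / Q2
models$flexo$evals             # five classifiers x seeds x partitions
models$meta$fit$coefficients   # stacked logistic weights
```

A complete simulated screen, including docking rescoring, is scripted
in the package's command-line tool (`inst/exec/stackscreen`), e.g.

```sh
stackscreen simulate --seed 1 --n 192 --out study
stackscreen screen --train study --out report --similarity 0.3
```

# Limitations

- Molecular descriptors come from OpenBabel plus graph indices
  (~27 columns), a smaller panel than large toolkit collections; the
  selection/AD machinery is descriptor-count-agnostic.
- The MCR stand-in reproduces the documented eccentricity rule, not
  any proprietary fragmentation.
- Fingerprint *generation* is out of scope; the package parses
  exported token strings.
- Docking itself (pose generation, energy evaluation) is upstream;
  the package consumes its outputs.
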