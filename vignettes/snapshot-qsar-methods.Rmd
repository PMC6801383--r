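---
title: "Image-based QSAR from omnidirectional molecular snapshots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based QSAR from omnidirectional molecular snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-throughput screens such as the Tox21 nuclear-receptor panels score
thousands of small molecules for endpoints like constitutive androstane
receptor (CAR) agonism. Predicting such an endpoint from structure alone
(QSAR) conventionally starts from hand-designed numeric descriptors. An
alternative is to let a convolutional network read the structure directly:
each molecule is embedded in 3D, drawn as a ball-and-stick model, and
*photographed* from a grid of camera angles; the resulting image stack is
the model input, and per-image predictions are aggregated back to one score
per molecule. `molsnap` implements that pipeline end to end on the CPU:
curation and labeling of activity tables, structure washing, deterministic
rendering, molecule-level data splits, a pluggable classifier with a small
reference CNN, a descriptor-table tree-ensemble baseline, and the
evaluation suite.

## Activity scores, labeling, and curation

Raw screen read-outs are normalised per plate as

\[
\%\,\mathrm{Activity} =
\frac{V_\mathrm{compound} - V_\mathrm{DMSO}}
     {V_\mathrm{pos} - V_\mathrm{DMSO}} \times 100 ,
\]

(`percent_activity()`), and scores are classed as inactive (exactly 0),
inconclusive (1–39), or active (40–100); the binary mode used downstream
maps inconclusive to inactive (`assign_label()`).

`curate()` keys every record by the canonical SMILES of its **largest
organic fragment** (salts and solvents stripped), because screening
libraries register the same parent compound under several salt forms and
accession numbers. Structures with no carbon atom are removed as
nonorganic. When two records share a structure key, consistent binary
labels collapse into one record (all source ids retained, score = median);
*conflicting* labels remove the structure entirely — a molecule whose
replicates disagree about activity is a labeling liability for training,
not a data point. Both choices are deliberately conservative; the removal
report lists every dropped record with exactly one reason so the curation
is auditable.

## Washing: protonation and 3D coordinates

A *wash* (`wash_spec()` + `wash()`) pairs a protonation adjustment with a
coordinate-generation mode, optionally chained:

* `none` leaves the input protonation; `neutralize` removes formal charges
  wherever valence rules permit (anions gain a hydrogen per unit charge,
  protonated cations lose one; quaternary centres stay charged);
  `dominant` applies a small acid/base rule table at pH 7 — carboxylic and
  sulfonic acid O–H deprotonated, aliphatic amines (not amides, not
  aromatic nitrogens) protonated. The rule table is an explicit,
  documented approximation of a full pKa model: it covers the ionisable
  groups in screening libraries' bulk, and anything it misses simply keeps
  its input state.
* `depict2d` produces a flat layout (Open Babel's 2D depiction);
  `rebuild3d` runs the package's seeded distance-geometry-style embedding;
  `corina_like` runs the same embedding to tight convergence with a
  deterministic multi-start, yielding exactly one low-energy conformer per
  molecule, which is the regime the imaging pipeline expects.

The embedding minimises a pairwise stress function: harmonic wells at
covalent-radius-sum bond-length targets (scaled 0.87/0.78/0.93 for
double/triple/aromatic bonds), 1–3 distances implied by idealised angles
(109.47° sp³, 120° sp², 180° sp), and one-sided repulsion below a fraction
of summed van der Waals radii (0.70 for 1–4 pairs, 0.80 beyond). Starting
coordinates are drawn from a seeded normal distribution and refined by
BFGS. Determinism is a contract: the same structure, wash and seed yield
bit-identical coordinates, and the per-molecule seed mixes the global seed
with a hash of the molecule id so results do not depend on library order.
The aim is a *plausible, reproducible* single conformer — not the global
minimum of a physical force field; conformational sampling beyond one
conformer per molecule is out of scope.

## Rendering

`render_snapshot()` is a self-contained software rasteriser, so image
bytes are a pure function of the molecule and parameters (no display
stack, fonts, or driver in the loop). Geometry: rotation about the
centroid applying x, then y, then z (right-handed axes); orthographic
projection; atom spheres at `at`% of the van der Waals radius in CPK
colors; bond cylinders of radius `br` (milli-Angstrom, with a 1-pixel
on-screen floor so thin bonds stay visible); z-buffered compositing. The
projection scale is frozen at the zero-rotation view so the molecule's
bounding sphere fills `zf`% of the edge and all rotations of one molecule
share one scale — rotated views stay mutually comparable, and the molecule
cannot leave the frame for `zf <= 100`.

Shading is deliberately classifier-oriented: a fixed directional light
with a high ambient floor (intensity `0.65 + 0.35·max(n·l, 0)`), so every
sphere keeps a near-constant CPK hue across its surface. Element identity
is the signal the downstream network needs; strong shading gradients would
smear distinct element hues into overlapping RGB ranges (a dimly lit
bright-red oxygen becomes indistinguishable from a dark-red bromine at
training resolutions).

Bond perception (`perceive_bonds()`) is distance-based: atoms are bonded
iff `mbd <= d <= r_cov(i) + r_cov(j) + bt`, with the covalent-radii table
shipped in the package; pairs closer than `mbd` raise a steric-clash
warning and are not bonded.

Defaults (`render_params()`): angle step 280° per axis (8 views), 100
molecules per structure-file chunk (IO batching only — chunking never
changes image content), zoom 100 %, atom size 23 %, bond radius 14.5 mÅ,
minimum bond distance 0.4 Å, bond tolerance 0.8 Å, 256×256 RGB PNG.

## Splits and the permutation control

`split_molecules()` assigns whole molecules — never individual images — to
train/validation/test, because rotated snapshots of one molecule are
near-duplicates and image-level splitting would leak test content into
training. Ratios such as 26:26:1 are integers; non-divisible totals are
resolved by largest-remainder apportionment, and stratification (on by
default) apportions each class separately so every split's active fraction
matches the global fraction within one molecule. An image-level mode
exists only for leakage comparisons.

`permute_labels()` reassigns the label multiset uniformly at random across
molecules. Training on permuted labels is the pipeline's negative control:
any apparent skill on permuted data is leakage or overfitting, so its test
AUC should be statistically indistinguishable from 0.5.

## The reference classifier

No deep-learning framework is assumed: the reference network is a small
CNN implemented in R with im2col convolutions — conv 5×5×8 / ReLU /
max-pool 2 / conv 5×5×16 / ReLU / max-pool 2 / **global average pooling**
/ dense 16 / dense 1 (sigmoid) — trained with minibatch SGD with momentum
0.9 on binary cross-entropy. The global-average-pooling head is the
important design choice: it makes the classifier respond to local
structural features wherever they appear in the frame (the invariance that
matters when each molecule is photographed from many angles) and keeps the
parameter count small enough to train on tens of molecules without
memorising individual training structures — a fully connected head
memorises pose layouts and fails to generalise across molecules at this
data scale. Images are block-averaged to 64×64 before entering the
network; intensities are centred at 0.5.

Defaults (`training_config()`): learning rate 0.02, batch size 32, 60
epochs, 64-pixel input. These are the reference network's own tuned
values, chosen for stable convergence in CPU minutes; GoogLeNet-scale
settings (e.g. learning rate 8e-4, batch 108) belong to external networks,
which plug in through `arch = "external"` with `train_fn`/`predict_fn`
hooks. Training records the loss(Tra)/loss(Val)/Acc(Val) monitors per
epoch, and is deterministic under a fixed seed.

## Descriptor baseline

`compute_descriptors()` builds the conventional-QSAR comparison table:
Open Babel physicochemical properties plus the 1024-bit FP2 path
fingerprint (1032 columns on the synthetic library). Columns with any
non-finite value are median-imputed and all-missing columns dropped, both
reported in attributes. `train_tree_baseline()` then runs repeated 1:1
hold-out evaluation (5 repeats by default): per repeat a fresh seeded
split, a random forest (`ranger`) or gradient boosting (`xgboost`) fit,
and the held-out AUC. The shared `max_features` grid value maps to `mtry`
(features per split) for the forest and to the per-tree column subsample
fraction `max_features / n_features` for boosting; the mapping is recorded
in the result's metadata because the two libraries have no parameter in
common with that exact name. Degenerate draws (a single-class half) are
redrawn with the next seed and counted; if the class counts make a
two-class split impossible the call errors rather than loops.

## Evaluation

Per-image probabilities are aggregated per molecule by the median
(`aggregate_median()`; even counts average the two central values) — the
median over views damps view-specific misclassifications. `roc_auc()`
computes AUC as the normalised rank statistic (ties ½), which equals the
trapezoidal area under the ROC curve; both routes are asserted equal in
the tests. The classification cutoff is selected on *validation* scores by
the Youden index J = sensitivity + specificity − 1 (ties broken toward
higher specificity) and reused frozen on the test set — selecting it on
test scores would bias every thresholded metric optimistically.
`confusion_metrics()` reports the full bundle: sensitivity, specificity,
balanced accuracy, accuracy, precision, recall, F, and the Matthews
correlation coefficient with the standard square-root denominator.
Zero-denominator conventions (precision 0 when nothing is called positive;
MCC 0 when a marginal is empty) keep the outputs total and are flagged.

## The synthetic library

`make_toy_library()` emulates the *shape* of a screening library — a
labeled set of parseable, structurally distinct small molecules whose
binary label is a deterministic function of a structural feature — without
any download. Structures combine ~20 scaffold cores (rings, chains,
heteroatoms, charged species for wash tests, one carbon-free structure for
the nonorganic filter) with alkyl-chain substituents; under the default
`halogen_present` rule, actives carry F/Cl/Br. Scores are drawn uniformly
from 40–100 (rule-satisfying) or 0–39; optional label noise flips a seeded
subset. The default active fraction 0.108 mirrors the class imbalance of
nuclear-receptor agonist screens; the test conditions use 0.5 so that
1:1:1 splits of 60 molecules retain both classes comfortably.
`make_plate()` inverts the percent-activity formula to simulate raw well
signals with optional Gaussian noise.

What the synthetic library deliberately does **not** emulate: real
structure–activity landscapes (activity cliffs, scaffold hopping),
tautomerism, stereochemistry, or assay artefacts. A pipeline that passes
the built-in checks is demonstrated to be *mechanically correct and
leakage-free with a learnable signal*; performance on real endpoints is a
scientific question these tests cannot answer.

## Problem sizes and numerical choices

The shipped checks run the full pipeline on 60 molecules × 8 rotations
(~480 images) with the reference CNN, and the tree baselines on a
200-molecule descriptor table — sizes chosen so the whole suite runs in
CPU minutes while leaving the learnability and permutation-control
contrasts unambiguous. Numerical conventions worth knowing: rotation
angles are taken modulo 360° (so 360 ≡ 0); the boundary rule is
`score >= threshold` → active; median over an even image count averages
the central pair; the embedding warns (not errors) when the stress at
convergence suggests a poor local minimum; and all Monte-Carlo tests fix
their seeds.

## Known limitations

* The dominant-protonation rule table is not a pKa predictor; unusual
  ionisable groups keep their input state.
* The embedding targets plausibility and reproducibility, not force-field
  accuracy; ring pucker and torsion preferences are approximate.
* The renderer's flat-ambient shading trades photorealism for hue
  constancy; it is not a Jmol replacement.
* The reference CNN is sized for desk-scale experiments; state-of-the-art
  accuracy on real libraries requires an external network via the
  `external` hook.
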