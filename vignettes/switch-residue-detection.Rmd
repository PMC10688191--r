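---
title: "Detecting switch residues and grading their dynamic stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting switch residues and grading their dynamic stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscan)
```

## The model

Individual amino acids in a protein can behave as two-state systems: some
internal angle of the residue occupies two well-separated values, and the
residue hops between them. switchscan detects these *switch residues* from
MD trajectories and grades the hopping kinetics. The procedure treats each
residue as a rigid body described by a reduced atom set, describes each
three-atom angle by the shape of its *density of states* (DoS) — the
normalized histogram of the angle over all frames — and makes two
decisions per angle:

* **switch vs nonswitch** — is the DoS bimodal with an unoccupied valley
  (no intermediate state) between the modes? This is a supervised
  classification on 14 engineered DoS features, because raw histograms vary
  too much in shape for fixed rules to generalize across residue types and
  proteins.
* **SS vs US** — given a switch, does the trajectory show a single jump
  between the states (stable switch) or constant oscillation (unstable
  switch)? This is decided from the *instability ratio*,
  100 × transitions / frames, via a one-dimensional logistic model.

Assumptions worth stating: angles live on the closed interval [0, π] (the
arccos of a normalized dot product), so binning is linear with no
wrap-around; residue-internal geometry is assumed whole (no
periodic-boundary imaging); pooling many short trajectories by
concatenation is valid for the DoS because the histogram is
order-insensitive, while transition counting respects the recorded segment
boundaries so a pooled seam never counts as a jump.

## Atom selection and triplet combinatorics

A residue with *k* selected atoms yields C(*k*, 3) angles; enumeration is
lexicographic in topological order (backbone N, CA, CB, side chain outward,
C, O) and the vertex of each unordered triplet is its topologically middle
atom — so the two backbone switch angles of an alanine are written
O–C–N and O–CA–N (vertices C and CA).

The shipped selection table pins the documented counts — ALA 5 atoms
(10 angles), SER 6 (20), TYR 7 (35), ILE and MET 8 (56), GLN 9 (84), ARG 10
(120, dropping the guanidinium CZ) — and generalizes the same reduction
rule to the remaining residue types: keep backbone N/CA/C/O and CB,
side-chain branch points, and terminal heteroatoms; drop intermediate ring
carbons (as TYR keeps CG and OH but not CD1/CE1/CZ/CE2/CD2). Two entries
are extrapolations with no printed constraint: GLY has only 4 heavy atoms
(4 angles) and PRO retains its ring CG/CD. The table is a YAML file
(`inst/extdata/selection_table.yaml`) so users can substitute their own —
note that bare `N` in YAML parses as a boolean, so atom names are quoted.

```{r}
vapply(c("ALA", "SER", "TYR", "ILE", "MET", "GLN", "ARG"), n_angles, 1)
```

## DoS construction and the 14 features

Angles are binned into `n_bins = 90` equal bins over [0, π] (2°
resolution). Typical switch modes are separated by ~0.9 rad (~26 bins) with
spreads of ~0.08 rad, so 2° bins resolve them with wide margin while
keeping per-bin counts stable at a few thousand frames. Peak detection runs
on a 5-bin moving average (reflective ends, renormalized to unit mass);
modes are local maxima above 5% of the tallest bin, merged within 5 bins,
sorted by height with ties going to the lower bin.

The 14 features are: mode count; major/minor mode locations and their
separation; major/minor heights and the minor/major height ratio; the
valley-to-minor-peak ratio (0 for a clean switch, near 1 for a filled
valley); the minor mode's mass fraction (capped at 0.5); both FWHMs; and
three moment summaries of the whole DoS — variance, skewness, and the
bimodality coefficient (skewness² + 1)/kurtosis. Single-mode densities take
sentinel values (zero separation, zero minor height/mass/FWHM) rather than
NAs so every row is finite. This concrete feature set is this package's
fixed, versioned choice; `dos_feature_names()` is the schema that models
are validated against.

`heuristic_label()` (exactly two modes, deep valley, non-trivial minor
mass) is a labeling aid for bootstrapping a training set; production calls
come from the trained classifier.

## Classifiers and cross-validation

Three backends are wrapped behind one interface: a single decision tree
(rpart), a 100-tree random forest (randomForest, unpruned trees), and
100 rounds of depth-3 gradient-boosted trees (xgboost, single-threaded for
determinism). Hyperparameters are deliberately plain defaults — the
separation in feature space does the work — and all are overridable.
Accuracy is reported as stratified 5-fold cross-validation (mean and
standard deviation over folds), with fixed-seed shuffling so reports
reproduce exactly. Fits are deterministic given (data, seed,
hyperparameters); models persist via `save_model()`/`load_model()` and
round-trip to identical predictions.

## State assignment and the instability ratio

Per-frame states come from 1-D k-means with k = 2, initialized at the 10th
and 90th percentiles and run to convergence with Lloyd iterations — a
deterministic choice (no random restarts) that is ample for
one-dimensional, well-separated data. State 0 is always the lower-angle
cluster. Transitions are counted on the raw k-means labels with no
dwell-time debouncing: ambiguity between SS and US in the intermediate
regime is resolved by the learned logistic boundary rather than by
smoothing the trace. The denominator of the instability ratio is the total
pooled frame count; if your frames have a physical time step the ratio can
be rescaled, but only the dimensionless form is used here.

The SS and US regimes are empirically clear below 1% and above 6%;
`stability_fit()` places a logistic boundary between them and
`default_stability_model()` provides a calibration trained on synthetic
ratios drawn from those two clear regimes (by construction its boundary
falls in the intermediate band, ~3–4%). A fitted slope must be positive —
a non-positive slope means flipped labels and is rejected. A ratio exactly
on the boundary is graded US (tie-to-US convention). A residue's grade is
SS if *any* of its switch angles is SS (`residue_grade = "majority"`
switches to majority vote); the any-rule matches how a residue with one
clean single-jump angle is described as a stable switch even if other
angles are noisier.

## What the synthetic generator emulates — and what it does not

`gen_angle_series()` draws truncated-Gaussian noise (rejection-sampled into
[0, π]) around per-frame mode centers with four dynamics: `unimodal` (one
center), `ss` (deterministic state schedule, default one jump mid-series),
`us` (symmetric two-state Markov chain, default per-frame switch
probability 0.1, spanning the <1% and >6% ratio regimes as the probability
is varied), and `intermediate` (i.i.d. three-mode mixture, default weights
0.4/0.2/0.4). Defaults — centers 1.6 and 2.5 rad, spread 0.08 rad — mirror
the ~0.9 rad separations and narrow mode widths typical of real switch
angles. `gen_labeled_corpus()` randomizes centers, spreads (0.05–0.12 rad)
and separations (≥ 6 spreads, i.e. clear margins) into a balanced
three-class corpus where only clean bimodal series are labeled switch.
`gen_toy_trajectory()` embeds a schedule geometrically: the vertex CA and
arm N are fixed and the O atom moves in-plane at exactly the scheduled
angle, so `measure_angle_series()` must recover the schedule to numerical
precision.

What this does *not* emulate: correlated noise and slow drift within a
state, asymmetric or multi-scale dwell times, mode spreads that differ
between states of one angle, crowded DoS shapes from long side chains, and
any coupling between residues. Passing tests therefore demonstrate that the
pipeline's logic and numerics are correct under the stated statistical
model, not that the classifier's accuracy on these fixtures transfers to
any particular protein — on real data the classifier should be trained or
at least spot-checked against a hand-labeled sample of that system's DoS
shapes.

## Numerical choices and degenerate inputs

Cosines are clamped to [−1, 1] before arccos; a zero-length arm (arm atom
coinciding with the vertex) is an error naming the frame. Values exactly at
π are assigned to the last histogram bin. A constant angle series has no
resolvable states and `assign_states()` refuses it rather than returning an
arbitrary split. RMSD uses least-squares (Kabsch) superposition over the
chosen atom subset via bio3d's fitting routine, with the mean square
computed at full precision. Angle-table CSVs store doubles at 17
significant digits so write/read round-trips are exact; reports avoid
timestamps so a rerun under the same configuration is byte-identical.

## Problem sizes

The shipped tests and the acceptance script run on deliberately compact
problems: corpora of 600 angle series (200 per class) at 2000 frames for
classifier evaluation, 1000–5000-frame series for stability checks, and a
4-residue toy system (800 frames) for the end-to-end scan. These sizes give
Monte-Carlo errors comfortably inside the asserted tolerances while keeping
a full run in seconds; all generators scale to larger settings by argument.

## Known limitations

* XTC trajectories are not read; convert to DCD or multi-model PDB.
* No periodic-boundary imaging; trajectories must have whole residues.
* Exactly two angular states per switch angle: three-state or higher
  dynamics are reported as nonswitch (by design), not decomposed.
* No kernel density estimation or automatic bin-count selection; the DoS
  is a plain histogram with fixed bins.
* The residue-level SS/US grade compresses per-angle grades; inspect the
  per-angle table in `switch_scan()$angles` when angles within one residue
  disagree.
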