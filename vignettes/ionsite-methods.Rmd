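---
title: "Methods: window encoding and evaluation of metal-ion binding-residue prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window encoding and evaluation of metal-ion binding-residue prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsite)
```

## The prediction problem

Ca²⁺ and Mg²⁺ ions are coordinated by a handful of residues — typically
acidic side chains (Asp, Glu) and backbone carbonyls in loop regions — and
identifying those binding residues from sequence alone is a strongly
imbalanced classification problem: non-binding residues outnumber binding
residues by roughly two orders of magnitude. `ionsite` classifies each
residue by excerpting a short window centred on it, encoding the window
into a fixed-length numeric vector, and scoring it with a small
fully-connected neural network. The package covers the complete
protocol: data ingestion, window extraction, feature encoding, model
training with a hyper-parameter search, and an evaluation scheme built
around the Matthews correlation coefficient (MCC), which remains
informative under extreme class imbalance.

## Windows and pad residues

For a chain of length $n$ and an odd window length $L$ (default 9), the
package appends $(L-1)/2$ pseudo residues to each end of the chain and
excerpts one window per residue, so every residue — including terminal
ones — centers exactly one fragment. A fragment is *positive* when its
center residue is annotated as binding the ion, otherwise *negative*.
The pad symbol is a first-class token: it forms the 21st residue class
('X', shared with non-standard residues) and a dedicated `PAD` class on
every structure track. Treating pads as a class rather than imputing
values is what gives each composition sub-block its "+1" dimension and
keeps terminal windows statistically comparable to interior ones.

## Class schemes

Continuous structure predictions are discretized before encoding:

* **Relative solvent accessibility** (fraction in $[0,1]$): four
  right-closed intervals $(0,0.2]$, $(0.2,0.45]$, $(0.45,0.6]$,
  $(0.6,0.85]$. The printed intervals do not cover $x = 0$ or
  $x \in (0.85, 1]$; the package clamps these to the first and last
  class so the mapper is total. The boundary mass is negligible in
  predicted-RSA data, and a four-class scheme implies full coverage.
* **Phi**: $[-180°,-75°]$ versus $(-75°,180°]$ — the split isolates the
  α/β backbone basin.
* **Psi**: $[-180°,15°]$, $(15°,135°]$, $(135°,180°]$.
* **Charge**: K/R/H positive, D/E negative, all else neutral (3
  classes).
* **Hydropathy**: R/D/E/N/Q/K/H strongly hydrophilic, L/I/V/A/M/F
  strongly hydrophobic, S/T/Y/W weakly hydrophilic, and P, G, C each a
  class of their own (6 classes).

Angles of exactly ±180° are both legal; +180° falls in the last class of
each scheme.

## The 129-dimensional encoding

Each fragment is encoded as the concatenation of three feature
families (129 dimensions at $L=9$):

**Composition (37 dims).** Class frequencies within the window, pads
included, for the five tracks: amino acids (21), secondary structure
(4), RSA class (5), phi class (3), psi class (4). Each sub-block is
`counts / L` and sums to 1.

**Positional conservation (2L×5 = 90 dims).** For each track a
*position weight matrix* is fitted on the positive training fragments
and another on the negative ones. With $n_{ij}$ the count of class $j$
at window site $i$ and $N_i$ the number of training fragments, the
pseudo-count probability is

$$p_{ij} = \frac{n_{ij} + \sqrt{N_i}/q}{N_i + \sqrt{N_i}}$$

and the matrix element is the log-odds $m_{ij} = \ln(p_{ij}/p_{0j})$
against a background $p_{0j}$. The $\sqrt{N}$ pseudo-count guarantees
$\sum_j p_{ij} = 1$ exactly and keeps unseen classes finite. $q$ counts
the pad class (21, 4, 5, 3, 4 per track). A fragment contributes, per
track, its $L$ positive-matrix scores followed by its $L$
negative-matrix scores at the observed classes.

The background probability is not pinned down by the formulation, so the
package makes it explicit: the default (`background = "empirical"`) is
the pseudo-count-smoothed class frequency pooled over *all* sites of the
combined positive-plus-negative training fragments — the conventional
reading of "background" — and `background = "uniform"` gives
$p_{0j} = 1/q$ for the alternative reading. The smoothing keeps
$p_{0j} > 0$ so no log-odds is infinite even for classes absent from
training.

**Physicochemical entropy (2 dims).** Shannon entropy (base 2) of the
window's residues over the 6 hydropathy classes and the 3 charge
classes, $H = -\sum_j p_j \log_2 p_j$ with $p_j = n_j/N$. Pads are
excluded and $N$ is the number of real residues: charge and hydropathy
are undefined for a placeholder, and including pads would add an
artificial class that dilutes terminal windows. Entropies are bounded
by $\log_2 6$ and $\log_2 3$ respectively.

Feature order is fixed and documented (composition, then conservation
track-by-track, then entropy) and every column is named in the written
matrix, so encodings are auditable.

## Classifier and training

The classifier is a fully-connected network written directly in R
matrix code: ReLU hidden layers of one shared width, a single sigmoid
output unit, binary cross-entropy loss, and Adam updates at the
conventional step size $10^{-3}$. Inputs are standardized with
training-set statistics only; zero-variance columns are pinned to zero
both in training and at prediction, so constant features can never leak
information or explode after shifting. A stratified 10% of the training
rows is held out as an early-stopping monitor: when its accuracy has
not improved for 10 consecutive epochs, training stops (cap 200
epochs) and the weights of the stopping epoch are kept. Given the
configured seed, training and prediction are bit-reproducible.

The probability threshold is 0.5 with the boundary counted as a
positive call.

## Hyper-parameter search

`coordinate_search()` optimizes the number of hidden layers, the hidden
width and the batch size in that fixed order: while one parameter sweeps
its grid exhaustively (layers 1–8; width and batch 2, 4, …, 128) the
others are held fixed, and each optimized value is frozen before the
next sweep — exactly $|g_1| + |g_2| + |g_3|$ model evaluations. The
not-yet-optimized parameters start at the mid-grid values 32/32 (the
starting point is configurable). The objective is the pooled MCC of an
inner stratified cross-validation; grids are swept in increasing order
and only a strict improvement replaces the incumbent, so ties resolve
to the smallest — i.e. cheapest — value. Learning rate is deliberately
not searched and stays fixed.

## Evaluation protocol

`metrics()` computes Sn, Sp, Acc (percentages) and MCC from the
confusion counts; a vanishing MCC denominator is defined as 0, the
standard convention where the coefficient is otherwise undefined.

Three protocols are provided:

1. **Stratified fivefold CV** (`kfold_cv`) on the full imbalanced
   fragment set. The PWMs and the standardizer are refitted inside
   every training fold — fitting them on all data would leak test
   windows into the features. Folds are fragment-level and stratified
   by default; `group_by_chain = TRUE` keeps chains whole for the
   stricter variant, since the natural sampling unit of real data is
   the chain.
2. **Averaged undersampling** (`undersample_eval`): each of 10 repeats
   draws, without replacement, exactly as many negatives as there are
   positives, runs the fivefold CV on the balanced set, and the four
   metrics are arithmetically averaged over repeats (averaging the
   metrics, not the confusion counts, is the plain reading of
   "average of the 10 results"; per-repeat dispersion is reported).
3. **Chain-level independent test** (`chain_split` +
   `independent_eval`): whole chains are assigned 80/20
   (`floor(0.8 n)` to training — 1237 chains give 989/248), models are
   trained on balanced draws from the training chains only, and every
   fragment of the withheld chains is scored. No chain ever straddles
   the split.

A single user seed drives everything through `derive_seed()`, a fixed
Lehmer-style congruence mapping (seed, stage, index) to per-stage
seeds, so one integer reproduces a full run.

## The synthetic proteome generator

Real benchmark data require a curated binding-site database and an
external structure predictor, so the package ships a generator that
emulates all three inputs jointly with a plantable association between
labels and features. Binding positions are drawn per residue at
`binding_rate`; residues at and adjacent (±1) to binding positions have
the log-probability of D/E/N boosted by `signal_strength`, secondary
structure is tilted toward coil, and RSA toward the buried classes —
the signature of genuine Ca²⁺/Mg²⁺ coordination sites, chosen so that
every feature family (composition, conservation, entropy) carries
recoverable signal. Dihedral angles carry no planted signal and act as
distractor tracks. Structure values are drawn uniformly inside each
class interval, so discretization never clamps; `structure_noise`
redraws a fraction of structure annotations from the background to
emulate predictor error.

Defaults — 200 chains of 50–150 residues, `binding_rate = 0.01`,
`signal_strength = 2.5`, `structure_noise = 0.05` — are fixed study
conditions, not tuning knobs: the binding rate reproduces the
~1–2% positive fraction of real Ca²⁺/Mg²⁺ data, a log-odds boost of 2.5
(≈ 12-fold preference) reflects the strong acidic-residue enrichment of
real coordination shells, and 5% annotation noise is a conservative
error rate for modern structure predictors. What the generator does
*not* emulate: homology between chains (no redundancy structure),
long-range sequence dependence, the true joint distribution of
secondary structure and accessibility, or database-scale fragment
counts. Passing the recovery tests therefore demonstrates that the
pipeline extracts a planted local signal through the full protocol —
not that any particular accuracy will be attained on curated real data.

On these defaults the balanced undersampling protocol recovers the
planted signal with pooled MCC well above 0.5, while shuffling the
labels (5 seeds) leaves the mean |MCC| below 0.1; the chain-level
independent test, scored on the imbalanced withheld chains, lands at a
much lower MCC with high sensitivity — the same qualitative gap between
balanced CV and independent testing that motivates reporting both.

## Numerical and design notes

* External files are 1-based (PDB/BioLip convention); all internal
  indices are 0-based.
* Chains shorter than 50 residues are dropped at join time (the
  dataset inclusion rule); redundancy and resolution filtering are out
  of scope and assumed applied upstream.
* Non-standard residues map to 'X' and share the pad class downstream,
  keeping the alphabet closed at 21 symbols; fragments centred on 'X'
  are kept by default (`drop_x_centers` removes them).
* Feature matrices and PWMs are serialized as delimited text at 17
  significant digits, which round-trips IEEE doubles exactly.
* PWM row sums are exact to 1e-12 by construction and asserted in the
  tests.
* Sn/Sp are reported as `NaN` when their own class is absent from the
  evaluated set; this cannot occur in the stratified protocols.
* Test and acceptance problem sizes — 200 chains (~20,000 fragments)
  for recovery runs, 10–60 chains for protocol contract tests, 10
  undersampling repeats with fivefold CV — were chosen so the balanced
  training sets (a few hundred fragments) train in well under a second
  while leaving the binomial noise on every asserted quantity an order
  of magnitude below its acceptance margin.

## Limitations

The encoder uses no evolutionary information (no PSSM from database
search), window length is a single global parameter, and the classifier
is a plain feed-forward network — all deliberate scope choices. Real
predicted-structure inputs are expected in the documented table format;
the package does not run a structure predictor itself.
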