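---
title: "Methods: structural longevity, order content, and order–disorder concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural longevity, order content, and order-disorder concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexlens)
library(dplyr)
```

## The problem

Intrinsically disordered regions (IDRs) lack a fixed native conformation.
Sequence-based disorder predictors disagree with one another, and regions
that move vigorously in molecular dynamics (MD) simulation are sometimes
missed by every predictor. flexlens implements a per-residue,
simulation-derived view of order and disorder and compares it, region by
region, against two families of sequence-based tools: secondary-structure
predictors (whose per-residue accuracy and confidence dip in flexible
regions) and disorder predictors (whose scores should rise there). The
package consumes the *outputs* of those tools — DSSP label trajectories,
PSIPRED-`.ss2`-style prediction tables, IUPred-style score tables,
Cα coordinate trajectories — and never runs MD or the predictors
themselves.

## Structural longevity

Given a trajectory of DSSP eight-state labels (one label per residue per
frame), each residue's label sequence is split into maximal constant runs.
The default longevity statistic is the average run length divided by the
total number of frames,

$$
L_i \;=\; \frac{\operatorname{avg}_r(\ell_{i,r})}{N}
\;=\; \frac{1}{R_i},
$$

where $\ell_{i,r}$ are the run lengths, $N$ the frame count and $R_i$ the
number of runs. We compute it as $1/R_i$ — the algebraic simplification —
so the value is exact in floating point. $L_i = 1$ means the assignment
never changed over the window; $L_i \to 1/N$ means it changed at almost
every frame. Because the statistic is a *rank* of persistence, downstream
comparisons use Spearman correlation, which is invariant to the
nonlinearity of $1/R$.

Two alternative summaries are exposed because "average persistence" is
genuinely ambiguous:

* `weighted` — the length-weighted mean run length over $N$,
  $(\sum \ell^2 / \sum \ell)/N$: the expected length of the run containing
  a randomly chosen frame. It dominates the mean mode on every series
  (length-biased sampling), which we property-test.
* `exp` — $\sum (b^{\ell} - 1)/(b^{N} - 1)$ with $b > 1$ (default 2),
  which rewards long constant stretches exponentially. The default stays
  the arithmetic form because it is the one with a closed definition; the
  exponential variant is provided rather than silently substituted.

`select_window()` restricts a trajectory to its trailing fraction
(default 0.3) before scoring, mirroring the common practice of analysing
only the equilibrated last stretch of a production run — e.g. the last
300 ns of a 1 μs simulation sampled every 200 ps (450 of 1500 frames).

## Order content and binning

A chain's structured content is scored by collapsing Q8 to Q3
(`H,G,I → H`; `E,B → E`; `T,S,C → C`), finding maximal helix/strand runs,
and summing $b^{\ell}$ over runs (default $b = 2$), normalized by chain
length. The exponential makes a few long structured elements count far
more than many fragments of the same total length; the base is
configurable because the scale is arbitrary-units — only the induced
ranking matters for binning. `assign_bins()` places proteins into bins of
increasing content at score quantiles by default; fixed edges can be
supplied when a particular partition is wanted. Ties go to the lower bin,
and an all-tied population collapses into bin 1 with a warning rather
than an error.

## Predictor evaluation

`signed_confidence()` scores each residue as $\pm\max_c p_c$: magnitude =
the predictor's maximum class probability, sign = whether the predicted
label matches the reference. Q8→Q3 collapse is many-to-one, so a correct
Q8 call is never made incorrect by the collapse; Q3 accuracy therefore
dominates Q8 accuracy, which we test exactly. Per-protein accuracy is
residue-averaged; per-bin accuracy is then protein-averaged (not
residue-pooled), with a two-sided Student-t interval on the bin mean
(default level 0.95), clipped to $[0,1]$ for reporting. The t construction
over proteins was an open choice; we prefer it because proteins, not
residues, are the sampling unit of a bin.

## RMSF

`rmsf_profile()` computes
$\mathrm{RMSF}_i = \sqrt{\tfrac1T \sum_t \lVert x_i(t) - \bar x_i \rVert^2}$
from a per-residue point trajectory (Cα-level; Å). With `align = TRUE`
each frame is superposed on frame 1 by the Kabsch algorithm (SVD of the
cross-covariance with a determinant sign correction so reflections are
never applied), and one refinement pass re-superposes all frames onto the
mean structure. Full iterative convergence changes values by far less
than the statistical noise at these trajectory lengths, so a single pass
is the default; `reference = "frame0"` skips it. Superposition weights
are uniform. For isotropic Gaussian fluctuation with per-axis standard
deviation $\sigma$, $\mathrm{RMSF} = \sigma\sqrt{3}$, which anchors the
closed-form tests and lets $\sigma$ be read back as
$\mathrm{RMSF}/\sqrt3$.

## Region calling and concordance

Profiles become regions in three steps: centred moving-average smoothing
(default window 5 residues; truncated at the ends), thresholding
(longevity below 0.2; signed confidence below 0; disorder score at or
above 0.5), merging runs separated by at most 2 non-qualifying residues,
and discarding merged runs shorter than 3 residues. A region's score is
the mean of the *raw* profile over it. Disorder consensus counts, per
residue, the predictors at or above threshold and calls regions where at
least $k$ (default 2 of 3) agree; the count profile is deliberately not
smoothed (window 1) so consensus boundaries stay exact. Discordant
regions are low-longevity regions whose overlap with every consensus
region is below `min_overlap` (default 1 residue) — flexible in
simulation, silent in every predictor.

No community standard defines these thresholds numerically; all are
declared, exposed, and deliberately conservative. Disorder inputs are
required pre-normalized to $[0,1]$; no predictor-specific calibration is
attempted.

`concordance_analysis()` bundles the region calls with pairwise Spearman
correlations between longevity, signed confidence, mean disorder and
RMSF; `tidy()` returns the regions, `glance()` a one-row summary,
`autoplot()` the profile/region figure.

## What the synthetic generator emulates — and what it does not

All generators hang off a latent per-residue flexibility $\phi \in [0,1]$:
block-constant (0.9 in coil runs and planted blocks, 0.1 in structured
runs) plus ±0.05 uniform jitter, so planted regions have crisp boundaries
for recovery tests.

* **Labels** (`sim_reference`): alternating structured/coil runs with
  geometric run lengths (defaults: helix mean 8, strand 5, coil 4
  residues, helix:strand mix 0.6:0.4 in population fixtures) at chain
  length 200 — the mid-sized single-domain scale the length filter
  (200 ± 20) targets.
* **Dynamics** (`sim_trajectory`): per-frame label flips with probability
  $f = f_{\min} + (f_{\max}-f_{\min})\phi$, new label uniform over the
  seven other states; defaults $f_{\min}=0.01$, $f_{\max}=0.9$ over 1500
  frames, the regime used for the rank-recovery check
  ($\rho(L, \phi) \le -0.9$).
* **Predictions** (`sim_predictions`): correct with probability
  $a = a_{\max} - (a_{\max}-a_{\min})\phi$ (defaults 0.9 → 0.5), emitted
  label carrying mass $q = 0.5 + g(a-0.5)$ (gain $g = 0.8$). With
  $\phi$ tied to coil content this puts per-protein accuracies in the
  0.6–0.8 band across the content range, the realistic operating range
  for three-state predictors.
* **Disorder** (`sim_disorder`): $\mathrm{plogis}(8(\phi-0.5)) +
  \mathcal N(0, 0.05)$, clipped; inside planted *blind* regions the score
  is computed from $\phi = 0.1$ regardless of the true $\phi$ — these are
  the ground-truth discordant regions.
* **Coordinates** (`sim_coordinates`): an ideal helix-like mean curve
  (1.5 Å rise, 2.3 Å radius, ~100° twist per residue) plus isotropic
  Gaussian noise with $\sigma = \sigma_{\min} +
  (\sigma_{\max}-\sigma_{\min})\phi$ (defaults 0.5–3 Å), optionally
  wrapped in a random per-frame rigid transform to exercise
  superposition.

Every generator takes a single integer seed and restores the caller's RNG
state; fixed seed means bit-identical output.

What is *not* emulated: real DSSP transition structure (flips are uniform
over the other seven states), amino-acid composition biases of real IDPs,
anisotropic or correlated atomic motion, and predictor error structure
beyond the monotone link to $\phi$. Passing tests therefore demonstrate
that the statistics recover *planted* structure under the stated noise
model — not that any particular real protein family behaves this way.

### The region-recovery fixture

Recovery tests plant three 21-residue flexible blocks on an otherwise
rigid 200-residue chain (`coil_flexible = FALSE`) and use a 200-frame
trajectory with $f_{\min}=0$, $f_{\max}=0.05$. The rates follow from the
statistic itself: mean-mode longevity is approximately $1/(1+(N-1)f)$, so
with the default call threshold of 0.2, rigid residues
($\phi \approx 0.1$, $f \approx 0.005$) sit near 0.4–0.5 and flexible
ones ($\phi \approx 0.9$, $f \approx 0.045$) near 0.1 — a comfortable
margin on both sides. Flip rates fast enough to randomize labels within a
frame or two would push *every* residue below any fixed threshold at
window lengths of hundreds of frames; discriminating regions requires the
rigid scaffold to hold its label for a substantial fraction of the
window, which is what these rates encode. Disorder predictors in the
fixture are blinded to the middle block, which the discordant call must
recover (residue-level Jaccard ≥ 0.8 for both checks).

## Numerical choices and degenerate inputs

* Probability class order is fixed (Q3 `C,H,E` as in `.ss2`; Q8
  `H,G,I,E,B,T,S,C`); argmax ties resolve by this order, and a file label
  disagreeing with the argmax is kept with a warning.
* Prediction probability rows summing within $[0.99, 1.01]$ are
  renormalized; anything further off is an error, as are scores outside
  $[0,1]$ anywhere (rejected, never clamped).
* Blank DSSP structure codes read as coil; `-` in label matrices
  likewise. Both mappings are idempotent.
* Region coordinates are 1-based inclusive in memory, BED-style 0-based
  half-open on disk.
* Kabsch superposition refuses fewer than 3 points or rank-deficient
  (collinear) configurations rather than returning an arbitrary frame.
* Zero-variance inputs to the rank correlation are an error, not `NA`:
  a silent `NA` propagates too easily into region summaries.
* Missing residues are excluded from accuracy denominators, never
  imputed.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in well under a minute: chains of 150–200
residues, trajectories of 200–1500 frames (5000 for the RMSF closed-form
check, where the $\sqrt3$ tolerance is 5%), populations of 60–100
proteins for binning, and 1000-case property sweeps for the exact
identities. These sizes are stated here as the package's own test design;
all statistics scale linearly in frames × residues.

## Known limitations

* Longevity treats label changes as exchangeable: a coil↔turn flicker
  counts the same as helix↔strand. On real trajectories coil/turn
  alternation dominates low-longevity regions, so mean-mode values skew
  low there; the Q3-collapsed trajectory can be scored instead by mapping
  labels before `longevity_profile()`.
* The order score's exponential base is a free parameter; only ranks are
  comparable across choices.
* Region thresholds are fixed, not adaptive; profiles with drifting
  baselines (e.g. temperature ramps) need pre-normalization.
* The consensus machinery treats disorder predictors as exchangeable
  $[0,1]$ score sources; predictors on other scales must be normalized
  upstream.
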