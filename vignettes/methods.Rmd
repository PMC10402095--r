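---
title: "Modeling graded sequence representations in multivoxel patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling graded sequence representations in multivoxel patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqgauss)
```

## The problem

When people learn a fixed sequence of environments, cueing one environment
can reactivate its neighbors in a graded way: nearby past and future
environments more strongly than distant ones. seqgauss implements an
analysis pipeline that quantifies this gradedness from multivoxel activity
patterns. Participants learn two *maps* of eight environments each; within a
map the same eight environments form two circular *paths* (green and blue)
in different orders. During an anticipation task a participant sees a cue
environment plus a path color; the cue-period activity pattern is compared
with *environment templates* — average activity patterns for each
environment, estimated from the other participants' localizer data — and
the resulting similarity values are arranged by signed circular distance
from the cue along the cued path. On an eight-long circle the four-step
neighbor is the same environment forward and backward, so its one
similarity value occupies both end positions; a cue-centered profile
therefore has 9 positions carrying 8 distinct values.

## The similarity model

The profile is fit with an asymmetric Gaussian,

$$\hat y(d) = b + A \exp\!\left(-\frac{d^2}{2\sigma(d)^2}\right),
\qquad \sigma(d) = \begin{cases}\sigma_b & d < 0\\ \sigma_f & d \ge 0,\end{cases}$$

with amplitude $A$ (peak height above the asymptote, in correlation units),
asymptote $b$, and separate forward/backward widths in steps. The fit
minimizes the squared residuals over the 9 points (the duplicated four-step
value contributes two residual terms) plus an L2 penalty
$\lambda\,(A^2 + b^2)$ with $\lambda = 0.01$; widths are bounded in
$(0, 10]$. The functional form above is the package's explicit commitment:
a two-sided Gaussian, continuous at the cue, with $A$ measured relative to
the asymptote.

Numerically, $A$ and $b$ are profiled out in closed form (for fixed widths
the penalized objective is a 2×2 ridge problem), and the remaining 2-D
width search uses a deterministic multi-start: a grid of width pairs from
0.1 to 8 steps is screened by direct evaluation, the best starts are
refined by Nelder–Mead, and the winner is polished at tight tolerance. Ties
prefer the narrower solution. Two deliberate numerical choices deserve
note:

* **Canonical orientation.** A profile and its mirror image are fitted via
  bit-identical arithmetic (the input is flipped to a canonical orientation
  and the widths swapped back), so mirror equivariance holds to machine
  precision rather than to optimizer tolerance.
* **Plateau collapse.** Below roughly $\sigma = 0.1$ the Gaussian basis
  underflows to an indicator at $d = 0$, leaving the objective numerically
  flat in that width; such plateaus are collapsed to the lower width bound
  so results are deterministic and the narrower-wins tie-break is
  canonical.

Two properties of the penalized model are easy to miss. A perfectly flat
profile is *not* fit by $A = 0$: splitting the constant between $A$ and $b$
at the width bound halves the penalty, so the optimum carries $A \approx
c/2$ with a near-flat curve. And the penalty shrinks $A$ more for wide,
flat profiles (as the basis approaches the intercept the two become less
identifiable), so the fitted amplitude declines by about 4% across widths
1.2–2.4 steps even for noiseless curves of constant amplitude — a small
deterministic width–amplitude coupling inherent to regularization, which is
why the independence checks below assert a magnitude band rather than a
rank correlation.

## Inference

Group-level support for the Gaussian uses leave-one-participant-out
cross-validation: the model is fit to the position-wise mean profile of all
but one participant and scored (sum of squared errors) on the held-out
profile; the mean over held-out choices is the observed error. The null
distribution shuffles, independently per participant per iteration, the 8
distinct values across the distinct circular positions (7 values when the
cue is excluded), rebuilds the profile with the four-step duplication, and
recomputes the error. The p-value is the fraction of shuffles with strictly
smaller error, and $R^2 = 1 - \text{observed}/\text{mean null}$, positive
exactly when the true ordering fits better than the average shuffle. Two
variants are reported: *including cue* (all 9 points) and *excluding cue*
(the cue's own value removed), the latter isolating graded structure beyond
cue reinstatement. Context specificity is tested by re-arranging the same
similarity values by the uncued path's order, and by a paired contrast of
cued vs uncued fit errors against the paired shuffled differences.
Parameter-level tests (amplitude above, asymptote below the different-map
baseline; Wilcoxon signed-rank on the two widths) are gated on a
significant permutation test. Shuffling operates on participant-mean
profiles, after trial-type averaging; 10000 shuffles for faithful runs and
200 in simulation studies.

## The synthetic generator and what it does (not) emulate

Every stage is driven by a generator that plants known structure:

* **Designs.** Green orders are sampled uniformly; the blue path applies
  one position reshuffle, shared across maps, sampled by rejection until
  (i) every environment's one- and two-step neighbors differ between paths
  and (ii) the number of far-offset coincidences (three- and four-step
  neighbors shared between paths) is the minimal achievable value of 2 —
  exhaustive enumeration shows zero is impossible on an eight-cycle, and
  3536 of the 40320 orderings satisfy (i) alone. Requirement (ii)
  operationalizes "as distinct as possible".
* **Patterns.** Environment tuning rows are independent unit-variance
  vectors; localizer betas add isotropic Gaussian noise; cue-period
  patterns are mixtures of the surrounding environments' tuning along the
  cued path, weighted by a planted asymmetric Gaussian (defaults $A = 1$,
  $b = 0.05$, $\sigma_f = 1.5$, $\sigma_b = 2.5$ steps; the four-step
  weight applied once). No structure is planted along the uncued order.
* **Behavior.** Steps-balanced trials with RT linear in steps
  (126 ms/step, 1000 ms intercept, 150 ms noise) and Bernoulli accuracy
  (86.86%). A coupling knob ties a participant's RT slope to their planted
  asymptote for linkage recovery studies.

The generator works at the beta level (no hemodynamics, no nuisance
structure) and uses spatially independent noise; passing tests therefore
validate the analysis logic, not robustness to autocorrelated fMRI noise.

Two study conditions are used throughout and are deliberately different.
The *recovery default* (2000 voxels, noise sd 0.5) yields near-noiseless
profiles for parameter-recovery checks; recovered widths land within 20%
of the planted 1.5/2.5 with the forward<backward ordering essentially
always. The *inference calibration* (156 voxels, anticipation noise sd 50)
reproduces a realistic hippocampal effect scale — on the order of 156
reliable voxels and fitted amplitudes of a few hundredths (mean ≈ 0.03,
participant sd ≈ 0.02), typical of hippocampal pattern-similarity
effects — and is where the specificity and workflow analyses run. The
calibration matters scientifically: because one reshuffle is shared per
study, the uncued arrangement of the planted weights is itself a fixed,
group-consistent pattern; enumeration shows it necessarily retains at
least two far-offset coincidences, and at unrealistically clean SNR the
uncued ordering becomes genuinely (if weakly) Gaussian-detectable. At the
hippocampal effect scale the cued ordering is detected while the uncued
ordering behaves as a null in most but not all runs — a property of the
circular design geometry worth knowing when interpreting uncued-path
nulls.

A related measurement fact: planting a width gradient with constant
pattern-level amplitude induces a gradient in *measured* amplitude at high
SNR, because a wider profile carries more signal energy and inflates the
correlation denominator. This mirrors the negative amplitude gradients
seen in real data and is why the hierarchy analyses pair the raw width
gradient with a partial correlation controlling amplitude; the volumetric
independence simulations run in the noise-dominated regime where the
coupling vanishes.

## Searchlight and hierarchy

The volumetric stage moves a 7-voxel cube across the grid in steps of 2
(cubes extending past the edge are dropped), keeps cubes with at least 64
environment-reliable voxels (across-participant tuning reliability ≥ 0.1,
inclusive), runs the full similarity-and-fit stage per participant per
cube, computes a goodness of fit $g = 1 - \text{SSE}_\text{correct} /
\overline{\text{SSE}}_\text{shuffled}$ from order shuffles of that
participant's profile, and assigns cube results to every member voxel;
voxels in several cubes get the unweighted average. Group maps use a
one-sided t-test on $g$ with optional Benjamini–Hochberg correction (a
deliberate simplification of cluster-enhanced permutation inference).
Posterior–anterior gradients are per-participant Spearman correlations
between a fitted parameter (by default the mean of the two widths) and the
voxel y-coordinate, tested against zero across participants; a partial
variant residualizes ranks on a control parameter. Across-region
hierarchies correlate region-mean widths with the region's rank along an
ordered list. When a planted gradient makes every participant's
correlation exactly 1, the group t-statistic is 0/0; the package reports
this as overwhelming evidence (p = 0) rather than erroring.

## Problem sizes and determinism

Simulation studies in the test-suite and acceptance script use 8–32
participants, 156–2000 voxels, 200 shuffles, and 50–500 replicates per
property — sizes chosen so each study answers its question with margin on
a single CPU. All generators and permutation engines draw from R's RNG and
are exactly reproducible given a seed; the pipeline derives every stage's
seed from one master seed.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  seed = 1, n_shuffles = 1000,
  synthetic = synthetic_config(n_participants = 32, n_voxels = 156,
                               anticipation_noise_sd = 50))
report <- run_pipeline(cfg)
print(report)
```

The numbered scripts under `analysis/` run the same stages as a narrated
workflow and write their tables under `results/`.

## Known limitations

* Beta-level generation: no hemodynamic convolution, motion, or
  physiological artifacts; spatial noise is independent across voxels.
* The uncued-order null is mildly anticonservative at high SNR for the
  geometric reasons above.
* Cluster-enhanced permutation inference and mixed-effects models of the
  behavioral and width data are out of scope; per-participant tables
  export as TSV for external modeling.
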