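---
title: "Modelling and measuring the larval Hunch/Head-Cast decision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring the larval Hunch/Head-Cast decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hunchcast)
```

## The scientific problem

When a *Drosophila* larva is hit by an air puff it chooses between two
mutually exclusive startle actions: a protective **Hunch** (head retraction
with body contraction) or an exploratory **Head Cast** (lateral head sweep).
The choice is implemented by a small ventral-nerve-cord circuit and is
biased by the animal's feeding state: sucrose-fed larvae cast more and hunch
less. `hunchcast` provides the three computational layers needed to study
this phenomenon end to end:

1. a **rate model** of the seven-population decision circuit, with
   neuromodulation and silencing variants;
2. a **kinematics and annotation pipeline** turning 11-point midline tracks
   into per-frame features, stride/run/pause epochs, and mutually exclusive
   action labels;
3. **behavioural statistics** built for this assay (the $\Theta$ resampling
   estimator, generalized likelihood-ratio transition tests, MMD two-sample
   tests on posture embeddings, calcium-response metrics),

plus a **synthetic-data generator** that produces tracks, cohorts, counts,
point clouds and fluorescence traces with known ground truth, so that every
stage is testable without any recorded data.

## The circuit model

Each population (MCh mechanosensory input; Basin-1/Basin-2 projection
neurons; feedforward inhibitory interneurons iLNb and iLNa; feedback
inhibitory interneurons Handle-a and Handle-b) is a single rate unit. The
connectivity was extracted from synaptic counts in the larval connectome and
is hard-wired in `build_circuit()`; the one free synapse is the MCh→iLNa
weight $w_\mathrm{iLNa}$, scanned over $[0.5, 1.5]$ to emulate the variety
of stimuli larvae receive. The dynamics are

$$\tau \dot r = -V_0 - r + s + i + \mathrm{recurrent}(r),$$

with per-population time constants $\tau$, thresholds $V_0$, a constant
stimulus $s$ entering only at MCh, and tonic input $i$ entering only at Hb.
Rates are clamped nonnegative: whenever a component of $r$ falls below
$10^{-9}$, negative derivative components are zeroed.

### The recurrent term and why it has three forms

The recurrent drive combines the excitatory and inhibitory coupling
matrices $A^{ex}$, $A^{in}$ with a gain $k_{ex}(r^{max} - r)$ that shuts
excitation down as a unit approaches its maximum rate. The package
implements three variants (argument `coupling` of `circuit_spec()`):

* `"shunting_exc"` (default):
  $k_{ex}(r^{max}-r)\odot(A^{ex}r) - A^{in}r$ — the saturating gain
  applies to excitation; inhibition is subtractive.
* `"shunting_all"`: $k_{ex}(r^{max}-r)\odot((A^{ex}-A^{in})r)$ — the gain
  multiplies the net drive.
* `"literal"`: the same with the gain written $k_{ex}(r-r^{max})$, under
  which excitatory input *suppresses* sub-maximal units; retained only for
  comparison.

The default was chosen on dynamical grounds. Under `"shunting_all"` the
loop gain at the printed parameters is so large that every recruited
population pins at either $0$ or $\approx r^{max}$: the circuit becomes a
binary switch in which the two neuromodulation parameters move the
decision threshold by only $\sim 10^{-3}$ in $w_\mathrm{iLNa}$, the
feedback unit Hb stays silent unless the stimulus exceeds $\sim 62$ a.u.,
and silencing experiments have no effect outside a sliver of parameter
space. Under `"shunting_exc"` the attractors are graded (B1 $\approx 12$,
B2 $\approx 7$ a.u. in the coactive state), $r^{max}_\mathrm{iLNa}$
multiplies iLNa's excitatory drive — so lowering it genuinely saturates
the population's response, which is exactly the stated interpretation of
that manipulation — and both modulations shift the transition threshold
by visible amounts with the correct signs. All headline analyses therefore
run under `"shunting_exc"`.

### Stimulus amplitude

The stimulus amplitude is not printed anywhere; it is the one tuning
parameter the package had to fix. We require (i) both attractors to be
reachable as $w_\mathrm{iLNa}$ spans $[0.5, 1.5]$, (ii) the full circuit —
including the feedback units — to be engaged in the coactive state, and
(iii) graded (non-pinned) rates. Under the default coupling this holds for
$s \approx 1\text{–}2.5$ a.u.; the default is $s = 1.5$ a.u., which places
the fed-state transition near $w_\mathrm{iLNa} \approx 1.09$, mid-range of
the scan. The value is exposed as `stimulus_amplitude` and every
qualitative result below is robust across the working range.

### States, labels, phase diagrams

`steady_state()` integrates from rest with the stimulus held on until
$\max|\dot r| < 10^{-6}$ (cap: $50\max\tau$). The outcome is classified two
ways: by k-means ($k = 2$, 10 restarts, seeded) on the (B1, B2) rates —
the cluster with higher B2 is *coactive* (Head Cast) — and by the scalar
$r_{B2}/r_{B1}$ with a 0.1 cut-off (`ratio_label()`). On the standard scan
the two labelers agree on 100% of grid points.

`phase_diagram()` scans $w_\mathrm{iLNa}$ against one neuromodulation
parameter ($r^{max}_\mathrm{iLNa}$ or $i_{Hb}$) and extracts, per
modulation value, the transition threshold as the midpoint of the grid
interval bracketing the first monoactive cell. Thresholds are not
root-polished: the grids are cheap to refine, and the midpoint convention
keeps the estimate monotone with the labels. Cells that do not converge
(boundary chatter of the positivity clamp can occasionally defeat the
adaptive solver) are flagged, excluded from threshold extraction, and
reported with a warning.

The model's headline predictions, all recomputed by the test suite and
`scripts/acceptance.R`:

* fed state: coactive below, monoactive above a threshold inside
  $[0.5, 1.5]$;
* lowering $r^{max}_\mathrm{iLNa}$ (17–20 a.u.) raises the threshold
  monotonically — more Head-Cast territory;
* raising $i_{Hb}$ (0–10 a.u.) raises it too;
* the combined sucrose state ($r^{max}_\mathrm{iLNa}=18$, $i_{Hb}=10$)
  has a strictly higher threshold than the fed state;
* silencing Hb increases iLNa activity (time integral over the stimulated
  epoch), more strongly in the sucrose state; silencing iLNa strongly
  increases Hb activity.

Silenced populations are removed by clamping both their rate and
derivative at zero, not by zeroing their output column, so the silenced
unit itself is dark in the reported trajectories.

## Kinematics

Tracks are 11-point midlines (head = point 1) at the tracker's irregular
framerate. Because tracking software does not always emit the spine
head-first, preprocessing first applies an orientation check — the head
accumulates more path than the tail over a recording — and flips the point
order when needed. `preprocess_track()` interpolates to a 0.1 s grid and applies a
zero-phase Butterworth low-pass at 2 Hz. The filter is 6th order: a
zero-phase 2nd-order design attenuates the dominant ~1.4 Hz crawl rhythm
by ~19%, which would corrupt stride detection, whereas the 6th-order
zero-phase response passes 1.4 Hz with <2% loss and rejects 5 Hz jitter by
>4 orders of magnitude. Odd-reflection padding suppresses filter edge
transients.

Feature definitions (all speed-like features in body lengths per second,
using the median midline length as the body length):

* **scaled speeds** of head, midline centroid $G$ (the mean of the 11
  points — the package's documented stand-in for the tracker's centre of
  mass) and tail;
* **nematic order** $S = (3\langle\cos^2\theta\rangle - 1)/2$, with
  $\theta$ the angle of each of the 10 segments to the tail→head axis;
* **shape factor** $\lambda = (\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$
  from the eigenvalues of the point covariance averaged over a ±3-step
  window ("covariance of movement" is read as the window-averaged
  point-position covariance, an assumption recorded here);
* **axis ratio** $\|HG\|/\|TG\|$, guarded (NA) when the tail sits on $G$;
* **velocity projections/cosines** of head (tail) velocity on the first
  (last) spine segment, oriented outward through the head (tail);
* per-frame features are stacked over a 7-step window (±3 steps, edge
  replication at track boundaries) for classification.

Trajectory metrics use midline point 9, a stable rear point: cumulative
**pathlength**, straight-line **dispersal**, and the **straightness
index** — the dispersal-to-distance ratio in a trailing 20 s window, 0 for
no movement by convention, 1 for straight motion. Stride detection takes
the dominant crawl frequency from the periodogram of the scaled centroid
speed inside 0.5–2.5 Hz; a **stride** is an epoch between consecutive
strict local speed minima (plateaus break at the leftmost sample)
containing a peak ≥ 0.3 BL/s and lasting 0.7–1.5 expected cycles; **runs**
merge consecutive strides (gap ≤ 1 step); **pauses** are maximal
stride-free epochs below 0.3 BL/s throughout, with fragments shorter than
0.5 s (less than one peristaltic cycle) discarded as meaningless.

## Action annotation

Ten random forests, each trained on a bootstrap resample with class
weights inverse to class frequency, vote per timestep; ties go to the
rarer class (hunch > back_up > stop > static_bend > head_cast > small >
crawl). The original study fine-tuned a pre-trained hierarchy on manually
annotated data; this package reproduces the architecture and rules but
trains on synthetic fixtures with known labels — the published bar of
≥ 80% held-out accuracy per class is kept as the acceptance bar.

Post-processing follows three rules. **Regularisation**: two-step actions
are expanded by five steps on each side; remaining intervals under three
steps (0.3 s — biologically unrealistic) are absorbed into their context,
adopting the flanking label when both sides agree and the longer
neighbour's otherwise (the N±2 rule is narrative in origin; this reading
is a documented choice). The pass is idempotent. **Hunch rules**: at most
one post-stimulus Hunch per larva (later ones become Head Casts); a Hunch
whose *effective length change* — (baseline median length − minimum length
in the interval)/baseline — fails the line-specific threshold (0.3–0.6;
default 0.3; the quantity is named but not defined in the source
literature, so this definition is recorded here) is demoted to `small`.
**Bend split**: a bend is a Static Bend when at least a fraction P
(default 0.75, boundary inclusive) of its timesteps have scaled motion
speed below p (default 0.5) times the larva's pre-stimulus mean head
speed; P and p are line-specific and never printed, so the defaults were
chosen once so that the synthetic templates straddle them cleanly.

## Behavioural statistics

* **Action probabilities**: cumulative (fraction of larvae performing the
  action at least once in the 5 s post-onset window, denominators
  restricted to larvae tracked through the whole window) or
  corrected-mean (post-window occupancy minus the 30–50 s baseline), for
  actions frequent at baseline.
* **$\chi$ and $\Theta$**: $\chi = p_A - p_B$ per group;
  $\Theta = \chi(\text{test}) - \chi(\text{control})$, in $[-1,1]$,
  antisymmetric. The resampling test redistributes each window's pooled
  responders between the groups with hypergeometric draws (both groups
  share the window's rate under the null), recomputes $\Theta$, and
  reports the two-sided add-one p-value. The single-draw
  $\mathrm{Hypergeometric}(N_{all}, N, 1)$ scheme described in the source
  is degenerate as written (it yields a 0/1 indicator); it is retained
  behind `scheme = "literal"` for comparison. Null calibration at
  $N = 100$/group is verified by simulation in the test suite.
* **Transitions**: ordered label changes in a 2 s post-onset window, with
  an automatic 10 s fallback when fewer than 100 transitions are counted.
  Group comparisons use the generalized likelihood-ratio statistic
  $z = -2\log\{B(\pi,N_m,n_m)B(\pi,N_0,n_0)/[B(\pi_m,N_m,n_m)B(\pi_0,N_0,n_0)]\}$
  with the pooled $\pi$, $p = \chi^2(z, 1)$, computed in log space with
  $0\log 0 = 0$.
* **MMD**: unbiased U-statistic with Gaussian kernel
  $\exp(-\|x-y\|^2/(2\sigma^2))$, $\sigma = 2$ ("width 2" is read as the
  bandwidth; the width-as-denominator reading is an option). The unbiased
  form can be slightly negative on identical samples — intended.
  Permutation p-values use pooled relabelling with the add-one rule and
  optional Bonferroni adjustment for the number of comparisons in a
  screen (45 in the motivating analysis). Segment vectors for embedding
  comparisons take 5 evenly spaced centres in 60–65 s, a 2 s window each,
  and the reduced 5-point spine — points {1, 3, 6, 9, 11}, a choice the
  upstream encoder inherits without listing indices — giving 200-element
  vectors.
* **Imaging**: $\Delta F/F_0$ against the baseline-window mean, trial
  failure when the stimulus-averaged response does not exceed 10%, cohort
  failure rates over repeated trials, and the sucrose preference index
  $PI = (N_s - N_a)/N_{tot}$.

Two-sided tests are the default throughout; the exceedance rule of the
$\Theta$ test (count of $|\Theta^*| \ge |\Theta_{obs}|$) is this package's
formalisation of the original, loosely specified acceptance event.

## The synthetic generator

`gen_track()` animates parameterised caricatures of each action — these are
not biomechanical models, just kinematic templates rich enough to exercise
every feature and rule: peristaltic speed oscillation at 1.4 Hz with peak
0.5 BL/s for crawling (straddling the 0.3 BL/s stride bar), a 0.4 Hz
lateral head sweep for casts, a slow ramp into a held bend, a 40%
head-ward length contraction for Hunches (straddling the 0.3–0.6 length
threshold), immobility, and slow backward motion. Timestamps are jittered
in the raw 8–12 Hz band and coordinates carry 0.01 mm Gaussian noise.
`gen_cohort()` draws per-larva scripts semi-Markov-style — i.i.d. actions
with exponential durations from a baseline table, plus a single response
action drawn at stimulus onset (60 s; the only point a Hunch can start,
matching the biology of the startle) — so cumulative ground-truth
probabilities are exactly the configured response rates. Everything is
seed-deterministic and returns its ground truth.

What passing tests on these data do **not** show: robustness to real
tracking artefacts (segmentation errors, collisions, head/tail flips),
realistic within-class kinematic variability, or classifier transfer to
real larvae. They do show that every formula, rule and test in the
pipeline is implemented correctly and that the pipeline as a whole
recovers known ground truth.

## Numerical choices and problem sizes

Integration uses LSODA at rtol = atol = $10^{-3}$ with the positivity
clamp above; steady states use $\max|\dot r| < 10^{-6}$ with a
$50\max\tau$ cap, checked every 250 a.u. The solver is validated against
an independently coded explicit-Euler oracle (dt $= 10^{-3}$, endpoint
agreement within 1%) on random circuit parameterisations whose dynamics
converge; random parameterisations that chatter on the positivity
boundary are reported as non-converged rather than compared. Default
problem sizes in the tests and the acceptance script — 21-point weight
scans, 500 outer replicates for $\Theta$ calibration at $n_{sim} = 10^3$,
200 runs at $B = 200$ permutations for MMD, cohorts of 40 larvae at 95 s,
four training larvae for the classifier — were chosen as the smallest
sizes at which the binomial/exact comparisons in the tests are
informative.

## Known limitations

* The circuit model's stimulus amplitude is a package choice (see above);
  absolute rate values are in arbitrary units and only orderings and
  threshold shifts are interpreted.
* The coupling-form question cannot be settled from the printed equation
  alone; the package makes its choice explicit and keeps the alternatives
  one argument away.
* The frame classifier ships untrained; users with annotated data should
  train on it rather than on the synthetic fixtures.
* The MMD layer expects embeddings from an external encoder; the package
  generates Gaussian stand-ins for calibration only.
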