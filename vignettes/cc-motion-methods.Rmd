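---
title: "Detecting co-confident motion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting co-confident motion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmotion)
```

This vignette documents the scientific and numerical choices behind
`ccmotion`: what each stage of the co-confident (CC) motion pipeline
computes, which parameters matter and why their defaults are what they are,
what the synthetic follower does and does not emulate, and where the design
was genuinely open.

## The stimulus model

A trial is a 60-second, one-dimensional rhythmic motion made of *sections*,
each defined by an oscillation frequency $f$ (Hz) and a peak speed
$v$ (cm/s). Within a section the position is a sinusoid about the workspace
center, so each half-cycle lasts $1/(2f)$ seconds, starts and ends at rest,
and has a half-sine speed profile peaking at $v$. These constraints fix the
movement extent (the distance between consecutive turning points):

$$ D = \frac{v}{\pi f}. $$

This is the unique amplitude consistent with half-sine speed pulses at a
given $(f, v)$; it is the identity `section_extent()` implements and the
property the tests verify by numerically integrating the speed profile.

The built-in program (`builtin_design()`) has 11 trials and 31 sections;
frequencies $\{0.25, 0.375, 0.5, 0.625, 0.75, 0.875\}$ Hz and peak speeds
$\{20.0, 26.7, 33.3, 40.0, 46.6\}$ cm/s each occur at least five times.
Two details the design leaves open were decided as follows:

- **Section durations.** Trials split nominally into equal thirds (or
  halves). `round_section_durations()` adjusts durations minimally so every
  section holds a whole number of half-cycles while the total stays 60 s.
  For three-section trials the nominal 20 s already works for all six
  design frequencies ($40f$ is an integer). For the two-section trial at
  (0.375, 0.625) Hz both 28/32 and 32/28 are feasible at distance 2 s from
  the nominal split; the tie is broken toward the shorter first section,
  giving 28 s / 32 s.
- **Join blending.** Where sections meet, position and velocity over
  ±250 ms around the join are replaced by the unique cubic matching both
  quantities at the window edges. Because consecutive sections generally
  differ in amplitude, the blend is a genuine swoop: it can contain its own
  acceleration zero crossings, which matters for classification (below).
  One design cell (0.25 Hz, 46.6 cm/s) implies an extent of 59.3 cm, wider
  than the 45.5 cm tablet the task models; the builder warns and proceeds
  without clipping (escalation to an error is available via
  `workspace_error = TRUE`).

## Kinematic preprocessing

Raw time/position tables are resampled to a uniform grid (100 Hz by
default — ten-fold margin on the 0.875 Hz stimulus and on the 0.15 s
timing threshold) and differentiated with zero-phase Savitzky–Golay
filters of polynomial order 2 and a 250 ms window; acceleration is the
smoothed derivative of the smoothed velocity rather than a one-pass second
derivative. The cascade matters: with realistic quantization noise
(position SD ~0.05 cm), a one-pass 150 ms second derivative leaves
acceleration noise well above any reasonable zero-crossing prominence
floor, and spurious AZC triples appear near every genuine crossing. With
the 250 ms cascade the noisy and noise-free AZC counts agree across seeds
(this is a regression test). Zero-phase filtering leaves AZC *locations*
unbiased, and the passband comfortably covers the ≤ ~3 Hz structure of
hand-tracking corrections.

Registration of a response to its stimulus is a single constant lag
maximizing the normalized cross-correlation of the velocities over
±0.5 s. Nonuniform time warping is deliberately out of scope: residual
per-segment timing differences are exactly what the segment metric $dT$
measures, and a constant lag keeps the registration deterministic and
testable (recovery of injected lags to one sample is a property test).

## AZC detection, jitter, and the CC rule

AZCs are sign changes of the acceleration, interpolated to sub-sample
precision. A crossing whose flanking extrema are both below 2% of the
trace's maximal $|a|$ is suppressed as noise; on noise-free traces the
detector provably equals a dense brute-force sign scan (tested against a
10 kHz oracle).

Response AZCs are matched one-to-one to stimulus AZCs within ±0.2 s.
Matching is the *optimal non-crossing* assignment (maximal number of
matches, then minimal total time mismatch), computed by dynamic
programming over the two sorted lists; for events on a line this attains
the exhaustive optimum, and the test suite verifies equality with a
brute-force assignment oracle on randomized small sets. A greedy
closest-pair heuristic is not equivalent: clustered blend AZCs produce
real cases where greedy strands a matchable crossing. Unmatched response
AZCs are the **jitter points**; the jitter frequency of consecutive jitter
points at spacing $\Delta$ is $0.5/\Delta$ (a full correction cycle spans
two of them), and the reported peak is the mean of the interval
frequencies in the modal 0.05 Hz histogram bin — an estimator chosen so
that values falling on bin boundaries (0.5, 0.625 Hz) are reported
exactly.

Segments are the stimulus half-cycles; a window that begins at a section
join is extended to include the join's blend (the blend window belongs to
the following half-cycle). Per segment:

- $\ell^*$ = the lag in ±0.5 s maximizing the segment-local velocity
  cross-correlation; $dT = |\ell^*|$;
- $dV$ = RMS velocity difference at $\ell^*$, relative to the stimulus RMS
  velocity;
- $dX$ = RMS position difference at $\ell^*$, relative to the segment
  extent.

These operationalizations are the package's own: the names, the observed
ranges (dV approaching 1 for dissimilar motion) and the threshold units
constrain them, but no closed-form definition is inherited. A segment is
**CC** iff it contains *no jitter point* and $dV < 0.95$, $dT < 0.15$ s.
For an ordinary half-cycle — exactly one stimulus AZC, its speed peak —
this is equivalent to the classic "exactly one AZC (i.e., no jitter)"
rule. The no-jitter formulation, rather than a literal AZC count, is what
survives the blend windows: a faithful response may reproduce the blend's
extra stimulus AZCs (matched, hence not jitter), or smooth over a
near-degenerate velocity dip so that its single AZC falls a few samples
across the window edge. Both are flawless tracking, and both would be
misclassified by a raw count. The identity that anchors this choice is
exact and tested: every built-in trial, classified against itself, yields
100% CC and zero jitter points. Trial-level `%CC` is time-based (CC-covered
time over trial time), matching the rendering of CC periods as time
intervals; whether the original measure was time- or segment-weighted is
not documented, and segment-weighted probabilities are used where segments
are the natural unit (the frequency bins below).

## Similarity of CC placement across participants

Per stimulus section, each participant's response becomes a binary
per-sample CC vector. Cross-participant similarity is the mean pairwise
Hamming distance over all unordered pairs (153 for $N = 18$), computed via
column counts. The null preserves each participant's repertoire while
breaking the section identity: per shuffle, every participant's vector for
a section slot is replaced by their own vector from a uniformly random
trial *at the same section index*. Two unstated details had to be decided:
sections of different trials differ in length (28–32 s halves vs 20 s
thirds), so vectors within a comparison are cropped to the overlapping
prefix; and trials 1 and 6 have no third section, so for section index 3
the shuffle draws from the nine trials that do. The 31 section scores are
averaged within trial before the paired t-test — 11 matched pairs, 10
degrees of freedom — because the trial, not the section, is the
independent unit of the design. The shuffle estimator is verified against
exhaustive enumeration on small cases, and its determinism under a fixed
seed is part of the contract.

## Frequency dependence and cross-experiment comparison

CC probability is segment-weighted: each half-cycle is one Bernoulli
trial, binned exactly at the six design frequencies (or five peak
velocities). Empty bins are flagged `NA`, never zero. Per-participant OLS
slopes of probability on the bin value are tested against zero one-sided
(the directional hypothesis is that faster rhythms make CC more likely).
Free-motion (two-player style) segments have no prescribed frequency; each
half-cycle's measured frequency is $0.5/\text{duration}$, consistent with
the design identity, and segments are histogrammed with the design
frequencies as centers, midpoints as edges, and open-ended outer bins.

The cross-experiment comparison is a mixed (split-plot) ANOVA —
between-subjects experiment, within-subject frequency — fitted as a
repeated-measures multivariate linear model with Type II sums of squares
(the experiment groups are unbalanced) and sphericity-assumed univariate
F tests; Tukey's HSD on participant means handles pairwise experiment
contrasts. On balanced designs the F statistics equal a hand-written
definitional sums-of-squares oracle to machine precision (tested), and
with one within level the between-factor F collapses to the squared
two-sample t (tested). Sphericity corrections are deliberately not
applied.

## The synthetic follower

No human tracking responses are distributed with the package, so the
generator is a first-class module: it encodes the intermittent-control
account the analysis is designed to detect, and every pipeline stage is
exercised against it.

The follower decomposes the *displayed* trajectory into strokes between
consecutive turning points, splitting multi-humped stretches (which arise
where a join blend extends a half-cycle) at velocity local minima so each
stroke carries one speed peak. Each stroke is mirrored, after a
sensorimotor delay, by minimum-jerk submovements
($x(\tau) = d\,(10\tau^3 - 15\tau^4 + 6\tau^5)$, peak speed $1.875\,d/T$,
exactly one AZC). The central mechanism is a stochastic ceiling on smooth
movement duration:

$$ T_{\lim} \sim \mathcal{N}(\mu_T, \sigma_T) \text{ truncated to } \mu_T \pm 3\sigma_T, $$

with defaults $\mu_T = 1.3$ s, $\sigma_T = 0.15$ s. A stroke standing for
a half-cycle of period $d$ is produced as a single submovement if
$d \le T_{\lim}$, and otherwise split into $k = \lceil d/T_{\lim} \rceil$
chained submovements through noisy via-points on the stimulus path —
the source of jitter. The ceiling is stochastic rather than a hard 1.0 s
cutoff because the motivating observations put the limit *around* one
second while tracking data show partial smoothness at 1.33 s half-cycles
and none at 2.0 s: with these defaults
$P(T_{\lim} \ge 1.33) \approx 0.4$ while the truncated support tops out at
1.75 s (and at 1.95 s for the most generous simulated participant), so
2-second half-cycles are *structurally* beyond reach — the zero-CC result
at 0.25 Hz is a property of the mechanism, not a tail event of a seed.
Two related decisions:

- The smooth-or-split decision uses the *rhythm's half-period* rather than
  the displayed stroke duration when a stroke stands for a half-cycle:
  join blends trim edge strokes of slow sections to ~1.8 s, and judging
  those by their trimmed length would (rarely) let a high-ceiling
  participant track a 0.25 Hz edge segment smoothly. The follower plans
  rhythm units; brief transit swoops keep their own duration.
- Chained pieces that meet at a non-rest velocity minimum get overlapping
  submovements (25% extension on each side), so the summed velocity stays
  up through the junction — the standard picture of overlapping
  submovements, and the only way a smooth two-humped sweep can be
  mirrored without a spurious rest.

Noise enters in three places, all configurable via `follower_params()`:
endpoint noise (SD = 5% of the stroke extent, applied to every planned
via- and endpoint), onset timing noise (SD 30 ms), and corrective
submovements. Corrections are a Poisson process whose intensity is
`correction_prob_per_excess_cm` (default 0.1 /cm/s of exposure) times the
momentary *realized* error — the endpoint misses interpolated between
submovement checkpoints. Two modelling dead-ends are worth recording: if
the error signal includes the planned mid-flight lag of a chained stroke
relative to the ideal sinusoid, corrections fire on their own plan and
cascade into runaway oscillations in wide-extent sections; and if multiple
corrections in a stroke each target the original error rather than the
residual, they over-correct multiplicatively. Corrections are brief
(0.15 s), so each injects a high-acceleration pulse that reliably produces
unmatched AZCs — jitter — in its segment.

Cohorts draw per-participant parameters around the defaults
($\mu_T \pm 0.1$ s and delay $\pm 0.03$ s, SDs truncated at 2 SD) from a
single master seed; all randomness in a cohort, follower or dyad is
reproducible from that one integer. Free dyads chain half-sine half-cycles
with frequency and peak velocity drawn uniformly per half-cycle
(defaults 0.1–1.2 Hz, 10–50 cm/s — spanning the design range on both
sides so all six analysis bins are populated in a three-minute game),
reflecting off the workspace edges.

**What the generator does and does not emulate.** It reproduces rhythmic
tracking with delay, minimum-jerk submovement structure, a smooth-duration
ceiling, endpoint/timing noise and error-driven corrections — enough for
every detector, resampling and inference path to be exercised on data with
the right structure. It does not model learning across trials, resonance
or biomechanics, leader-follower role dynamics, or the empirically
observed small *positive* effect of peak velocity on CC probability: in
the generator, larger extents mean larger absolute errors and slightly
*more* corrections, so the simulated velocity effect is small and
negative. The tests therefore assert only that the velocity effect is
much smaller in magnitude than the frequency effect, which is the
qualitative contrast of interest. Likewise, the generator's CC probability
saturates near 1 at the two highest frequencies: the increase from 0.75 to
0.875 Hz is within sampling noise (strictly increasing at the cohort seed
the tests fix, but a plateau in general), which parallels the reported
non-significance of that last pair rather than a strict gradient.
Passing tests demonstrate internal consistency of pipeline and mechanism,
not fidelity to any particular human dataset.

## Problem sizes and numerical details

The test suite and the acceptance script run the full study geometry: 18
simulated participants × 11 trials at 100 Hz (721 segments per
participant), 10,000 shuffles for the similarity null in the acceptance
script (500 in the routine test, which checks direction and significance
rather than the null's third decimal). The shuffle null is computed from
a per-section Gram matrix of the stacked CC vectors
($H(u,v) = (\|u\|^2 + \|v\|^2 - 2\,u^\top v)/L$), making 10,000 shuffles
a few seconds' work. Degenerate statistics are reported, not silently
propagated: a paired test with zero-variance differences returns $t = 0$
(equal means) or $\pm\infty$ with a `degenerate` flag, zero-variance
ANOVA cells report $F = 0$, and zero-variance stimulus segments are an
error in the metric computation. Floating-point boundary cases in the
jitter histogram are handled by rounding before binning so design-typical
frequencies land in a unique bin.

## Known limitations

- The dX/dV/dT formulas are this package's operationalization; absolute
  values are comparable within analyses run by this package, not
  necessarily to other implementations of similarly named measures.
- Registration is constant-lag; data with drifting latency would need
  elastic alignment upstream.
- The generator's corrective-submovement rate is calibrated only
  qualitatively (it produces plausible jitter frequencies around
  0.4–0.8 Hz); it is not fitted to any dataset.
- `%CC` from real tablet recordings will depend on the preprocessing
  window if the hardware noise differs materially from the ~0.05 cm
  quantization the defaults assume.
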