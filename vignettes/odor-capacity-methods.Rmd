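---
title: "Counting discriminable stimuli: encoding models, the odd-man-out protocol, and why sphere packing overcounts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting discriminable stimuli: encoding models, the odd-man-out protocol, and why sphere packing overcounts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorspace)
```

## The question

A popular strategy for estimating how many stimuli a sensory system can
discriminate runs as follows. Build mixtures of N components drawn from a
pool of C primaries; measure, as a function of the overlap O between two
mixtures, the fraction of mixture pairs that subjects can tell apart;
read off the *critical distance* D — the number of unshared components
(D = N − O) at which half the pairs are discriminable; then count how
many "spheres" of diameter D pack into the space of all N-of-C mixtures
and declare that count the number of discriminable stimuli.

`odorspace` implements that entire pipeline — the mixture designs, three
perceptual encoding models, the odd-man-out discrimination protocol, the
psychometric curves, and the exact sphere-packing combinatorics — so
that the extrapolation can be exercised on systems whose true perceptual
capacity is known by construction. The pipeline reliably reports
astronomical capacities for systems that, by construction, distinguish
three categories (a sum-threshold responder), about a million stimuli
(trichromatic color vision), or about ten (a one-dimensional circular
code). That is the point: the sphere count does not measure the number
of percepts.

## The three encoding models

**Sum-threshold ("microbe") model.** Each of the C = 128 primaries is an
attractant (+1) or repellent (−1) with probability 1/2. A mixture's
percept is a category of its component sum s: "yum" if s > 2, "yuck" if
s < −2, "meh" for −2 ≤ s ≤ 2 (boundaries inclusive to "meh"). The
response is deterministic, so two mixtures are discriminable exactly
when their categories differ, and every class-level quantity has a
closed form. The mean fraction of discriminable pairs at overlap O is

E[1 − Σ_c P(c | shared sum)²],

averaged over the binomial distribution of the shared sum; the test
suite uses this analytic curve as an independent oracle. At O = 0 it
equals 1 − (p_meh² + 2·p_yum²) = 0.6566, and it crosses 0.5 at
O* = 15.256 — so the protocol assigns this three-percept system a
critical distance of 15 and, through the packing formula, ~9·10¹¹
"discriminable odors".

**Color model.** Percepts live in the RGB unit cube. Primaries have
coordinates uniform on [0,1], rescaled to Euclidean norm 1/N (equal
parts at fixed total intensity; 1/30 for the standard 30-light
mixtures). Mixing is exact vector addition; trial noise adds independent
Gaussians to the three coordinates, with no clipping (the decision rule
uses distances only, and clipping would add an unstated nonlinearity).
The noise scale is not free: it is calibrated so that two stimuli at
Euclidean separation jnd = 0.01 are just discriminable, which puts ~10⁶
percepts on a 3-D grid. A variant draws every pair's component vectors
fresh from all directions instead of from a 128-primary pool, emulating
an unbounded-dimensional stimulus space.

**Ring model.** Primaries are unit vectors at uniform random angles; a
mixture maps to the angle of the component sum, renormalized to unit
length — normalization emulates the removal of intensity cues. Trial
noise is Gaussian on the angle with SD σ = 0.4 rad (the single tunable
parameter; 0.3 and 0.5 bracket it in the pointwise-dominance property
test). Mixtures whose sum vector is numerically zero (probability ~0
for N ≥ 10 random angles) raise a degenerate-mixture error rather than
returning an arbitrary angle.

## The odd-man-out protocol

Each trial presents three vials: two containing one mixture of a pair
and one (position-randomized) containing the other. Each sample is
independently corrupted by the model's noise; the two samples at the
smallest distance (Euclidean in RGB, circular arc on the ring) are
declared identical and the remaining one is chosen as odd. Chance is
1/3. A pair is *discriminable* when 14 or more of 26 trials (>50%) are
correct; a mixture class is summarized by the fraction of its 20 pairs
that are discriminable; and the whole design — fresh random primaries
included — is replicated 1000 times to give the mean ± SD curve against
overlap.

Design choices where the protocol description left room:

* Which mixture of a pair plays target is re-randomized per trial. The
  statistic is exchangeable, so this only symmetrizes it.
* All 26 trials of a pair share one noise level; no per-subject
  heterogeneity is modeled.
* Distance ties are broken uniformly at random. They are measure-zero
  under continuous noise and matter only in degenerate tests (e.g.
  noiseless identical mixtures, where the chance floor of 1/3 must
  still emerge).
* The shared components of a pair occupy the middle O positions of the
  2N − O index draw. Draws are exchangeable, so any convention gives
  the same distribution; a fixed block is the easiest to verify.
* Replicate r of a curve runs under a seed drawn up front from the root
  seed, so single replicates can be reproduced in isolation.

**Critical distance.** The mean curve is linearly interpolated between
adjacent overlap grid points at the 0.5 level; D = N − O*. If the curve
never falls below 0.5 for any O ≤ N − 1, a single unshared component
already suffices and D = 1 (the color model's case). A curve entirely
below 0.5 has no critical distance and raises an error. The real-valued
D is retained; the integer report rounds it.

**Noise calibration.** "Just discriminable at separation 0.01" is
interpreted as *Euclidean* separation (not per-axis) and as single-trial
odd-man-out P(correct) = 0.5, found by bisection on σ with common
random numbers (≥10⁵ trials per evaluation, achieved probability within
0.005 of target or the calibration errors out). This lands at
σ_rgb ≈ 0.0057, i.e. a critical separation of ≈1.75σ. An alternative
`"majority26"` protocol — calibrate so a 14-of-26 majority is reached
half the time — is exposed as a switch, since the source description
does not pin this down; it yields a slightly smaller σ and does not
change any headline conclusion.

## The capacity arguments

**Sphere-packing count.** With C primaries and N per mixture, the
extrapolation divides the number of mixtures by the volume of a
Hamming-type ball of radius D/2 in replacement distance:

S = ⌊ C(C,N) / Σ_{R=0}^{D/2} C(N,R)·C(C−N,R) ⌋.

Everything is computed in exact integer arithmetic (base-10⁷ limb
big-integers implemented in the package, since no arbitrary-precision
dependency is available); logarithms appear only in reports. For odd D
the summation limit D/2 is not an integer; the package computes the
exact counts at radii (D−1)/2 and (D+1)/2, reports both, and
interpolates log-linearly (their geometric mean) as `S_interp`. For
(C, N, D) = (128, 30, 15) the brackets are 5 354 954 038 767 and
162 358 561 878 and the geometric mean is 9.3·10¹¹ — the headline
"about a trillion" magnitude — so the geometric-mean reading is the one
that reproduces the printed estimate; floor/ceiling variants are
options. D = 1 needs no division: S = C(C,N) ≈ 1.5·10²⁹.

**Why the count is not a percept count.** The measured criterion only
constrains *neighboring* spheres to differ in percept half the time. An
equal-frequency labeling with k percepts makes any sphere differ from a
fraction (k−1)/k of its neighbors, so a criterion of q is met with
k = ⌈1/(1−q)⌉ labels: two labels at q = 0.5 (alternating "white" and
"black"), 10 at q = 0.9, and 10 000 only once q = 0.9999
(`min_percepts_for_criterion()`; the implementation guards the ceiling
against floating-point representation of q). In replacement distance a
30-of-128 mixture has 30·98 = 2940 one-replacement neighbors, so a
three-percept system plainly cannot make every sphere differ from *all*
neighbors — it does not have to, which is exactly the flaw.

**Ring capacity.** With the 50% single-trial criterion, bisection (with
common random numbers) locates the separation δ₅₀ at which odd-man-out
accuracy is 0.5 — about 0.59 rad at σ = 0.4 — and the number of
neighbor-discriminable equally spaced vectors on the circle is
⌊2π/δ₅₀⌋ = 10. Capacity counts neighbor-discriminability, not all-pairs
discriminability, matching the construction being critiqued. δ₅₀ scales
with σ, so capacity scales as ⌊const/σ⌋.

**Critical mixture size.** In the color model, one unshared component
separates two mixtures by up to 2/N (two norm-1/N vectors), which at
N = 30 comfortably exceeds the 0.01 JND — hence D = 1. Only at N around
55–60 lights does the single-component separation fall to the 50% class
criterion; `critical_mixture_size_color()` locates this by bisection
over N on the fresh-vector protocol. The number of such ~60-light
mixtures is C(128,60) ≈ 10³⁷ — "even more discriminable colors", by the
logic under test.

## What the synthetic world does and does not establish

The generator *is* the stated experimental design: 128 random primaries
(redrawn every replicate — the replicate variability explicitly includes
primary-assignment variability), 20 pairs per (N, O) class, 26 trials
per pair at a single noise level, 1000 replicates. It emulates nothing
about real olfactory psychophysics beyond that design: no inter-subject
ability differences, no stimulus-identity effects, no learning, and no
attempt to spread primaries "well" in perceptual space (random
primaries are the conservative choice here). A green acceptance suite
therefore establishes that the *analysis pipeline* reproduces the
published numbers on the stated models — not that any model describes
human olfaction; the models are chosen precisely because their true
capacities (3, ~10⁶, ~10) contradict the pipeline's outputs
(~9·10¹¹, ∞, consistent-with-anything).

One shape deviation is worth recording: under the Euclidean/0.5
calibration above, the fresh-vector color curve's O = 29 class sits
near 0.8–0.85 rather than ≈1.0, because a minority of random direction
pairs are nearly parallel and separate by less than the JND. The
conclusion the pipeline extracts from the curve — D = 1 in both color
variants — is unaffected (the curve never approaches 0.5 for O ≤ 29),
and no parameter was adjusted to push the plateau up.

## Numerical choices

* Big-integer limbs are base 10⁷, so limb products (≤10¹⁴) and short
  convolution partial sums stay exact in doubles (<2⁵³); long-division
  quotient digits are found by binary search, making every comparison
  exact. Verified against `choose()` wherever doubles are exact and
  against the multiply-back identity beyond that.
* `grid_percept_count()` and the capacity floors add a 10⁻⁹ guard
  before `floor()` so that binary representation of 0.01 cannot turn
  1/jnd = 100 into 99.
* Monte-Carlo roots (σ_rgb, δ₅₀) use 40 bisection steps with common
  random numbers; the Monte-Carlo SE (~0.0016 at 10⁵ trials) dominates
  the bisection residual.
* Reduced-replicate mode (`n_replicates = 100`–`400`) is used in parts
  of the test suite for speed, with tolerances widened to the
  replicate SD; the acceptance script always runs the full
  1000-replicate protocol.

## Limitations

* The packing count is an estimate of the Hamming-bound type; no claim
  is made that a packing attaining it exists, and none is needed for
  the critique.
* The analytic microbe oracle covers means, not the replicate SD
  (pairs within a replicate share primaries and are weakly dependent);
  SDs are asserted only qualitatively.
* The box-and-whisker view of per-pair correct fractions is
  reproducible from `pair_discriminability()` but no numeric values
  are asserted for its percentiles, which were never printed.
* `critical_mixture_size_color()` assumes monotonicity of class
  discriminability in N, which holds because separation scales as 1/N
  at fixed JND.
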