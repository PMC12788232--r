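---
title: "Muscle synergy extraction and PAPE statistics: methods and design"
author: "synergetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy extraction and PAPE statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Post-activation performance enhancement (PAPE) protocols — a brief,
high-intensity conditioning activity performed minutes before an explosive
task — are believed to reshape both performance (e.g. vertical jump height)
and the underlying neuromuscular coordination. `synergetics` implements the
full analysis chain used to compare three such protocols (a squat combined
with neuromuscular electrical stimulation, ESG; band-resisted lateral
stepping, RBG; a heavy barbell squat, SQG) in a within-subject crossover:
15-channel surface EMG recorded at 2000 Hz during maximal side kicks is
reduced to muscle synergies by non-negative matrix factorization (NMF), jump
heights are obtained from flight times, and a repeated-measures statistical
layer compares protocols.

Because raw data of this kind are rarely deposited, the package ships a
seeded synthetic-study generator with *known* ground-truth synergy
structure, so every downstream stage is testable end to end without any
download.

# The envelope pipeline

Each raw trial passes through the standard sEMG envelope chain:

1. **Band-pass** 20–400 Hz, 4th-order Butterworth, applied zero-phase
   (forward–backward). The nominal order is the total filter order, i.e. a
   prototype of order 2 on each band edge; the forward–backward pass doubles
   the effective roll-off.
2. **Full-wave rectification** (elementwise absolute value).
3. **Linear envelope**: 4th-order 20 Hz Butterworth low-pass, zero-phase.
4. **Amplitude normalization**, by default to the per-muscle MVC reference
   (`normalization = "mvc"`); a `task_max` mode dividing by the channel's
   session maximum is available because study descriptions of "the subject's
   maximum sEMG value" are ambiguous between the two. The mode in force is
   written to every run log.
5. **Time normalization**: the annotated movement cycle (event stamps a–e,
   preparation through recovery) is linearly interpolated onto 100 equally
   spaced points, removing cycle-duration variation.
6. **Trial averaging**: the six time-normalized trials of a session are
   averaged elementwise into one representative activation matrix.

Zero-phase filtering is a deliberate choice: causal filtering would add a
group delay that biases onset/offset timing features. The implementation
pads by reflection with steady-state initial conditions; the band-pass uses
*odd* (antisymmetric) reflection, appropriate for zero-mean signals, while
the envelope low-pass uses *even* reflection, because the odd mirror image
of a non-negative rectified signal dips below zero and would drag boundary
envelope values towards zero. Small negative undershoot of the linear
low-pass is clamped to zero so the factorization input is non-negative, as
NMF requires. Linear interpolation is used for time normalization because it
is monotone and preserves non-negativity.

# Synergy model

The activation matrix $D$ (15 muscles × 100 points) is decomposed as
$D \approx W C$ with $W \ge 0$ (muscles × $N_{syn}$, unit-norm columns) and
$C \ge 0$ ($N_{syn}$ × 100). The solver is Lee–Seung multiplicative updates
for the squared Frobenius loss: 20 seeded uniform-random restarts, at most
1000 iterations each, stopping when the relative change in reconstruction
error falls below $10^{-6}$ (checked every 10 iterations); the restart with
the highest VAF is kept. Weight columns are rescaled to unit Euclidean norm
with the scale carried by $C$, which keeps weights comparable across
subjects and bounded near [0, 1].

Reconstruction quality is measured by the variance accounted for,

$$\mathrm{VAF} = 1 - \mathrm{SSE}/\mathrm{SST},$$

with **uncentered** SST ($\sum D^2$), the convention standard in the
muscle-synergy literature; it makes VAF well defined for non-negative
envelopes and gives VAF = 0 for a zero reconstruction. A centered variant is
available behind a flag. The model order is the smallest $N_{syn}$ whose
best-of-restarts VAF reaches 0.90; the full VAF-versus-order curve is
retained on the selected model.

Within a model, synergies are labelled SYN1..SYNk by ascending coefficient
peak time. Across conditions, synergies are matched by the permutation
maximizing total cosine similarity between weight columns (exhaustive over
the at most $k!$ permutations; ties broken towards matching earlier peaks).
In the pipeline, each session's synergies are matched to the subject's
first-protocol model, and all sessions are refit at the modal selected order
so group tables are comparable.

# Temporal activation features

For each coefficient curve, a sample is *active* when it is at or above 20%
of the curve maximum — a common EMG activation convention; the threshold is
configurable and surfaced in every output. Features on the 0–100% cycle
timeline: activation duration (count of active samples, hence bounded by
100), peak time (first sample on ties), onset (first active sample) and
offset (last active sample). An all-zero curve is flagged inactive rather
than given fabricated times. Published duration values for this task exceed
the 100-point normalized cycle, so their definition and units are unclear;
this package's bounded definition is therefore *not* comparable to those
printed values, and no test treats them as targets.

# Jump height and the statistical layer

Jump height uses the flight-time method, $h = g t^2 / 8$ with
$g = 9.81\,\mathrm{m/s^2}$, reported in cm; the best of the three jumps per
time point enters analysis. The statistical layer:

* **Power / sample size** for a within factor, under the G*Power
  within-factor convention: noncentral $F$ with
  $\mathrm{df} = (m-1)\varepsilon,\ (N-1)(m-1)\varepsilon$ and noncentrality
  $\lambda = N f^2 m \varepsilon / (1-\rho)$. For $f = 0.30$,
  $\alpha = 0.05$, power 0.80, $m = 3$, $\rho = 0.5$, $\varepsilon = 1$ this
  yields a minimum of **20** subjects (power at 16 is 0.706). The
  implementation is anchored to an independent noncentral-$t$ route: for
  $m = 2$ the within test is a paired $t$ test with
  $d_z = f\sqrt{m/(1-\rho)}$, and the computed powers agree with
  `power.t.test(strict = TRUE)` to 10⁻⁶ (e.g. $f = 0.25$, power 0.95
  $\Rightarrow N = 54$). A published design value of 16 for these inputs is
  not reproducible under this (or the SPSS-style) effect-size convention;
  the package reports what the stated procedure computes.
* **Two-way within-subject RM-ANOVA** (protocol × time) by direct
  sums-of-squares partition, each effect tested against its own
  subject-by-effect interaction; $\eta_p^2 = SS_e/(SS_e+SS_{err})$.
  Sphericity is assumed ($\varepsilon = 1$, no Greenhouse–Geisser
  correction), matching integer dfs (2, 34) and (4, 68) for an 18-subject
  3 × 3 design. Verified against `aov()` error strata to 10⁻⁶.
* **Normality gate**: Shapiro–Wilk per cell at $\alpha$ = 0.05; a variable
  routes parametric only if no cell rejects. Zero-variance cells are flagged
  degenerate and routed non-parametric.
* **Post hocs**: paired $t$ tests with Bonferroni correction on the
  parametric branch (effect size $d_z$); Wilcoxon signed-rank with Holm
  correction on the non-parametric branch, zero differences dropped
  (Wilcoxon's rule), midranks for ties, normal approximation without
  continuity correction, and Cohen's $d$ converted from the $Z$ statistic by
  $r = Z/\sqrt{n}$, $d = 2r/\sqrt{1-r^2}$.
* **Friedman test** with the tie-corrected chi-square; completely tied data
  yield a flagged undefined statistic, not a number.
* $\eta_p^2$ thresholds 0.01 / 0.06 / 0.14 are used only for verbal labels,
  never for inference.

# The synthetic-data generator

The generator is the package's stand-in for the recording hardware and the
athletes; its defaults are the emulated study conditions:

* **Design**: 18 subjects × 3 protocols × 6 side-kick trials, 15 channels at
  2000 Hz; trial duration 1.2 s with ±10% jitter; 3 jumps at each of 6, 8,
  10 min post-intervention.
* **Ground truth**: 3 synergies. Weight columns are drawn sparse (a random
  dominant-muscle subset at U(0.6, 1) over a U(0.02, 0.10) baseline),
  unit-normalized, and rejection-sampled until all pairwise cosine
  similarities fall below 0.6. Coefficients are single Gaussian bumps with
  centers spread over the cycle (base 20/50/80 ± 5) and widths 6–9 points.
  This separation is calibrated so that the generative order is actually
  identifiable: with looser weights/wider bumps, two synergies can already
  reconstruct 90% of noise-free data, and the VAF criterion would
  legitimately stop early. Under the defaults, order selection recovers 3
  for 30/30 tested seeds, noise-free and at 5% noise.
* **Raw signal model**: the clean envelope $E = (W \cdot \text{protocol
  modifier}) C$, upsampled to the trial duration, multiplies a
  constant-modulus random-FM carrier — a unit-amplitude sinusoid whose
  instantaneous frequency random-walks inside the flat middle of the
  analysis band (~70–250 Hz, where physiological sEMG power concentrates).
  Its rectified mean is exactly $2/\pi$ regardless of the frequency path, so
  the envelope chain recovers $E$ (per-channel correlation > 0.95 on
  noise-free trials; in practice ≈ 0.999). An amplitude-modulated Gaussian
  carrier was considered and rejected: the rectified-and-smoothed version of
  band-limited Gaussian noise carries ~17% multiplicative ripple at the
  20 Hz envelope bandwidth, which breaks envelope recoverability on
  low-dynamic channels. Additive Gaussian noise is applied at `noiseSd`
  (default 5%) of the mean clean envelope amplitude. Amplitudes are
  arbitrary units; no hardware-specific scaling is modelled.
* **Protocol effects** are multiplicative boosts (+25% by default) on
  protocol-specific muscles — ESG: GM, RF, RFR; RBG: VL, GMed; SQG: RF,
  RFR — mirroring the direction of the reported between-protocol weight
  differences; magnitudes are configuration, not empirical claims.
* **MVC references** are set 25% above each subject's maximum clean
  envelope, so MVC-normalized activations stay below 1.
* **Jumps**: the recorded (best-of-three) height of each protocol × time
  cell is drawn normal with the configured cell mean/SD, decomposed into a
  shared subject effect (weight $\sqrt{\rho}$, $\rho = 0.5$ to match the
  repeated-measures correlation assumed in the power analysis) plus
  independent cell noise; the two non-best jumps are scaled slightly below
  the best; heights are truncated just above zero and inverted to flight
  times through $h = g t^2/8$.
* **Seeding**: one global seed fans out through a congruential hash
  (`childSeed`) into per-stage, per-subject, per-trial seeds, so a subset
  rerun in isolation reproduces the full run exactly.

What the generator does **not** emulate: motor-unit-level EMG structure,
fatigue across trials, electrode or movement artifact beyond white noise,
kinematics. Passing tests therefore demonstrate that the *pipeline*
recovers what this signal model encodes — they do not validate the
physiology of real recordings.

# Numerical choices and degenerate inputs

* Multiplicative updates guard denominators with $10^{-12}$; all-zero data,
  negative entries and out-of-range orders are errors, not silent results.
* An unreachable VAF threshold raises a typed condition carrying the full
  VAF curve; an unreachable power target likewise carries the power curve.
* Zero MVC references, degenerate cycles (start = end), non-increasing
  event stamps, missing muscle columns and non-numeric cells are all
  located, named errors.
* Consensus order across sessions is the modal selected order (smallest on
  ties); sessions are refit at it so weight tables align.
* Problem sizes in the test suite are scaled down (3–6 subjects, 2–3
  trials, shortened trials, 4–10 NMF restarts) relative to the 18-subject
  defaults; the full-size study is exercised once for its design-shape
  contract. These sizes are the package's choice of test fixtures; the
  statistical calibration checks use 1000 analytic-layer replicates where
  distributional claims need precision.

# Known limitations

* Only the global VAF criterion is implemented (no per-muscle VAF gate).
* One factorization per session; shared (concatenated-condition)
  factorizations, sparse/regularized NMF variants and bootstrap confidence
  intervals on weights are out of scope.
* Automatic movement-cycle detection is out of scope; cycle events come
  from the generator or from annotation files.
* The Wilcoxon branch uses the normal approximation throughout; exact small
  sample p-values are not computed.
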