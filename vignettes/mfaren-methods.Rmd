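---
title: "Gait-phase recognition from surface EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-phase recognition from surface EMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfaren)
```

## The problem

A gait cycle — one stride of walking — decomposes into four phases: first
double support (DS1), single support (SS), second double support (DS2) and
swing (SW). Lower-limb exoskeletons and prostheses need to know the current
phase within tens of milliseconds to time their assistance. Surface
electromyography (sEMG) is attractive for this because muscle potentials
precede mechanical motion, but raw sEMG is noisy, nonstationary and similar
between adjacent phases, so the feature extracted from each short window
matters as much as the classifier.

This package implements a complete recognition pipeline for 12-channel
lower-limb sEMG (left/right rectus femoris, vastus medialis,
semitendinosus, biceps femoris, tibialis anterior, medial gastrocnemius):
band-pass/notch preprocessing, phase labeling from a hip goniometer and an
in-shoe pressure sensor, sliding-window segmentation, the MFAREn nonlinear
feature, and an attention CNN with a parallel LSTM branch (EMACNN) for
4-phase classification. A seeded synthetic generator stands in for private
laboratory recordings.

## The MFAREn feature

The per-window feature combines a complexity term and an energy term.

**Fuzzy approximate entropy.** For a window $u(1),\dots,u(N)$, template
vectors of length $m$ are formed and each has its own mean subtracted:
$X_i^m = (u(i),\dots,u(i+m-1)) - \bar u_i$. Templates are compared by
Chebyshev distance $d_{ij}$, and similarity is graded by a Gaussian
membership $\mu(d_{ij}, r) = \exp(-d_{ij}^2 / 2r^2)$ instead of a hard
threshold. With
$\phi^m(r)$ the mean over $i$ of $\log$ mean over $j$ of $\mu(d_{ij},r)$,

$$\mathrm{fApEn}(m, r) = \phi^m(r) - \phi^{m+1}(r),
\qquad r = k \cdot \mathrm{sd}(u).$$

Both $\phi$ terms share one tolerance $r$, computed from the window being
analyzed. Because templates are baseline-removed and $r$ scales with the
signal, fApEn is invariant under $u \mapsto a u + b$ ($a > 0$); the test
suite asserts this to $10^{-9}$. Self-matches ($j = i$) are included in the
similarity sums, following the plain form of the defining sums; excluding
them is available as an option.

**Multi-scale extension.** Scales $\tau_i \in \{1, 2, 3\}$ re-evaluate the
entropy at enlarged embedding dimensions $m\tau_i$ (template length grows;
the series is not coarse-grained). Two constructions are tracked per scale:
$E_X$ at template length $m\tau_i$ and $E_Y$ at $m\tau_i + 1$. Their
disagreement across scales is aggregated as a Kullback–Leibler-style
divergence:

$$\mathrm{MfApEn} = -\frac{1}{|\tau|} \sum_{s}
E_Y[s]\,\log\frac{E_Y[s] + \varepsilon}{E_X[s] + \varepsilon},
\qquad \varepsilon = 10^{-6}.$$

Two readings of this aggregate circulate: a literal one in which numerator
and denominator are both $E_Y + \varepsilon$ — identically zero, hence
carrying no information — and the divergence between the two embedding
constructions, which matches the stated KL intent. The package implements
the divergence reading and keeps the literal variant behind
`entropy_params(literal = TRUE)` purely for auditability.

**Fusion with RMS.** The final feature is
$\mathrm{MFAREn} = \mathrm{MfApEn} + \mathrm{RMS}$. MfApEn is
amplitude-invariant; RMS carries the contraction intensity. On
microvolt-scale signals the RMS term dominates numerically, which is
precisely what separates resting from active muscle states, while the
entropy term contributes amplitude-independent irregularity structure.

**Windowed extraction.** Within each 100 ms (100-sample) segment an inner
window of $w = 10$ samples slides with stride 1, yielding
$F = L - w + 1 = 91$ values per channel — the $1 \times 12 \times 91$
classifier input. The entropy kernel is implemented in C++; a naive
double-loop R implementation of the defining sums serves as an independent
oracle in the tests, with agreement required to $10^{-10}$.

### Numerical choices

* **Tolerance floor.** A constant window has $\mathrm{sd} = 0$ and hence
  $r = 0$; `r_floor = 1e-12` makes all memberships 1, so
  $\mathrm{fApEn}(\text{const}) = 0$ exactly rather than undefined.
* **Negative entropy estimates.** With $N = 10$ inner windows and template
  lengths up to 8, only a handful of templates exist and the finite-sample
  estimate of $\phi^m - \phi^{m+1}$ can dip below zero. Entropy is
  nonnegative in expectation, so the aggregate clamps negative per-scale
  estimates at zero before the logarithm; without the clamp the log of a
  negative ratio would be undefined. `fapen()` itself returns the raw
  (possibly negative) estimate.
* **Tolerance coefficient.** $k$ in $r = k\,\mathrm{sd}$ is set to 0.2,
  standard practice in the ApEn/SampEn literature; it is a parameter.
* **Scale constraint.** The constraint $\tau_i < m + 1$ sometimes quoted
  for multi-scale entropy would forbid the reference setting $m = 2,
  \tau = 3$; since that setting is the one actually used, scales default
  to $\{1,\dots,\tau\}$ unconstrained.
* **Per-window tolerance.** $r$ is computed from each 10-sample inner
  window (not the 100 ms segment), matching the windowed-feature framing;
  $\phi^m$ and $\phi^{m+1}$ always share it.

## The EMACNN classifier

The input is the $1 \times 12 \times 91$ feature matrix. Three parallel
branches with $5\times5$, $3\times3$ and $1\times1$ kernels extract
multi-scale views and are concatenated; Layer 1 applies three $3\times3$
conv blocks and an attention module; Layers 2 and 3 repeat with two and one
blocks. Every conv block is convolution + batch normalization + ReLU with
"same" padding, and each layer ends with $2\times2$ max pooling (average
pooling by option), so the map shrinks $12\times91 \to 6\times45 \to
3\times22 \to 1\times11$. In parallel an LSTM reads the matrix as a
91-step sequence of 12-dimensional vectors; its final hidden state is
concatenated with the flattened convolutional features before the fully
connected softmax head. Training uses Adam at $10^{-3}$, halved every 20
epochs, with categorical cross-entropy (the 4-phase generalization of the
binary form).

**EMA attention.** The efficient multi-scale attention module splits the
$C$ channels into groups (default 4) that share weights, folding groups
into the batch. Per group: means over width and over height give
directional descriptors, passed through a shared $1\times1$ transform and
a sigmoid to gate the group (the X1 branch); a parallel $3\times3$
convolution captures local context (X2); each branch's channel-softmax
descriptor then weights the other branch's spatial map, and the summed
cross-spatial maps pass through a sigmoid to gate the input. Output shape
equals input shape, so the module stacks anywhere. The group-normalization
step some formulations insert before the cross-spatial weighting is
omitted here; batch normalization in the surrounding conv blocks already
stabilizes the scale.

**Implementation.** No deep-learning framework is involved: layers,
attention, LSTM and Adam are implemented in this package, with analytic
backward passes. Convolutions exploit the small height of the feature maps
by folding the row axis into the channel axis, turning each horizontal
kernel tap into one contiguous shifted copy plus one BLAS matrix product.
Every backward pass is verified against central finite differences in the
test suite (relative error below $10^{-4}$ across randomly sampled
parameters of the full graph).

**Unpublished details.** Filter counts per layer, LSTM width, dropout and
batch size are not fixed by any public description of this architecture
family; defaults of 16/32/64 filters and a 64-unit LSTM give a parameter
count in the usual range for this model class, and `n_parameters()`
surfaces the count so configurations can be matched to a target size. The
`mcnn` / `ema` / `lstm` / `full` variants of `variant_config()` support
ablation studies; removing attention and LSTM yields the multi-channel CNN
baseline.

## Preprocessing

* Butterworth band-pass, order 4, 20–200 Hz, plus a 60 Hz notch
  (constrained-pole biquad, $q = 30$, giving a ~2 Hz stopband). The notch
  frequency is configurable; 60 Hz is the default mains assumption.
* Filtering is **causal** by default because the intended use is on-line
  phase recognition; zero-phase (forward–backward) filtering is an
  off-line option. The stated contracts (≥ 20 dB notch depth, band-pass
  response per the analytic transfer function) are asserted in the tests.
* **Phase labeling.** Cycle boundaries sit at hip-angle maxima; stance vs
  swing comes from the pressure signal (threshold 5% of maximum). How
  stance splits into DS1/SS/DS2 is a design decision: DS1 starts at the
  pressure onset and DS2 ends at the offset, each taking a fixed fraction
  of the stance samples (default 24%, configurable). When labeling
  simulator output, passing the generator's own stance fractions recovers
  the ground truth to within rounding at the phase edges.
* **Segmentation.** 100 ms windows with 100 ms step; each window takes the
  majority phase of its samples, and windows whose majority falls below
  60% (straddling a boundary near-evenly) are dropped and counted. Where a
  per-window label convention is unstated, majority voting is the least
  arbitrary choice; start- or center-sample labeling are trivial
  alternatives a user can emulate by relabeling.

## The synthetic generator

The generator emulates the statistical structure of treadmill-free gait
recordings: 1000 Hz sampling; four phases per 1 s cycle with fractions
0.12/0.38/0.12/0.38 (typical gait-literature proportions, configurable);
five locomotion modes (LW, SA, SD, RA, RD) whose activation profiles
differ in at least four (muscle, phase) amplitudes; amplitude-modulated
band-limited (20–200 Hz) Gaussian noise as the sEMG surrogate — the
standard surrogate model, since surface EMG during sustained activation is
well approximated by filtered Gaussian noise; a smoothed activation
envelope (30 ms rise time) driven by per-phase amplitudes, with early
stance of level walking activating ST/BF/TA/MG while RF/VM rest; the right
leg mirrors the left with a half-cycle shift. A 60 Hz mains line and slow
baseline drift are optional additive components to exercise the filters.
The hip angle is a two-arc cosine with its maximum at the cycle start and
minimum at swing onset; pressure is a half-sine bump, strictly positive in
stance, exactly zero in swing; amplitudes are scaled to ~150 µV at full
activation. All randomness derives from one seed: identical configurations
produce bit-identical recordings.

What the simulator deliberately does **not** model: motor-unit physiology,
electrode-shift and cross-talk artifacts, inter-subject anatomy,
cycle-duration variability within a recording, and phase-transition
co-articulation. Synthetic phases are therefore considerably more
separable than real ones: passing end-to-end tests demonstrates that the
pipeline is implemented correctly and that its pieces compose, not that
real-data accuracies would be reproduced. Published accuracies on private
laboratory recordings are out of reach by construction.

## Problem sizes used in the tests

The checked-in experiments are sized for routine re-running on one CPU:
the end-to-end check simulates 2 subjects × 2 modes × 50 cycles (~2000
windows), extracts the full 12 × 91 feature tensor per window, trains a
compact EMACNN (4/8/16 filters, 16-unit LSTM, ~6.5k parameters) for 30
epochs and requires ≥ 90% held-out accuracy; the ablation check trains the
full model and the MCNN baseline on 10 paired seeds at 6 epochs on a
400-window subsample and requires the full model's mean accuracy to be at
least the baseline's. Larger configurations change runtime, not code
paths.

## Known limitations

* Entropy estimates from 10-sample inner windows are statistically crude;
  they are used as *features*, not as physiological complexity estimates.
* The per-sample recognition time reported by `predict_emacnn()` is
  amortized over a forward batch and is hardware-dependent; it is reported
  but never asserted against.
* Batch normalization uses running statistics at prediction time; models
  trained for very few epochs may predict with poorly converged statistics
  (visible only in deliberately undertrained smoke tests).
* The divergence reading of the multi-scale aggregate is an
  interpretation; the literal (identically zero) form is retained behind a
  flag so the two can be compared on any input.
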