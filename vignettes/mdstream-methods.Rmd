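---
title: "mdstream: methods, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mdstream: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the tunable parameters and their defaults, what the
synthetic-data generator emulates, and the numerical and design decisions
taken where several reasonable choices existed.  Nothing here states an
empirical result that the test suite does not itself compute.

# The streaming data model

## Slicing

All data is carried as n-dimensional complex arrays with up to 16
dimensions (trailing extents 1).  A *slice* of `X` fixes the indices on a
selected axis set `S`; the remaining axes are free.  Two encodings make
slices cheap to talk about across process boundaries:

* the **bitmask** of the selected axes, `bitmask(S) = Σ_{i∈S} 2^i`
  (axes are 0-based throughout the package for exactly this reason);
* the **serial number** `c = Σ_k a_k Π_{l<k} N_{S(l)}` of a slice's
  multi-index `a`, with the smallest selected axis varying fastest.

`slice_serial()`/`serial_to_index()` are exact inverses, and
`extract_slice()`/`insert_slice()` keep selected axes at extent 1, so a
slice has the same rank as its parent.  These conventions are verified
exhaustively in the tests (all axis subsets of shapes up to 5×4×3×2).

## Wire protocol

The protocol's structure is: static header, stream header, then one
message per slice, in serial order.  The concrete framing is this
package's own dialect:

```
# Dimensions
<16 space-separated extents>          <- byte-identical to a cfl .hdr
# shared <path>                       <- shared-storage transport only
# meta <key>=<value>                  <- optional stream metadata
# stream <flags> <binary|shared>
<blank line>
slice <serial> <payload-bytes> <n-meta>
<n-meta lines of key=value>
<payload-bytes of raw little-endian complex float32>   <- binary mode
```

Two transports exist.  **Inline binary** (`binary = TRUE`, the
`--stream-bin-out` CLI flag) embeds each payload in the byte stream
itself, so the protocol crosses machine boundaries through anything that
relays bytes (pipes, `ncat`, files).  **Shared storage** (the default
between local endpoints) writes payloads into a preallocated file named
in the header and uses the byte stream only for completion messages;
this is the portable realization of a shared-memory transport and keeps
the synchronizing channel tiny.

The **synchronization contract** is: a payload is fully written and
flushed *before* its slice message is emitted.  A consumer that has read
`slice c ...` may therefore rely on slice `c` being complete; the tests
enforce this with a producer that sleeps random intervals between
slices.  End of stream is a clean close after the last slice; a close
inside a payload raises a truncation error, and out-of-order serials are
protocol errors on both ends.  Unknown header comment lines are ignored
(forward compatibility); per-slice metadata is `key=value` text with a
count prefix, and consumers ignore unknown keys.

Interoperability with any other implementation of a streamed-cfl format
is *not* claimed — the structure matches, the bytes are this package's
own.

## Looping

`run_looped()` applies a tool to every slice selected by the loop
bitmask.  Semantics worth stating precisely:

* **Broadcasting.**  An input with extent 1 on *every* looped axis is
  passed unchanged to every invocation (a trajectory shared across
  frames); an input matching the reference extents is sliced; anything
  else is a shape error naming the offending axis — never a silent crop.
* **Ranges.** `start`/`end` select serials `[start, end)`; unprocessed
  output slices are zero.  When both a reference and explicit extents are
  given, the explicit extents win.
* **Workers.**  `workers > 1` forks slice computations but assembles
  results in serial order, so parallel output is identical to the serial
  run (`workers = 1` is the reference semantics, and the tests compare
  against it).
* **Streamed looping** (`run_looped_streamed()`) takes the loop flags
  from the input stream and runs the tool on every slice as it arrives;
  output slices are emitted immediately, so a consumer sees the first
  result long before the producer finishes.  At most `workers` slice
  buffers are held at any time (the observed peak is reported, and the
  acceptance tests assert the bound over 1–200 slices) — memory does not
  grow with the stream length.
* **Stream-aware tools** (temporal median, RT-NLINV, the compression
  stages) thread explicit state through the slices, which is what makes
  temporal regularization possible in a stream.

In-place assembly of streamed output uses precomputed linear indices
(`x[ind] <- slice`) rather than a functional update, because a
whole-array copy per slice would make the consumer compute-bound and
mask the pipelining benefit the framework exists to provide.

# Reconstruction operators

## Gridding path

The lightweight reconstruction is Ram-Lak filter → adjoint NUFFT → root
sum of squares → centered resize.

* **Ram-Lak.**  Radial sampling density falls off as `1/|k|`, so each
  sample is weighted `w = max(|k|, Δk/8)` with `Δk` the radial sample
  spacing.  The floor at DC is needed because a zero weight would drop
  the mean signal entirely; it is deliberately a *continuous* floor — an
  earlier hard rule ("replace the weight of samples with `r < Δk/2`")
  made the reconstruction discontinuous in sub-sample trajectory shifts,
  which matters once gradient-delay correction moves the samples.
  The absolute scale of the output is not normalized; quality metrics use
  `nrmse()`, which fits the optimal complex scale first.
* **Adjoint NUFFT.**  Kaiser–Bessel interpolation, kernel width 4 grid
  cells, grid oversampling 1.5, Beatty-style shape parameter, apodization
  by the kernel's analytic transform.  The result matches the exact
  adjoint `ρ(x) = Σ_j y_j e^{+2πi k_j·x/N}` to about 0.2 % relative
  error (tested against a brute-force sum).  One grid cell of slack is
  allowed beyond the nominal band `±N/2` so that delay-corrected
  trajectories remain gridable; genuinely out-of-band samples are an
  error.
* **Oversampling removal.**  Gridding is done at twice the target matrix
  (the readout-oversampled field of view); `resize_center()` crops to the
  final matrix.  Crop and pad both place the center at offset
  `floor((larger − smaller)/2)`, so crop∘pad is the identity.
* **View sharing.**  Frame `f` is reconstructed from the spokes of
  frames `f−T+1 … f` (`T` = number of turns).  For a static phantom this
  equals reconstructing the union of the turns' spokes, which is tested.

## Temporal filters

The **median filter** is causal: frame `t` is the per-pixel median of
frames `max(1, t−L+1) … t` (all frames seen so far during start-up).
Causality is what makes it usable in a live stream; the cost is that a
content change reaches the output `⌊L/2⌋` frames late, and the
step-response test pins that delay down exactly.

The **non-local means filter** is strictly frame-wise.  Patch 5×5,
search window 11×11; a candidate patch at distance `d` (mean squared
difference) gets weight `exp(−max(d − 2σ², 0)/h²)`, with `σ` a robust
MAD-based noise estimate from the Laplacian-difference response and
`h = 0.4 σ`.  The `2σ²` offset is the expected distance of two noisy
copies of identical content, so flat regions average maximally while
edges (whose distance exceeds the noise floor) are preserved.  Without
the offset the filter trades resolution for denoising and can make a
reconstruction *worse* than its input at realistic noise.

# Coil compression

`cc_svd()` takes the top right-singular vectors of the
`(samples × coils)` frame matrix — the energy-optimal projection; all
samples of a radial frame serve as calibration because radial sampling
is densest at the k-space center.  The SVD basis is unique only up to a
unitary rotation of the virtual coils, so per-frame recomputation makes
the virtual coil profiles jump between equivalent bases (image
flickering).  `align_matrices()` removes the ambiguity causally: each
matrix is right-multiplied by the unitary `Q = U Vᴴ` from the SVD of
`M_fᴴ M_{f−1}` — the orthogonal Procrustes solution, which subsumes both
rotations and sign flips and leaves column spaces (hence captured
energy) untouched.  `cc_stream()` exposes the three strategies: static
(first-frame matrix reused), dynamic-unaligned, dynamic-aligned; the
tests assert the smoothness contrast on a simulated slice-reposition
series and that compression to the true coil-map rank is lossless.

# Gradient delays

The model is a symmetric 2×2 matrix `S` (units: readout samples): a
spoke with unit readout direction `n` is shifted by `S n` in k-space.
Per frame, `estimate_delay()` fits the three entries from two kinds of
shift observations:

* **Absolute, per spoke:** the coil-summed power profile `Σ_c |s_c(t)|²`
  of a spoke peaks where the spoke passes closest to the k-space origin,
  i.e. at minus the parallel shift component `nᵀS n`.  The peak is
  localized to sub-sample precision by a log-parabola through the three
  samples around the maximum (exact for a locally Gaussian peak).
* **Differential, per spoke pair:** the lag between two spokes of the
  same frame, from the mean phase increment of their image-domain
  cross-spectrum summed over coils, observes
  `n_iᵀS n_i − n_jᵀS n_j`.  Because both spokes see the same object
  *and the same coils*, coil phases cancel exactly, making these
  observations very precise.

The differential block determines the traceless (anisotropic) part of
`S`; the absolute block supplies the isotropic part (the pairwise
differences are blind to it).  A design based on cross-correlating
nearly antiparallel spoke pairs was considered and rejected: a frame of
13 spokes uniformly covering half the circle has no partner pair within
a usable angular tolerance, and correlating projections at angles
~14° apart is biased by object structure.  The hybrid above needs only
the stated precondition — at least 3 distinct spoke angles for the
3 unknowns — and recovers injected matrices with entries up to 0.8
samples to well within 0.1 samples in the tests, equivariantly under
in-plane rotation.

`correct_trajectory()` assigns the measured positions `k + Δk · S n` to
the nominal trajectory; reconstructing with the corrected trajectory
restores near delay-free quality, and correcting with a stale, wrong
matrix is demonstrably worse (the interactive-rotation failure mode).
`delay_ellipse()` is the eigendecomposition view used for visualization:
absolute eigenvalues as principal axis lengths, principal eigenvector
angle as orientation in `[0, π)`.  `estimate_delay_stream()` optionally
smooths estimates across frames (exponential decay 0.5); smoothing is
off in all tests.

# Real-time nonlinear inversion

RT-NLINV jointly estimates the image `ρ` and coil sensitivities `c_j`
from one undersampled frame by an iteratively regularized Gauss–Newton
method on `‖F(ρ, c) − y‖² + α‖(ρ, ĉ) − prior‖²`.  Coils are
parameterized in k-space with the Sobolev weight
`w(k) = (1 + a|k|²)^{−b/2}` (`a = 220`, `b = 32`, `|k|` normalized to
`[−½, ½]`), which makes sharp structure in the coils expensive and
pushes it into the image.

Numerical decisions, all deliberate:

* **Normal-operator evaluation.**  The non-Cartesian sampling enters
  only through `AᴴA`, evaluated exactly as a Toeplitz convolution with
  the PSF kernel on a 2N grid (kernel by direct DFT summation, cached per
  trajectory), so every inner iteration is FFTs only and no forward
  NUFFT is needed.  The operator is normalized to unit norm (division by
  the PSF-spectrum peak) so that `α` lives on a fixed scale across
  trajectories.
* **Data scaling.**  The adjoint image is rescaled to unit RMS per
  pixel.  This keeps `ρ` and `c` on comparable scales; without it the
  multiplicative coupling `ρ·c` equilibrates at wildly different block
  scales and the joint Newton system becomes so ill-conditioned that the
  image stalls in the coils.  The first frame's scale is reused for the
  whole stream, which is what makes the output linear in the input data
  (tested to 1 %).
* **Regularization schedule.**  `α_n = max(α₀ qⁿ, α_min)` with `α₀ = 1`,
  `q = 1/3`, `α_min = 0.005`.  The floor matters: without it, "more
  iterations" silently means "less regularization", and extra iterations
  amplify noise instead of refining the estimate.  With the floor,
  iterations beyond the 6th refine at fixed regularization — 6 steps are
  the default, 8 the high-quality configuration.
* **Inner solver.**  Plain CG, fixed 10 iterations per Gauss–Newton
  step, no adaptive stopping — deterministic and reproducible.
  Divergence (the normal-equation residual increasing three consecutive
  steps) raises an error with the residual history.
* **Initialization and temporal prior.**  The classic start is `ρ = 1`,
  `ĉ = 0`.  In a stream, each frame starts from (and, with
  `prior = TRUE`, is regularized toward) `0.9 ×` the previous frame's
  estimate; `temporal_damping = 0` decouples the frames exactly (tested
  bitwise).  Frame `t` depends only on frames `≤ t` — truncating the
  input stream leaves earlier outputs bitwise unchanged.
* **Output.**  `image = ρ · sqrt(Σ_j |c_j|²)`, which removes the
  `ρ ↔ c` scale ambiguity.

The inversion runs on the target grid `N` with the object assumed inside
the field of view (no image-domain oversampling in the inversion
itself); the gridding path, in contrast, grids at `2N` and crops.

# The synthetic-data generator

The generator emulates an RF-spoiled radial FLASH acquisition.  Defaults
are the sequence values of such a protocol: 256 ADC samples at 2×
readout oversampling, 13 spokes per frame, matrix 192, TR 2.1 ms,
TE 1.25 ms, FOV 256 mm, turn-based pattern with 5 turns (ADC samples and
matrix are independent inputs; 256 is the vendor value and deliberately
not forced to 2×192).  `frame_time()` is `spokes × TR` = 27.3 ms at the
defaults.  Tests and the acceptance suite run the desk-scale analogue:
matrix 64, 128 ADC samples, 8 coils (compressed to 4 virtual), 13 spokes
per frame, 5 turns, streams of 5–20 frames — sizes chosen so the whole
suite runs in minutes on one CPU while remaining fully sampled at the
5-turn union (65 spokes ≳ π/2·64).

Content and conventions:

* **Phantom:** ellipses (default: a large tube with two inner
  structures), rasterized with 4×4 subpixel averaging.  The averaging is
  the partial-volume effect of a real voxel grid; a hard-edged indicator
  rasterization is not band-limited and no reconstruction could get
  closer than ~6 % NRMSE to it at matrix 64, which would drown every
  quality comparison in Gibbs residue.
* **Coil maps:** 8 receivers on a ring (Gaussian magnitude, radius
  0.55·FOV/2, width 0.6·N), smooth linear phase pointing inward plus a
  per-coil offset; a symmetric array, as in practice.  Slice-reposition
  events swap in a rotated coil configuration while the phantom stays
  put.
* **Motion:** rigid sinusoidal translation (amplitude in pixels,
  period in frames) — a moved water tube, not deforming anatomy.
* **Forward model:** exact DFT summation at the (optionally
  delay-shifted) trajectory positions, using a per-spoke geometric phase
  recurrence.  The generator shares no code with the gridding
  reconstruction path, so reconstruction tests are not inverse crimes.
  (The NLINV normal operator also uses exact DFT sums for its PSF — that
  is a property of the reconstruction method, not a shared shortcut with
  the generator.)
* **Noise:** additive complex Gaussian; `noise_sigma` is quoted relative
  to an order-1 phantom (internally scaled by the matrix size to sit on
  the DFT-sum scale).  The noisy study condition used in the ordering
  tests is `noise_sigma = 0.05`, which produces visibly noisy gridding
  reconstructions (~25 % NRMSE from 13 spokes) — a plausibly realistic
  regime for single-frame radial real-time imaging.
* **Trajectories:** turn-based (frame angles uniform at π/13, turn `t`
  offset by `t·π/65`, so 5 consecutive frames tile 65 uniform angles
  over π) and rational golden angle (increment `π·F(n−2)/F(n)`,
  13-periodic for `F(7) = 13`).

What the generator does **not** emulate — and hence what passing tests
do and do not show: no Bloch simulation or T1/T2 contrast dynamics, no
off-resonance or trajectory errors beyond the delay model, no coupled or
correlated coil noise, no through-plane or non-rigid motion, and phantom
geometry far simpler than anatomy.  Tests built on it validate the
*algorithms and their orderings* (alignment smoother than no alignment,
NLINV better than gridding on the same undersampled data, delay
closed-loop recovery), not clinical image quality.

# Latency instrumentation

Per-frame records hold four monotonic timestamps (last spoke arrived,
preprocessing done, reconstruction done, post-processing done); per-stage
durations are their differences and per-frame latency the total.
`steady_state()` models the start-up transient: the warm-up is the
shortest prefix after which the moving-average slope (window 5) stays
below 2 % of the series mean per frame — the detector's parameters are
declared here, not claimed canonical.  A series that never settles
returns a diagnostic (`steady = FALSE`), not an error.

`crosscorr_delay()` estimates the lag between two movement curves as the
argmax of their zero-padded cross-correlation, refined by parabolic
interpolation around the peak.  Correlation uses raw sums, not per-lag
means: by Cauchy–Schwarz the self-correlation then peaks exactly at lag
zero, whereas a per-lag mean is biased toward lags whose overlap window
happens to cover the energetic part of the curve.  Camera/video
segmentation is out of scope; the functions consume already-extracted
curves (two-column text files).

The end-to-end experiment wires the simulator through `md_copy()` with a
per-slice delay (the "scanner") into a reconstruction consumer; with
per-slice compute below the delay, the pipelined run beats the blocked
one — asserted as a sign, never as hardware milliseconds.

# Pipelines

`pipeline_config()` + `build_pipeline()` assemble the stage graph;
`run_pipeline()` executes it.  Three presets mirror common real-time
configurations: (1) gridding + view sharing + 4 static virtual coils,
(2) RT-NLINV + gradient-delay correction (the latency-measurement
setup), (3) RT-NLINV + aligned dynamic compression + NLM + 8 iterations
(highest quality).  `trace_graph()` emits the graph in DOT, including
the `tee → cc → ccapply` split of the compression path.

The executor is the in-memory streamed mode: frames flow through the
stage chain one at a time with per-stage state, which has the same
causal semantics as a process graph.  True multi-process execution
(fork + FIFOs) is provided where concurrency is the point: the
`md_copy`-producer experiments, and `run_pipeline()` accepting a live
FIFO source so reconstruction overlaps a delayed producer.  A full
per-stage process graph with one OS process per tool is not constructed;
on one machine it would add only scheduling noise to what the FIFO
source already demonstrates.

# Known limitations

* The wire protocol dialect is self-consistent but not interoperable
  with other cfl-streaming implementations.
* RT-NLINV is a compact reference implementation: single 2D slice,
  no image-domain oversampling, no GPU, fixed inner CG; it is tuned for
  clarity and testability, not throughput (seconds per frame at
  matrix 64 in pure R).
* The delay estimator assumes a mostly real-valued object with a
  dominant k-space center peak (true for magnitude phantoms and typical
  anatomy) and 2D trajectories.
* Multi-consumer fan-out, encryption/authentication, and resumption
  after truncation are deliberately outside the protocol; use OS tools
  (`tee`, `ncat`) around it.
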