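---
title: "Denoiser-regularized refinement: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoiser-regularized refinement: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
statistical model behind noise2noise training on half-maps, the recycling
loss, the spectral-trailing safeguard, the numerical and design choices that
were genuinely open, and what the desk-scale synthetic studies do and do not
demonstrate.

## 1. The statistical idea

Gold-standard cryo-EM refinement reconstructs two half-maps from disjoint
halves of the particles. They share the signal and carry independent noise —
exactly the structure noise2noise training needs: a network trained to map
one noisy observation onto *another* noisy observation of the same signal
converges (in L2) to the conditional expectation of the signal, without ever
seeing clean data. The package's augmentation therefore builds the *input*
patch from one half and the *target* patch from the other:

* input: `y = H_{C,A}[x^(1-k) + e]`, with `e` seeded colored noise so the
  network sees a range of noise levels;
* target: `ȳ = H_{C̄,A}[x^(k)·M + h(x^(k))·(1-M)]`, where `M` is a smooth
  molecule mask and `h` a 15 Å low-pass. Disordered regions (detergent
  micelles, solvent) are filled with low-passed density instead of zeros so
  the network learns to smooth them while keeping their mean density.

`H_{C,A}` applies, in this order, an anisotropic Gaussian filter (covariance
`C`, Fourier gain `exp(-2π² kᵀCk)`), a rigid rotation+translation, a crop to
a cubic patch, and standardization to zero mean / unit variance. Input and
target of one example share `A` and the crop; only the filters and noise
differ. The input-side resolution cutoff is constrained to be no finer than
the target's: the network may denoise and even blur-match, but is never
trained to sharpen, which would invite hallucinated high-resolution features.

## 2. The network and the recycling loss

The denoiser is a residual volumetric U-net `f(v) = v + g(v)`: encoder blocks
(3×3×3 convolution → instance normalization → SiLU, then 2× average pooling),
a bottleneck block, decoder blocks (2× nearest-neighbor upsampling, skip
concatenation, convolution → normalization → SiLU), and a 1×1×1 head
initialized to zero, so a freshly built model is *exactly* the identity.
That initialization matters: plugged into refinement, an untrained model
reproduces the baseline, and training only ever moves the reference away from
baseline in directions the loss supports.

The loss recycles the network's own output:
`L = (1/2b) Σ_i Σ_k ‖ȳ_i^(k) − f(R_r[f, y_i^(k)])‖²` with `r` drawn uniformly
from `{0,…,r_max}` per example. Within an iterative refinement the denoiser is
applied at every iteration, so artifacts it introduces would be re-amplified;
training on its own `r`-fold output teaches it to suppress them. Three
choices here were open and are package decisions:

* recycled passes run in inference mode (no dropout) and are not
  differentiated (stop-gradient); only the final application carries
  gradients — bounded memory, standard recycling practice;
* `r` is uniform on `{0,…,r_max}`;
* the optimizer is Adam with a cosine-decayed learning rate. None of these is
  dictated by the method's definition.

Normalization is a documented ambiguity in the method's public descriptions
(instance vs batch normalization); the package defaults to instance
normalization, which is insensitive to mini-batch size, and makes it
configurable. The reference configuration (depth 5, base width 25, 64³
patches at 1.5 Å voxels) lands at ~13.0 M parameters; exact parity with any
particular published network is not claimed. The entire network stack —
forward, backward, optimizer — is implemented in the package (R over two
compiled 3×3×3 convolution primitives), so every gradient is checked against
central finite differences in the test suite.

## 3. Refinement with spectral trailing

The toy refinement loop is deliberately minimal but structurally faithful:
hard-assignment projection matching over a fixed orientation grid (the
expectation step), direct-Fourier backprojection per half-set with 3×
oversampled trilinear gridding, and a reference update that is the object of
study:

* **baseline**: each half-map is weighted per shell by the Wiener gain
  `2·FSC/(1+FSC)` (clamped to [0,1]) and low-passed at the current
  solvent-corrected FSC-0.143 shell `ρ` — the standard practice of filtering
  references to the current resolution so alignment cannot lock onto noise;
* **blush**: the filtered half-map is passed through the denoiser, then
  spliced by the trailing filter: denoised content up to `ρ − 2` shells,
  zeros above, and — when `ρ` exceeds the denoiser's 3 Å Nyquist limit —
  the standard-regularized map above that limit.

Two design points deserve emphasis. First, the denoiser input is the
*filtered* map from the regularized-likelihood update (configurable to the
raw backprojection): that is the rule the method's classification variant
states explicitly, and at desk scale it is also what makes the comparison
meaningful — a 200-step toy network cannot by itself out-regularize a Wiener
filter. Second, the trailing cutoff is a *hard* zero beyond `ρ − 2` (a
soft-edged option exists): the safeguard's point is that Fourier components
near the reported resolution were never touched by the prior, which the
hard cutoff makes provable (`trail_shell < ρ` is asserted at every
iteration). The final map is always the Wiener-filtered average of the last
half-maps, never denoised.

The `spectral_trailing = FALSE` ablation uses the denoised references
full-band. It exists because the safeguard itself is the thing under test in
the phase-randomization experiment, and because with the identity denoiser it
makes blush and baseline *exactly* coincide — the reduction property the test
suite asserts.

## 4. Fourier conventions and numerics

* Shells are one Fourier voxel wide: voxel with integer frequencies
  `f` belongs to shell `round(|f|)`; shell `s` corresponds to `n·voxel/s` Å.
  Resolution→shell conversion rounds down (never passes frequencies beyond a
  stated resolution). Grid corners beyond Nyquist are excluded from FSC
  curves and inherit the last shell's gain in filters.
* `ρ` uses the first-crossing rule at 0.143: the largest shell such that the
  curve stays at or above threshold everywhere below it; 1 if already below
  at shell 1; `n/2` if it never crosses.
* Solvent correction: `(FSC_t − FSC_n)/(1 − FSC_n)` with `FSC_n` the masked
  FSC after phase-randomizing both maps beyond a chosen shell (Hermitian
  symmetry preserved, amplitudes exact), averaged over a configurable number
  of draws, applied beyond the randomization shell plus a 2-shell margin.
* Phase randomization takes its phases from a white Gaussian field's
  transform, which preserves amplitudes bit-exactly and keeps the output
  real.
* Voxel-size rescaling is pure Fourier cropping/padding. The output edge is
  `round(extent/target)` rounded *up* to even, so the result is never coarser
  than requested; the stored voxel size is the effective spacing
  `extent/n_out`, and the mean density is preserved exactly.
* Patch blending uses separable raised-cosine ramps renormalized per axis to
  an exact partition of unity; tile→stitch is the identity to ~1e-15.
* Projection/backprojection embed the volume at the center of a 3×-padded
  grid circularly shifted to the origin, giving `F_pad(3k) = F(k)·(−1)^Σk`
  exactly and a slowly varying transform that trilinear interpolation
  handles; backprojection normalizes accumulated slice values by accumulated
  interpolation weights per Fourier voxel. With dense noiseless coverage the
  reconstruction-to-phantom FSC exceeds 0.95 to 80% of Nyquist, which is the
  accuracy ceiling of this gridding at these grid sizes.

Degenerate inputs are contracts, not accidents: zero-variance patches are
rejected during augmentation (with bounded retries) and passed through
unchanged during inference; all-constant references tie-break alignment to
the lowest grid index; empty or zero-power shells yield FSC 0.

## 5. The synthetic data and the study conditions

Phantoms are sums of 10–12 anisotropic Gaussian blobs (σ 1.2–3 Å at 1.5 Å
voxels, centers snapped to voxel centers), deliberately not atomic models:
they exercise the pipeline without implying atomic realism. The blob widths
were chosen so that map power reaches the mid shells the way experimental
maps do — with very smooth blobs the half-map FSC crosses 0.143 so early
that a ρ−2 trailing cutoff leaves almost no alignment band at a 24-voxel
grid. The mask is a soft blob indicator (exactly 1 at blob centers); an
optional "micelle" region is filled with ≥20 Å band-limited texture and
excluded from the mask.

Half-map noise in the toy training corpus is *white* with amplitude 0.8.
This was measured, not assumed: the noise of backprojected half-maps at the
toy refinement conditions is spectrally flat (per-voxel weight normalization
whitens the white image noise), and a corpus with the falling
(`1/(1+(s/s₀)²)`) spectrum — which remains the generator's default for
half-map simulation — taught the denoiser to damp exactly the low shells
where deployment SNR is highest. Matching the training noise to the
deployment noise is a study condition, stated here once.

The desk-scale reference conditions, used by the tests and the acceptance
script:

* toy denoiser: depth 2, base width 4, 16³ patches, dropout 0.5, instance
  normalization; `r_max = 2`;
* toy training: 16 pairs of 32³ phantoms, 200 Adam steps (500 for the
  reference model used inside refinement experiments), batches of 2 pairs
  (both half-directions each), peak learning rate 2e-3;
* toy refinement: 24³ grids at 1.5 Å, particles projected over a
  192-orientation grid (32 directions × 6 in-plane angles), 3 iterations,
  solvent-corrected FSC randomized from shell 8. The low-SNR study uses
  white pixel noise with σ = 5 and 480 particles: the noise puts baseline
  misassignment around 0.3–0.6 while the particle count keeps the half-map
  FSC cutoff at ρ ≈ 6–8, so the ρ−2 trailing band still carries alignment
  information — with fewer particles ρ collapses and the trailing rule
  (2 shells ≈ a third of the usable band at this grid size) starves the
  denoised references regardless of denoiser quality.

These sizes keep a full test run within tens of minutes on one CPU; the
reference (non-toy) defaults remain the method's own (64³ patches at 1.5 Å,
batch 8, depth 5, dropout 0.5, r ∈ {0,…,5}).

## 6. What the studies show — and what they cannot

* *Noise2noise recovery*: toy networks trained only on noisy pairs get
  closer (MSE) to the clean phantom than their noisy input in ≥9/10 seeded
  runs. This validates the training construction, not cryo-EM performance.
* *Overfitting guard*: after phase-randomizing all particle images beyond
  shell 6, refinement in either mode yields a solvent-corrected half-map FSC
  whose mean beyond that shell is ~0 (|mean| < 0.05). At 24³ the correction
  must be applied from the randomization shell itself (margin 0, 2 draws):
  the soft mask convolves genuine below-cutoff correlation about 3 shells
  upward, which at this scale is a quarter of the whole band and is mask
  leakage, not overfitting — it is present with true orientations and no
  refinement at all.
* *Low-SNR benefit*: at pixel noise where baseline misassigns well over 30%
  of orientations, the denoiser-regularized refinement matches or beats
  baseline (shell-integrated FSC to the phantom) in ≥8/10 seeds.

What passing these tests does **not** show: anything about real micrographs
(no CTF, no ice gradients, no beam-induced motion, no atomic-model
validation), about marginalized orientation assignment (the toy E-step is
hard assignment over a coarse grid), about resolutions beyond a 12-shell
Nyquist, or about the behavior of a full-scale (~13 M parameter, ~10⁶-step)
network. The trailing rule in particular does not scale *down* gracefully:
two shells is 2% of the band on a real grid but ~40% of the usable band
here, which is why the toy baseline is a genuinely strong opponent.

## 7. Known limitations

* Hard-assignment alignment makes orientation errors all-or-nothing;
  probabilistic weighting would soften both modes' failure modes.
* Trilinear gridding (even 3× oversampled) caps attainable FSC near 0.95 at
  these grid sizes; a Kaiser–Bessel kernel with gridding correction would
  raise the ceiling at some cost.
* The denoiser processes overlapping patches independently; seams are
  handled by partition-of-unity blending but not learned.
* Training runs single-threaded and deterministic given a seed and thread
  configuration; BLAS-level reductions may differ in the last ulp across
  builds, so traces are compared at 1e-6, not bit-for-bit, across machines.
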