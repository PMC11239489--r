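# blushr

Denoiser-regularized cryo-EM map refinement with spectral trailing, at desk
scale, in R.

## The problem

Single-particle cryo-EM determines macromolecular structures by aligning very
noisy 2D projection images of individual particles against a 3D reference and
reconstructing a new reference from the aligned images, iterating to
convergence. Because alignment degrades with particle size, small complexes
hit a signal-to-noise wall: the refinement either stalls at low resolution or
overfits noise into protein-looking artifacts. The standard safeguard —
gold-standard refinement of two independent half-sets with a Fourier-space
Wiener filter derived from their Fourier shell correlation (FSC) — encodes
only a weak smoothness prior.

`blushr` implements, end to end and at a size a laptop CPU handles, the
alternative studied in recent work on learned regularization (known in the
field as *Blush regularization*): replace the Wiener filter step with a
volumetric denoising neural network trained on pairs of half-maps in the
noise2noise fashion, and guard the resolution estimate with *spectral
trailing* so information introduced by the denoiser never reaches the
frequencies used to report resolution.

## The method

**Training pairs** (augmentation). From a half-map pair
`x⁽⁰⁾, x⁽¹⁾` sharing signal but with independent noise, training examples are

    y     = H_{C,A}[ x⁽¹⁻ᵏ⁾ + e ]                        (input)
    ȳ     = H_{C̄,A}[ x⁽ᵏ⁾ ⊙ M + h(x⁽ᵏ⁾) ⊙ (1 − M) ]      (target)

where `H_{C,A}` applies an anisotropic Gaussian filter with covariance `C`, a
rigid transform `A`, a crop to a cubic patch and voxel standardization; `e` is
seeded colored noise; `M` is a smooth molecule mask and `h` a 15 Å low-pass
used to fill disordered regions (micelles stay dense but featureless). The
input-side cutoff is never sharper than the target's, so the network is never
trained to deblur.

**Loss** (recycling). With `R_r[f, y]` the result of feeding `y` through the
denoiser `r ∈ {0,…,5}` times,

    L = (1/2b) Σ_i Σ_{k∈{0,1}} ‖ ȳᵢ⁽ᵏ⁾ − f( R_r[f, yᵢ⁽ᵏ⁾] ) ‖²

so the network learns to suppress artifacts amplified by its own repeated
application across refinement iterations. `f` is a residual 3D U-net
(`f(v) = v + g(v)`, zero-initialized head, SiLU activations, instance
normalization, 50% dropout); the reference configuration has ~13 M
parameters. The network, its backpropagation and the Adam optimizer are
implemented in the package (vectorized R over compiled 3D convolution
primitives).

**Refinement** (spectral trailing). Each iteration aligns each half-set
against its own reference, backprojects, and estimates the shell `ρ` where
the solvent-corrected half-map FSC drops below 0.143. Denoised references are
then low-pass cut two Fourier shells below `ρ`; shells beyond the denoiser's
3 Å Nyquist limit are taken from the standard Wiener-weighted reconstruction.
The final map never passes through the denoiser — it is the Wiener-filtered
average of the last half-maps, so the reported resolution cannot be inflated
by the prior.

Everything runs on synthetic phantom data built by the package (Gaussian-blob
"molecules" with soft masks, optional micelle-like disordered regions,
half-map pairs with independent seeded noise, projection datasets with
ground-truth orientations), so the full pipeline is testable without any
downloads.

## Worked example

```r
library(blushr)

# a tiny synthetic corpus of half-map pairs and a toy denoiser
fit <- train_toy_denoiser(seed = 101, steps = 200)
round(tail(fit$trace$loss, 3), 1)
#> [1] 3840.7 3818.2 4112.3

# does the denoiser recover signal it never saw? (noise2noise check)
r <- noise2noise_experiment(seed = 1)
round(c(noisy = r$mse_noisy, denoised = r$mse_denoised), 3)
#>    noisy denoised
#>    0.643    0.521

# refine a low-SNR particle dataset with and without the denoiser
model <- train_toy_denoiser(101, steps = 500)$model
cmp <- low_snr_experiment(model, seed = 2)
round(unlist(cmp[c("misassign_baseline", "int_fsc_baseline", "int_fsc_blush")]), 3)
#> misassign_baseline   int_fsc_baseline      int_fsc_blush
#>              0.258              3.602              3.755
```

The first block trains the depth-2 toy U-net on 16 synthetic half-map pairs;
the loss is the recycling objective above (a sum of squared differences over
a 16³ patch, so O(10³) values are normal, and it fluctuates because every
step draws fresh augmentations). The second block shows the denoised map is
closer to the clean phantom (mean squared error 0.52 vs 0.64) than its noisy
input, although the network only ever saw noisy pairs. The third block runs
two complete refinements of the same 480-particle dataset at a noise level
where baseline misassigns a quarter of the orientations on this draw (a
third or more on typical draws): the shell-integrated FSC between the final
map and the ground-truth phantom rises from 3.60 to 3.76 when the denoiser
regularizes the references.

There is also a command-line front end:

```sh
inst/bin/blush simulate corpus --out corpus_dir --seed 1 --n 4
inst/bin/blush fsc --half1 a.mrc --half2 b.mrc --mask m.mrc --out fsc.txt
inst/bin/blush denoise --model ckpt.rds --in-mrc in.mrc --out-mrc out.mrc --patch 16 --overlap 8
```

## Package layout

| Area | Files |
|---|---|
| Volumes, MRC2014 I/O, patch tiling | `R/volume.R`, `R/mrc.R`, `R/patches.R` |
| Fourier-shell machinery (FSC, phase randomization, filters, noise) | `R/spectral.R` |
| Training-pair augmentation | `R/augment.R` |
| Residual 3D U-net + compiled conv kernels | `R/nn.R`, `R/denoiser.R`, `src/conv3.cpp` |
| Recycling loss, Adam, training loop | `R/training.R` |
| Toy refinement with spectral trailing | `R/reconstruct.R`, `R/star.R` |
| Synthetic phantoms, half-maps, particles | `R/synthetic.R` |
| Study harnesses and CLI | `R/experiments.R`, `R/cli.R`, `inst/bin/blush` |

The methods vignette (`vignettes/blush-methods.Rmd`) documents the model, the
numerical choices and the limits of what the synthetic studies show.
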