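---
title: "Few-view DPC-CT reconstruction with explicit BM3D filtering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-view DPC-CT reconstruction with explicit BM3D filtering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The imaging model

X-ray grating interferometry (Talbot or Talbot-Lau) measures, besides
attenuation, the *refraction angle* of the beam: the transverse derivative of
the wavefront phase, proportional to the transverse derivative of the line
integral of the refraction index decrement $\delta$. A DPC-CT scan therefore
delivers, for every view angle $\theta$ and detector position $s$,

$$ y_\theta(s) \;=\; \int \frac{\partial \delta(i,j)}{\partial l'}\, \mathrm d l
   \;=\; \frac{\partial}{\partial s} p_\theta(s), $$

where $l$ runs along the ray, $l'$ is the in-plane direction perpendicular to
it, and $p_\theta$ is the ordinary (Radon) projection of $\delta$. The
reconstruction problem is to recover the 2-D image $\delta$ from these
*differential* projections, ideally from as few views as possible, since every
view costs a full phase-stepping acquisition (examination time and dose).

### Phase stepping and information retrieval

The stepping simulator models the per-pixel intensity oscillation over
analyzer-grating positions $x_g$ as
$I(x_g) = a_0\,[1 + V \cos(2\pi x_g/p_2 + \phi_1)]$, with the steps uniformly
covering exactly one period. With uniform single-period sampling the zeroth
and first discrete Fourier components give $(a_0, a_1, \phi_1)$ *exactly* in
the noiseless case — this is why retrieval is implemented as a DFT rather than
a least-squares fit (which would only be needed for non-uniform steps, which
are unsupported). Attenuation, dark-field and differential-phase images follow
as $T = -\log(a_0^s/a_0^r)$, $S = -\log(V_s/V_r)$, $\mathrm{DP} = \phi_1^s -
\phi_1^r$ wrapped to $(-\pi, \pi]$. The physical constant linking refraction
angle to fringe phase (wavelength, inter-grating distance, $p_2$) is collapsed
into a single conversion factor, default 1, so simulator round trips map DP
images directly onto refraction-angle projections. Optional Poisson noise
treats intensities as expected photon counts; the study default is noiseless,
as in the simulation experiment the package reproduces.

## The differential projector B

The operator is assembled ray by ray as a Joseph-style interpolated line
integral composed with a transverse central difference of half-pixel pitch:
the row for detector bin $s$ is
$[A(s + \Delta s/2) - A(s - \Delta s/2)]/\Delta s$, where $A(\cdot)$ is the
interpolation row of the ordinary line integral. By linearity this equals the
detector-coordinate derivative of the Radon projection, which provides the
independent oracle used in the tests: on smooth $64^2$ images, $Bx$ agrees
with the central difference of a densely sampled Radon sinogram to well under
2% of peak.

Conventions (used consistently everywhere): the image centre is the rotation
centre, pixel $(1,1)$ is top-left with rows growing downward, and a view angle
is the detector-axis direction measured counter-clockwise from $+x$, so the
Fourier-slice direction of a view coincides with its view angle. The default
detector has $\lceil n\sqrt 2\rceil$ bins of one pixel width, covering the
image diagonal at every angle.

Two properties worth noting. Applying $B$ to a constant image gives exactly
zero only for rays whose half-pixel neighbours traverse identical chords of
the support; rays clipping the corners of the square see the boundary of the
constant region and correctly report a nonzero derivative. And each view's
detector sum telescopes to (near) zero, since it is the difference of the two
outermost interpolation rows, which miss the support.

The simulation study generates its data with this same operator
(`forward_project`). This is the usual inverse-crime caveat of algorithmic
simulation studies; the oracle projector in the test helpers provides the
independently generated alternative, and the projector-equivalence tests bound
the difference between the two.

## Reconstruction algorithms

### Hilbert-filter FBP

Because the data are already differentiated in the detector coordinate, the
ramp filter $|f|$ of absorption FBP reduces to
$G(f) = |f|/(2\pi i f) = -i\,\mathrm{sgn}(f)/(2\pi)$, an imaginary sign
(Hilbert-type) filter. Rows are filtered via zero-padded FFT (padding factor
2, next power of two, Nyquist bin zeroed; optional Hann apodization) and
backprojected with linear detector interpolation and angular weight
$\Delta\theta$. The scale constant follows from the discretization
($\Delta s \cdot \Delta f = 1/L$ cancels all grid factors) and was verified
against a dense-view disk reconstruction: the recovered amplitude is within a
few percent of truth with correlation above 0.99.

### DART (row-action Kaczmarz)

The printed update of the differential algebraic reconstruction technique is
treated as shorthand for classical relaxed Kaczmarz: for each ray $i$ in fixed
view-major order,
$x \leftarrow x + \beta\,(y_i - \langle b_i, x\rangle)\,b_i/\lVert b_i\rVert^2$,
skipping zero rays; an unnormalized update diverges for this operator's row
scales. Defaults: $\beta = 0.5$; nonnegativity clamp after each sweep (the
refraction index decrement is physically nonnegative; can be disabled); a
random ray ordering is available behind a flag but off by default so runs are
reproducible. The per-sweep log records the true residual
$\lVert y - Bx^k\rVert$ (evaluated after the sweep's ART and filtering steps,
before any excitation noise) and, when a ground truth is supplied, the MSE.

### TV regularization

`tv_regularize` performs plain gradient descent on smoothed isotropic total
variation ($\epsilon = 10^{-8}$), `tv_subiterations = 20` steps per sweep with
step size `lambda_reg`. The step size is the one genuinely free parameter; a
pilot sweep on the $128^2$ study (2000 sweeps, $\lambda \in
\{10^{-4}, 2\cdot10^{-4}, 5\cdot10^{-4}, 10^{-3}\}$) showed $10^{-4}$ clearly
best and larger values over-smoothing, so $10^{-4}$ is the default.

### Explicit filtering: DART_BM3D

Each sweep runs (B) one DART pass, (C) the BM3D filter, and (D) injection of
*excitation noise* — seeded Hermitian-symmetric complex Gaussian noise added
to the image spectrum only on the unmeasured angular wedges — before looping
back to (B). The noise stirs the unmeasured frequency components so that the
collaborative filter, which strongly prefers piecewise-regular images, can
re-synthesize them; the DART pass then re-enforces fidelity on the measured
slices, which the injection never touches. Step (D) is skipped after the final
sweep, since its only purpose is to seed the next one.

**The unmeasured mask.** By the central-slice theorem each view measures the
spectrum line along its detector axis. A frequency sample counts as measured
when its polar angle lies within `measured_halfwidth_deg` of some view angle
(mod 180°); the default of 0.5° credits each view with the 1° wedge it would
own in a dense clinical reference scan, so a 180-view/1° scan has no
unmeasured region at all, while a 10-view/18° scan leaves ~93% of the plane
unmeasured. (Crediting each view with half its *own* angular interval instead
would tile the full circle for any uniform scan and leave nothing to excite,
which contradicts the premise of few-view recovery.) The DC sample is always
kept. The mask is symmetric under point reflection, and the injected noise is
Hermitian-symmetrized (and rescaled by $\sqrt 2$ so the per-coefficient
complex variance is exactly $\sigma^2$), keeping the image real.

**The noise schedule.** A constant $\sigma$ cannot converge: the measured
slices are untouched by the injection and the DART pass does not act on the
null space, so constant-level noise accumulates there as a random walk — this
is directly observable by starting the loop at the true phantom, which is an
exact fixed point at $\sigma = 0$ but drifts away linearly in sweeps at any
fixed $\sigma > 0$. A spectrum-adaptive rule (proportional to the spread of
the current masked-spectrum magnitudes) is worse still: it feeds back on its
own injections and self-amplifies. The default is therefore an annealed
schedule — the *image-domain* injected noise sd starts at
`excitation_sd0 = 0.015` (about a tenth of the phantom's soft-tissue
contrast) and decays geometrically by `excitation_decay = 0.9973` per sweep —
stirring strongly at first, then letting the filter and the data polish. Both
knobs, a fixed $\sigma$, and fully custom rules (including the adaptive one,
exported as `adaptive_excitation_sigma`) are exposed in `iterative_config`.

## The BM3D filter

Single-stage hard-threshold BM3D. Blocks of side `block_size = 8` on a stride
grid (`step = 3`, with a final row/column clamped to the border so every pixel
is covered) are matched within a `search_window = 16` pixel neighbourhood
using the per-pixel mean squared difference
$d(Z_1, Z_2) = \lVert Z_1 - Z_2\rVert_2^2 / N_\mathrm{mat}^2$; candidates with
$d \le$ `match_threshold = 0.05` (the canonical matching threshold expressed
on a $[0,1]$ intensity scale) are kept, sorted by distance (scan order breaks
ties, the reference always first) and truncated to `max_group = 16`. Each
group is transformed by a separable orthonormal 3-D transform — 2-D DCT per
block, 1-D Haar along the stack, the stack padded to a power of two by
repeating the last block — hard-thresholded at
`hard_threshold = 2.7` $\times\ \sigma$, inverse-transformed, and aggregated
into the output as a similarity-weighted average with group weight
$w = 1/(\sigma^2 N_\mathrm{har})$ ($w = 1$ for all-zero groups or $\sigma=0$).
Padded duplicates are filtered but not aggregated. The group's global DC
coefficient is exempt from thresholding, which makes constant images exact
fixed points of the filter for *any* parameter setting.

Numerical choices: when `sigma_denoise` is not supplied it is estimated per
call as $\mathrm{median}(|d|)/0.6745$ over the finest diagonal Haar subband
(the standard robust MAD estimator), which naturally anneals inside the
reconstruction loop as the image cleans up. The stride default of 3 (rather
than the looser 4) was chosen after measuring denoising quality: halving the
stride roughly halves the residual MSE on a noisy phantom at quadratic cost,
and 3 is the balance point at which the reconstruction loop's ranking
behaviour is stable while a $256^2$, 2000-sweep run stays tractable on one
CPU. The literal printed form of the aggregation (indicator rather than
weighted denominator) is available behind `literal_eq11` for comparison; it is
not a weighted average and is not the default.

## The simulation study

`run_experiment` reproduces the validation design: a $256^2$ modified
(Toft-contrast) Shepp-Logan phantom — the variant whose composite values lie
in $[0,1]$, matching the stated display window; the classic table is exposed
and swappable — scanned densely at 180 views/1° over 180°, angularly
downsampled by 18 to 10 views/18°, and reconstructed with FBP and DART at both
samplings and DART_TV / DART_BM3D at 10 views (500 dense-DART sweeps, 2000
few-view sweeps). Outputs: a six-row MSE table, line profiles (1-based row
indexing, so "the 128th line" means row 128), lossless NPY images, CSV
iteration logs and a JSON report that contains no timestamps — two runs with
the same seed are byte-identical. (Images can also be written as 32-bit TIFF,
but that container quantizes to the \[0, 1\] display window; NPY — a minimal
float64 reader/writer is included, since no installed package provides one —
is the lossless interchange format for sinograms and out-of-range data.)

Problem sizes used in the shipped checks: the test suite exercises the full
study at $128^2$ with 200 sweeps per algorithm (which preserves the algorithm
ranking), and the acceptance script runs the full $256^2$ configuration.

## What the generator emulates, and what it does not

The synthetic arm generates ideal, noiseless, inverse-crime-consistent
differential sinograms of a piecewise-constant phantom. It does not emulate:
photon noise in the stepping curves feeding through retrieval (available via
the Poisson option but off in the study), phase wrapping in strongly
refracting samples, grating imperfections or visibility loss, beam hardening,
or detector cross-talk. Consequently, passing tests demonstrate correctness of
the operators and solvers and the relative behaviour of the algorithms under
the study's own conditions — not performance on measured interferometer data,
where data inconsistency typically narrows the gap between the regularized
methods.

## Known limitations

* Parallel-beam, single-slice geometry only; no fan/cone beam, no 3-D.
* The few-view recovery of the explicit-filtering loop is substantially better
  than TV's in ranking experiments but does not reach machine-precision
  recovery; its floor is set by the annealing schedule and by how well
  grid-stride block matching represents the streak structure.
* Single-stage BM3D (no Wiener refinement stage).
* `dart_sweep` visits rays in fixed raster order by default; ordered-subset
  accelerations are out of scope.
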