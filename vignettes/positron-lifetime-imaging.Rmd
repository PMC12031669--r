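---
title: "Positron lifetime tomography with time-weighted reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positron lifetime tomography with time-weighted reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simplepli)
```

## The problem

A positron emitted in tissue annihilates after a delay that depends on its
interaction pathway: direct annihilation (~0.4 ns), para-positronium
(~0.125 ns), or ortho-positronium, whose lifetime in tissue (roughly
1.8–4 ns) is shortened by pick-off annihilation and spin exchange and is
therefore sensitive to the tissue microenvironment (void structure,
dissolved oxygen). With a radionuclide that emits a prompt gamma at
positron birth (e.g. the 1157 keV line of ⁴⁴Sc or 1275 keV of ²²Na), a
TOF-PET scanner can record *triple coincidences* — the two 511 keV
annihilation photons plus the prompt gamma — and measure, per event, both a
TOF sinogram bin $i_k$ and a lifetime $\tau_k$, the travel-time-corrected
delay between prompt-gamma and pair emission.

`simplepli` reconstructs the *positron lifetime image* $m_j$: the mean of
the per-voxel lifetime mixture

$$p(\tau \mid \boldsymbol\lambda_j, \boldsymbol A_j)
  = g(\tau - \mu) * \sum_{l \in \{o,p,d\}} A_l \lambda_l
    e^{-\lambda_l \tau} u(\tau), \qquad
  m_j = \sum_l A_{l} / \lambda_{l},$$

where $g$ is the Gaussian detector timing response with offset $\mu$ and
$u$ the unit step. $m_j$ averages over all pathways, so no per-voxel
spectral decomposition is needed — the key to the method's robustness.

## The SIMPLE estimator

Rather than fitting spectra voxel-wise, the method reconstructs the
*lifetime-weighted activity* $w_j = x_j m_j$. Its forward projection
$\bar z_i = \sum_j H_{ij} x_j m_j$ equals the expectation of the per-bin
lifetime sums, so the data vector is simply

$$z_i = \sum_{k \in K_i} \tau_k,$$

the sum of lifetime measurements of the events in TOF sinogram bin $i$.
$\hat w$ minimises the Kullback–Leibler distance $KL(z, Hw)$ by the
multiplicative update

$$w_j \leftarrow \frac{w_j}{\sum_i H_{ij}} \sum_i
  \frac{H_{ij} z_i}{\sum_l H_{il} w_l},$$

identical to MLEM except every event carries its lifetime as a weight
(`update_w()`, with a mathematically equivalent list-mode form in
`update_w_listmode()`). Because $z$ is not Poisson, this estimator is not
maximum likelihood — the KL distance is kept because the update is then a
trivial modification of MLEM; and a few $\tau_k < 0$ (timing noise around
$\tau \approx 0$) violate the nonnegativity the KL distance formally
requires. Both are tolerated deliberately: the reconstruction window's
lower edge sits just below zero so few negative weights enter, and the
image is clamped at a small positive floor after each update
(`recon_config(clamp_negative = )`; zeroing negatives is the alternative).

Random triple coincidences are classified by which singles share a decay:
type I (real pair + unrelated prompt gamma), type II (one 511 keV photon
unrelated), type III (all three unrelated). Only type I is corrected — the
others are orders of magnitude rarer at realistic activities. Type I
lifetimes are uniformly distributed, so a correction window
$[t_{c1}, t_{c2}]$ shifted away from the true spectrum counts them, the
reconstruction-window count follows by the window-width ratio, and
$\gamma$ = (type I count)/(doubles count) scales the doubles activity image
$x_0$. The lifetime image is then

$$\hat m_j = \frac{\hat{\tilde w}_j - \tfrac{t_{r1}+t_{r2}}{2}\,\gamma\,
  \hat x_{0j}}{\hat{\tilde x}_j - \gamma\,\hat x_{0j}} - \hat\mu ,$$

with $(t_{r1}+t_{r2})/2$ the mean lifetime of a uniform random inside the
reconstruction window. The prompt-gamma detection efficiency (the diagonal
matrix $Q$ in the full system model $P = HQ$) scales $\tilde w$ and
$\tilde x$ identically and cancels in the ratio, so it never needs to be
measured; the suite verifies this invariance numerically to 0.01 ns.

The direct TOF-backprojection baseline (`reconstruct_tofbp()`) forms
$\hat w_d = H'z$, $\hat x_d = H'y$, $\hat x_{0d} = H'y_0$ with a single
adjoint application and combines them by the same ratio; its spatial
resolution is limited by the TOF kernel (~16 mm Gaussian sd at 250 ps),
which is what the iterative method improves on.

## Projector and geometry

The 2D single-ring geometry (`ring_geometry()`) enumerates LORs as
unordered crystal pairs at a minimum angular separation (default
`n_crystals/8`; chords missing the image grid are skipped — their rows are
identically empty). The system matrix is applied on the fly in compiled
code: a Siddon-style trace gives per-voxel intersection lengths, each
multiplied by the Gaussian TOF kernel integrated over the event's TOF bin
(kernel sd $c \cdot \mathrm{FWHM}/2.355/2$ along the LOR; bins assigned by
nearest bin centre). TOF bin width defaults to FWHM/2.5; the default bin
count covers the field of view plus 5.5 kernel sd, so per-voxel kernel
factors sum to 1 across bins to better than $10^{-6}$. Indexing is
LOR-major with the central bin at zero time difference. A dense
materialisation (`dense_system_matrix()`) exists purely as a test oracle;
`forward_project()`/`back_project()` are verified adjoint to $10^{-10}$
against it. An image-domain PSF was deliberately not added (the study's
standard corrections — normalisation, attenuation, PSF — are orthogonal to
the contribution and a uniform-sensitivity 2D model is used throughout).

OSEM subsets partition LORs round-robin by azimuthal angle index —
seedless and deterministic; reconstruction stops at a fixed iteration
count (default 2 iterations, 3 subsets, matching the study design; early
stopping doubles as regularisation, which is otherwise out of scope).
Images initialise to 1 inside the inscribed field-of-view circle.

## The simulator

`rodent_phantom()` builds the 2D analog of the simulated small-animal
scan: an elliptical body (72 × 54 mm) with two kidney disks, a liver disk
and a 10-mm lesion, relative activities 10:15:2:1
(lesion:kidney:liver:background), pathway intensities (o, p, d) =
(0.30, 0.10, 0.60) everywhere, o-Ps lifetime 2.0 ns in the lesion and
2.5 ns elsewhere — mean lifetimes 0.8525 and 1.0025 ns.

`simulate_triples()` draws, per true event: an emission voxel proportional
to activity × prompt-gamma efficiency, a uniform in-plane pair angle
(back-to-back, no acollinearity, positron range, scatter or attenuation),
the exact TOF coordinate blurred by the 250 ps pair resolution and binned,
and a lifetime from the local decay model. Photons snap to the nearest
crystal centre and the emission point is projected onto the recorded
chord, which makes the travel-time correction exactly invertible on
noiseless streams (verified to $10^{-9}$ ns). Type I randoms reuse the
real pair process with uniform lifetimes over the retention range
(default [−20, 20] ns); types II/III use independent emission draws for
the replaced photons with pair-time offsets uniform in the pair window —
an acknowledged approximation of pile-up in a full photon-transport
simulation, adequate because those classes are at the 0.1% and 0.003%
level. Randoms ratios are specified as randoms-to-trues *within the
reconstruction window*, the convention in which the study quotes
4.9%/0.1%/0.003%. Ground-truth class and emission voxel are always kept
alongside each event so the randoms treatment can be validated.

`simulate_singles()` instead emits a time-ordered raw singles stream
(prompt gamma at decay time, pair delayed by the sampled lifetime, Gaussian
energy blur of 13% FWHM at 511 keV scaled by $\sqrt E$), which
`group_triples()` turns into triples with the take-all-good policy: every
energy-gated 511 keV single acts once as reference, a forward window forms
pairs, and *every* prompt-gamma candidate in the prompt-gamma window joins
each pair — multiples are kept, not discarded. Window boundaries are
closed; duplicate triples sharing all three singles can optionally be
deduplicated (`dedup`, default keep-all, since the reference convention
already forms each pair once).

**Effective lifetime timing resolution.** The study states only the 250 ps
pair TOF resolution. Propagating a per-single jitter
$\sigma_1 = \sigma_{CTR}/\sqrt2$ through
$\tau = (t_1 + t_2 - d/c)/2 - t_{PG}$ gives
$\sigma_\tau = \sigma_{CTR}\sqrt{3/2} \approx 0.092$ ns, the default of
`timing_model()`. ROI means are insensitive to this choice (the blur is
symmetric); it matters only for the shape of the spectrum near zero.

What the simulator does *not* emulate — photon transport (scatter,
attenuation), detector blocks, dead time, acollinearity, positron range —
means that passing tests demonstrate the estimator's statistical
properties under its own forward model, not scanner-level accuracy. The
study-scale checks are therefore run as scaled-down 2D reproductions with
wider tolerances than the published 3D values.

## Timing-offset calibration

The scanner offset $\mu$ (different timing response to prompt gammas and
511 keV photons) is fitted on the pooled spectrum with a deliberately
reduced two-component model plus uniform background,
$p_1(\tau) = G[g(\tau-\mu) * \sum_{l=1}^2 A_l\lambda_l e^{-\lambda_l\tau}
u(\tau) + b]$, minimising the count-weighted least squares
$\sum_i (p_1(\tau_i) - n_i)^2 / n_i$. Implementation choices: zero-count
bins are excluded (their weight is undefined); the loss is non-convex in
$\mu$, so Levenberg–Marquardt runs from a grid of $\mu$ starts (default
−0.5…0.5 ns in 0.25 ns steps) and keeps the best; $\sigma$ is fitted by
default and fixable; histogram bin width defaults to 50 ps; the fitted sum
spans the full spectrum range (configurable to the reconstruction window).
Rates, amplitudes and scale are fitted on log/logit scales to keep them in
bounds. A background-dominated spectrum, where $\mu$ is unidentifiable, is
flagged with `mu = NA` rather than returned silently. The EMG components
are evaluated with a stabilised scaled-erfc form (asymptotic series for
large arguments), exact down to $\sigma = 0$. Recovery on synthetic
spectra: bias below 0.005 ns and sd below 0.02 ns at $10^5$ events over 20
seeds (frozen in the test suite).

## Numerical conventions

Times are ns, distances mm, $c = 299.792458$ mm/ns; energies keV.
Divisions in the multiplicative updates are guarded at
$\varepsilon = 10^{-10}$; zero-sensitivity voxels stay zero. Window gating
uses closed intervals on both ends (ties kept; the convention is
documented since the boundary treatment is otherwise arbitrary). The
"most likely position" used by the travel-time correction is the TOF
centroid along the LOR (the Gaussian mean), which needs no image. The
display mask zeroes voxels whose activity falls below half the mean
background activity; the background reference region must be supplied
explicitly (from the phantom label image in simulations) because its
placement is a free choice. ROI statistics use the full labelled regions
by default — the convention under which a 10-mm lesion's quantification
includes its partial-volume rim — with optional erosion margins for
interior-only statistics.

## Problem sizes used in the checks

The packaged study reproduction runs 5 seeds of $10^6$ true triples
(plus 4.9%/0.1%/0.003% randoms and $2\times10^6$ doubles) on a
384-crystal, 520-mm ring with 250 ps TOF, reconstructed on a 72 × 72 grid
of 1.25 mm voxels with OSEM 2 iterations × 3 subsets — a 2D desk-scale
analog of the published 3D study (94 M triples), chosen so one seed
simulates and reconstructs in well under a minute. Property tests run on
8 × 8 to 32 × 32 grids where dense-matrix oracles are exact.

## Known limitations

* 2D single-ring only; no oblique sinograms or depth of interaction.
* The estimator inherits the ratio image's noise behaviour: at low counts
  the lesion mean biases a few hundredths of a ns below truth (the bias
  halves when counts quadruple in the packaged study; the published 3D
  study sits at far higher counts). Regularisation is explicitly future
  work.
* Type II/III randoms are generated by an independent-draw approximation
  and are not corrected, mirroring the method's own scope.
* No scatter, attenuation or normalisation modelling; the $Q$-cancellation
  makes the lifetime image robust to these only insofar as they act
  equally on triples and doubles data.
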