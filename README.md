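# simplepli

Positron lifetime tomography in R: the **SIMPLE** method (Statistical
IMage reconstruction of Positron Lifetime via time-wEighting) for
time-of-flight PET triple coincidences, with a synthetic list-mode
simulator, a direct TOF-backprojection baseline, random-coincidence
correction, and timing-offset calibration.

## The problem

With a prompt-gamma-emitting radionuclide (⁴⁴Sc, ²²Na, ...), a TOF-PET
scanner can record *triple coincidences*: the two 511 keV annihilation
photons plus a prompt gamma marking positron birth. Each event yields a
TOF sinogram bin *i_k* and a lifetime measurement *τ_k*. The mean positron
lifetime — averaged over direct annihilation, para- and ortho-positronium
pathways, *m_j = Σ_l A_l/λ_l* — is sensitive to the tissue
microenvironment (o-Ps is quenched by pick-off annihilation and spin
exchange), making lifetime images a candidate biomarker for, e.g.,
hypoxia.

Voxel-wise spectral fitting is noisy and expensive. SIMPLE instead
reconstructs the *lifetime-weighted activity* `w = x·m` from per-bin
lifetime sums `z_i = Σ_{k∈K_i} τ_k` with a time-weighted MLEM update

    w_j ← w_j / Σ_i H_ij · Σ_i H_ij z_i / (Hw)_i

(the only change from MLEM: every event is weighted by its τ_k), then
forms the lifetime image as the randoms-corrected ratio

    m̂ = (ŵ̃ − ((t_r1+t_r2)/2)·γ·x̂₀) / (x̂̃ − γ·x̂₀) − μ̂

where `x̂̃` is the triples activity image, `x̂₀` the doubles activity
image, `γ` the type I randoms fraction estimated from a shifted
correction window, and `μ̂` the scanner timing offset. The cost is that of
two standard activity reconstructions. Prompt-gamma detection efficiency
cancels in the ratio and never needs to be measured.

## Worked example

Simulate a rodent-like 2D phantom — 10-mm lesion, activity ratio
10:15:2:1 (lesion:kidneys:liver:background), mean lifetime 0.8525 ns in
the lesion and 1.0025 ns elsewhere, 250 ps TOF — and reconstruct it:

```r
library(simplepli)

geom <- ring_geometry(384, 520, tof_fwhm = 0.25)   # 520-mm ring, 250 ps
grid <- image_grid(72, 72, spacing = 1.25)          # 1.25-mm voxels
phan <- rodent_phantom(grid)
rois <- phantom_rois(phan)

ev <- simulate_triples(phan, geom, timing_model(0.092, 0), n_true = 1e6,
                       randoms = c(0.049, 0.001, 0.00003), seed = 1)
db <- simulate_doubles(phan, geom, 2e6, seed = 501)

cfg <- recon_config(n_iterations = 2, n_subsets = 3,
                    windows = time_windows(c(-1, 15), c(-20, -5)))
res <- reconstruct_simple(ev, geom, grid, cfg, doubles = db,
                          background_roi = rois$background)
evaluate_rois(res, rois)
```

which prints (seed 1; truth 0.8525 ns lesion, 1.0025 ns elsewhere; means
and voxel noise in ns over the labelled regions, inside the 50 %-of-
background activity mask):

```
         roi      mean         sd n_voxels
1 background 0.9866921 0.11646532     1448
2      liver 0.9903724 0.09410054      162
3     kidney 0.9955232 0.06164449      120
4     lesion 0.8465037 0.05876873       51
```

The direct TOF-backprojection baseline (`reconstruct_tofbp()`, same call
signature) reads 0.897 ns in the lesion on the same events: its

resolution is limited by the ~16-mm TOF kernel, so the low-lifetime
lesion is contaminated by the longer-lived surroundings — the
partial-volume bias the iterative method removes.

A raw singles stream can be processed the same way:
`simulate_singles()` → `group_triples()` (take-all-good policy) →
`triples_to_events()` (travel-time correction) → `reconstruct_simple()`.
The scanner timing offset is calibrated with `histogram_spectrum()` +
`fit_offset()` (two-component exponentially-modified-Gaussian fit with
uniform background). A command-line front end for all steps is installed
at `inst/cli/simplepli.R` (subcommands `simulate`, `group`, `calibrate`,
`reconstruct simple|tofbp`, `evaluate`).

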