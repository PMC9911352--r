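# phasorUnmix

Hybrid phasor-encoded linear unmixing (HyU) for hyperspectral fluorescence
microscopy, with a synthetic spectral-image simulator and quantitative
evaluation tools.

## The problem

Multiplexed fluorescence imaging records a full emission spectrum (here 32
channels, 410.5–694.9 nm at 8.9 nm binning) at every voxel and must
decompose each spectrum into fluorophore abundances. Live samples force low
excitation, so pixels carry only a handful of photons; per-pixel linear
unmixing (LU) then amplifies Poisson noise into channel cross-talk, and a
gigavoxel time-lapse needs one solver call per voxel. This package is for
microscopists and image analysts who need reliable unmixing of
photon-starved hyperspectral data — fluorophores and autofluorescence alike
— and a controlled synthetic benchmark to quantify it.

## The method

Each pixel spectrum `I_j` is mapped to spectral phasor coordinates at
harmonic `n`:

    G(n) = Σ_j I_j cos(nωj) / Σ_j I_j ,   S(n) = Σ_j I_j sin(nωj) / Σ_j I_j ,   ω = 2π/c.

Similar spectra cluster in the phasor plane independent of brightness. A
2-D histogram groups pixels into bins, whose average spectra cancel photon
noise; optional 3×3 median filters on the G/S maps (0–5 passes) suppress it
further. Linear unmixing

    I(λ) ≈ Σ_i R_i · fp_i(λ),   Σ_i R_i = 1,  R_i ≥ 0

is solved once per occupied bin (normal equations by default; NNLS, FCLS
and fixed-spectra NMF also provided), and the per-bin ratios are broadcast
back to member pixels and scaled by each pixel's own intensity integral.
Accuracy improves where photons are scarce, and the solve count drops from
the voxel count to the occupied-bin count.

## Worked example

```r
library(phasorUnmix)

sim <- simulate_biological(photons_target = 16, image_size = 128, seed = 1)
lu  <- lu_pixelwise(sim$cube, default_library())
hy  <- hyu(sim$cube, default_library(), passes = 5)

hy
#> <unmixed_image> method=hyu solver=lstsq, t=1 z=1 i=4 y=128 x=128
#>   solver calls: 5135

mse(lu, sim$truth)$overall   # 26379 DL^2
mse(hy, sim$truth)$overall   # 15930 DL^2
residual_map(sim$cube, lu)$summary$mean   # 82.9 %
residual_map(sim$cube, hy)$summary$mean   # 49.5 %

operations_count(c(512, 768, 17, 6))$pixelwise_millions  # 40
```

At 16 expected photons per spectrum, hybrid unmixing needed 5,135 solver
calls instead of 16,384 (one per pixel), cut the mean squared error against
ground truth from 26,379 to 15,930 DL², and reduced the mean relative
unmixing residual from 82.9% to 49.5%. The last line shows the computational
contrast for a realistic time-lapse volume: pixelwise unmixing would need
~40 million solves, while hybrid unmixing needs one per occupied phasor bin
(typically thousands).

`photon_sweep()` runs the full photon-starvation benchmark (LU vs HyU at
0–5 filters across a photon grid with seeded replicates) and returns a tidy
tibble; `summarize_sweep()`, `glance()` and `autoplot()` summarize and plot
it. A command-line interface (`inst/cli/phasorunmix`, or `hyu_main()` from
R) exposes `simulate`, `unmix`, `phasor`, `metrics` and `sweep`
subcommands over TIFF/CSV/JSON files.

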