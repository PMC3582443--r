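# spintraj

Trajectory-based EPR analysis for spin-labeled proteins.

Site-directed spin labeling (SDSL) attaches a nitroxide side chain (MTSSL,
"R1") to an engineered cysteine; the continuous-wave EPR spectrum of the
label then reports on how freely the nitroxide reorients, and pairs of
labels report on intra-molecular distances. Relating those measurements to
structure requires turning *orientation trajectories* of the nitroxide —
from molecular dynamics or from a model of restricted rotational diffusion
— into the observables an experiment produces. `spintraj` implements that
pipeline for R users in structural biology and magnetic resonance:

* **Nitroxide frame geometry** — x along the N-O bond, z along the
  nitrogen p orbital; label position at the N-O midpoint.
* **β-angle statistics** — β is the deviation of the nitroxide z-axis from
  the mode of its orientational distribution; histograms with Gaussian
  fits, FWHM, and the mobility parameter ⟨(Δβ)²⟩ (raw and normalized by
  the uniform-sphere reference π²/4 − 2 rad²).
* **cw EPR spectrum simulation** — first-derivative X-band spectra from
  the time-dependent resonance offset
  Δω(t) = (μ_B B₀/ħ)(g_eff − g_ref) + m_I γ A_eff with
  g_eff = Σ g_ii n_i², A_eff = Σ A_ii n_i²; FID accumulation, Fourier
  transform to field, Gaussian broadening, central peak-to-peak linewidth
  ΔH₀ and its inverse; rigid-limit (powder) and fast-limit closed-form
  reference spectra; mobile/immobile spectral-weight diagnostic.
* **Distance distributions** — inter-nitroxide distance series, Gaussian
  mixture decomposition (EM + BIC) into modes "m1(w1%) m2(w2%)".
* **RMSF** — per-residue Cα fluctuations after proper-rotation
  least-squares superposition onto an iterated mean reference.
* **Mobility painting** — writing mobility values into the B-factor
  column of a PDB file (optionally scaled, e.g. ×1.5) for structure-viewer
  color maps.
* **Synthetic dynamics generator** — rotational Brownian dynamics in a
  uniaxial orienting potential U/kT = −λ cos²β (order parameter S(λ)
  available in closed quadrature form), slow two-state mobile/immobile
  exchange, Gaussian-mixture distance fluctuations, and
  helix/loop-patterned Cα ensembles, all bit-reproducible from a seed.

Multi-model PDB I/O is handled through `bio3d`; the orientation-trajectory
exchange format is plain text (a `dt_ps` header plus nine reals per frame,
row-major rotation matrices, validated orthonormal on read).

## Worked example

```r
library(spintraj)

# a restricted label: 30 ns of rotational Brownian dynamics, lambda = 5 kT
p <- dynamics_params(D_rot = 0.5, lambda_ord = 5, dt_ps = 2,
                     n_steps = 15000, seed = 42)
traj <- simulate_orientation(p)

order_parameter(traj)           # sampled S
#> [1] 0.6736132
maier_saupe_order_parameter(5)  # Boltzmann value it converges to
#> [1] 0.6463993

bs <- beta_series(traj)
bd <- beta_distribution(bs)
round(c(mu = bd$gaussian_mu, sigma = bd$gaussian_sigma, fwhm = bd$fwhm), 2)
#>    mu sigma  fwhm
#> 22.43 13.90 32.73
round(unlist(mobility_parameter(bs)), 3)
#>            msf_beta normalized_mobility
#>             184.694               0.120

# cw EPR spectrum of an isotropic ensemble of such labels
trajs <- randomize_directors(
  lapply(1:20, function(i) simulate_orientation(
    dynamics_params(D_rot = 0.5, lambda_ord = 5, dt_ps = 2,
                    n_steps = 15000, seed = 42 + i))),
  seed = 1)
sp <- simulate_spectrum(trajs, magnetic_tensors(), spectrum_settings())
sp
#> <epr_spectrum> 1024 points, 332..344 mT, dH0 = 0.3002 mT

# a bimodal inter-label distance distribution, decomposed
d <- simulate_distance_series(list(c(7.3, 0.3, 0.65), c(9.0, 0.3, 0.35)),
                              2000, seed = 1)
decompose_distribution(d)
#> <distance_distribution> n = 2000, mean = 7.89 A, FWHM = 2.20 A, components: 7.31 (65%) / 8.99 (35%)
```

The sampled order parameter sits near its Boltzmann value; a λ = 5 label
shows a ~33° wide β distribution and a normalized mobility of 0.12
(strongly restricted); the ensemble spectrum has a 0.30 mT central
linewidth; and the mixture decomposition recovers the 7.3/9.0 Å modes at
their 65/35 weights.

## The demo pipeline

```sh
Rscript inst/cli/spintraj.R fixtures --seed 1 --outdir fx
Rscript inst/cli/spintraj.R run-all --config fx/config.yaml --outdir out
```

generates the full synthetic study (twelve labeled sites on an idealized
five-helix bundle, residues 879–1066) and writes per-site β and mobility
tables, spectra and linewidths, distance decompositions, an RMSF profile,
a mobility-painted PDB, and a manifest with md5 sums; rerunning the same
configuration reproduces every output byte-identically. The same
functionality is available in R via `make_fixtures()` and
`run_pipeline()`.

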