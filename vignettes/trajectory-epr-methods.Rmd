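---
title: "Methods: from orientation trajectories to EPR observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from orientation trajectories to EPR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spintraj)
```

# Scope

`spintraj` turns time series of nitroxide spin-label orientations into the
quantities site-directed spin labeling (SDSL) EPR reports on: the
distribution of the reorientation angle beta, scalar mobility parameters,
simulated first-derivative continuous-wave (cw) spectra with central
linewidths, inter-label distance distributions with mixture decomposition,
per-residue root-mean-square fluctuations (RMSF), and mobility maps written
into the B-factor column of PDB files. Because full atomistic molecular
dynamics of a labeled protein is outside the package's scope, a rotational
Brownian dynamics generator with controlled orientational order stands in
for MD trajectories; it produces data with the statistical structure the
analysis assumes, so every stage can be validated against closed-form
oracles.

# The nitroxide frame and the beta angle

The nitroxide molecular frame has x along the N-O bond, z along the
nitrogen p orbital (perpendicular to the ring plane), and y completing a
right-handed system; `build_frame()` constructs it from the N, O and one
ring-carbon position, and uses the N-O bond midpoint as the point position
of the label (the unpaired spin density is shared between N and O; any
other convention shifts inter-label distances by well under the width of
the distributions analyzed here). The tether angles relating the frame to
the side-chain are not analyzed; all orientational statistics are carried
by the z-axis.

The mobility coordinate is the angle beta between the instantaneous z-axis
and the *mode* of its orientational distribution. The mode is estimated by
a spherical kernel density estimate with a Fisher kernel evaluated at the
sample directions and refined by mean-shift iterations
(`estimate_mode_axis()`). The kernel concentration is set to
1/(circular variance) of the z sample — sharp for concentrated clouds,
flat for diffuse ones; both the candidate set and the kernel sample are
thinned by fixed stride for long trajectories, and ties between antipodal
maxima are resolved into the hemisphere of the first frame. All choices
are deterministic, so the same trajectory always yields the same axis.

# The synthetic dynamics generator

`simulate_orientation()` integrates rotational Brownian motion on SO(3)
with an Euler scheme: each step composes the current frame with a random
lab-frame rotation whose rotation-vector components are iid
Normal(0, 2 D dt), followed by a deterministic drift that rotates the
z-axis toward the nearer minimum of a uniaxial (Maier-Saupe-type)
orienting potential

$$U(\beta)/k_BT = -\lambda\,\cos^2\beta$$

about the lab z-axis, by the angle $D\,\lambda\,\sin(2\beta)\,dt$. The
stationary density of the z-axis is then the Boltzmann density
$\propto e^{\lambda\cos^2\beta}$ on the sphere, up to an Euler
discretization bias controlled by the step-size precondition (per-step
angular displacement sd below 0.2 rad). The equilibrium order parameter

$$S(\lambda) = \frac{\int_0^\pi P_2(\cos\beta)\,e^{\lambda\cos^2\beta}
\sin\beta\,d\beta}{\int_0^\pi e^{\lambda\cos^2\beta}\sin\beta\,d\beta}$$

is available in closed quadrature form
(`maier_saupe_order_parameter()`), and the test suite checks that the
simulated S converges to it at lambda = 0, 2, 5 and 10.

Parameters and defaults: `D_rot` (rotational diffusion coefficient,
rad^2/ns, default 0.5 — a ~0.3 ns correlation time, typical of a nitroxide
side chain), `lambda_ord` (ordering strength in kT units, default 3),
`dt_ps` (default 2 ps, a typical snapshot spacing), `n_steps` (default
15000, i.e. a 30 ns run). Temperature is bookkeeping only: the potential
is expressed in kT units, so a hotter, restraint-softened condition is
emulated by lowering `lambda_ord`, not by a thermostat. One global seed
fans out to per-trajectory streams by fixed increments, making whole
ensembles reproducible.

Three deliberate consequences of this design are worth noting:

* **The potential is antipodally symmetric.** A long trajectory at
  moderate lambda occasionally crosses between the two equivalent wells
  (+z and -z), so a beta histogram taken against the estimated mode can
  carry a minority peak near 180 degrees. Real labels are tethered and do
  not populate the antipodal orientation; the analysis therefore fits the
  Gaussian around the dominant histogram peak (see below).
* **The director is the lab z-axis for every trajectory.** For ensemble
  spectra this would represent a macroscopically oriented sample;
  `randomize_directors()` composes each trajectory with one fixed random
  rotation, which makes the ensemble isotropic — each label then librates
  about its own random axis, as labels on randomly oriented proteins do —
  without changing any single-trajectory statistics relative to its own
  director.
* **Exchange is slow.** `simulate_exchange()` assigns each trajectory to
  the mobile or immobile mode for its whole length; two-component spectra
  arise from superposition, not from intra-trajectory switching.

`simulate_distance_series()` draws inter-label distances from a Gaussian
mixture truncated at zero (unimodal or bimodal fluctuation patterns), and
`simulate_ca_ensemble()` builds multi-model CA ensembles from an idealized
coil trace (3.8 Angstrom CA-CA spacing, non-collinear by construction)
with per-segment isotropic Gaussian displacements — small for helices,
large for loops — optionally composed with a random global rigid motion
per model. The bundled demo emulates a five-helix bundle over residues
879-1066 with twelve labeled sites whose ordering strengths follow the
buried/exposed pattern of such a fold; the helix limits are round-number
placeholders, labelled synthetic, not deposited coordinates.

# Beta statistics and the mobility parameter

`beta_distribution()` bins beta on [0, 180] degrees (default bin width 2
degrees) and fits $a\,e^{-(x-\mu)^2/2\sigma^2}$ to (bin center, density)
by unweighted least squares — the red-curve-on-histogram procedure — and
reports FWHM $= 2\sqrt{2\ln 2}\,\sigma$. The fit uses the bins within 60
degrees of the dominant peak so that a minority antipodal population
cannot drag it away from the main orientation mode; bounds keep mu in
[0, 180] and sigma positive. If the fit fails or collapses below one bin
width, the result is flagged and the FWHM falls back to the empirical
half-maximum crossing width, bounded below by one bin.

The scalar mobility parameter is the mean-square fluctuation amplitude
$\langle(\Delta\beta)^2\rangle$ about the series mean, in deg^2. (The
deviation is taken from the mean, not the mode, so that the variance
identity msf = sigma^2 holds exactly for Gaussian series; the
distribution analysis still uses the mode, per the definition of beta.)
Because no universal normalization exists for this quantity, both the raw
value and a normalized variant are reported; the latter divides by the
beta variance of a uniform distribution on the sphere,
$\pi^2/4 - 2\ \mathrm{rad}^2 \approx 1534\ \mathrm{deg}^2$ — the
free-diffusion limit — and clips to [0, 1], which maps rigid to 0 and
freely diffusing to 1 and is the scale used when mobility is painted into
B-factors.

# Spectrum simulation

`simulate_spectrum()` implements the standard trajectory-based lineshape
calculation. For each trajectory and each ^14N hyperfine manifold
$m_I \in \{-1, 0, +1\}$ the resonance offset

$$\Delta\omega(t) = \frac{\mu_B B_0}{\hbar}\left(g_{\mathrm{eff}}(t) -
g_{\mathrm{ref}}\right) + m_I\,\gamma\,A_{\mathrm{eff}}(t)$$

is accumulated into a phase; the free induction decay
$\langle e^{-i\phi(t)}\rangle\,e^{-t/T_2}$ is averaged over trajectories
and manifolds with equal weights, Fourier transformed, and mapped to field
via $\Delta B = -\Delta\omega\,\hbar/(g_{\mathrm{ref}}\mu_B)$ with
$g_{\mathrm{ref}} = g_{\mathrm{iso}}$; the absorption is convolved with a
Gaussian (inhomogeneous broadening, standard deviation
`gaussian_broadening_mT`) and differentiated with a central finite
difference.

With the lab field direction expressed in the nitroxide frame as
$n = R^{\mathsf T}\hat z$, both interactions use the same first-order
secular quadratic form:

$$g_{\mathrm{eff}} = \sum_i g_{ii} n_i^2, \qquad
A_{\mathrm{eff}} = \sum_i A_{ii} n_i^2 .$$

Using the quadratic form for A (rather than the root-sum-square form some
adiabatic treatments use) is deliberate: its isotropic motional average is
exactly $a_{\mathrm{iso}} = (A_{xx}+A_{yy}+A_{zz})/3$, so the
motional-narrowing limit lands on the correct three-line splitting, while
the rigid-limit outer splitting is still $2A_{zz}$ (the outer extrema come
from orientations with z along the field, where both forms coincide).
Nonsecular terms and the nuclear Zeeman interaction are neglected — the
standard X-band first-order treatment — so the spectrum is exact in the
static and fast limits and approximate at intermediate rates.

Numerical choices: the phase is accumulated at the trajectory time step
(per-step increment must stay below 0.5 rad, enforced), but the FID is
stored at a coarser, automatically chosen interval whose Nyquist range
still covers the spectral content, and zero-padded so the transform grid
is finer than the requested field axis. Trajectories shorter than the FID
window (default 500 ns, at least 5 T2) are extended by periodically
repeating their phase increments, which is phase-continuous by
construction; the repetition artifacts are sidebands far outside the
swept window that additionally average out over an ensemble. Default
tensors are literature-standard MTSSL values (g = 2.0086, 2.0066, 2.0026;
A = 0.52, 0.52, 3.5 mT), fully configurable; acquisition defaults are
B0 = 338 mT, 12 mT sweep, 1024 points, T2 = 50 ns, 0.1 mT broadening.

Two independent field-domain references exist for validation:
`rigid_limit_spectrum()` sums closed-form Lorentzian lines over a
deterministic Fibonacci orientation grid (powder pattern), and
`fast_limit_spectrum()` places three Lorentzians at the isotropic
position. The test suite requires the trajectory path to agree with the
powder reference in normalized RMS and to reproduce the closed-form
Lorentzian peak-to-peak width $\Delta H_{pp} = 2/(\sqrt3\,\gamma T_2)$.

`central_linewidth()` reports the peak-to-peak width of the central
(m_I = 0) derivative line, searching a window of 0.6 a_iso around the
center field and refining extremum positions by parabolic interpolation;
if the window contains no positive-then-negative lobe pair the spectrum
is reported as unresolved rather than guessed. `classify_components()`
integrates absorption weight in an immobile window at the low-field
hyperfine extreme (center - Azz +/- 1 mT) and a mobile window around the
center — a descriptive diagnostic of two-component spectra, not a fit.

# Distance distributions

Inter-nitroxide distances are N-O midpoint separations per model.
`decompose_distribution()` fits 1- and 2-component Gaussian mixtures by
EM with deterministic quantile-based initialization (component means at
the 25th/75th percentiles) and selects the component count by BIC, which
penalizes the second component conservatively at the sample sizes used
here; a selected component with weight below 1% is collapsed and flagged.
The overall FWHM is read off the fitted mixture density by half-maximum
crossing, which reduces to $2\sqrt{2\ln2}\,\sigma$ for one component.
Histogram bin width defaults to 0.25 Angstrom (the features of interest
are sub-Angstrom).

# RMSF

`superpose()` performs rigid-body least-squares superposition (SVD
solution with the determinant constrained to +1, so reflections are never
applied) of every model onto the first model and then once more onto the
mean of that pass — one refinement iteration keeps the reference
deterministic. `rmsf()` is the per-residue root-mean-square deviation
about the ensemble mean position; summed over residues, rmsf^2 equals the
total mean-square deviation of the selection (an identity the tests check
to 1e-9). Equilibration trimming is exposed as `skip_models`.

# Pipeline and reproducibility

`make_fixtures()` writes the full synthetic input set and a demo
configuration; `run_pipeline()` validates the configuration (flat
key-value YAML, versioned schema, unknown keys rejected; a missing tensor
block falls back to the MTSSL defaults with a warning), executes all
stages, and writes a manifest with the seed and the md5 of every output.
Problem sizes in the demo (12 sites, 8 ns trajectories at 2 ps, 8
trajectories per site spectrum, 2000 distance samples, 40-model CA
ensemble) are chosen so a full run takes seconds on one CPU while every
downstream contrast (wide vs narrow beta distributions, broad vs narrow
central lines, unimodal vs bimodal distances, loop vs helix RMSF) remains
clearly resolved. Rerunning with the same configuration is byte-identical.

When a deposited structure is analyzed, chain selection is explicit: the
paper-style residue numbering is kept exactly as deposited, and
`chain_covering()` exposes the choice of chain as a visible parameter
rather than a silent guess; alternate locations other than blank/'A' are
dropped so derived distances are deterministic.

# What the synthetic data does and does not show

The generator reproduces the statistical structure the analysis assumes:
restricted rotational diffusion with tunable order, slow two-state
exchange, Gaussian-mixture distance fluctuations, and helix/loop-patterned
coordinate ensembles. It does not model the R1 side-chain chemistry
(rotamer states, chi-dihedral correlations), protein-specific tertiary
contacts, solvent, or anisotropic (non-uniaxial) ordering; and inter-label
distances are sampled directly rather than derived from a fluctuating
structure. Passing tests therefore demonstrate that the analysis chain
recovers known inputs under realistic noise — not that any particular
protein's MD ensemble would be reproduced. Real-data magnitudes
(per-residue mobility values, spectral lineshape details at intermediate
motion, absolute RMSF) depend on the underlying trajectories and force
fields and are outside what desk-scale synthetic data can certify.

# Known limitations

* First-order secular spin Hamiltonian: intermediate-regime lineshapes
  are approximate (no nonsecular contributions, no nuclear Zeeman, no
  field modulation model).
* The Euler integrator has an O(D dt) equilibrium bias; the step-size
  guard keeps it within the tolerances the tests assert, but very strong
  potentials need proportionally smaller steps.
* The Gaussian beta fit targets the dominant peak by design; genuinely
  multimodal beta distributions (two rotameric states) are better read
  from the histogram itself, and the fit flag marks degenerate cases.
* Mixture decomposition assumes Gaussian components; heavy-tailed or
  skewed distance distributions will be summarized, not modeled.
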