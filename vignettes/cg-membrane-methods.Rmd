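---
title: "Methods: coarse-grained lipid membranes, splay elasticity and parameter sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained lipid membranes, splay elasticity and parameter sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmembrane)
```

This vignette documents the models and numerical choices behind
`cgmembrane`: what each estimator assumes, which knobs matter, what the
synthetic generators do and do not emulate, and where the design was
genuinely open.

## The coarse-grained model

Each phosphatidylcholine lipid is represented by 13–17 beads, each bead
standing for 2–4 heavy atoms plus their hydrogens and placed at the
group's center of mass. The head region uses a choline bead (CHO, 4:1),
a phosphate bead (PO2, 3:1), a glycerol-backbone bead (COH, 3:1) and one
ester bead per chain (MTF, 4:1); acyl chains are partitioned into
3-carbon mid beads (C3M), 2-carbon filler beads (C2M), a 3-carbon bead
containing any cis double bond (D3M), and terminal beads carrying the
methyl end (C3E/C2E). Water maps two molecules to one W bead. All beads
are neutral: zwitterionic PC bilayers assemble through hydrophobic and
steric interactions, so the model omits explicit electrostatics entirely
(this is a modeling assumption, not a numerical approximation — charged
lipids are out of scope).

The potential is

$$E = K_b (b - b_0)^2 + K_\theta (\theta - \theta_0)^2 +
      4\varepsilon\left[\left(\tfrac{\sigma}{r}\right)^{12} -
      \left(\tfrac{\sigma}{r}\right)^{6}\right]$$

with the CHARMM/NAMD conventions throughout: no ½ on the harmonics,
Å / kcal/mol / amu / fs units, $k_B = 0.0019872041$ kcal/mol/K, angles in
degrees in files and radians internally. Dihedrals and impropers are
deliberately absent (they would force smaller timesteps for little gain
at this resolution). Unparametrized bead pairs resolve through
Lorentz–Berthelot mixing; explicit pair overrides (the headgroup–water
terms) take precedence. Nonbonded interactions are truncated at 12 Å by
default — plain truncation, matching the target simulation engine; an
energy-shifted variant (`lj_shift = TRUE`) is available and is what the
energy-conservation tests use, since plain truncation injects an energy
jump whenever a pair crosses the cutoff. Exclusions default to 1–2
(directly bonded pairs only), so beads joined through an angle still
interact sterically; the 1–3 policy is implemented for comparison because
angle-connected head-region beads sit close enough to feel van der Waals
repulsion, and removing it measurably changes bonded distributions.
Minimum-image periodicity supports orthorhombic boxes only.

The shipped parameter file (`extdata/cg_lipid_synthetic.prm`) is a
*synthetic, best-effort* parameter set covering every packaged template in
the CHARMM dialect (negative well depths, `r_min/2` column). It exists so
that loaders, the toy engine and demos run out of the box; it is not an
optimized production force field, and no test depends on its specific
values.

## Membrane structural observables

Lipids are assigned to leaflets by the sign of their PO2 bead's height
relative to the instantaneous mean PO2 plane — translation-invariant and
robust for planar bilayers. `A_L` is the lateral box area divided by the
per-leaflet lipid count (leaflets averaged when unequal); `D_PP` is the
distance between the two leaflet-mean PO2 planes. This plane-mean
estimator, rather than a density-peak distance, was chosen because it is
unbiased and low-variance at the 10²-lipid scale where peak fitting is
noisy; for vesicles, radial density profiles provide the peak-based
alternative. The hydrophobic thickness `2D_C` is measured between the
mean planes of each leaflet's first chain beads (the beads bonded to the
ester region); the literature does not fix this estimator precisely, so
the boundary bead set is an argument.

Long-run properties are summarized by block averaging: window means form
block values, the reported value is their unweighted mean and the spread
their standard deviation. Published validation tables that aggregate
per-block means carry a "±" that is the root-sum-square of per-block
spreads rather than the across-block standard deviation; the package
reports the latter (it is the honest between-block dispersion) and keeps
full precision internally, rounding only for display.

## Bending modulus by real-space splay fluctuations

The bending modulus is estimated from the statistics of local splay: for
every lipid tail, the angle $S$ between the tail vector (first chain bead
to terminal bead) and the local bilayer normal, obtained from a
least-squares plane through same-leaflet PO2 neighbors within 15 Å (with
a global-z fallback below 3 neighbors). Pooling $S$ from all lipids and
frames, the distribution follows a Boltzmann form

$$P(S) = C \exp\!\left(-\frac{\kappa\, S^2 a_L}{2 k_B T}\right),$$

so the potential of mean force is quadratic:
$-(2 k_B T / A_L)\,\ln P(S) = \kappa S^2 + C'$. Unlike Fourier undulation
analysis, this real-space method needs no large box — the locality of the
statistic is what makes 10²-lipid systems usable.

Numerical choices, all configurable:

* **Units in the exponent.** With $\kappa$ in $k_B T$ and $S$ in radians,
  dimensional consistency requires $a_L$ in the exponent to carry the
  nm² scale of the splay-fluctuation literature; Å² inputs are converted
  internally ($a_L = A_L/100$). Under this reading a fluid bilayer with
  $\kappa \approx 20\,k_BT$ shows splay fluctuations of ≈ 9–15°, which is
  precisely what 2° histogram bins and ±1σ…±2σ fit windows presuppose;
  reading $a_L$ in Å² would concentrate the distribution into a single
  bin and make the stated protocol unusable. The sampler
  (`sample_splay()`) and the fitter (`fit_kappa()`) share one density
  definition (`splay_density()`), so the generator/estimator round-trip
  tests the fit itself, not the unit convention.
* **Histogramming.** 2° bins on $[0, \pi/2]$; empty bins are dropped (no
  pseudo-counts), and the weighted least squares uses bin counts as
  weights so sparsely populated tail bins cannot dominate.
* **Windows.** Five windows centered on the sample mean with half-widths
  1.0, 1.25, 1.5, 1.75, 2.0 σ — linear interpolation between the stated
  ±1σ and ±2σ endpoints, since only the endpoints and the count of five
  are fixed by the protocol. κ is reported from the ±1σ window; the
  standard deviation of the five slopes is the quoted uncertainty. A
  window with fewer than three populated bins is a fit error rather than
  a silent extrapolation.
* **Sampling domain.** The synthetic sampler draws by inverse CDF from
  the truncated density on $[0, \pi/2]$ without a solid-angle Jacobian:
  the quadratic-PMF fit inverts exactly the stated density, and
  self-consistency between the two is what the method assumes. On
  noise-free densities the fit is exact to machine precision, which the
  tests assert at $10^{-6}$ relative.
* **Splay definition.** The splay is tail-vector-versus-local-normal, as
  the protocol words it, not the pairwise director-divergence variant of
  the older fluctuation literature; the histogram/fit layer is agnostic
  to the sample source, so the alternative can be plugged in upstream.

At $5\times10^5$ samples the fit recovers generating moduli across
15–35 $k_BT$ with median error well under 5%, and the ±1σ/±2σ window
spread shrinks with sample size.

## Area compressibility

Two estimators are provided. From projected-area fluctuations,
$K_A = k_B T \langle A\rangle / \mathrm{var}(A)$ with $A$ the *total*
box cross-section (the common convention; with Å² inputs the result in
mN/m is $1.380649\,T\,\langle A\rangle/\mathrm{var}(A)$). From local
thickness fluctuations, each frame's PO2 surfaces are mapped onto a
lateral grid and the constant-volume relation $\delta A/A = -\delta t/t$
converts per-cell thickness variance into
$K_A = k_B T\, \bar t^2 / (a_{cell}\, \mathrm{var}\,t)$, averaged over
cells; the cited real-space method does not print its formula, so this
documented closed form is the package's own choice, validated by
round-trip against a synthetic thickness field of prescribed variance.
Empty cells are dropped with a warning; a fluctuation-free input is an
error, not a zero.

## The toy MD engine

The engine integrates the CG potential with velocity Verlet wrapped in a
BAOAB Langevin thermostat (γ in 1/ps; γ = 0 recovers NVE) and an optional
Berendsen-style barostat (isotropic, or xy-coupled for membranes), with a
hard divergence guard that aborts with advice to reduce the timestep.
Forces come from the same compiled kernel as `total_energy()`, and the
binding contract — forces equal the negative numerical gradient to 1e−4
relative — is asserted in the tests, as are the harmonic-dimer
oscillation period, equipartition at 298 K within 3%, NVE drift below
1e−4 relative per 10⁴ steps, and bitwise reproducibility per seed. Pair
interactions use a plain $O(N^2)$ minimum-image loop rather than a cell
list: at the ≤ 10²–10³-bead scale this engine targets, a cell list buys
nothing and the single code path doubles as the oracle-comparable route.
This engine exists for correctness plumbing and toy demos (dimer
oscillations, 64-bead fluids, micelle-scale aggregates), not production
membranes; production-scale work should export parameter files to a real
MD engine.

## Parametrization and the surrogate

The optimization objective is the weighted sum of relative errors over
lipids and properties,
$\sum_\ell \sum_p w_p\,|x_p^{sim} - x_p^{exp}|/x_p^{exp}$ with
$w = (1.5, 1.2, 1.0)$ for $(A_L, D_{PP}, \kappa)$ — relative errors are
the only scale-free combination consistent with percent-error accounting,
and the weights prioritize the structural observables. Failed property
evaluations contribute a penalty (10× the worst observed error) instead
of shrinking the swarm. The PSO is the standard global-best variant with
constriction defaults (w = 0.729, c₁ = c₂ = 1.49445), five particles,
bound clamping with velocity zeroing, and per-seed determinism.

Because full MD inside an optimization loop is not desk-scale, an
analytic surrogate backend with a planted optimum stands in for the
simulator in end-to-end tests. Its responses carry the qualitative signs
seen in practice (area per lipid rises with self-interaction σ;
headgroup–water σ pushes water between head beads and thins the bilayer,
so $D_{PP}$ falls) and are modulated per lipid with distinct sign
patterns per parameter. That modulation is deliberate: it keeps the
stacked parameter→property Jacobian well conditioned, so the planted
optimum is the unique zero of the objective and a 5-particle swarm
reaches it to machine precision. With near-collinear responses the
weighted-L1 objective develops oblique polyhedral valleys in which small
swarms stagnate — a property of the objective geometry, not of the
optimizer implementation, and worth knowing when fitting real backends
with few particles.

## Sensitivity analysis

Parameter robustness is probed by perturbing each parameter within ±5%
of its base value on a Sobol low-discrepancy design (n = 5000 by
default). The Sobol generator is implemented in the package (Gray-code
construction over the published Joe & Kuo (2008) direction numbers,
dimensions ≤ 23, first point included) because no installed R package
provides one; a seed applies a per-dimension digital-shift scramble and
the unscrambled points are pinned against an independent reference
implementation in the tests. Property tables are screened in a single
pass, dropping rows where any property deviates more than 3σ (sample sd)
from its column mean — joint across columns, since a run that is an
outlier in any observable is suspect as a whole. Dispersion is summarized
as the coefficient of variation (100·sd/mean, sample sd), and
parameter–property association as partial correlation coefficients:
Pearson correlation of the residuals of $x_j$ and $y$ after regressing
each on all other parameters. On jointly Gaussian data this equals the
precision-matrix formula $-\Omega_{jy}/\sqrt{\Omega_{jj}\Omega_{yy}}$,
which the tests assert to 0.02 at n = 5000. The |PCC| > 0.2 threshold
used when annotating heatmaps is a presentation filter, not a statistic.

## Synthetic generators: what they do and do not emulate

Every estimator in the package is validated against generators that
produce data with exactly the statistical structure the estimator
assumes: lattice bilayers with prescribed $A_L$/$D_{PP}$ and Gaussian
jitter, concentric-shell vesicles on Fibonacci lattices, Boltzmann splay
samples, Gaussian area series with variance implied by a target $K_A$,
and random mixtures with minimum-separation packing. Fixtures are built,
not simulated, so estimator tests cannot fail through simulation quality;
each generator is deterministic per seed and echoes its spec as
provenance metadata.

The corresponding caveat: passing these tests shows the estimators are
correct *given their assumptions* — planar bilayers normal to z,
Gaussian fluctuations, a quadratic splay PMF, uncorrelated frames. Real
trajectories add undulations, protrusions, frame-to-frame correlation
and non-Gaussian tails that the generators deliberately omit; block
averaging addresses correlation, but none of the tests here certify
force-field quality on real membranes.

## Degenerate inputs and tie-breaks

Zero-variance distributions (harmonic inversion, $K_A$ series, thickness
fields) raise typed errors rather than returning infinities. Odd water
counts leave one molecule unpaired with a warning. Collinear angle
geometries guard the $1/\sin\theta$ force singularity at $10^{-8}$.
Distances exactly on an RDF bin edge count into the upper bin
(left-closed binning). Molecules are made whole across periodic
boundaries before centroids are taken, since a centroid of wrapped
coordinates is meaningless. A single-leaflet "bilayer" warns rather than
fails, because vesicle intermediates legitimately look that way.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
bilayers of 16–200 lipids, trajectories of 2–120 frames, fluids of 64
beads, 10⁴ MD steps, $2\times10^5$–$10^6$ splay samples, Sobol designs of
256–5000 points. These sizes were chosen so that every check closes its
statistical tolerance with comfortable margin while the whole suite stays
fast enough to run on every change.
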