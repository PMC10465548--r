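---
title: "Methods: atomistic liquid-liquid phase equilibrium with phasemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atomistic liquid-liquid phase equilibrium with phasemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasemap)
```

## The problem and the model

Structured proteins such as the eye-lens gamma-crystallins phase separate
into dilute and dense liquid phases only at very high concentrations and
low temperatures, driven by weak, nonspecific pairwise attractions. The
thermodynamics are fully encoded in the chemical potential
$\mu(\rho, T) = \mu_\mathrm{id} + \mu_\mathrm{ex}$: the ideal part is
$\beta\mu_\mathrm{id} = \ln(\rho/\rho_0)$ and the excess part is obtained
by Widom test-particle insertion,
$e^{-\beta\mu_\mathrm{ex}} = \langle e^{-\beta U(\mathbf X, \Omega,
\mathbf R)}\rangle$, where $U$ is the interaction energy of a fictitious
test copy (position $\mathbf R$, orientation $\Omega$) with a sampled
solution configuration $\mathbf X$.

Each molecule is rigid, and the pair energy is additive over cross pairs
of atoms:

$$u_{ij}(r) = u^{\mathrm{st}}_{ij}(r) + s_1\, u^{\mathrm{np}}_{ij}(r)
            + s_2\, u^{\mathrm{elec}}_{ij}(r)$$

* **Steric**: infinite for $r < (\sigma_{ii}+\sigma_{jj})/2$, where
  $\sigma_{ii}/2$ is the hard-core radius of atom $i$; zero otherwise.
* **Nonpolar** (van der Waals plus hydrophobic): a 12-6 Lennard-Jones
  form, $4\epsilon_{ij}[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6]$,
  scaled by $s_1 = 0.16$.
* **Electrostatic**: a Debye-Hueckel form,
  $332\, q_i q_j e^{-\kappa r}/(\varepsilon r)$ kcal/mol with $r$ in
  Angstrom and charges in $e$, scaled by $s_2 = 1.6$, which absorbs
  effects such as dielectric reduction in crowded solutions.

All pair terms are truncated sharply at 12 Angstrom, with no shift: the
same truncation is used in the direct (oracle) evaluation and in the FFT
kernels, so the two routes agree exactly rather than approximately.

### Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `s1` | 0.16 | -- | nonpolar scaling |
| `s2` | 1.6 | -- | electrostatic scaling |
| `dielectric` | 78.5 | -- | solvent dielectric (not printed by most force-field sources; exposed because `s2` partially compensates it) |
| `ionic_strength` | 0.24 | mol/l | physiological-phosphate-like screening |
| `cutoff` | 12 | Angstrom | sharp pair truncation |
| `spacing` | 0.6 | Angstrom | translational grid resolution |
| `bin_width` | 0.016 | kcal/mol | insertion-energy histogram bin |

The Debye parameter $\kappa$ is derived from the ionic strength with the
standard aqueous closed form ($1/\kappa = 3.047/\sqrt{I}$ Angstrom at
298 K and $\varepsilon = 78.5$) and is **frozen at the 298 K reference**:
the whole energy function is evaluated once at the reference temperature
and only $\beta$ changes when chemical potentials are requested at other
temperatures. This "change beta only" shortcut assumes a
temperature-independent energy function and lets one histogram serve an
entire temperature sweep.

Combining rules are geometric for both $\epsilon$ and $\sigma$
($\epsilon_{ij} = \sqrt{\epsilon_i\epsilon_j}$,
$\sigma_{ij} = \sqrt{\sigma_i\sigma_j}$). Geometric $\sigma$ is what makes
the $r^{-12}$ and $r^{-6}$ lattice sums factorize into two
cross-correlations (weights $\sqrt{\epsilon_i}\sigma_i^6$ and
$\sqrt{\epsilon_i}\sigma_i^3$); the $s_1$ calibration absorbs the modest
difference from Lorentz-Berthelot mixing.

LJ parameters for PQR input come from a bundled element-keyed table of
AMBER-generic van der Waals values (H, C, N, O, S, P), with an override
mechanism for specific (residue, atom-name) rows and a loud failure for
unknown elements. Whether the tabulated $R_\mathrm{min}/2$ is itself the
hard-core radius (`sigma_convention = "rmin"`, the default) or should be
converted to the LJ zero crossing by $2^{1/6}$ (`"sigma"`) is exposed as a
flag, since force-field tables are printed in the $R_\mathrm{min}$
convention but hard-core radii are a modelling choice.

## The FFT engine

For one solution configuration and one test orientation, the insertion
energy at all $n^3$ grid positions is a set of cross-correlations, each
evaluated with FFTs:

* **Energetics.** Solution atoms are spread onto the grid with trilinear
  weights; each weight grid is convolved with a truncated kernel
  ($r^{-12}$, $r^{-6}$, or the Debye-Hueckel kernel) sampled at
  minimum-image voxel offsets. The test molecule's own weight grids are
  then cross-correlated with these potential fields. When atoms sit
  exactly on lattice points the trilinear stamp is a delta and the scan
  equals the direct atom-pair sum to machine precision; this is the
  oracle-equivalence contract the tests enforce on lattice-aligned toys.
* **Clash detection.** One steric indicator field is built per distinct
  test-atom core radius $b$: a voxel is occupied when some solution atom
  $j$ (at its exact, off-lattice position) lies within
  $\sigma_{jj}/2 + b$. Correlating with the test atoms' nearest-voxel
  point stamps makes the clash criterion *exactly* the hard-core
  inequality for lattice-snapped test positions -- no ball-vs-ball
  rasterization artifacts. We chose this construction over stamping both
  partners as balls because voxelized ball-ball overlap does not reduce
  exactly to "centre distance below the radius sum" on a lattice.
* **Kernel capping.** Power-law kernels diverge at the origin. They are
  capped at the smallest distance any clash-free atom pair can attain
  (the minimum solution core radius plus the minimum test core radius,
  never below one voxel). Any value inside that radius is masked by the
  clash test, so the cap cannot bias clash-free energies; keeping the
  capped values small also keeps FFT round-off far below the 1e-6
  oracle-equivalence tolerance, which a one-voxel cap would not.
* **Convention.** Energies are indexed by the test molecule's centre of
  geometry on the lattice, which is also how pose records are stored.

Off-lattice solution atoms (the generic case for sampled configurations)
make the trilinear energetics an interpolation; the clash test remains
exact. The 0.6 Angstrom production resolution keeps that interpolation
error well below the energy-bin width; tests run coarser grids with the
oracle defined on the same lattice.

## Configuration sampling

Equilibrium configurations of N rigid copies in a periodic cubic box are
generated by Metropolis Monte Carlo using exactly the pair energy above:
single-molecule Gaussian translations plus small axis-angle rotations,
auto-tuned toward 30-50% acceptance during equilibration only (tuning
during production would violate detailed balance). Initial placements are
random sequential clash-free insertions with a bounded retry budget.
Because the excess chemical potential depends only on the equilibrium
ensemble and not on dynamics, a Markov-chain sampler is a valid
replacement for a Brownian-dynamics engine; the distributional contract
is tested directly -- an isolated pair's centre-distance histogram must
match $e^{-\beta u(r)}$, near-ideal particles must give uniform pair
statistics, and the energy series must be trend-free after equilibration.
Note the sampler uses the same insertion energy function, whereas a
solvation-aware dynamics engine would sample a slightly different
ensemble; at high density this can shift mu_ex, which is why the
pair-distribution check is part of the contract rather than assumed.

## Insertion histograms and chemical potentials

Clash-free insertion energies are pooled over configurations and
orientations into a fine histogram (bin width 0.016 kcal/mol), together
with the pooled clash-free fraction $f_\mathrm{CF}$, treated as a
constant across configurations and orientations:

$$e^{-\beta\mu_\mathrm{ex}} = \frac{f_\mathrm{CF}}{M_\mathrm{CF}}
  \sum_U H(U)\, e^{-\beta U}$$

evaluated by log-sum-exp ($\beta|U_\mathrm{min}|$ can exceed 700). In the
$\beta \to 0$ limit this reduces to $-\ln f_\mathrm{CF}$, the steric
(infinite-temperature) excess chemical potential. Alongside the total
histogram, a coarser two-dimensional histogram of the *raw* nonpolar and
electrostatic components is kept so that $s_1$/$s_2$ can be rescanned
without re-running any FFT. Per-orientation Boltzmann sums feed the
Flyvbjerg-Petersen blocking estimator (plateau-detected, propagated
through $-\ln$ with asymmetric bounds), and per-orientation lowest
energies feed the bound estimation below. Poses below -8 kcal/mol are
archived during insertion scans (-6 kcal/mol in pair-virial scans).

One caveat worth knowing: binning to 0.016 kcal/mol zeroes the huge
far-field shell where $|U|$ is below one bin. For strongly interacting
proteins this is negligible, but for weakly attracting toys it can shift
Mayer integrals by a few cubic Angstrom; the virial tests therefore use a
finer bin. The bin width is exposed everywhere.

## Stabilising the low-temperature tail

At low temperatures the Boltzmann sum is dominated by the lowest-energy
bins, where counts are noisy or outliers lurk. The cumulative
distribution $C(U)$ of insertion energies is empirically exponential,
$C(U) = A e^{\alpha U}$, over many orders of magnitude. We:

1. fit $\ln C(U)$ with loess (degree 1, span 0.75) over the window
   bounded below by $C = 10^4$ and above by $U = -4$ kcal/mol;
2. extrapolate below the window linearly with the local slope at the
   window's lower edge (continuity of value and derivative);
3. truncate the extrapolation at a bound $U_\mathrm{min}$, by default
   solving $C(U_\mathrm{min}) = B f_\mathrm{CF}^{\gamma}$ with $B = 1$,
   $\gamma = 0.25$ (the `fcf_rule`); the alternative `block_fit` route
   fits the mean lowest energy per block of $M$ orientations to
   $\hat U_\mathrm{min} = U_\mathrm{min} + E/(1 + (M/D)^\delta)$ with
   $\delta \in [0.6, 1]$ and $D$ shared across concentrations
   (bounded Levenberg-Marquardt; initial values $\delta = 0.8$,
   $D = \mathrm{median}(M)$, $E$ from the data range);
4. replace $H(U)$ below the window edge by the derivative of the
   extrapolated CDF and redo the Boltzmann sum.

A lowest observed energy more than 1.0 kcal/mol below the energy at which
the extrapolated CDF reaches 1 is flagged as an outlier; the corrected
chemical potential is insensitive to such single counts by construction,
because everything below the fit window is replaced by the model.

The exactness statement "corrected equals raw for exactly exponential
data" holds when the truncation endpoint coincides with the histogram's
actual bound; an endpoint below the data bound (as the `fcf_rule` gives
for an arbitrary amplitude $A$) legitimately extends the tail and shifts
the sum. Parameter-recovery tests simulate block minima directly from the
analytic minimum distribution of the bounded power law, which exercises
the fit without generating billions of samples.

## Binodal, spinodal, critical temperature

$\beta\mu_\mathrm{ex}(\rho)$ at one temperature is fitted to a fifth-order
polynomial through the origin (no intercept: the excess part vanishes at
zero concentration); its first-order coefficient is twice the second
virial coefficient, which provides an internal consistency check against
the Mayer-integration route. Adding $\ln(\rho/\rho_0)$ gives the full
chemical potential; $\rho_0$ cancels in the construction. Below the
critical temperature the curve has a van der Waals loop: the horizontal
line bisecting it with equal areas (found by bisection on the signed
area, with adaptive quadrature on the analytic polynomial-plus-log form
and a tolerance scaled to the loop size) yields the coexisting
concentrations at its outer intersections and the spinodal at the loop
extrema. The search range must bracket both binodal branches -- the
dilute branch sits near $\rho_0 e^{\mu^*}$, which can be orders of
magnitude below the sampled concentrations for deep quenches.

The critical temperature is reported as a bracket (warmest loop-bearing
temperature, coolest loop-free temperature) plus its midpoint, rather
than a fitted scaling-law extrapolation, because the loop-vanishing
temperature is the only information the construction itself provides.

## Second virial coefficients

FMAP-style Mayer integration: a single central copy in a periodic box
(at least twice the molecular diameter plus the cutoff, so periodic
images cannot interact), the test molecule scanned over the grid for
every orientation of a deterministic SO(3) covering. Clashed points
contribute $-1$ and clash-free points $e^{-\beta U} - 1$ to the Mayer
average; $B_2 = -(V/2)\langle f\rangle$, with one histogram serving the
whole temperature grid. The steric-only value defines the steric volume
$V_\mathrm{st} \equiv B_2^{\mathrm{st}}/4$, and the empirical
Vliegenthart-Lekkerkerker rule $B_2(T_c)/V_\mathrm{st} \approx -6$ gives
a quick critical-temperature indicator by bisection on the reduced
curve.

The orientation covering is a Hopf-style grid: rotated-axis directions on
a spherical Fibonacci lattice (pole included, so the identity rotation is
in the set) crossed with uniformly spaced twist angles; counts scale as
(resolution)$^{-3}$ and the 6-degree set has 68,760 members. The
contract is a covering-radius bound (every rotation within 1.5x the
nominal resolution of some member) and robustness of $B_2$ to the count,
not any particular member list. Per-mass units use
$B_2[\mathrm{mol\,ml/g^2}] = B_2[\mathrm{\AA^3}] \times 10^{-24}
N_A / M^2$.

On a lattice, the steric part of $B_2$ inherits a few-cubic-Angstrom
oscillation from counting lattice points inside a sphere (worst when the
contact distance is commensurate with the spacing); the attraction part
converges much faster. Tests therefore compare the two parts against
their analytic values separately.

## Pose and sequence analyses

Low-energy pair poses are ranked (ties broken lexicographically for
determinism), clustered greedily from the lowest-energy seed with a
10 Angstrom ligand-RMSD cutoff (each cluster's members lie within the
cutoff of its seed; no stealing by later clusters), and decomposed
per-residue both ways (test split against whole central, central split
against whole test), averaging over poses first and then over the two
directions. Differences between two proteins' profiles are flagged
beyond mean +/- 3 SD; positions aligned to gaps contribute zero.
Site-site distance histograms between the partners' sidechain centroids
support optional Mayer-factor weighting.

Grantham distances are regenerated from the 1974 composition/polarity/
volume properties ($d = 50.723\sqrt{1.833\,\Delta c^2 + 0.1018\,\Delta
p^2 + 0.000399\,\Delta v^2}$, rounded to integers); a few entries of the
historical published matrix differ by one unit from the exact
recomputation because of rounding in the original table, so tests pin
well-known spot values (S-W = 177, L-I = 5, R-L = 102) rather than all
400 entries. The residual inter-group distance at an alignment column is
the inter-group mean minus the larger intra-group mean, with pairs
touching a gap dropped; columns where more than half the inter-group
pairs are undefined are zeroed and flagged gap-dominated (the stated gap
policy generalised from its single published example). Flags use
mean + 3 SD over columns, which requires an alignment long enough for
the column distribution to be meaningful.

## What the toy generator does and does not emulate

The built-in fixtures (single sphere, charged two-residue dumbbell,
four-atom two-residue tetramer) have exact analytic references for
excluded volume, dipole moments, residue decomposition and Boltzmann
statistics, and they make every stage testable without external
structures. They do **not** emulate: thousands of atoms per molecule,
the heterogeneous charge/LJ texture of a protein surface, anisotropic
binding patches of realistic strength, or histograms spanning ten
decades. Passing tests therefore demonstrate correctness of the
machinery (energetics, FFT equivalence, ensemble sampling, tail
inference, phase construction) at small scale, not predictive accuracy
for any particular protein. Production-scale inputs are prepared
structures in PQR form; protonation, mutation modelling and
minimization are upstream concerns.

## Problem sizes and numerics

The test and acceptance runs use boxes of 8-42 Angstrom at 0.3-1.25
Angstrom resolution, 1-14 copies, tens of Monte Carlo sweeps per
concentration, and 1-2 test orientations for isotropic toys -- sizes
chosen so the whole suite completes in minutes while still exercising
every code path end to end; production-scale runs (hundreds of copies,
540^3 grids, 500 orientations, 2000 snapshots) use identical code with
different arguments. Degenerate inputs are contracts, not accidents:
empty boxes give $f_\mathrm{CF} = 1$ and zero excess chemical potential,
monotone chemical-potential curves return a no-loop verdict rather than
an error, constant blocking input returns zero error, and identical
groups give $t = 0$, $p = 1$.

## Known limitations

* Rigid molecules only; no sidechain repacking or conformational
  libraries beyond the multi-structure $B_2$ averaging hook.
* The energy function is frozen at the reference temperature; genuinely
  temperature-dependent dielectrics or hydration effects are outside the
  model.
* Mean-field-like finite-size effects of the equal-area construction on
  small boxes are not corrected.
* The R implementation favours clarity over throughput; production-scale
  grids (540^3) are feasible in principle but are the domain of compiled
  pipelines, and the package's value at that scale is the reference
  semantics and the analysis layers.
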