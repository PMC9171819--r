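---
title: "Deriving 12-6-4 C4 coefficients from chelator binding energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving 12-6-4 C4 coefficients from chelator binding energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chbe)
```

## The model

Nonbonded interactions between a metal ion and a ligating atom are
described by the 12-6-4 Lennard-Jones plus Coulomb potential

$$U(r) = \frac{A_{ij}}{r^{12}} - \frac{B_{ij}}{r^{6}} - \frac{C_{ij}}{r^{4}}
        + \frac{k\,q_i q_j}{r},$$

where the $r^{-4}$ term models the dipole the ion's charge induces on its
neighbour. $A_{ij}$ and $B_{ij}$ come from Lorentz–Berthelot combination of
per-atom-type parameters; $C_{ij}$ is pairwise and is *never* combined —
the whole point of the method is that each ion/atom-type pair carries its
own value. Internally all energies are kcal/mol (the unit of $C_{ij}$
tables), with `kcal_to_kj()`/`kj_to_kcal()` for the kJ/mol used by binding
energies. The Coulomb prefactor is fixed at the AMBER-family convention
`amber_coulomb_constant()` = 332.0522 kcal mol⁻¹ Å e⁻², for consistency
with the force fields this parameterization extends. The module is an
analytic evaluator: no cutoffs or switching functions are applied; the
Monte Carlo sampler applies minimum-image truncation itself.

## The parameterization

Simulated metal–chelator binding free energies respond linearly to the
ligating-atom $C_{ij}$ values over the relevant range, so a chelator–metal
pair is summarized by a linear model
$$\Delta G_b(C_O, C_N) = \Delta G'(0,0) + m_O C_O + m_N C_N .$$

*Gradients.* `fit_gradient()` fits ordinary least squares to a scan in
which exactly one coordinate varies (the other held at its default);
mixed or degenerate designs are errors. The intercept is free by default —
the scans are fitted as straight lines through the simulated points — and
an anchored variant (line forced through the default-parameter point) is
available for sensitivity checks.

*Zero-C4 reference.* Directly simulating with both $C_{ij}$ set to 0 is
unreliable: without the attractive $r^{-4}$ terms the ion can leave the
chelation pocket, and the resulting energies can even invert the
experimental EDTA/NTA ordering. The reference is therefore
back-extrapolated from the default-parameter simulation,
$\Delta G'(0,0) = \Delta G(\text{default}) - m_O C_{O,\text{def}} -
m_N C_{N,\text{def}}$. This intermediate is carried at full precision into
the solve: rounding it to one decimal shifts the solved Y³⁺ nitrogen
coefficient by about 1.5%.

*Two-chelator system.* One experimental binding energy constrains
$(C_O, C_N)$ only to a line (the contour `contour_line()` draws). A second
chelator breaks the degeneracy. Because its own gradients and zero-C4
reference inherit the same reliability problems, both are replaced by
reference-chelator quantities: the zero-C4 energy is scaled by the ratio
of experimental binding energies (`scale_reference_zero()`), and the
gradients are scaled by denticity ratios $\rho_O$, $\rho_N$ — the ratios
of the numbers of ligating atoms the two chelators offer. For the EDTA/NTA
pair the defaults are $\rho_O = 3/4$ (3 vs 4 carboxylate oxygens within
reach) and $\rho_N = 1/2$ (1 vs 2 tertiary nitrogens); `denticity_ratios()`
accepts other values for other chelator pairs, and `solve_cij_lsq()`
extends the exactly determined 2×2 solve to an over-determined
least-squares solve for three or more chelators (an extrapolation beyond
the validated method, provided for sensitivity analysis).

`solve_cij()` solves

$$\begin{aligned}
\Delta G^{exp}_{ref} &= \Delta G'(0,0) + m_O C_O + m_N C_N\\
\Delta G^{exp}_{2} &= \Delta G'(0,0)\,\frac{\Delta G^{exp}_{2}}{\Delta G^{exp}_{ref}}
  + \rho_O m_O C_O + \rho_N m_N C_N
\end{aligned}$$

and flags solutions with a negative coefficient as non-physical (an
attractive induced-dipole term cannot have negative weight — exactly the
failure mode the substitutions above avoid; `solve_cij_direct()` exposes
the naive route so the failure is reproducible). Systems with determinant
magnitude below $10^{-10}$ (e.g. equal denticity ratios, which make the
rows proportional) raise an error rather than silently pseudo-inverting.

Conditioning matters here: the nitrogen gradients are 3–10× smaller than
the oxygen ones, so the residual surface is a long shallow valley
(condition numbers ~30–70 for the packaged metals). The solved oxygen
coefficient is sharply determined; the nitrogen coefficient inherits most
of the input-rounding uncertainty. This is why the test suite compares a
brute-force grid scan to the analytic solution by non-inferiority plus a
conditioning-aware localization bound rather than naive cell adjacency.

```{r}
solve_chbe()
```

## Experimental binding energies

Stability constants ($K_1$) convert as
$\Delta G = -RT\ln 10 \cdot \log_{10} K_1$ with
$R = 8.31446\times10^{-3}$ kJ mol⁻¹ K⁻¹ at 298 K by default; dissociation
constants use the opposite sign so that more negative always means tighter.
Which sign convention a given $K_d$ table uses should be checked against
its source; both are expressible. `combine_cycle()` assembles simulated
binding energies from replicate electrostatic+polarization decoupling legs
and a van der Waals leg, whose near-constancy across chelators motivates
the fixed 9 kJ/mol preset; the cycle orientation is a named convention
(`"subtract-vdw"` default) so both directions are expressible.

## RDF analysis

`compute_rdf()` histograms ion–site distances into half-open bins
$[r, r+dr)$ of width 0.01 Å by default, reported at bin centers, and
normalizes by shell volume $4\pi r_c^2\,dr$, bulk density and frame count,
with the minimum-image convention in periodic boxes ($r_{max}$ capped at
half the box). For open-boundary frame sets the bulk density is estimated
from the outer 10% of the $r_{max}$ sphere, falling back to the mean
density of the whole sphere when that shell is empty (an isolated
solvation shell); the fallback scales $g$ by a constant and therefore
cannot move peak or minimum positions.

Operational definitions, since "first peak" and "first minimum" need them:

* Detection runs on a count-weighted 5-bin running mean (summed counts
  over summed expected counts), which keeps single counts in tiny small-$r$
  shells from dominating a plain average of $g$ values.
* The **first peak** is the first smoothed bin that is its 5-bin
  neighbourhood's maximum, exceeds the threshold $g = 1$, exceeds the bulk
  level by at least 3 Poisson standard errors of its smoothing window, and
  is eventually followed by a drop below half its height. The two last
  gates jointly reject statistical ripples in structureless (ideal-gas)
  data, which cannot produce both a significant peak and a deep valley.
* The **ion–oxygen distance** is the vertex of a least-squares parabola
  through the raw bins within ±0.1 Å of the raw first-peak bin (falling
  back to the bin center if the parabola opens upward). The fit
  interpolates below the bin width: shell fixtures of known radius are
  recovered to better than 0.01 Å at 0.01 Å resolution.
* The **first minimum** is the first smoothed local minimum after the peak
  (a genuine dip — a flat plateau does not count; ties break toward
  smaller $r$) whose depth falls below half the peak height. If no
  candidate qualifies the result is flagged `minimum_clear = FALSE` with a
  CN range over the candidate minima — mirroring how fluctuating binding
  modes are reported as CN ranges rather than forced to a single number.
* The **coordination number** integrates the *raw* curve,
  $n(r) = 4\pi\rho\sum r_c^2 g\,dr$, to the first minimum; smoothing is
  used for detection only. `cn_to()` integrates to an explicit cutoff,
  which is also how occupancies should be compared across simulations
  whose detected shell boundaries differ (the boundary itself contracts
  as the ion–site attraction grows).

## The Monte Carlo sampler

`run_mc()` is a single-ion Metropolis sampler: one ion fixed at the origin
of a cubic periodic box of solvent-like sites, single-site displacement
moves with uniform proposals, acceptance on the total pairwise energy
(12-6-4 ion–site, 12-6 site–site) under minimum image. It emulates the
*equilibrium* structure of a solvation shell — enough to give the RDF
module trajectories with known ground truth — and deliberately nothing
else: no dynamics, no barostat, no Ewald electrostatics, no water–water
hydrogen-bond network, no alchemical free energies. Passing its tests
therefore shows the analysis chain is correct on equilibrium ensembles,
not that real solvent structure is reproduced. The default site is a
water-oxygen-like Lennard-Jones sphere (r_min/2 = 1.768 Å,
ε = 0.152 kcal/mol, charge −0.834 e with an implicit neutralizing
background) — a fixture convention, not a physics claim. Every public call
takes an explicit seed (R's Mersenne-Twister, applied locally and
restored, so no hidden global state) and reproduces its trace bitwise.
The box must exceed four times the combined ion+site minimum-distance
radius so a first shell fits without self-interaction artifacts.

The sampler's anchor property is the two-body system: the sampled radial
distance distribution, conditioned on $r \le L/2$ (where the minimum-image
shell is a complete sphere), must match numerical quadrature of
$r^2 e^{-U(r)/k_BT}$ bin by bin. The anchor system uses a neutral pair
with a C4 well of a few $k_BT$ so the distribution has visible spread, 400k
moves thinned to every 50th to decorrelate samples, and 0.25 Å histogram
bins compared at 3 counting standard errors where the expected count is at
least 5 (below that the Gaussian error model itself is invalid).

## Problem sizes and statistical choices in the tests

The suite runs on one CPU in a few minutes: shell fixtures use 500 frames
(IOD recovered to ±0.01 Å, CN to ±0.02), the ideal-gas null uses 200
frames × 100 sites at 0.25 Å bins (expected counts ≥ 20 in every compared
bin, so the 3-standard-error band is meaningful and the familywise false
alarm rate across its 18 bins stays low), the two-body anchor uses 8000
thinned samples, and the C4 response ladder spans 0, 100, 200
kcal mol⁻¹ Å⁴ at 40k moves per rung. Brute-force solver comparisons scan
$C_O, C_N \in [0, 300]$ at 0.05 resolution. Parameter recovery plants
known coefficients through the forward model and requires recovery to
$10^{-6}$.

## Configuration and outputs

The command-line drivers (`cmd_fit()`, `cmd_solve()`, `cmd_rdf()`,
`cmd_simulate()`, `cmd_affinity()`, dispatched by `chbe_cli()`) read a
flat YAML config mirrored by `--key value` flags, flags winning on
conflict; YAML was chosen because it is the config format R tooling reads
natively. Unknown keys are errors, referenced inputs must exist at
validation time, and ratio keys are validated to (0, 1]. Every emitted
table carries unit-suffixed column headers, values are written with full
precision (so downstream comparisons are never masked by output rounding),
and identical config plus seed reproduce outputs byte for byte. A solve
that fails for one metal writes an error row and continues; the run fails
only if every metal fails.

## Known limitations

* The linear-response assumption is inherited, not tested here: gradients
  fitted far from the default point, or chelators whose binding mode
  changes with $C_{ij}$, can break it.
* The denticity-ratio substitution assumes the second chelator's ligating
  groups sit in chemical environments similar to the reference's; ether
  oxygens and amide/backbone oxygens are outside its scope and retain
  default coefficients.
* The nitrogen coefficient is intrinsically soft (see conditioning above);
  reporting it without the oxygen value it was solved with is not
  meaningful.
* The sampler's open-boundary density fallback makes $g(r)$'s absolute
  scale approximate for isolated shells; positions and integrals to a
  cutoff are unaffected.
* Binding free energies themselves (TI or otherwise) are inputs, not
  something this package computes.
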