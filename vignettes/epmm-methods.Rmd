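---
title: "Pseudoatom databank electrostatics: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudoatom databank electrostatics: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epmm)
```

## The model

`epmm` reconstructs a continuous molecular electron density from
transferable pseudoatom parameters and computes intermolecular
electrostatic interaction energies from it. Each atom is a Hansen–Coppens
pseudoatom,

$$\rho(\mathbf r) \;=\; P_{core}\,\rho_{core}(r)
 \;+\; P_{val}\,\kappa^3 \rho_{val}(\kappa r)
 \;+\; \sum_{l=0}^{4} \kappa'^3 R_l(\kappa' r)
        \sum_{m=-l}^{l} P_{lm}\, d_{lm}(\theta,\varphi),$$

where $\rho_{core}$ and $\rho_{val}$ are spherically averaged free-atom
core and valence densities normalized to one electron, $R_l$ is a
density-normalized single-zeta Slater radial function
$R_l(r) \propto r^{n(l)} e^{-\zeta r}$, and $d_{lm}$ are
density-normalized real spherical harmonics evaluated in an atom-local
frame built from bonded neighbors. $P_{core}$, $P_{val}$ and $P_{lm}$ are
populations (electrons); $\kappa$ and $\kappa'$ are expansion–contraction
parameters. The net atomic charge is $Z - P_{core} - P_{val}$ (minus
$P_{00}$ when a monopole deformation is present). Parameters are
*transferred*: atoms of a target structure are typed by their chemical
environment and matched against a databank of pseudoatom parameters.

Interaction energies between two such charge distributions (electrons plus
nuclear point charges) are computed with the hybrid
exact-potential/multipole-moment (EPMM) scheme:

* **EP** — for atom pairs closer than the critical radius
  $r_{crit}$ the full Coulomb integral of the two continuous densities is
  evaluated numerically;
* **MM** — beyond $r_{crit}$ the Buckingham-type spherical-tensor
  interaction of the atomic multipole moments (orders $l \le 4$ on each
  center) is used, which is exact for non-overlapping densities.

The pure multipole energy over *all* pairs (often written aMM) is always
computed alongside; the **charge penetration energy** is defined as their
difference, $E_{pen} = E_{EPMM} - E_{MM}$. It is the short-range correction
that arises when electron clouds overlap and a point-multipole picture
breaks down; it vanishes at large separation.

## Units and constants

All internal mathematics runs in Hartree atomic units. The user-facing API
takes angstrom and returns kcal/mol, using CODATA values
1 Bohr = 0.529177210903 Å and 1 Hartree = 627.509474 kcal/mol. The
point-charge Coulomb mode (`point_charge_energy()`) uses the conventional
force-field constant 332.0637 kcal Å mol$^{-1}$ e$^{-2}$. These constants
are exported as `epmm_constants`.

The density-normalization convention for the deformation functions is
$\int |d_{lm}|\,d\Omega = 2$ for $l \ge 1$ and
$\int d_{00}\,d\Omega = 1$: a population $P_{lm} = 1$ transfers one
electron from the negative to the positive lobe. The normalization
constants are computed once by adaptive one-dimensional quadrature and
cached; low-order values are verified against hand-derived closed forms in
the test suite.

## Numerical scheme

**Analytic potentials.** All spherical density components are sums of
Slater-type primitives $c\,r^m e^{-\alpha r}$, whose electrostatic
potentials have closed forms in incomplete gamma functions; the
deformation terms have the analogous $l$-resolved closed forms. The exact
potential of a pseudoatom is therefore analytic everywhere, and the
nucleus–nucleus and nucleus–electron terms of an EP pair energy are
evaluated in closed form. Only the smooth electron–electron integral
requires quadrature.

**EP quadrature.** The electron–electron term is integrated on
atom-centered grids: Gauss–Chebyshev (second kind) radial points mapped to
$[0,\infty)$ with the rational map $r = r_m(1+x)/(1-x)$ (the map midpoint
$r_m$ is element-dependent), and a product Gauss–Legendre × uniform
azimuthal angular grid. The integral is symmetrized over both centers,
which makes $E(a,b) = E(b,a)$ exact by construction and cancels the
leading one-center quadrature error. The angular grid is anchored to the
pair geometry (polar axis along the interatomic vector, azimuth from the
atom-local frame), so energies are invariant under rigid motion of the
whole complex to machine precision.

Defaults follow common practice for databank electrostatics: 99 radial
points, the 590-point angular level and $r_{crit} = 5$ Å. The angular
"ladder" (26, 50, 110, 194, 302, 434, 590, 974 nominal points) is realized
as product rules whose exactness grows with the nominal size. A
method-definition value of 4.5 Å for the exact zone circulates alongside
the 5 Å run setting; both are accepted through `quadrature_spec()` and the
package defaults to 5 Å. At these settings the EP energies of fixture
pairs change by less than 0.01 kcal/mol when the grids are refined to
199/974, and agree with closed-form two-exponential Coulomb integrals to
better than $10^{-3}$ kcal/mol.

**MM energies without interaction tensors.** The truncated multipole
interaction is evaluated by contracting the analytic point-multipole
potential of one atom against an "equivalent shell": a sphere of small
radius $s = \min(0.4\,\mathrm{Bohr}, R/4)$ around the partner carrying a
surface density with exactly the partner's multipole moments and no
others. Because every term of the multipolar potential is harmonic away
from its center, the angular quadrature of this contraction is exact up to
a re-expansion error that decays like $(s/R)^{\text{grid order}}$ —
negligible at all relevant separations. This reproduces Coulomb's law for
a monopole pair to better than $10^{-6}$ relative and the closed-form
dipole–dipole energy to the same level, without implementing explicit
spherical interaction tensors.

**Local frames.** Frames are built from bonded neighbors ranked by
(nuclear charge, distance, coordinates): rule `ZX` points local $z$ at the
first neighbor and orthogonalizes $x$ toward the second; `BISECT_Z` points
$z$ along the bisector of the first two neighbors (used for water oxygen,
so the dipole lies on the C$_2$ axis and the frame is rotation
equivariant). Terminal atoms fall back to a deterministic perpendicular.
An atom with aspherical populations and no resolvable frame is an error,
never a silent default. Global multipole moments are obtained from
local-frame moments with real-harmonic rotation matrices computed exactly
by angular quadrature (the integrands are polynomials well inside the grid
order).

## Databank transfer

Atom typing uses a simplified topological key: element plus the sorted
multiset of bonded-neighbor elements, with specificity-ordered fallback
(full key, then element + coordination number, then element alone) and an
error on ambiguous equal-specificity matches. Published pseudoatom
databanks use richer connectivity descriptors (ring membership,
hybridization trees); this key is a documented fidelity limitation, and no
numerical agreement with energies published from such databanks is
claimed.

The transfer runs in two passes, following standard practice for
metal-containing structures: first bonds are detected with the Mg covalent
radius overridden to 0.01 Å — suppressing all Mg bonds so every hydrogen
has a single heavy neighbor — and X–H bonds are extended to standard
neutron distances (C–H 1.083, N–H 1.009, O–H 0.983, S–H 1.338 Å;
user-editable); second, bonds are re-detected with the default Mg radius
(1.36 Å), so metal-coordinating atom types (e.g. water oxygen bound to
Mg) are assigned, and the model is built. The bond criterion is
$d \le r_i + r_j + 0.4$ Å.

After transfer, each residue (or user-defined grouped fragment) is scaled
to its formal charge by adjusting valence populations. The shift is
distributed proportionally to each atom's current $P_{val}$
(multiplicative scaling); an additive-uniform mode is available via
`mode = "uniform"`. Proportional scaling was chosen because it preserves
the relative valence populations of the transferred parameters; the
reference transfer software does not document its choice, so the mode is
switchable. Alternate-location atoms keep the highest-occupancy conformer
by default, with an explicit `altloc` argument for conformer selection.

## The analysis pipeline

`partition_fragments()` splits a protein–RNA complex into the interaction
units used throughout: the first RNA residue together with the metal
cation and the waters of its first coordination shell (O–Mg ≤ 2.6 Å;
more than three coordinating waters is an error), the further RNA
residues, and one fragment per protein residue.
`residue_energy_table()` computes $E_{MM}$, $E_{EPMM}$ and $E_{pen}$ for
every residue × fragment pair and applies three binding-site filters:

1. geometric — any atom (hydrogens included) within 5 Å of any RNA
   fragment atom, closed interval;
2. energetic — $|E_{EPMM}|$ strictly greater than 5 kcal/mol against any
   fragment;
3. penetration — $|E_{pen}| \ge 2$ kcal/mol within the geometric site.

The energy filter boundary is strict ("over ±5 kcal/mol"); the
penetration threshold is not pinned by published usage, so it defaults to
2 kcal/mol, is configurable, and raw $E_{pen}$ values are always included
in the report so thresholds can be revisited post hoc.
`compare_sequences()` compares per-fragment and grand totals across
complexes and reports the maximum pairwise discrepancy relative to the
mean magnitude, in percent.

## Electrostatic potential maps

`esp_on_grid()` evaluates the total potential (nuclei plus continuous
electron density) on a cubic grid: the analytic exact potential within
$r_{crit}$ of each atom and that atom's point-multipole far field beyond.
Voxels inside a 0.1 Å nuclear cap are evaluated on the cap sphere and
flagged. `isodensity_mask()` thresholds the electron density
(conventionally 0.002 e Bohr$^{-3}$ for a molecular envelope) and marks
surface voxels by their 6-neighborhood. Output is the Gaussian cube
format. The default desk-scale setting is a 250 Å box with 0.5 Å voxels;
finer combinations are accepted but a very large voxel count triggers a
warning — a published grid description of "500 × 500 × 500 Å at 0.1 Å
voxels" would imply 5000³ voxels and is presumably a units slip, so it is
not a default.

## The synthetic study system

Because published pseudoatom parameter sets and deposited structures are
external inputs, the package carries its own fixtures so every stage runs
offline:

* a **fixture databank** for H, C, N, O, P, S and Mg with physically sane
  synthetic parameters, self-consistent with a packaged single-zeta
  wavefunction table in the Clementi–Raimondi style. Deformation radial
  powers follow the common conventions, including $n(l) = 2,4,6,8$ for P
  and $6,6,6,6$ for S. The Mg entry is a nearly spherical cation whose
  modeled charge drops well below +2 after fragment scaling — the
  qualitative charge-transfer behavior of metal coordination — with no
  claim of equality to unpublished metal atom types.
* **Slater dimers** — single-atom models with pure 1s-Slater clouds whose
  Coulomb interaction has a symbolic closed form; these anchor the
  exact-potential integrals to textbook values.
* **toy protein–RNA complexes** — a triphosphate-like first "nucleotide"
  (formal −4 e), further −1 e nucleotides, a +2 e metal with three
  coordinating waters at ~2.1 Å, and charged/neutral residue blobs placed
  on a 3–12 Å shell. Placement derives from integer grids through a small
  deterministic generator, so a seed reproduces coordinates bit-identically
  on any platform, and PDB round trips are exact. The first nucleotide,
  metal, waters and one carboxylate-like residue form a grouped charge
  fragment of −3 e, mirroring the grouped treatment of a metal-bridged
  binding site.

The toy residues are coarse chemical mimics: correct formal charges,
coordination geometry and H-bond-capable contacts, not full amino-acid or
nucleotide atom graphs. Consequently the pipeline's numbers on toys test
the *mechanics* (typing, scaling, energy decomposition, filters,
determinism), not biochemical realism: toy binding-site totals are an
order of magnitude smaller than in a real protein, and complexes generated
from different seeds differ far more than a nucleotide substitution in a
fixed crystal structure would, so cross-complex discrepancies on toys are
large by construction.

One fixture choice deserves a note: with single-zeta densities, the sign
of the H-bond penetration energy is a balance between genuine cloud
overlap (negative) and the truncation residual of the multipole series
(either sign), and it is sensitive to the hydrogen bond-directed dipole
population. The fixture uses moderate H dipoles ($P_{10} \approx 0.05$–
0.06) so that H-bonded contacts show the physically expected negative
penetration of a few kcal/mol; large H dipoles ($P_{10} \gtrsim 0.1$)
would flip the sign for some contacts, which real multi-zeta densities do
not do.

## The independent oracle

`brute_force_coulomb_oracle()` cross-checks the exact-potential energies
by an entirely different numerical route: electron potentials are built as
cumulative-trapezoid tables on dense uniform radial grids (no incomplete
gamma functions), and the electron–electron integral runs on uniform
spherical-coordinate grids (composite Simpson on the substitution
$r = t^2$, exact polar bin masses, trapezoid azimuthal). On Slater dimers
spanning 1.5–6 Å the oracle and the production EP path agree to better
than 0.01 kcal/mol, an order of magnitude inside the 0.1 kcal/mol
acceptance band; a resource guard caps the grid size.

## Problem sizes and defaults used in validation

The shipped validation runs use the default toy complex (8 protein
residues, 3 nucleotides, metal + 3 waters; ~95 atoms), the production
quadrature (99 radial / 590 angular / $r_{crit}$ 5 Å) for the acceptance
script, and a reduced 60/194 grid inside the fast unit tests (the
convergence tests demonstrate both are inside 0.01 kcal/mol of the refined
grids). ESP map tests use desk-scale grids of up to 36³ voxels.

## Known limitations

* The simplified atom-type key cannot reproduce a published databank's
  parameter assignment; agreement with published per-residue energies is
  therefore reported, never asserted.
* Only electrostatics: no polarization, exchange-repulsion, dispersion,
  solvation or periodic sums; no forces.
* Single-zeta fixture densities underestimate long-range density tails,
  which damps penetration magnitudes relative to multi-zeta reference
  densities.
* Protonation states, side-chain flips and metal identity validation are
  assumed to be handled upstream; input structures must already carry
  hydrogens.
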