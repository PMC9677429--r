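# epmm — pseudoatom databank electrostatics for macromolecular complexes

Electrostatics dominates how proteins recognize nucleic acids: a
triphosphate-bearing RNA 5′ end, a coordinated Mg²⁺, and a basic binding
pocket interact through forces that point-charge force fields only
approximate. `epmm` is an R package for computing those interactions from
*continuous* electron densities reconstructed with the Hansen–Coppens
multipole pseudoatom model, the approach used by transferable aspherical
atom databanks in quantum crystallography. It is aimed at structural
bioinformaticians and computational chemists who want per-residue
electrostatic energy decompositions — including the charge penetration
term that point charges miss — for protonated PDB structures.

## The model in brief

Each atom is a pseudoatom

ρ(**r**) = P_core ρ_core(r) + P_val κ³ ρ_val(κr) +
Σ_l κ′³ R_l(κ′r) Σ_m P_lm d_lm(θ, φ),

with per-electron core/valence densities from an atomic wavefunction
table, density-normalized Slater radial functions R_l and real spherical
harmonics d_lm in an atom-local frame. Parameters (P_val, P_lm, κ, κ′) are
*transferred* from a databank by chemical atom typing, hydrogens are
extended to neutron distances, and each residue (or grouped fragment) is
scaled to its formal charge.

Interaction energies between two molecules use the hybrid **EPMM** scheme:
the exact Coulomb integral of the two continuous densities (EP) for atom
pairs within r_crit = 5 Å, and the Buckingham multipole-moment expansion
(MM, orders l ≤ 4 per atom) beyond. The penetration energy is
E_pen = E_EPMM − E_MM: the short-range correction from overlapping
electron clouds, zero at large separation and typically a few negative
kcal/mol per hydrogen bond.

The package covers the full analysis pipeline: PDB input (bio3d), bond
detection with metal-radius overrides, two-pass databank transfer,
fragment partitioning (first nucleotide + metal + coordinating waters),
per-residue × per-fragment energy tables with the 5 Å / ±5 kcal/mol /
penetration binding-site filters, cross-complex comparisons, electrostatic
potential and density maps on cubic grids with 0.002 e Bohr⁻³ iso-density
masks (Gaussian cube output), and point-charge Coulomb energies for
force-field comparisons. Synthetic fixtures (a fixture databank, analytic
Slater dimers, toy protein–RNA complexes) make everything runnable and
testable offline.

## Worked example

Build a toy protein–RNA complex (triphosphate nucleotide, Mg²⁺ with three
waters, charged and neutral residues), transfer the fixture databank,
scale fragment charges, and run the binding-site analysis:

```r
library(epmm)

db    <- make_fixture_databank()
toy   <- make_toy_complex(toy_complex_spec(seed = 42))
model <- transfer_parameters(toy$structure, db)
model <- scale_fragment_charges(model, toy$charge_specs)
model
#> Molecular density model: 95 pseudoatoms, charge -3.0000 e

part <- partition_fragments(model$meta$structure)
part
#> Fragment partition: 3 RNA fragments ( 26/8/8 atoms ), 8 protein residues

report <- residue_energy_table(model, part, quad = quadrature_spec(99, 590, 5))
report
#> Binding-site report
#>   residues within 5 A: 4
#>   significant (|E| > 5 kcal/mol): 5
#>   strong penetration (|Epen| >= 2 kcal/mol): 0
#>   grand totals: whole -109.61 / site -25.52 kcal/mol (Epen -0.20 / -0.20)

head(report$per_residue, 4)
#>   residue  fragment      e_mm    e_epmm e_pen
#> 1      A1 fragment1 -60.98041 -60.98041     0
#> 2      A1 fragment2 -17.98706 -17.98706     0
#> 3      A1 fragment3 -13.04910 -13.04910     0
#> 4      A2 fragment1 -59.57648 -59.57648     0
```

The model charge is −3 e because the grouped fragment (triphosphate
nucleotide −4, metal +2, three waters 0, one carboxylate-like residue −1)
is scaled to its formal charge as a single unit, and every other residue
to its own. `report$per_residue` holds the multipole (e_mm), hybrid
(e_epmm) and penetration (e_pen) energies in kcal/mol for every residue ×
fragment pair: A1, a +1 ammonium-like residue near the triphosphate, is
the strongest attractor (−61 kcal/mol to fragment 1); zero e_pen marks
pairs with no density overlap.

Penetration on an overlapping neutral pair:

```r
dm <- make_slater_dimer(1.0, 1.4, 2.0)   # two neutral 1s clouds, 2 A apart
epmm_energy(dm$a, dm$b, breakdown = FALSE)
#> Electrostatic interaction energy (kcal/mol):
#>   E_MM   =     0.0000
#>   E_EPMM =    -0.5804
#>   E_pen  =    -0.5804
```

Two neutral spherical atoms have no multipole interaction at all; the
−0.58 kcal/mol is pure penetration — each nucleus attracted by the
partner's overlapping cloud.

A thin command-line interface wraps the same functions
(`exec/epmm transfer|energy|binding-site|compare|map|make-fixtures`);
`make-fixtures` writes a complete offline workspace (toy PDB, databank,
wavefunction table, YAML config).

## Databank and wavefunction file formats

`inst/extdata/fixture_databank.txt` is the plain-text databank: per entry
a `KEY` line (element + sorted bonded-neighbor elements, or `ANY` /
`COUNT n` fallbacks), a `PARAM` line (P_core, P_val, κ, κ′), optional
`PLM l m value` lines, a `RADIAL` line (ζ and n(l) for l = 0..4) and a
`FRAME` rule. `inst/extdata/wavefunctions.txt` lists per element the
Slater shells (label, n, ζ, occupancy, core/valence) from which the
spherical densities are built; swap in other wavefunctions by editing it.
The fixture parameters are synthetic: physically sane, self-consistent,
and not a published databank.

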