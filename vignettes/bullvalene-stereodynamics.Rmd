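---
title: "Bullvalene stereodynamics: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bullvalene stereodynamics: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Bullvalene (BV) is the tricyclic C10H10 cage in which every carbon can visit
every position through fast, reversible Cope rearrangements.  A substituted
bullvalene is therefore not one molecule shape but an equilibrating network
of constitutional isomers with distinct 3D shapes.  `bvstereo` models the
three layers of that problem — which isomers exist, how they interconvert,
and what they look like — and summarises the shapes the network can reach
with the descriptors used in fragment-based drug discovery: normalised
principal-moment-of-inertia ratios (NPR) and exit-vector parameters, each
optionally weighted by Boltzmann populations.

This vignette records the package's scientific conventions, the design
choices that were genuinely open, the numerical parameters and their
defaults, and the limitations a user should know about.

## Barcodes, symmetry and counting

Each of the ten scaffold carbons holds a digit: 0 for hydrogen, 1..k for
the non-hydrogen substituent types.  The fixed position order is

```
[alpha, beta, gamma, delta, beta', gamma', delta', beta'', gamma'', delta'']
```

i.e. the apical sp3 carbon first, then the (beta, gamma, delta) triple of
each arm.  Digit codes above 9 serialise as letters, so ten mutually
distinct substituent types still give 10-character strings.  The exact
digit-to-atom order is an internal convention: any fixed order compatible
with the symmetry operations yields the same counts, networks and
descriptors up to relabelling.

The scaffold's threefold rotation `rho` cycles the arms; two barcodes
related by `rho` describe the same isomer.  The canonical representative
of an orbit is the rotation that is *lexicographically greatest*, which
places substituents on arm 1 ("0000100000" canonicalises to
"0100000000").  Reflections are deliberately not quotiented out:
enantiomers are distinct isomers, as they must be for population and
exit-vector analysis.  An isomer is achiral exactly when the canonical
form of its mirror image equals itself (`classify_chirality()`); this is
a barcode-level test, not a 3D-geometry CIP assignment, which is out of
scope.

The closed-form count implemented by `count_isomers()` is

```
N_iso = (10! / prod_a N_a!  +  2 S) / 3
```

with the product over all substituent types including hydrogen, and `S`
(`compute_S()`) the number of C3-symmetric arrangements: an apical
occupant whose removal leaves every type count divisible by three, times
the distinct orderings of the per-arm triple.  `S` can only be 0, 1, 3 or
6.  The enumeration oracle (`enumerate_isomers()`, C++ scan over all
distinct digit permutations) is kept entirely independent of the closed
form and the two are cross-checked for all 42 substitution variations
(integer partitions of 10) in the test suite and in `variation_table()`.

## The Cope step and its orientation subtlety

A Cope rearrangement happens on one of three 1,5-hexadiene faces, each
spanning two arms.  Tracking atoms through the bond reorganisation (the
delta-delta bond of the participating arms breaks, the corresponding
beta-beta bond forms, the spectator delta becomes the new apical carbon)
gives a position permutation realising the four elementary exchanges:
alpha -> delta and beta -> gamma on non-participating arms,
beta -> delta and gamma -> gamma on participating arms.

One subtlety is easy to get wrong: the labels of the three product arms
are *not* arbitrary.  Canonicalisation removes rotations but not
reflections, so an orientation-inconsistent labelling maps chiral
products onto their enantiomers and corrupts every network downstream.
The package fixes the handedness of the base permutation numerically (the
new apical carbon keeps all three of its bonds through the rearrangement,
so the sign of the determinant of its bond-vector triad is conserved) and
derives the other two faces by conjugation with the C3 rotation, which
guarantees a consistent orientation.  Tests assert that each face
permutation is an involution on all ten positions and that reflecting,
rearranging on the mirrored face and reflecting back reproduces the
original step.

Degenerate steps are stored as self-loops, so every node has exactly
three face-transitions.  Face multiplicities between two isomers are
direction-dependent when their rotational stabilisers differ — the
C3-symmetric alpha-monosubstituted isomer reaches the delta isomer
through all three faces, while the reverse transition uses one — obeying
`m(u→v)·|orbit(u)| = m(v→u)·|orbit(v)|`.  Network edges therefore carry
both direction counts (`mult_from`, `mult_to`).

## 3D structures

Structures are generated by grafting substituents onto a fixed parent
template rather than embedding every isomer from scratch: per-isomer
distance-geometry embedding proved unreliable for the strained cage
(neighbouring cyclopropane substitution patterns collapsed it) and gives
no control over which enantiomer is produced.  The template is embedded
once with Open Babel's deterministic builder, relaxed, and averaged over
the six C3v symmetry operations so that symmetry-related positions are
exactly equivalent; a bundled copy of these coordinates serves as a
fallback when embedding is unavailable.  Each substituent SMILES is
embedded once as a hydrogen-capped fragment, tightly minimised, and
snapped into a canonical frame (attachment atom at the origin, bond axis
aligned, roll and atom order fixed); grafting replaces a scaffold
hydrogen with the fragment along the C-H exit vector.

Conformers: `n_conf` starting geometries differ in the substituent
torsions about their exit bonds (the first untwisted, the rest drawn from
the seeded RNG), each is relaxed, duplicates below 0.1 Å RMSD are
removed, and the `keep` lowest-energy structures are retained.  The
defaults `n_conf = 10`, `keep = 1`, `seed = 42` suit methyl-like
substituents, which are conformationally trivial; flexible substituents
need larger `n_conf`.  Population weighting uses the single best
conformer per isomer — no conformational partition function.

For a chiral barcode the geometry is built for the reference member of
the enantiomer pair and the partner is produced by reflecting the
optimised coordinates and relabelling positions through the mirror
operation.  This makes enantiomer pairs exact mirror images with
identical energies by construction — which is also the physically correct
force-field result — rather than relying on a minimiser to find two
mirror minima independently.

**Force field.**  The default is MMFF94, with UFF, GAFF and Ghemical
selectable.  The choice was made on the dimethyl system: UFF's minimum
for the beta,beta' isomer is symmetry-broken (dihedral near 10 degrees
where the molecular Cs symmetry requires 0) and was rejected; GAFF
reproduces olefinic geometry beautifully but ranks alpha-substituted
isomers lowest, which is chemically wrong, so it was rejected as a
default despite its geometry; MMFF94 gives correct symmetric geometries,
sensible distances, and the expected identity of the four most stable
dimethyl isomers.  Force-field energies are a *surrogate* for the
electronic-structure level used for quantitative populations; the
intended workflow for publication-grade numbers is `write_qc_input()`
(template-driven, bundled PBE0-D3/def2-SV(P) ORCA template) followed by
`ingest_energies()` on the external outputs.

**Determinism.**  Open Babel's builder randomises fragment orientation;
the canonical fragment frame removes this, and a snap-and-reminimise pass
removes the residual path noise, so builds are reproducible across
sessions for rigid substituents.  For conformationally flexible
substituents the embedder's conformer choice may still differ between
sessions; within a session all results are reproducible through the
fragment cache.

## Shape descriptors

`pmi()` computes the centre-of-mass inertia tensor over *all* atoms with
standard atomic masses (hydrogens included), eigenvalues ascending, and
the normalised ratios NPR1 = I1/I3, NPR2 = I2/I3.  Rod, disc and sphere
vertices are (0, 1), (0.5, 0.5) and (1, 1); NPR1 + NPR2 >= 1 is the
perpendicular-axis bound and is asserted on every structure.  Collinear
input returns the rod vertex with a flag.

`exit_vectors()` reports, for a substituent pair, the scaffold carbon
distance `r`, the signed dihedral `theta` = X1-C1-C2-X2 (right-handed
convention; mirror images negate it; the sign refers to the lower-to-
higher barcode position ordering), and plane angles `phi1`, `phi2`.  The
plane-angle convention — the angle between the exit vector and the C-C
axis directed *away* from the partner carbon — was an open choice; it was
fixed empirically because only this convention places the bullvalene
values in the 15-60 degree band where they are expected to lie (the
complement convention lands at 120-165 degrees).  It is isolated in one
internal function with a `phi_convention = "complement"` switch.  For a
multi-atom substituent X is its attachment atom; there is no centroid
option.  Report rounding (0.1 Å, 1 degree) is applied only in
`write_descriptor_csv(rounded = TRUE)`; tables keep full precision.

## Populations

`boltzmann_weights()` uses p_i = exp(-dE_i/RT) / sum_j exp(-dE_j/RT) with
R = 8.314462618 J mol^-1 K^-1, energies in kJ/mol (Hartree, kcal/mol and
eV inputs are converted by `ingest_energies()`; 1 Hartree = 2625.4996
kJ/mol) and T = 298 K by default.  Each enantiomer is a separate ensemble
member with its own weight; partners are isoenergetic and hence equally
populated.  Degenerate-rearrangement statistical factors (self-loop
counts) are *not* folded into the weights: the ensemble is over distinct
canonical isomers.  The energies may be electronic or free energies — the
package records what it is given and does not correct between the two.

## What the tests do and do not show

The combinatorial layer is verified exactly: closed form against
exhaustive enumeration for all 42 substitution variations, chirality
splits, network sizes and the monosubstituted exchange table.  The
geometric layer is verified at force-field level on the di-, tri- and
tetramethyl systems (15 + 42 + 72 isomers, one conformer each in the
standard runs; eight-conformer searches for the two dimethyl isomers
whose geometry is quoted to print precision).  These sizes keep the whole
suite under a minute of force-field work.

At the MMFF94 level the beta,beta' distance (2.5 Å), the beta,gamma'
distance (3.1 Å), the dihedral bound (max |theta| = 54.6 <= 60 degrees)
and the dimethyl NPR sum band (1.44-1.57) agree with
electronic-structure values; the beta,gamma' dihedral converges to
|theta| = 26.2-26.6 degrees where the electronic-structure value is 30 —
a genuine force-field limitation, recorded as a known deviation rather
than patched over by switching force fields per quantity.  Force-field
populations compress the energy scale relative to DFT (the four most
stable dimethyl isomers carry essentially all the weight instead of
~93%), so only the *identity* of that top-4 set is asserted, not its
percentages; quantitative populations require external
electronic-structure energies via `ingest_energies()`.

The synthetic fixtures (analytic rod/disc/sphere mass distributions,
mirrored point clouds, uniform/two-level/random energy tables) exercise
the descriptor and ensemble layers against closed-form expectations; they
emulate idealised inputs, not the noise or conformational breadth of real
experimental structures.

## Worked example

```{r}
library(bvstereo)

s <- substituent_set("C", 2)        # dimethyl
count_isomers(s)                    # 15
net <- build_network(s)             # 15-node Cope network

batches <- build_isomers(s, n_conf = 4, keep = 1, seed = 42)
pop <- boltzmann_weights(isomer_energies(batches))
head(pop, 4)

pt <- weighted_descriptor_table(pop, pmi_table(batches))
et <- weighted_descriptor_table(pop, ev_table(batches))
plot_pmi(pt); plot_ev(et)
```

## Known limitations

* Quantitative isomer populations need external quantum-chemistry
  energies; the force-field surrogate is for screening and testing.
* Chirality is classified from the barcode reflection test; CIP R/S
  labels are not assigned.
* Kinetics are out of scope: the network is connectivity, not rates.
* The reference regions of published exit-vector plots (CSD-derived
  cycloalkane areas) are not bundled; they can be overlaid from
  user-supplied data.
* Cross-session bit-reproducibility holds for rigid substituents;
  flexible substituents may embed in different conformers between
  sessions.
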