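# bvstereo

Stereodynamic analysis of substituted bullvalenes in R.

Bullvalene (BV) is the tricyclic C10H10 cage whose strain-promoted,
degenerate Cope rearrangements let every carbon visit every position: the
parent compound fluctuates between 1,209,600 equivalent valence isomers.
A *substituted* bullvalene instead shapeshifts between non-degenerate
constitutional isomers with genuinely different 3D shapes, which makes BV
scaffolds interesting as dynamic, quasi-spherical building blocks in
fragment-based drug discovery.  Reasoning about such a system needs
answers to three questions:

1. **Which isomers exist?**  Positions are encoded as a 10-digit barcode
   (apical `alpha`, then the `beta, gamma, delta` triple of each arm;
   digit 0 = hydrogen).  Barcodes related by the threefold scaffold
   rotation describe the same isomer, and enantiomers are kept distinct.
   The number of unique isomers for substituent multiplicities `N_a` is

   ```
   N_iso = ( 10! / prod_a N_a!  +  2 S ) / 3
   ```

   where the product runs over all types including hydrogen and `S`
   (0, 1, 3 or 6) counts the C3-symmetric arrangements.  The package
   implements both this closed form and an independent exhaustive
   enumeration oracle, and cross-checks them.

2. **How do they interconvert?**  Each Cope step acts on one of three
   1,5-hexadiene faces and induces a fixed position permutation (the four
   elementary exchanges `alpha->delta`, `beta->gamma` on non-participating
   arms and `beta->delta`, `gamma->gamma` on participating arms).
   `build_network()` assembles the full isomer interconversion multigraph,
   with degenerate steps as self-loops and per-direction face counts.

3. **What do they look like?**  `build_isomer()` grafts substituents
   (SMILES) onto a symmetrised 3D scaffold template, searches substituent
   torsions, and relaxes each candidate with a force field through Open
   Babel (MMFF94 default).  Shape is summarised by normalised
   principal-moment-of-inertia ratios (`pmi()`: NPR1 = I1/I3,
   NPR2 = I2/I3; rod (0,1), disc (0.5,0.5), sphere (1,1)) and by
   exit-vector parameters (`exit_vectors()`: distance `r`, signed dihedral
   `theta`, plane angles `phi1`, `phi2`), with Boltzmann population
   weighting at 298 K (`boltzmann_weights()`) to reflect the equilibrium
   composition of the shapeshifting network.

## Worked example: dimethylbullvalene

```r
library(bvstereo)

s <- substituent_set("C", 2)   # two methyl substituents
count_isomers(s)
#> [1] 15
chirality_split(s)
#> achiral   pairs   total
#>       9       3      15

batches <- build_isomers(s, n_conf = 4, keep = 1, seed = 42)
pop <- boltzmann_weights(isomer_energies(batches))
head(pop, 4)
#>      barcode   dE weight chirality    partner
#> 1 0100000010 0.00 0.4447    chiral 0100010000
#> 2 0100010000 0.00 0.4447    chiral 0100000010
#> 3 0010010000 5.18 0.0549   achiral       <NA>
#> 4 0100100000 5.35 0.0512   achiral       <NA>

st <- best_structure(batches[["0100100000"]])   # beta,beta' isomer
exit_vectors(st, 2, 5)
#>      barcode pos1 pos2    locants    r theta phi1 phi2
#> 1 0100100000    2    5 beta,beta' 2.51 0.157 52.1 52.1
pmi(st)
#> PMI: I1 = 417.76, I2 = 463.76, I3 = 594.71 amu A^2
#>      NPR1 = 0.702, NPR2 = 0.780, sum = 1.482
```

Fifteen unique isomers, nine achiral plus three enantiomeric pairs.  At
force-field level the four most stable isomers are the beta,beta' and
gamma,gamma' isomers and the (+-)-beta,gamma' pair — the same four that
dominate at the electronic-structure level, although a force field
compresses the energy spread, so quantitative populations should come
from external quantum-chemistry energies (`write_qc_input()` emits
ready-made inputs, `ingest_energies()` reads the resulting energies from
CSV or ORCA/Gaussian outputs).  The beta,beta' exit vectors sit at
r = 2.5 Å with coplanar C-Me bonds (theta = 0), and the NPR sum of about
1.48 places the isomer in the quasi-spherical region of the PMI triangle,
comparable to substituted adamantanes and cubanes.

`plot_pmi()`, `plot_ev()` and `plot_ev_phi()` draw the standard
(optionally population-weighted) shape plots;
`write_network_graphml()` / `write_network_edgelist()` export networks;
`variation_table()` tabulates all 42 substitution variations with their
counts and chirality splits.

A thin command-line wrapper over the same functions is installed at
`inst/cli/bvstereo` (subcommands `count`, `enumerate`, `network`,
`build`, `describe`, `populate`, `fixtures`).

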