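# thermgroups

Group-additivity prediction of five phase-change thermodynamic descriptors
of organic molecules at 298.15 K, for computational and medicinal chemists
who need fast, structure-only estimates and a transparent, auditable model:

* standard enthalpy of vaporization (kJ/mol),
* standard enthalpy of sublimation (kJ/mol),
* standard enthalpy of solvation in water (kJ/mol),
* entropy of fusion of ordinary organic molecules (J/mol/K),
* total phase-change entropy of liquid crystals (J/mol/K),

plus the standard enthalpy of fusion, derived as the difference between the
sublimation and vaporization predictions.

## The model

Every heavy atom of a molecule is assigned to exactly one *atom group*
defined by the central atom's element, hybridization and formal charge and
by its immediate bonded neighbourhood (e.g. `C sp3|H2CO` for the methylene
carbon of ethanol). A handful of whole-molecule *special groups* capture
effects that atom-centered fragments cannot: intramolecular hydrogen
bonding, per-carbon corrections for pure hydrocarbons, the number of
endocyclic single bonds and small-ring angle strain. A descriptor is then
the linear combination

    Y = sum_i a_i A_i + sum_j b_j B_j + C

where `A_i` and `B_j` are the group and special-group counts and `a_i`,
`b_j`, `C` are tabulated contributions shipped with the package as
plain-text, checksummed tables. A prediction is refused — not guessed —
whenever the molecule contains a group that is absent from a table, has a
blank contribution, or is supported by fewer than three independent
training molecules ("valid group" rule).

The training side is included: contributions are evaluated from
experimental data by Gauss-Seidel iteration on the least-squares normal
equations, with valid-group gating iterated to a fixed point, iterative
outlier removal against the cross-validated standard deviation, and 10-fold
cross-validation statistics (Q², average and standard deviations).

## Worked example

```r
library(thermgroups)

ethanol <- readSMILES("CCO", "ethanol")
fragmentMolecule(ethanol)
#> FeatureVector: 3 typed centers in 3 heavy atoms
#>   C sp3|H2CO                   1
#>   C sp3|H3C                    1
#>   O|HC                         1

predictDescriptor(ethanol, "dHvap")
#> PredictionResult <dHvap>
#>   value 42.02 +/- 4.56 kJ/mol

predictFusionEnthalpy(ethanol)
#> PredictionResult <dHfus>
#>   value 19.11 +/- 12.27 kJ/mol
```

42.02 kJ/mol is the exact sum 8.61 (constant) + 3.07 (`C sp3|H3C`) + 15.79
(`C sp3|H2CO`) + 14.55 (`O|HC`); the quoted 4.56 kJ/mol is the vaporization
model's cross-validated standard deviation. The fusion estimate is the
sublimation prediction minus the vaporization prediction, and its 12.27
kJ/mol uncertainty is the quadrature combination of the two parent
deviations (11.39 and 4.56 kJ/mol).

Refusals are explicit:

```r
predictDescriptor(readSMILES("CCB(CC)CC", "triethylborane"), "dHvap")
#> PredictionResult <dHvap>
#>   not predictable: missing groups
#>   missing/invalid: B|C3; C sp3|H2BC
```

A command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","thermgroups.R",package="thermgroups"))') \
    predict --descriptor dHvap --in molecules.sdf --out results.tsv
```

Subcommands: `fragment`, `predict`, `tables`, `fit`, `crossvalidate`,
`fixtures`.

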