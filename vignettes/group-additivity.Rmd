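---
title: "Atom-group additivity for phase-change thermodynamics: methods and design"
author: "thermgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-group additivity for phase-change thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermgroups)
```

## The model and its assumptions

The package estimates five phase-change descriptors of organic molecules —
enthalpies of vaporization, sublimation and solvation (kJ/mol), the entropy
of fusion and, for liquid crystals, the total phase-change entropy
(J/mol/K) — all referenced to 298.15 K and 100 kPa, as the linear
additivity model

$$Y = \sum_i a_i A_i + \sum_j b_j B_j + C,$$

where $A_i$ counts occurrences of the $i$-th atom-centered group, $B_j$
counts the special (whole-molecule) groups, and $a_i$, $b_j$, $C$ are
tabulated contributions. The core assumptions are:

* **Locality.** Each heavy atom's contribution depends only on its element,
  hybridization, formal charge and first bonded shell. Longer-range effects
  must be carried by the special groups or they are simply model error.
* **Topology only.** Nothing depends on 3D geometry; conformational and
  crystal-packing effects are averaged into the contributions.
* **Reference state.** Experimental values used for fitting must already be
  at 298.15 K; the package performs no temperature adjustment.
* **Element scope.** Only H, B, C, N, O, P, S, Si and the halogens are
  covered; anything else makes the molecule "out of element scope".

The enthalpy of fusion is not fitted separately but derived as
$\Delta H^\circ_{fus} = \Delta H^\circ_{sub} - \Delta H^\circ_{vap}$, with
uncertainty $\sigma = \sqrt{\sigma_{sub}^2 + \sigma_{vap}^2}$ (quadrature
propagation of the two cross-validated deviations, 11.39 and 4.56 kJ/mol,
giving 12.27 kJ/mol).

## The typing grammar

A group key is `"<atom type>|<neighbours>"`. The atom type encodes element
and hybridization (`C sp3`, `C aromatic`, `N sp2`, ...), the central
charge (`N(+)`), and for sulfur and phosphorus the valence class (`S2` vs
`S4`, `P3` vs `P4`). The neighbour descriptor lists implicit hydrogens
first (`H3`, `H2`, `H`), then each heavy neighbour as a bond marker
(nothing, `=`, `#`, `:`) plus element symbol, aggregated with
multiplicities. Tokens are ordered by element (B, C, N, O, S, P, Si, F,
Cl, Br, J — iodine is spelled `J` in descriptors) and, within one element,
by bond marker. Neighbour formal charges are appended to the element run
(`CO=O(-)` for a nitro nitrogen). Centers of type `N sp3`, ether-type `O`
and divalent `S2` carry a `(pi)`/`(2pi)`/`(3pi)` suffix counting their C
and N neighbours engaged in a pi system.

Three decisions deserve explanation because the vocabulary itself forced
them:

* **Which atoms are centers.** The vocabulary has no rows for halogen
  centers or for terminal multiply-bonded atoms (carbonyl oxygen, nitrile
  nitrogen, thiocarbonyl sulfur, nitro oxygens). These atoms are treated as
  *decorations*: they appear only inside the neighbour strings of the atoms
  they are bonded to. A heavy atom is a typed center iff it is not a
  halogen and has at least one hydrogen or at least two heavy neighbours.
  Every heavy atom is then either a center or a decoration, which is the
  partition property the tests enforce.
* **Aromaticity is six-membered.** The vocabulary describes five-membered
  heteroaromatics in kekulized form: furan appears as two `C sp2|H=CO`
  carbons, two `C sp2|HC=C` carbons and an `O|C2(2pi)` oxygen — not as
  aromatic atoms (there are no `O aromatic` rows, and the sp2 spellings
  carry the large occurrence counts). Perception therefore marks only
  six-membered rings aromatic (every ring atom carrying an endocyclic
  double bond, iterated so that fused systems such as the middle ring of
  anthracene resolve), while five-membered heteroaromatics keep their
  kekulé pattern and decorate their heteroatom with `(2pi)`.
* **Pi counting is restricted to C and N neighbours.** Trialkyl phosphates
  must type their ester oxygens as `O|CP` (no annotation) even though the
  phosphorus carries a double bond, while nitrate esters type as
  `O|CN(+)(pi)`; counting only C/N pi neighbours reproduces both spellings.

The special groups are whole-molecule corrections: `H/H Acceptor` counts
donor-acceptor pairs (N/O/S-H donor, N/O acceptor, charge $\le$ 0)
separated by exactly 3 or 4 bonds, i.e. closing a 5- or 6-membered
hydrogen-bonded ring — one count per unordered pair, so ethylene glycol
counts 1; `Alkane/No. of C atoms` and `Unsaturated HC/No. of C atoms` add
one count per carbon for pure hydrocarbons only; `Endocyclic bonds` counts
single-order ring bonds (aromatic bonds are excluded); `Angle60`,
`Angle90` and `Angle102` count ring *atoms* whose smallest ring has size
3, 4 or 5. The per-atom reading of the angle groups is a package decision —
the unit (atoms, bonds or rings) is not fixed by the tables' prose, and
per-atom counting is the only one consistent with the high
occurrences-per-molecule ratios in the fusion-entropy table.

## Parameter tables and the validity rule

The five contribution tables ship as plain-text TSV with an MD5 manifest;
a checksum mismatch refuses the load. Blank printed contributions are
stored as missing (`NA`), making any molecule containing such a group
unpredictable for that descriptor. A group is *valid* when at least three
independent molecules supported it during fitting (`min_support = 3`,
configurable); predictions touching invalid groups are refused with the
offending keys listed, never silently extrapolated.

The packaged metadata is audited rather than trusted:
`transcriptionAudit()` recomputes each table's valid-group count from the
per-row molecule support and compares it with the printed "Valid groups"
row. The two disagree for all five tables (e.g. 200 computed vs 185
printed for vaporization — a table whose own source text also says 187).
The audit surfaces these gaps as data notes; nothing is adjusted to match,
because the printed summary rows evidently reflect a later fitting run
than the printed per-row metadata.

```{r audit, eval = FALSE}
transcriptionAudit()
```

## Fitting: Gauss-Seidel, gating, outliers, cross-validation

`buildDesignMatrix()` turns a training set into a count matrix with a
trailing constant column. Groups below `min_support` are removed and the
molecules containing them dropped; because dropping molecules can push
further groups under the threshold, the gate iterates to a fixed point
(the only self-consistent reading of the rule).

`solveGaussSeidel()` iterates the coordinate-wise update on the normal
equations $X^TX\beta = X^Ty$. Numerical choices, all fixed for
auditability: initialization at zero, canonical column order, convergence
when the largest relative coefficient change drops below `1e-10`, cap of
$2\times10^5$ sweeps. The normal matrix of a full-rank design is symmetric
positive definite, for which Gauss-Seidel provably converges; correctness
is anchored to a direct least-squares oracle in the tests (agreement to
1e-6 on 100 random systems), not to the iteration scheme itself.
Rank-deficient designs are flagged (`unique = FALSE`) and non-convergence
is reported, never returned silently.

`fitDescriptor()` runs the full loop: gate, solve, cross-validate, remove
records whose absolute residual exceeds `outlier_k` times the
cross-validated standard deviation, repeat (at most `max_rounds = 5`).
The enthalpy models use `outlier_k = 4`, the entropy models 3, the
solvation model none — and the threshold is measured against the cv
deviation, the more conservative of the two candidates the source
alternates between. All removals are logged with their values.

`crossValidate()` refits inside each of $k = 10$ uniform random folds
(assignment is per record, unstratified, seed recorded in every report)
and predicts the held-out records; records whose groups fall out of the
fold model are excluded and counted, which is why the cross-validated N is
below the training N. Definitions, printed here because the summary rows
never state them: training $R^2$ is the squared Pearson correlation of
experimental and fitted values; $Q^2 = 1 - \sum(y-\hat y_{cv})^2 /
\sum(y-\bar y)^2$ with $\bar y$ the full-set mean; "Deviation Standard" is
$\sqrt{\sum r^2/N}$ without degrees-of-freedom correction and "Deviation
Average" is the mean absolute residual, consistent with the relative magnitudes of the
printed rows; regression lines regress calculated on experimental.
Outlier removal happens on the full fit before the final cross-validation
statistics are reported.

## The synthetic-data generator

`generateSyntheticTraining()` draws group counts as independent Poisson
variables (mean 1.2) over a chosen vocabulary and responses $y = C +
\sum_i a_i A_i + \varepsilon$ with Gaussian noise. The default
demonstration conditions are $n = 500$ records and $\sigma = 4.5$ —
the order of the vaporization model's cross-validated deviation, i.e. a
realistic experimental noise floor. What it emulates is exactly the
generative assumption of the additivity model; what it does *not* emulate
is real chemistry: group counts in real molecules are strongly correlated
(valence constraints, homologous series), supports are highly skewed, and
experimental errors are neither independent nor homoscedastic. Passing the
recovery tests therefore shows the estimator is correct under the model's
own assumptions, not that real training data are this benign. Identifiability
requires $n \ge$ number of groups + 1; degenerate specs are refused.

Test problem sizes — recovery at $n$ = 50/200/1000, calibration with 20
seeds at $n = 500$, 100 random solver systems of 15-40 records — were
chosen so the whole suite stays interactive while keeping Monte-Carlo
noise on the checked statistics well inside the asserted margins.

## Degenerate inputs and edge cases

* Records without bonds (single heavy atoms) are parsed directly, since the
  SDF backend refuses them; methane types as `C sp3|H4`, which is outside
  the vocabulary and reported as such.
* Malformed SDF records produce record-level warnings with their index;
  the remaining records are still returned.
* Unsupported elements flag the whole molecule out of scope before typing;
  this status is distinct from "missing group".
* Charges are read from `M CHG` lines (which take precedence) or the
  legacy atom-block column; nitro/N-oxide groups must be drawn in
  charge-separated form, matching the vocabulary's `N(+)...O(-)`
  spellings.
* Zero-variance responses make $R^2$ undefined; the statistics object
  flags this instead of dividing by zero.

## Known limitations

* The liquid-crystal model is included for completeness but its predictive
  power is poor (cross-validated $Q^2 \approx 0.58$ in the source data);
  the class is too heterogeneous for a single additive model, and the
  package makes no attempt to predict phase sequences.
* Predictions are refused rather than extrapolated; coverage is therefore
  bounded by the tables' valid groups.
* The intramolecular hydrogen-bond rule is a topological surrogate; the
  original criterion is not documented and borderline geometries
  (seven-membered pseudo-rings, bifurcated donors) are not counted.
* No stereochemistry, tautomer handling or 3D effects; input tautomer
  choice can change the typing.
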