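---
title: "Methods: hybrid descriptor selection and 2D-QSAR modeling for S2R ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid descriptor selection and 2D-QSAR modeling for S2R ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greedgene)
```

## The modeling problem

The Sigma-2 receptor (S2R) is implicated in several cancers and in
neurodegenerative disease, but no experimental structure of the receptor is
available, so structure-based design is not an option. The practical
alternative is ligand-based 2D-QSAR: collect published binding affinities
(Ki, in nM) for known S2R ligands, compute conformation-independent 2D
descriptors from their molecular graphs, and regress

$$\mathrm{pKi} = \beta_0 + \sum_{j=1}^{k} \beta_j \, d_j, \qquad
\mathrm{pKi} = 9 - \log_{10}(K_i\,[\mathrm{nM}]),$$

on a small, carefully selected descriptor subset. This package implements
that workflow end to end: curation, descriptor computation and screening,
four subset-selection algorithms (forward stepwise, the lasso path, a
genetic algorithm, and the hybrid GreedGene), repeated-split validation,
and a virtual-screening stage with decoy-based enrichment metrics.

With roughly 127 modeling compounds, models are limited to $k = 5$
descriptors (a 1:25 descriptor-to-compound ratio); all selectors therefore
return exactly-$k$ subsets rather than choosing the size automatically.

## Curation rules

`curate()` keeps a record only if all of the following hold, and otherwise
rejects it with the complete list of violated rules:

* **Molecular weight** below 500 g/mol.
* **Affinity**: Ki below 5000 nM. Ki is assumed to be in nM throughout; no
  unit autodetection is attempted.
* **Basic ring nitrogen.** High-affinity S2R ligands are protonated at a
  basic nitrogen, so a qualifying nitrogen must be present. The literature
  phrasing ("embedded in a rigid cyclohexyl ring") is looser than the
  collections it describes - piperazines and morpholines qualify - so the
  rule is operationalized as: a non-aromatic, non-amide nitrogen (SYBYL
  type N.3 or N.4 after perception) that is a ring member or directly
  attached to a ring atom. Pyridine-type (aromatic) and amide nitrogens do
  not qualify.
* **Stereochemistry.** A molecule is rejected when it has at least one
  potential stereocentre whose configuration the input SMILES leaves
  undefined; molecules whose stereocentres are all specified pass. The
  detector is a documented heuristic: a tetravalent sp3 carbon with at most
  one hydrogen whose four substituent branches receive distinct
  Morgan-refined canonical ranks, compared against the count of `@`/`@@`
  annotations in the input. Global Morgan ranks resolve local and
  para-type symmetry; exotic stereogenicity (atropisomerism, stereogenic
  N/S, double-bond geometry) is out of scope for these ligand classes.
* **Scaffold exclusion.** Structures containing the bridged
  9-azabicyclo[3.3.1]nonane (granatanine) core are excluded; it is
  chemically remote from the modeled ligand families. The match is a
  substructure SMARTS match by default (a full-scaffold-only match would
  silently admit decorated variants); the pattern list is configurable.

Unparsable structures are rejected with reason `parse_error`, never an
error, so a single bad record cannot abort a curation run.

## Split protocol

`make_split_plan()` first separates the curated set into modeling and
external-testing subsets at 4:1, then re-splits the modeling set into
training/validation at 4:1, 50 times. All sizes use round-half-up of the
4/5 fraction - the only rounding convention that reproduces both published
partitions (159 compounds into 127/32, and 127 into 102/25; `floor` and
`ceiling` each contradict one of the two). Repeat $r$ draws with seed
`seed + r`, so any single split is reproducible without regenerating the
other 49. Ids are sorted before sampling, making the plan a function of the
id *set* and seed only.

## Descriptor analogs

`compute_descriptors()` produces, among simple graph counts, the five
descriptors of the published model. The published coefficients were fit on
a commercial provider's descriptor values; this package computes
open-toolkit analogs, documents each definition, and labels every matrix
with its provider. **Numerical parity across providers is deliberately not
promised** - a model fit on one provider's values should only score
matrices from the same provider, which is why the published-model scorer
also accepts externally computed descriptor CSVs
(`read_descriptor_csv()`).

* `balabanJ`: Balaban's distance connectivity index
  $J = \frac{B}{C+1}\sum_{(i,j) \in E}(s_i s_j)^{-1/2}$ over the
  heavy-atom graph, with $s_i$ the distance-matrix row sum, $B$ the bond
  count and $C$ the cyclomatic number. Computed on the largest connected
  component; undefined cases (no heavy-atom bond) return 0 with a warning.
* `b_max1len`: the number of bonds in the longest path of the subgraph
  restricted to acyclic single bonds between heavy atoms - a measure of
  the longest flexible chain. Ethane scores 1; benzene 0.
* Surface-area bins use a Labute-style approximation of per-atom van der
  Waals surface area: each atom's sphere (Bondi radius) minus the
  spherical caps buried by bonded neighbours, with ideal bond lengths from
  covalent radii, shortened slightly for higher bond orders. Hydrogens are
  explicit during this computation.
  * `Q_VSA_PNEG`: summed surface area of atoms with Gasteiger partial
    charge below -0.2, computed on the neutral (uncharged) form.
  * `vsa_acc`: summed surface area of *pure* hydrogen-bond acceptors -
    N or O carrying no hydrogen, excluding amide and planar aniline-type
    nitrogen (acceptor-and-donor atoms are not "pure" acceptors).
  * `SlogP_VSA1`: summed surface area of atoms whose atomic logP
    contribution lies in $[-0.4, -0.2)$ - mildly hydrophilic atoms such
    as ether/hydroxyl oxygens and heteroatom-substituted sp3 carbons. The
    atomic contributions come from a reduced typing (element, SYBYL type,
    hydrogen count, heteroatom context) with Wildman-Crippen-like values;
    it is a self-consistent simplified scheme, not a reimplementation of
    any published full table.

Descriptor values are a pure function of the molecular graph: permuting
the atom order of an input SMILES changes nothing (tested).

## Descriptor screening and correlation pruning

`screen_descriptors()` drops, in order: blacklisted names (defaults cover
synthesizability-type scores, which have no physical relationship to
binding), columns that are zero in more than 95% of molecules (they cannot
rank affinities), and near-binary columns with at most two distinct
values. Each excluded name carries exactly one reason, the first rule that
fired.

`prune_correlated()` then greedily groups descriptors whose absolute
Pearson correlation exceeds 0.9 and keeps one representative per group.
The representative is the member most correlated with the response when a
response is supplied, otherwise the lexicographically smallest name; a
seeded random choice is available but determinism is the default because
it makes selection runs reproducible. Group membership is retained - the
GreedGene swap stage needs it. Zero-variance columns are excluded as
degenerate. Both operations are idempotent.

## Selection algorithms

All four selectors share one objective. The objective actually used by the
original GA-based selection is not documented anywhere we could follow, so
the package makes a choice and states it: **leave-one-out Q2 of the
k-descriptor MLR** (default), because it matches the validation criterion
used downstream and penalizes overfit subsets that inflate training R2;
`r2_train` is available as an alternative. Q2 is computed by the exact
hat-matrix identity $e_{(i)} = e_i/(1-h_{ii})$, which tests verify against
a literal refit-per-row oracle to 1e-10. Ties everywhere break
lexicographically by descriptor name, so every selector is deterministic
given its seed.

* **Forward stepwise** adds the fitness-maximizing descriptor at each
  step; `classic = TRUE` switches to the traditional
  correlation-with-residual entry rule.
* **Lasso path** standardizes columns, traverses a fine descending-lambda
  lasso path, and selects the first $k$ distinct variables to enter the
  active set, then refits unpenalized least squares on them. On orthogonal
  designs the entry order provably follows descending absolute correlation
  with the response (tested against that closed form).
* **Genetic algorithm**: individuals are exactly-$k$ index subsets.
  Crossover keeps the parents' intersection and fills the remainder from
  their symmetric difference; mutation swaps genes out of the subset with
  per-gene probability $1/p$; tournament selection (size 2) and one-elite
  survival complete the generation. An exactly-$k$ representation with
  repair was chosen over penalized variable-length bitstrings because the
  models are exactly-$k$ by design. Defaults: population 100, 50
  generations.
* **GreedGene** runs the GA `ga_repeats = 5` times with derived seeds.
  Descriptors present in at least `core_consensus_fraction = 0.8` of the
  repeats' results form the *consensus core* - the descriptors the GA
  finds "synergistic" regardless of its random start (if more than $k$
  qualify, the $k$ most frequent are kept). Every completion of the core
  to size $k$ is then evaluated exhaustively: exactly
  $\binom{p-|\mathrm{core}|}{\,k-|\mathrm{core}|}$ regressions, a count
  the result records and which `count_combinations()` checks against a
  budget *before* starting (the unconstrained search over 160 descriptors
  would need $\binom{160}{5} = 820{,}384{,}032$ fits). The hybrid also
  compares its completion against each GA repeat's own best subset - a
  repeat need not contain the full core - so its fitness is structurally
  at least the maximum over its repeats. Finally, *swap refinement*
  revisits correlation pruning: each selected descriptor is tentatively
  replaced by every member of its correlation group, keeping strict
  improvements until a fixed point.

On instances small enough to enumerate, GreedGene's fitness equals the
global exhaustive optimum whenever the consensus core is contained in that
optimum; the test suite checks equality on planted instances with
$p \le 25$.

## Model validation

`run_protocol()` fits the MLR on each training split, records training R2
and LOO Q2, and scores the held-out validation split; after the repeats it
refits on the full modeling set and scores the external testing set. The
split criteria mirror their sources: training R2 must *exceed* 0.6 (strict)
while Q2 and validation R2 use non-strict $\ge 0.5$; a model is "stable"
when at least 95% of splits meet the validation criterion.

Out-of-sample "squared correlation" is ambiguous: the coefficient of
determination $1 - SS_{res}/SS_{tot}$ about the evaluated subset's own mean
(default here) and the squared Pearson correlation differ on new data. Both
are implemented (`pearson2 = TRUE`); the default is the stricter
coefficient of determination, which also penalizes calibration error.

Selection can run once on the full modeling set or per split. Per split is
the default: reselecting inside every resample is the honest protocol, and
the reported ranges are per-split ranges.

The frozen `published_model()` is a constant: intercept 11.29 with
coefficients -3.77 (`balabanJ`), +0.23 (`b_max1len`), -0.029
(`Q_VSA_PNEG`), +0.043 (`vsa_acc`), -0.026 (`SlogP_VSA1`). Its training
data's proprietary descriptor values are not redistributable, so the
coefficients are not a recomputation target; the scorer itself is verified
by exact spot values (an all-zero descriptor vector scores 11.29).

## Virtual screening

`filter_library()` applies Lipinski's Rule of Five (strict by default;
one tolerated violation is a flag away), requires a basic nitrogen, rejects
more than two positively chargeable groups, rejects unspecified
stereocentres (a racemic input is outside the model's applicability
domain), enforces an organic-element whitelist
\{H,C,N,O,S,P,F,Cl,Br,I\} as the inorganic-compound proxy, and flags
more than four amide bonds as peptidomimetic. The last two are documented
heuristics standing in for judgments a human curator would make.

`predict_library()` scores a descriptor matrix with any linear model and
applies the activity cutoff pKi >= 5.5 *inclusively* (a prediction exactly
at the cutoff passes).

Decoy selection sorts candidate decoys by their maximum Tanimoto
coefficient against the actives set and keeps the most dissimilar
`floor(0.25 * n)` (ties at the boundary break by id). The fingerprint
defaults to Open Babel's FP2 path fingerprint (1024 bits); the similarity
source is configurable, and `select_decoys()` accepts precomputed `max_tc`
columns so the cutoff logic is independent of the fingerprint choice. A
1:50 actives:decoys assembly ratio is conventional but not enforced -
`assemble_screening_set()` records the realized ratio instead.

`evaluate_enrichment()` reports the confusion counts and
sensitivity $= TP/(TP+FN)$, specificity $= TN/(TN+FP)$, and enrichment
factor $EF = (TP/Ht)/(A/D)$; with `top_fraction < 1` the ranked hit list is
truncated first (top-1% EF is the common summary). Count identities
($TP+FN=A$, $TP+FP=Ht$, $TP+TN+FP+FN=D$) are asserted on every input, and
EF is invariant to uniform duplication of the database. An empty hit list
yields an explicitly flagged undefined EF rather than a division error.

## Synthetic data

`generate_matrix()` draws equicorrelated standard-normal descriptor
columns (pairwise correlation 0.2 by default - descriptors computed from
the same graphs are never independent) and a response that is a linear
combination of a planted support plus Gaussian noise. Given a target
population R2, the noise SD is derived analytically from
$\sigma^2_{signal} = \beta^{\top}\Sigma\beta$, so "population R2 = 0.7" is
a property of the generator, not a fitted afterthought. Options add
near-duplicate columns (r > 0.9, to exercise pruning and swap refinement)
and pathological screening columns (a 96%-zeros column and a two-valued
column). `toy_molecule_set()` provides ~20 hand-written SMILES that
jointly trigger every curation rule at least once.

What the generator does *not* emulate: real descriptor distributions are
skewed, heteroscedastic, and block-correlated by descriptor family, and
real activity data carry inter-laboratory noise and activity cliffs.
Passing tests on synthetic data therefore demonstrate the algorithmic
properties (recovery, optimality, calibration of the protocol), not
predictive performance on new chemistry.

## Numerical choices and problem sizes

* Least squares is solved by QR (`fit_mlr()`); the selection inner loop
  uses a Cholesky factor of the normal equations with the PRESS identity,
  returning $-\infty$ on singular or leverage-one designs so that the
  selectors simply skip degenerate subsets.
* Rank deficiency in a final fit is an error that names the collinear
  columns; in LOO it is an error, never silently imputed.
* The test suite exercises selection at $n = 160$, $p = 60$, $k = 5$,
  population R2 0.7 (20 trials), global-optimality at $p \le 25$ (10
  seeds), and the scrambling control through a 50-repeat protocol (20
  scrambles) - sizes chosen to make each property statistically meaningful
  while keeping a full run on one CPU comfortable.

## Known limitations

* Descriptor analogs are documented approximations; absolute predicted
  pKi values from `published_model()` on package-computed descriptors will
  differ from scores on the original provider's descriptors. Use supplied
  descriptor CSVs when faithful scoring matters.
* Stereocentre detection is a heuristic (see above); it is designed to be
  conservative for the amine-rich ligand classes modeled here.
* The amide-count and element-whitelist screening rules approximate
  "peptidomimetic" and "inorganic" exclusions.
* Aromaticity, SYBYL typing and Gasteiger charges are delegated to Open
  Babel; molecules it cannot perceive are rejected as `parse_error`.
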