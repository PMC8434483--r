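# greedgene

Ligand-based 2D-QSAR modeling and virtual screening for Sigma-2 receptor
(S2R) ligands.

S2R is a drug target implicated in several cancers and in
neurodegenerative disease, with no experimental structure available. This
package implements the ligand-based alternative end to end: curate
published binding data, compute 2D descriptors from molecular graphs,
select a small descriptor subset, fit and validate multivariate linear
regression (MLR) models of binding affinity, and use them to screen
compound libraries.

The central model is

```
pKi = b0 + b1*d1 + ... + bk*dk,        pKi = 9 - log10(Ki [nM])
```

with k = 5 descriptors chosen by one of four selectors: forward stepwise
regression, the lasso path, a genetic algorithm (GA), or **GreedGene** — a
hybrid that runs the GA several times, takes the descriptors common to
most runs as a *consensus core*, completes the core to size k by
exhaustive search (exactly `C(p - |core|, k - |core|)` regressions,
checked against a budget via `count_combinations()` — the unconstrained
search would cost `C(160,5) = 820,384,032` fits), and finishes with a
correlated-descriptor swap refinement. The selection objective is
leave-one-out Q2 = 1 − PRESS/SS_tot of the k-descriptor MLR.

Model quality follows the repeated-split protocol: a 4:1 modeling/testing
split, then 50 seeded 4:1 training/validation re-splits of the modeling
set; a model is *stable* when ≥ 95% of splits reach validation R2 ≥ 0.5
(training R2 > 0.6, Q2 ≥ 0.5). A frozen `published_model()` exposes the
reported five-descriptor S2R model (intercept 11.29; coefficients −3.77
balabanJ, +0.23 b_max1len, −0.029 Q_VSA_PNEG, +0.043 vsa_acc, −0.026
SlogP_VSA1). The screening stage adds Lipinski/applicability-domain
filters, a pKi ≥ 5.5 activity cutoff, Tanimoto-based decoy selection
(most dissimilar 25% by maximum Tc against the actives), and enrichment
metrics (sensitivity, specificity, EF = (TP/Ht)/(A/D)).

Chemistry (SMILES parsing, Gasteiger charges, FP2 fingerprints, Rule-of-
Five properties) is delegated to ChemmineR/ChemmineOB (Open Babel); the
descriptor analogs, selectors, validation protocol and enrichment math are
implemented here. See the methods vignette
(`vignettes/greedgene-methods.Rmd`) for every analog's definition and
every documented heuristic.

## Worked example

```r
library(greedgene)

# 1. curate a ligand table (the shipped toy set trips every rule at least once)
cur <- curate(toy_molecule_set())
nrow(cur$kept); nrow(cur$rejected)
#> [1] 12
#> [1] 8
head(cur$kept[, c("id", "ki_nM", "pki")], 3)
#>                 id ki_nM      pki
#> 1  keep_piperidine   120 6.920819
#> 2  keep_piperazine    45 7.346787
#> 3 keep_pyrrolidine   800 6.096910

# 2. a synthetic benchmark with 5 planted descriptors out of 60, population R2 = 0.7
fx <- generate_matrix(synthetic_spec(n_molecules = 160, n_descriptors = 60,
                                     support_size = 5, target_r2 = 0.7, seed = 1))
plan <- make_split_plan(rownames(fx$matrix$values), seed = 1, n_repeats = 50)

# 3. GreedGene descriptor selection
sel <- greedgene(fx$matrix, fx$y, selection_config(k = 5, seed = 1))
sel
#> greedgene selection: {D004, D017, D022, D040, D050}
#>   fitness = 0.7658
#>   consensus core: {D004, D017, D022, D040, D050}
#>   exhaustive completions evaluated: 1
fx$true_support      # the planted truth
#> [1] "D004" "D017" "D022" "D040" "D050"

# 4. repeated-split validation of the selected subset
run_protocol(fx$matrix, fx$y, sel$descriptor_names, plan)
#> Repeated-split QSAR validation (50 splits)
#>   training R2:    0.74-0.83
#>   training Q2:    0.70-0.80
#>   validation R2:  0.20-0.88
#>   % splits meeting validation criterion: 96% (stable: TRUE)
#>   modeling R2 = 0.79, modeling Q2 = 0.76, testing R2 = 0.76

# 5. score a library with the frozen published model
published_model()
#> Linear QSAR model (published-moe)
#>   pKi = 11.29 - 3.77 * balabanJ + 0.23 * b_max1len - 0.029 * Q_VSA_PNEG
#>         + 0.043 * vsa_acc - 0.026 * SlogP_VSA1
```

Here the selector recovered all five planted descriptors (its fitness,
LOO Q2 ≈ 0.77, is the exhaustive optimum given the consensus core), and
the 50-split protocol certifies the subset as stable: 96% of validation
splits reach R2 ≥ 0.5 while the untouched external testing set scores
R2 = 0.76.

A command-line front end wrapping the same functions ships in
`inst/cli/s2rqsar.R` (subcommands `curate`, `split`, `describe`,
`screen-desc`, `select`, `fit`, `predict`, `screen`, `decoys`, `enrich`,
`synth`).

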