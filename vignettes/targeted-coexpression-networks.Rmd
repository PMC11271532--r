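---
title: "Targeted gene co-expression networks: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted gene co-expression networks: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the method it implements: the
statistical model, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical and design choices that were genuinely open.

## The model

A targeted gene co-expression network (TGCN) reverses the usual order of
co-expression analysis. Instead of clustering the whole transcriptome and
asking afterwards which modules relate to a trait, it first finds the
transcripts that predict the trait and then reconstructs the co-expression
neighbourhood of each. The underlying biological picture is additive: several
pathways influence the trait roughly independently, each pathway is
represented in the data by a co-expressed group of transcripts, and one
well-chosen representative per pathway ("seed") suffices to predict the
trait. The network is then the collection of pathway reconstructions, one
small module per seed.

### Step 1 — seed selection by bootstrapped LASSO

The LASSO minimises `RSS + lambda * sum |beta_j|`; the L1 penalty zeroes
most coefficients, which is what makes it a feature selector. On expression
data the selection is notoriously unstable: thousands of collinear
predictors admit many near-equivalent models, so small changes in the sample
set change the selected genes. `run_lasso_bootstrap()` therefore repeats the
fit on `b` bootstrap resamples and scores each transcript by its
*eligibility* — the number of runs in which it received a non-zero
coefficient. Transcripts with eligibility at least `r` (default 8 of 10)
become seeds. A plain OLS model on the seeds, evaluated by repeated k-fold
cross-validation (`fit_seed_model()`), measures what the seeds explain;
held-out R-squared is computed as `1 - RSS/TSS` around the held-out mean, so
an uninformative model scores at or below zero.

Each run trains on a bag of `n` samples drawn with replacement and tests on
the out-of-bag samples. We initially used replacement-free 80/20 splits, but
those training sets share 80% of their samples pairwise, so spurious
correlates of the trait — which are properties of the fixed data matrix, not
of any particular resample — get re-selected run after run and look stable.
With true bootstrap bags the training sets differ enough that, on the
default planted cohort, the rate of unstructured noise genes reaching
eligibility 8 drops by a factor of about four while driver recovery stays at
100%. The replacement-free variant remains available
(`resample = "subsample"`).

Two facts about the null behaviour are worth stating plainly, because they
shape what can honestly be tested. First, with the CV-minimum lambda the
LASSO is deliberately permissive, and on *any* fixed data set some
transcripts are spuriously correlated with a given trait vector strongly
enough to be selected in most bootstrap runs. A permuted trait therefore
does not yield an empty stable-seed set; what it yields is a *different*
stable set for every permutation. The meaningful calibration property — the
one the test suite asserts — is at the transcript level: no fixed transcript
is stably selected across most independent null traits. Second, the
eligibility threshold, not the LASSO itself, is what controls the error
rate; lowering `r` towards 1 admits the spurious tail (the selection union
keeps growing with `b`), which is visible in `eligibility_curve()`.

### Step 2 — module growth

Co-expression of two transcripts is the absolute Pearson correlation of
their profiles. For each seed, `rank_by_coexpression()` orders all other
transcripts by `|r|` (ties broken lexicographically by gene id, so rankings
are deterministic), and every module is a prefix of that ranking — a
property the tests verify exactly. Three sizing strategies:

* **fixed** — every module gets `size` transcripts (default 100);
* **proportional** — module `n` gets `S_n = S_1 * |beta_n| / |beta_1|`
  transcripts, where the betas are the seed-model coefficients and `S_1`
  (default 100) goes to the largest; sizes are rounded half-to-even and
  clamped to `[min_size, max_size]` (defaults 10 and 100);
* **enrichment** — start from the top `step` (default 10) transcripts and
  repeatedly offer the next `step`; a batch is accepted only if every added
  transcript's correlation with the seed survives BH at `alpha` within the
  batch *and* the module's functional abundance strictly improves. Equal
  abundance stops growth; a module whose first offer is rejected keeps its
  initial `step` transcripts and carries a `no_growth` flag.

The seed is a member of its module but is *not* counted against the size
budget, so `size = 100` yields 101 transcripts including the seed. The BH
family for the growth gate is the tentative batch: the rule being encoded is
"all transcripts added still show significant correlation", and the batch is
the set being added. Correlation p-values use the two-sided t-test with
n − 2 degrees of freedom.

### Step 3 — annotation

`compute_eigengene()` returns PC1 of the module's samples-by-members
submatrix (genes centered), the standard module summary profile. The sign of
a principal component is arbitrary, so it is oriented to make the mean
correlation of members with the eigengene positive; trait correlations are
then reproducible. `trait_association()` uses Pearson correlation for
continuous traits and the point-biserial correlation (numerically the same
statistic, equivalent to a two-sample t-test) for binary ones, with BH
across the modules of a network applied by `annotate_modules()`.

Enrichment is local: one-sided Fisher exact tests of a gene set against
each term of a user-supplied GMT collection, BH across terms. The enrichment
universe is the full expression gene list, not the union of the collection —
the choice changes every p-value, so it is fixed and stated. The
*functional abundance* of a gene set G is

\[
\frac{1}{|G|} \sum_{i=1}^{n} -\log_{10} p(t_i)
\]

over the `n` BH-significant terms. The p entering the sum is the raw
enrichment p-value of each significant term (the adjusted one is available
via `p_use = "adjusted"`): significance decides *which* terms count, and the
raw p then measures their strength without double-counting the correction.

## Diagnostics, replication, comparison

*Independence.* Seeds are meant to represent distinct pathways, so per run
the maximum absolute Spearman correlation over pairs of selected transcripts
is compared with the same maximum over a size-matched random draw (excluding
that run's selections); the per-run series are compared by two-sample
t-test. Spearman is used here (elsewhere co-expression is Pearson) because
the statistic of interest is a worst-case monotone association.

*Stability.* Mean pairwise Jaccard of the selected sets across runs; a pair
of empty selections counts as identical (Jaccard 1) by convention.

*Replication.* A discovery module replicates if it has at least one
BH-significant Fisher overlap with any module of the replication network
over the shared gene universe (the intersection of the two cohorts' gene
lists — stated because the Fisher tables depend on it). Seed-set
predictivity in a new cohort is calibrated against `n_perm` random
size-matched seed sets drawn from that cohort's genes excluding the real
seeds, with the plus-one empirical p-value `(1 + exceed) / (1 + n_perm)` —
never exactly zero. Null and dropout models are scored by in-sample
R-squared: tens of thousands of OLS fits are required, the comparison is
between models of identical dimension, and the real model is scored the same
way, so the comparison is fair.

*Comparison with a genome-wide partition.* Module membership (MM) is the
correlation of a gene with its partition module's eigengene; hub transcripts
are the top-|MM| genes of each partition module. |MM| stands in for the
intramodular adjacency a full WGCNA run would provide — building WGCNA
networks is out of scope, and |MM| is computable from the partition alone;
it is documented as an approximation. The crosstab counts shared genes per
(partition module, TGCN module) cell with a rightmost "none" column for
partition genes untouched by the TGCN; a TGCN module counts as "included in
a single partition module" when its BH-significant overlaps involve exactly
one partition module.

## The synthetic-data generator

`fixture_spec()`/`generate_fixture()` produce the planted cohort every test
runs against. Each block is a single-factor model: gene `i` of a block with
target correlation `rho` is `sqrt(rho) * f + sqrt(1 - rho) * eps_i`, giving
expected within-block correlation exactly `rho`, unit marginal variance, and
mutually independent blocks — closed forms that tolerance-based tests can be
written against. The trait is a weighted sum of one driver gene per block
plus Gaussian noise; one GMT term per block and marker sets for a subset of
blocks (labelled with brain cell types) align the annotation machinery with
the ground truth; the manifest records everything needed to score recovery
exactly.

Defaults mirror a study-scale targeted network: 25 blocks, 500 samples,
2000 noise genes, `rho = 0.8`, driver weights 1, trait noise sd 0.5. Block
sizes cycle over 10, 20, ..., 80 — the 10–80 range of a realistic module-size
distribution, placed on the grid of the default growth step because module
growth proceeds in batches of `step`: a block of, say, 16 genes can never be
recovered with Jaccard above ~0.7 by a step-10 procedure (the final batch
mixes the block tail with outsiders whichever way it is decided), so
off-grid sizes would measure the step granularity, not recovery quality.

What the generator does *not* emulate, and what passing tests therefore do
not show: count noise (negative-binomial overdispersion, library-size
artefacts), batch effects and covariates, correlated blocks (pathway
cross-talk), hub-and-spoke topology within modules, and traits with
non-additive or non-linear dependence on expression. Results on real
RNA-seq data depend on preprocessing (the package provides `log2(x+1)`,
quantile normalization with a per-rank-mean reference, and per-gene
z-scoring, in that canonical order) and on the adequacy of the additive
model — the generator validates the machinery, not the biology.

## Numerical choices and degenerate inputs

* RNG protocol: run `i` of the bootstrap uses seed `rng_seed + i - 1`, so
  results are bit-reproducible and a larger-`b` set of runs contains any
  smaller-`b` set as a prefix (this is how `eligibility_curve()` derives all
  its curves from one set of runs).
* Duplicate gene symbols on input keep the copy with the highest mean
  expression (warning); duplicate sample ids are an error. Missing values
  are refused rather than imputed.
* Zero-variance genes: dropped with a warning under z-scoring; correlation
  with a seed defined as 0 (ranked last); a zero-variance seed is an error.
* Collinear seed designs fall back to a pseudoinverse solution with a
  warning rather than silently dropping predictors.
* Proportional sizes round half to even (base R `round`), then clamp.
* Empirical p-values use the plus-one convention and a shared null stream:
  two seed sets scored under the same `rng_seed` see identical random draws,
  so a strictly better model never receives a larger p-value.
* Expression files are written with 17 significant digits so read/write
  round-trips at full double precision.

## Problem sizes used by the test suite

The suite validates study-scale behaviour on the default cohort (500 x 3090,
one bootstrapped-LASSO pass, module growth for all seeds, one twin cohort)
and uses reduced cohorts from the same generative family — 200–400 samples,
5–10 blocks, a few hundred genes — for repetition-heavy calibration checks
(200 repetitions for p-value uniformity, 20 permuted-trait bootstrap
passes, 5 repetitions per training fraction for stability). These sizes were
chosen so the full suite completes in a couple of minutes while every
statistical claim is still tested at a scale where its signal is
unambiguous.

## Known limitations

* Binary traits are fit with the squared-error LASSO and point-biserial
  association by default; the logistic variant exists
  (`family = "binomial"`) but is not the default, for parity with the
  continuous path.
* The enrichment-growth gate tests each batch in isolation; it does not
  revisit earlier batches, so a module can keep a transcript that a global
  test over the final module would reject.
* With the CV-minimum lambda the seed list at low `r` is permissive by
  design; users wanting conservative seed sets should use `r` close to `b`
  or the `lambda_rule = "1se"` flag.
* Gene-set collections are taken as given; no ontology-aware pruning of
  redundant terms is attempted, so functional abundance counts related terms
  separately.
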