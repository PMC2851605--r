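# i2r — indirect two-sided relative ranking for gene expression similarity

Expression databases mix profiles measured in different delivery vehicles
(water, DMSO, EtOH, MeOH) and different processing batches. For
signature-based similarity search — "which treatments perturb the cell
like this one?" — these confounders are poison: a query's nearest
neighbours under a direct profile-to-profile score tend to be its
batch-mates rather than its pharmacological relatives. `i2r` is for
computational biologists doing expression-based drug repositioning or
sample classification who need a similarity measure that sees across such
barriers, and the evaluation machinery to prove whether it does.

## The statistics

**Direct (CMAP-style) score.** Each instance is ranked by amplitude
(expression difference versus control), rank 1 = most up-expressed, and
summarised by its signature: the k uptags and k downtags. For a tag set
with sorted positions V(1) < … < V(t) in a target's ranking of m probes,
the one-sided truncated Kolmogorov–Smirnov statistic is

    a = max_j ( j/t − V(j)/m ),   b = max_j ( V(j)/m − (j−1)/t )

scoring `a` if a > b else `−b`. The two-sided score is 0 when the uptag
and downtag statistics share a sign, otherwise `KS_u − KS_d` in [−2, 2].

**Indirect (I2R) score.** Let `KS_D(q)` be q's vector of direct scores
against every instance in the database (self included). Then

    I2R(t, q) = Spearman( KS_D(q), KS_D(t) )

— two instances are similar when they rank the whole database the same
way, a vantage-point construction that pools evidence from every
instance instead of trusting one noisy pairwise comparison. Ties (common:
the zero rule produces many exact zeros) use Pearson on fractional ranks.

Around these two scores the package provides barrier-aware retrieval
evaluation (recall at rank k across different vehicles/batches, percent
improvement with zero-baseline special cases, group PPV), majority-vote
classification, average ranks, paired rank t-tests with a top-100
inclusion rule, ROC/AUC with DeLong comparison, a permutation test for
set cohesion, and a generator of synthetic confounded databases with
known ground truth.

## Worked example

A synthetic database of 120 instances (3 therapeutic classes × 40), 1000
probes, spread over 12 batches whose probe-specific effects (sd 2) are
twice the class signal (sd 1):

```r
library(i2r)

db <- simulate_database(sim_config(batches = 12, seed = 1))
ks <- ks_similarity(db$expression, k = 50)   # direct, queries in rows
i2 <- i2r_similarity(ks)                     # indirect, symmetric

recall_report(ks, i2, db$metadata, k = 10, barrier = "batch")
#> # A tibble: 3 × 10
#>   group   n_instances     k barrier direct_count indirect_count improvement_pct
#>   <chr>         <int> <int> <chr>          <int>          <int>           <dbl>
#> 1 class01          40    10 batch             29             74            155.
#> 2 class02          40    10 batch             33             77            133.
#> 3 class03          40    10 batch             28             58            107.
#>   special_case ppv_direct ppv_indirect
#>   <lgl>             <dbl>        <dbl>
#> 1 FALSE            0.0725        0.185
#> 2 FALSE            0.0825        0.192
#> 3 FALSE            0.07          0.145
```

Reading: querying with each class01 instance and counting same-class hits
from a *different batch* in the top 10, the direct score recalls 29 true
positives over the 40 queries, the indirect score 74 — a 155% improvement
in cross-batch recall, with PPV rising from 7.3% to 18.5%. The
permutation test asks whether the class01 set is more indirectly cohesive
than 1000 random 40-instance sets:

```r
permutation_test(i2, db$metadata$instance_id[db$metadata$class == "class01"],
                 trials = 1000, seed = 11)
#> Permutation test (pairs statistic): observed I2R_0 = 0.0469, 71/1000 trials exceeded, p = 0.071
```

The gain is concentrated where it matters, at the top of the retrieval
list: over *all* (query, true-positive) pairs the indirect method's mean
rank can trail the direct one even while its top-10 recall doubles, which
is why the report above, not a global rank average, is the headline
analysis. The regime matters too: with only a few large batches the batch
blocks dominate the score vectors themselves and neither method crosses
the barrier (see the methods vignette's limitations section).

A thin command-line wrapper over the same functions lives in
`inst/cli/i2r.R` (subcommands `simulate`, `ks`, `indirect`,
`eval-recall`, `classify`, `rank-ttest`, `permtest`, `pipeline`).

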