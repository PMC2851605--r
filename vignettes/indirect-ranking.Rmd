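---
title: "Indirect two-sided relative ranking: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect two-sided relative ranking: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(i2r)
```

## The problem

Gene expression databases accumulate treatment profiles measured under
heterogeneous experimental conditions: different delivery vehicles (water,
DMSO, EtOH, MeOH), different processing batches, different laboratories.
When the question is *"which other treatments perturb the cell like this
one?"* — the core query of expression-based drug repositioning — these
nuisance factors corrupt direct profile-to-profile comparisons: a query's
nearest neighbours tend to be its batch-mates, not its pharmacological
relatives.

This package implements two similarity measures over ranked probe lists
and the evaluation machinery to compare them:

* the **direct** two-sided truncated Kolmogorov–Smirnov score, the
  connectivity-map (CMAP) style query statistic, and
* the **indirect two-sided relative ranking (I2R)** score, which compares
  two instances through their relationship to the *entire* database rather
  than to each other directly.

## The direct statistic

Each instance is reduced to its ranking of $m$ probes by amplitude
(expression difference versus a vehicle/batch-matched control), rank 1
being the most up-expressed probe. A query is represented by its
*signature*: the $k$ uptags (ranks $1..k$) and $k$ downtags (ranks
$m-k+1..m$). The choice of $k$ is the user's; a sensible default keeps
$k/m$ in the few-percent range (for example $k = 250$ at $m \approx
12{,}500$, $k = 10$ at $m = 320$). `ks_similarity()` requires $2k \le m$
so the two sides cannot overlap.

For one tag set of size $t$ whose sorted positions in the target ranking
are $V(1) < \dots < V(t)$, the one-sided truncated KS statistic is

$$a = \max_{j=1..t}\Bigl(\tfrac{j}{t} - \tfrac{V(j)}{m}\Bigr), \qquad
  b = \max_{j=1..t}\Bigl(\tfrac{V(j)}{m} - \tfrac{j-1}{t}\Bigr),$$

with score $a$ if $a > b$ and $-b$ otherwise: the maximal signed gap
between the tags' empirical distribution and a uniform spread. The
two-sided score combines the uptag side $KS_u$ and downtag side $KS_d$:
when both sides shift toward the same end of the target ranking
($KS_u \cdot KS_d > 0$) the score is 0 — no clean separation — otherwise
it is $KS_u - KS_d \in [-2, 2]$. A side exactly equal to 0 does not
trigger the zero rule, and an $a = b$ tie returns $a$; both conventions
are deterministic choices for events of probability zero on continuous
data. The final score is the raw difference; no rescaling to $[-1, 1]$ is
applied.

## The indirect statistic

Let $KS_D(q)$ be instance $q$'s vector of direct scores against every
instance in the database — self-scores included, so the extreme self-match
is part of both rankings. Then

$$I2R(t, q) = \mathrm{Spearman}\bigl(KS_D(q),\, KS_D(t)\bigr).$$

Two instances are indirectly similar when they rank the whole database the
same way, a vantage-point construction: the pair is compared through its
distances to a common reference collection. The Spearman correlation uses
the classical $1 - 6\sum d_i^2 / (n(n^2-1))$ shortcut on tie-free vectors
and the Pearson correlation of average (fractional) ranks when ties are
present. Ties are the norm, not the exception: the zero rule of the direct
score produces many exact zeros, so the rank-Pearson path is the effective
default. A constant score vector (possible on degenerate inputs) has no
defined correlation; `i2r_similarity()` records 0 with a warning so
downstream rankings stay total.

`i2r_similarity()` consumes the one KS matrix for all $n^2$ correlations —
each row is rank-transformed once and correlated by matrix product —
keeping the indirect pass cheaper than the direct pass that feeds it.

## Evaluation protocols

*Barrier retrieval.* `recall_at_k()` queries the database with every
member of a therapeutic group and counts same-group instances in the top
$k$ (default 10) that differ from the query in vehicle, batch, or both —
only such hits demonstrate robustness to the confounder. Percent
improvement of indirect over direct is $100([i]-[d])/[d]$; a zero direct
baseline is reported as a special case (`is_special_case()`), excluded
from improvement averages. Group PPV is recalled true positives over
retrieval slots (queries $\times k$), averaged unweighted across groups.
Groups below 10 instances are dropped by default to avoid small-sample
artefacts.

*Classification.* `classify_majority()` labels each instance by the modal
class of its top 11 neighbours (odd to avoid two-class ties; residual
multi-class ties go to the larger summed similarity, then name order).
`average_ranks()` reports the mean retrieval rank of class-mates, the
per-sample quantity used when there are too few groups for recall
analysis.

*Rank significance.* `paired_rank_ttest()` compares per-(query,
true-positive) retrieval ranks of the two methods, keeping a pair when
*either* method places it within the search threshold (default 100) and
dropping pairs missed by both. Differences are direct minus indirect rank,
so positive means the indirect method retrieved earlier. All-zero
differences give p = 1; constant non-zero differences are flagged as
degenerate with no finite t statistic. `roc_auc()` (rank-sum identity,
ties counting one half) and `delong_test()` (DeLong covariance of paired
curves, via pROC) compare methods over pooled pair scores, where each
ordered (query, target) pair is scored by the negative retrieval rank —
the same ranks the t-tests use.

*Set cohesion.* `permutation_test()` measures whether a set of $t$
instances is more indirectly similar than random sets: the observed mean
within-set pairwise I2R is compared against $r$ uniform draws of $t$
instances, and $p = s/r$ where $s$ counts draws strictly exceeding the
observed mean. The statistic is reported exactly as this frequency (no
$+1$ smoothing by default, so $p = 0$ is possible; a smoothed option
exists). An alternative reading of set cohesion — mean similarity of
members to one fixed reference instance — is available via
`statistic = "reference"`. Note the counting is one-sided even though such
frequencies are often quoted as two-sided p-values.

## The synthetic confounded database

`simulate_database()` draws amplitudes

$$A(p) = \delta\, s_c(p) + \beta_b(p) + \gamma_v(p) + \varepsilon(p)$$

for an instance of class $c$ in batch $b$ with vehicle $v$: $s_c$ is
$\pm 1$ on the class's up/down signature probes and 0 elsewhere (class
signatures disjoint, so ground truth is unambiguous);
$\beta_b(p) \sim N(0, \sigma_b)$ is drawn once per (batch, probe) and
$\gamma_v(p) \sim N(0, \sigma_v)$ once per (vehicle, probe), so nuisance
effects are probe-specific and shared within a batch or vehicle — they
perturb *rankings*, which is what both methods consume; $\varepsilon$ is
per-instance probe noise. Batches and vehicles are assigned by cycling
within class ("crossed": every class spans every batch, and batch/vehicle
combinations are crossed with class) or tied to class ("nested", complete
confounding).

Defaults describe a strongly batch-confounded retrieval study: $m = 1000$
probes, $g = 3$ classes of 40 instances, $B = 4$ batches, $V = 2$
vehicles, class effect $\delta = 1$ against batch effects $\sigma_b = 2$,
vehicle effects $\sigma_v = 0.5$ and probe noise $\sigma_e = 0.5$, with
50-probe signature sides. $m = 1000$ keeps $k/m$ at the few-percent ratio
used on real arrays while staying cheap; $\sigma_v$ is set below
$\sigma_b$ because solvent effects are milder than processing-round
effects on these arrays. A useful derived fact: a signature probe carries
its $\pm\delta$ only in its own class's columns ($1/g$ of instances), so
its pooled amplitude variance is $\sigma_b^2 + \sigma_v^2 + \sigma_e^2 +
\delta^2/g$, which the test suite verifies empirically.

What the generator emulates: class-consistent two-sided signal, additive
rank-perturbing nuisance structure, annotated confounders, replicate-like
within-class redundancy. What it does not: probe saturation and
cross-hybridisation, dose–response (the molar amount is carried but
unused), correlated probe sets, heavy-tailed noise, unbalanced group
sizes. Passing tests on this generator therefore demonstrate the
machinery and the confounding mechanism, not performance on any real
platform.

```{r example}
db <- simulate_database(sim_config(m = 300, n_per_class = 8, classes = 2,
                                   batches = 8, sig_size = 15,
                                   batch_sd = 1, seed = 7))
ks <- ks_similarity(db$expression, k = 15)
i2 <- i2r_similarity(ks)
recall_report(ks, i2, db$metadata, k = 5, barrier = "batch",
              min_group_size = 5)
```

## Numerical and design choices

* **Amplitude ties** are ranked by probe id (lexicographic) so every
  ranking is a bijection — the KS statistic needs unique positions. Ties
  are measure-zero on real amplitudes; the convention only matters for
  synthetic integer data. Ranking raw expression values instead of
  amplitudes is supported by passing the raw-value table; amplitudes are
  the recommended basis because they measure the treatment effect.
* **$KS_D$ orientation.** The score matrix is query-by-target; I2R
  correlates query rows. The transposed reading (each instance as target
  under all signatures) gives near-identical indirect rankings on
  confounded synthetic data; the row convention was fixed once.
* **Self-pairs** are computed, stored, and included in the correlated
  vectors.
* **Matrix round trips** are written at 17 significant digits and read
  back with the C `strtod` parser, reproducing every double bit-exactly;
  indirect matrices are symmetry-checked (1e-9) on load. Human-facing
  reports print at 4 decimals.
* **Leave-one-out vote bias.** With perfectly balanced classes and no
  signal, majority-vote accuracy sits *below* $1/g$, not at it: the
  query's own class has one fewer available neighbour. The no-signal
  sanity check in the test suite therefore uses retrieval fractions,
  whose chance level $(n/g - 1)/(n - 1)$ is exact.

## Known limitations

The indirect method's advantage depends on the batch-block geometry of
the database. When batches are numerous and small relative to $n$ — the
situation in real repositories, where hundreds of instances spread over
many processing rounds — aggregating over the database dilutes any single
batch's imprint on the score vectors, and the indirect method recovers
cross-batch neighbours the direct method misses; the test suite asserts
this regime. When a few large, class-balanced batch blocks dominate (for
example 4 batches of 30 in a 120-instance database) the block structure
drives the Spearman vectors themselves and the indirect score inherits,
rather than escapes, the confounding; under the suite's most extreme
confounding settings both methods fail the cross-batch task and the
indirect average rank trails the direct one. The package reports what it
measures in either regime.

Problem sizes throughout the test suite (databases of 12–120 instances,
200–1000 probes, Monte-Carlo calibrations of 400–1000 replicates) were
chosen as the smallest scales at which each property is distinguishable
from noise.
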