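---
title: "Error-tolerant biclustering of real-valued expression data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-tolerant biclustering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etbicluster)
```

## The model

A gene-expression data set is a real-valued matrix with genes as rows and
experimental conditions as columns. A *constant-row bicluster* is a subset of
genes whose expression values are nearly equal within each of a subset of
conditions — each supporting condition sees the gene group at a coherent
level, though that level may differ between conditions. In association-mining
vocabulary the genes are items and the conditions are transactions.

Two measures define the pattern:

* **range** — a transaction (condition) is coherent for a gene set when the
  retained expression values all share a strict sign and their relative
  spread of absolute values, $(\max|v| - \min|v|)/\min|v|$, is at most a
  threshold $\alpha$. The sign requirement means a supporting condition sees
  the whole gene group either up- or down-regulated; the same group may be
  up-regulated in one condition and down-regulated in another.
* **RangeSupport (RS)** — each supporting transaction contributes its minimum
  absolute retained value, and the bicluster's RangeSupport is the sum of
  contributions. It replaces binary support: a condition where the group sits
  at expression ratio 6.5 is stronger evidence than one at 0.1.

Real data fragment such patterns: a single corrupted cell breaks a
transaction's coherence for every gene set containing that gene. The
error-tolerant extension allows each supporting transaction of a $k$-gene
bicluster to discard up to $\lfloor k\varepsilon\rfloor$ values as errors,
for a tolerance $\varepsilon \in [0,1)$. A bicluster $B$ with gene set $G$ is
valid when

1. $\mathrm{RangeSupport}(B) \ge RS$, and
2. every supporting transaction has at most $\varepsilon\cdot|G|$ error
   values under the range criterion.

At $\varepsilon = 0$ this degenerates to the exact range-support pattern
model (RAP mode), with no error discards. We accept $\varepsilon$ on
$[0, 1)$: the zero case is the exact mode used as the baseline throughout,
while a tolerance of 1 would permit all-error transactions and make the
definition vacuous.

### Which values count as errors

Candidate errors are confined to the extremes of a transaction's sorted value
list: with a budget of $e$, all splits discarding $i$ smallest and $j = e-i$
largest values are enumerated, for $e$ increasing from 0. This mirrors the
natural procedure for one and two permissible errors (drop the minimum, the
maximum, or one of each) and keeps the per-transaction check $O(e^2)$.
Interior values are never discardable — and nothing is lost by this: if any
retained subset of size $m$ is coherent, the contiguous sorted window spanned
by its minimum and maximum is also coherent and at least as large, so the
minimal error count over extreme splits equals the minimal error count over
arbitrary subsets. The test suite verifies this equivalence by exhaustive
subset enumeration on small inputs.

Three further conventions make the measure total:

* **Signs** apply to retained values only; a discarded error may have any
  sign, since errors are arbitrary corruptions.
* **Zeros** are never retained (the relative range $(x-0)/0$ and the sign of
  0 are undefined) but are discardable within the budget.
* **Negative blocks** are scored on absolute values within a same-sign
  retained set, so down-regulated biclusters are found symmetrically to
  up-regulated ones.
* **Tie-breaks**: among passing splits at the minimal error count, the split
  maximizing the contribution wins; remaining ties prefer fewer discards from
  the maximum end. This makes every decision, and hence the whole mining
  output, deterministic.

## The mining algorithm

`et_bicluster()` grows biclusters level-wise, Apriori-style. Level 1 keeps
every gene whose summed absolute expression reaches $RS$. Level $k+1$
candidates join two level-$k$ biclusters sharing a $(k-1)$-gene prefix under
the matrix row order (row order fixes gene order, for determinism), and a
candidate is kept only when all of its $k$-gene subsets are valid. The error
budget at level $k$ is $\lfloor k\varepsilon\rfloor$. When the budget grows
at a level transition (an *error-extension step*) the range criterion is
checked on the union of the subsets' supporting transactions; when it stays
constant (*non-error step*) only the intersection needs checking — a
transaction supporting the candidate under an unchanged budget must support
every subset, so the restriction is lossless, and we still re-run the full
check there because retained/discarded partitions can shift when a gene is
added. All levels are emitted; redundancy is the selection step's problem.

RangeSupport is anti-monotone for exact patterns, so at $\varepsilon = 0$ the
search is exhaustive: the test suite checks equality with brute-force subset
enumeration on random matrices. The range criterion is *not* anti-monotone
once errors are allowed, so for $\varepsilon > 0$ the level-wise procedure is
an avowed heuristic; what it guarantees — and what the tests assert — is
that every emitted bicluster satisfies the two defining conditions when
re-verified from scratch, and that the output always subsumes the exact-mode
output at equal parameters.

Two parameter regimes from practice: tight coherence on log-ratio compendia
(e.g. $\alpha = 0.3$–$0.5$) with $RS$ chosen so that a handful of strong
conditions suffice, and $\varepsilon = 0.25$, which permits one error at
levels 4–7 and three at level 12. When a full error-tolerant run is too
expensive, the conventional protocol is an exact run at a lower $RS$ merged
with a tolerant run at a higher one; `merge_runs()` unions the two keyed by
gene set, keeping the variant with the wider supporting set.

## Selection, residue, and evaluation

`select_top()` ranks by gene count only — wide error-tolerant biclusters
would otherwise dominate a genes-times-conditions measure — breaking ties by
the Cheng–Church mean squared residue
$H = \operatorname{mean}\left[(a_{ij} - a_{iJ} - a_{Ij} + a_{IJ})^2\right]$,
computed on retained cells only (error cells are excluded from the means and
the sum, as the model treats them as corruptions), then lexicographically for
determinism. It then greedily admits biclusters whose gene-set overlap with
everything already selected is at most 25%, up to 500. The overlap metric is
$|G_1 \cap G_2| / \min(|G_1|, |G_2|)$ — the strictest of the common choices;
it stops a large bicluster from absorbing a smaller near-subset, which is
precisely the redundancy the selection exists to remove. Singletons are
excluded by default (`min_level = 2`); size distributions of interest start
at pairs.

Enrichment of a bicluster against a gene-set collection uses the upper-tail
hypergeometric probability $P(X \ge k)$ of the observed overlap, with the
bicluster restricted to the annotation universe first and no
multiple-testing correction (the p-values are used comparatively, never as
calibrated error rates). Discriminative (biomarker) filtering builds the
2×2 table of case/control versus supporting/not-supporting conditions and
keeps biclusters with a two-sided Fisher exact $p < 0.05$ and sample odds
ratio above 2 or below 0.5; the exact test is the standard companion of the
odds ratio on 2×2 tables, and the Haldane–Anscombe $+0.5$ correction is
applied to all cells when any cell is zero so the ratio stays finite.

Two randomization tests estimate significance. The size-matched test draws,
for each bicluster of gene-size $s$, `reps` uniform random $s$-subsets of the
universe and reports the fraction whose enrichment score
($-\log_{10}$ of the minimum p-value) *strictly* exceeds the actual score —
ties do not count against the actual bicluster. A bicluster nothing beats is
reported as `< 1/reps` rather than 0; mapping it to any fixed number would be
a presentation choice, not a computation. The data-centric test permutes each
gene's values across conditions, conserving every row's value multiset while
destroying inter-gene correlation; mining the shuffled matrix shows how much
structure the marginals alone produce.

## The synthetic-data generator

`simulate_expression()` plants constant-row blocks in a uniform background
on $[-2, 2]$, the range typical of $\log_{10}$-ratio compendia. Within a
block, gene $g$ has a base magnitude $b_g$ (drawn from $[2, 2.4]$ by
default) and each planted cell is $b_g \cdot \mathrm{sign} \cdot (1+u)$ with
$u$ uniform on $[-0.03, 0.03]$; the worst-case within-transaction relative
range is then $(2.4 \times 1.03)/(2 \times 0.97) - 1 \approx 0.27$, below
the $\alpha = 0.3$ the recovery demonstrations mine at. A fraction
`error_rate` (default 0.1) of each block's cells is replaced by fresh
background draws — the corruption the tolerant miner is meant to absorb.

Corrupted cells are capped at $\lfloor \varepsilon \cdot n_\text{genes}
\rfloor$ per planted condition *and* spread across genes (at most
$\lceil \text{error\_rate} \cdot n_\text{conditions} \rceil$ per gene). The
per-condition cap keeps every planted condition supportable at tolerance
$\varepsilon$; the per-gene cap models scattered noise rather than a dead
probe, and matters because the early levels carry a zero error budget
($\lfloor 2 \cdot 0.25 \rfloor = \lfloor 3 \cdot 0.25 \rfloor = 0$): if a few
genes absorbed most corruption, their pairs and triples would lose enough
clean conditions to fall below any RangeSupport threshold that still excludes
the exact-mode full pattern, and subset pruning would block recovery for the
tolerant miner too.

That arithmetic also fixes the demonstration threshold. For the default
5-gene × 10-condition block with five corrupted cells (one per gene, one per
condition), a triple retains at least 7 clean conditions, each contributing
at least $2 \times 0.97$, so its exact RangeSupport is at least ~13.6; the
full 5-gene set retains exactly 5 clean conditions, at most
$5 \times 2.4 \times 1.03 \approx 12.4$. Mining at $RS = 12.5$ therefore
separates the two regimes: the tolerant run (budget 1 from level 4) supports
all 10 conditions and recovers the full planted set, while the exact run
recovers only proper subsets. One caveat the tests respect: a corrupted
cell's replacement is a background draw and occasionally lands back inside
the coherent band, in which case the exact miner may see an extra clean
condition — the exact-mode statement is therefore probabilistic across
seeds, not certain.

What the generator does *not* emulate: correlated noise across genes,
heavy-tailed measurement error, condition-specific scaling, overlapping
planted modules sharing genes, and the scale of real compendia (thousands of
genes, hundreds of conditions). Passing the recovery tests shows the
machinery behaves as designed under the stated noise model, not that any
particular biological data set will yield biclusters of a given size.

## The worked fixture

`worked_example_matrix()` is a 5-gene × 8-condition matrix built so that
mining at $RS = 5$, $\alpha = 0.5$, $\varepsilon = 0.25$ exercises every
stage: all five singletons; pair `ab` supported by six conditions with
contributions 2, 2.1, 4, 6.5, 3, 2 (RangeSupport 19.6) while condition `t5`
(values 8 and 20) fails the range test; triple `abc` restricted to the
intersection `{t2,t4,t8}` with RangeSupport 10.6; the level-4
error-extension step admitting one discard per transaction and yielding
`abcd` and `abce` over `{t1,t2,t3,t4,t5,t6,t8}` with RangeSupport 33.6
(errors 8 at `t1`, 9 at `t3`, 20 at `t5`; `t7` fails even after a discard);
and the quintuple `abcde` with the same support — which the exact mode
cannot find, because gene `d` carries an outlier in each of the three
conditions that are otherwise coherent across all five genes. Only a
minority of cells are pinned by those constraints; the free cells are one
frozen choice among many, and every constraint is asserted in the test
suite. One consequence of the arithmetic worth noting: for `abcd` to gather
supporting transactions `{t5,t6}` at the union step, triples such as `acd`
and `bcd` must themselves be valid (any transaction giving `abcd` a
contribution of ~8 or ~9 gives its triples the same), so the mined output
contains more triples and quadruples than the canonical walk-through names.

## Numerical choices and scales

* Threshold comparisons (range against $\alpha$, RangeSupport against $RS$)
  use an absolute slack of $10^{-9}$ so decimal fixtures like 19.6 compare
  stably in floating point; no scientific decision rides on values that
  close to a boundary.
* Degenerate inputs: an empty transaction, a budget equal to the gene count,
  an all-zero value set, an unlabeled condition in biomarker mode, and a
  gene set larger than the universe are all rejected with explicit errors
  rather than coerced.
* The test and demonstration scales — matrices up to 8 × 10 for the
  brute-force equivalence, 20 × 30 with one or two planted 5 × 10 blocks for
  recovery, 1000 replicates for randomization — were chosen so the whole
  suite and the acceptance script run in minutes on a laptop while every
  qualitative conclusion (recovery with tolerance, fragmentation without,
  destruction under shuffling, enrichment of planted modules) is exercised
  end to end. Absolute bicluster counts from published compendium-scale runs
  depend on those external data sets and are out of scope here; the package
  reproduces the behaviours, not the counts.

## Limitations

* For $\varepsilon > 0$ the search is heuristic and makes no completeness
  claim; patterns whose subsets all fall below $RS$ are unreachable.
* Error tolerance is enforced per transaction (row-wise) only: a gene inside
  a large bicluster can in principle be an error in many of its supporting
  transactions. A complementary per-column constraint is a known extension
  and is not implemented here.
* Candidate growth is exponential in the worst case; `max_candidates` exists
  as an explicit guardrail and is off by default.
* Enrichment p-values are uncorrected by design; treat them as ranks.
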