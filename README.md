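# etbicluster

Error-tolerant biclustering of real-valued gene-expression matrices.

## The problem

A bicluster is a group of genes that is coherently expressed across a subset
of experimental conditions. Association-mining approaches find *constant-row*
biclusters exhaustively and allow overlap, but classical support demands that
every gene behave in every supporting condition — so a single noisy cell
fragments a real pattern into pieces or hides it entirely, and binary
transaction data cannot represent how strongly a condition expresses the
group. This package mines biclusters directly from the real-valued matrix
while explicitly budgeting for errors, for anyone analysing microarray or
similar expression compendia (functional-module discovery) or case/control
cohorts (biomarker discovery).

## The model

Genes are items, conditions are transactions. A transaction supports a gene
set *G* when, after discarding at most ⌊ε·|G|⌋ extreme values as errors, the
retained values share a strict sign and have relative range
(max|v| − min|v|)/min|v| ≤ α. Each supporting transaction contributes its
minimum absolute retained value, and a bicluster *B* is valid when

1. RangeSupport(B) = Σ contributions ≥ RS, and
2. every supporting transaction has at most ε·|G| error values.

Mining proceeds bottom-up, level by level, Apriori-style: candidates join two
(k)-gene biclusters sharing a (k−1)-prefix, all subsets must be valid, and
the per-transaction error budget ⌊k·ε⌋ decides whether the range check runs
on the intersection (budget unchanged) or the union (budget grown) of the
subsets' supports. At ε = 0 the miner is the exact range-support pattern
miner (RAP mode) and is provably exhaustive; with ε > 0 it is a heuristic
whose output always subsumes the exact output. Downstream: redundancy-aware
top-bicluster selection with Cheng–Church mean-squared-residue tie-breaks,
hypergeometric gene-set enrichment, odds-ratio/Fisher biomarker filtering,
and two randomization significance tests.

## A worked example

The package ships a 5-gene × 8-condition matrix that walks the algorithm
through every stage:

```r
library(etbicluster)
x <- worked_example_matrix()
fit <- et_bicluster(x, alpha = 0.5, rs = 5, epsilon = 0.25)
fit
#> Error-tolerant bicluster mining
#>   alpha = 0.5, epsilon = 0.25, RangeSupport threshold = 5
#>   data: 5 genes x 8 conditions
#>   31 biclusters (levels 1-5)
#>   per level: 1:5, 2:10, 3:10, 4:5, 5:1

subset(as.data.frame(fit), level >= 4)
#>      genes           conditions level n_transactions range_support n_errors
#>    a;b;c;d t1;t2;t3;t4;t5;t6;t8     4              7         33.60        7
#>    a;b;c;e t1;t2;t3;t4;t5;t6;t8     4              7         33.60        4
#>    a;b;d;e t1;t2;t3;t4;t5;t6;t8     4              7         33.80        5
#>    a;c;d;e t1;t2;t3;t4;t5;t6;t8     4              7         33.75        6
#>    b;c;d;e t1;t2;t3;t4;t5;t6;t8     4              7         34.35        6
#>  a;b;c;d;e t1;t2;t3;t4;t5;t6;t8     5              7         33.60        7
```

Pair `ab` is supported by six conditions with contributions
2 + 2.1 + 4 + 6.5 + 3 + 2 = 19.6; the level-4 error-extension step grants one
discard per transaction (⌊4 · 0.25⌋ = 1), which stitches seven conditions
together for `abcd` (RangeSupport 33.6, error values 8, 9 and 20 in
conditions t1, t3, t5) and carries through to the full quintuple `abcde`.
The exact mode at the same thresholds cannot see it:

```r
exact <- et_bicluster(x, alpha = 0.5, rs = 5, epsilon = 0)
"a;b;c;d;e" %in% as.data.frame(exact)$genes
#> [1] FALSE
```

`abcde` is fragmented by its three corrupted cells, and with no error budget
no single condition is coherent across all five genes. Selecting the top
non-redundant biclusters surfaces the quintuple first:

```r
as.data.frame(select_top(fit, x))[, c("genes", "level", "range_support")]
#>      genes level range_support
#>  a;b;c;d;e     5          33.6
```

The same interface scales to data frames read from disk
(`read_expression_tsv()`), GMT gene-set collections (`read_gmt()`), and a
shell pipeline (`inst/cli/etbicluster.R` with subcommands `mine`, `select`,
`enrich`, `biomarker`, `randomize`, `simulate`).

## Documentation

The methods vignette (`vignettes/error-tolerant-biclustering.Rmd`) describes
the model and its assumptions, the parameters and their defaults, the
synthetic-data generator and what it does and does not emulate, the
numerical conventions, and known limitations.
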