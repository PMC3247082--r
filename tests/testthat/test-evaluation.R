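# Enrichment statistics, biomarker filtering and randomization tests.

toy_universe <- paste0("g", 1:20)

test_that("hypergeometric p-values match direct combinatorial evaluation", {
  u <- toy_universe
  # drawing all 5 annotated genes: p = 1 / C(20, 5)
  expect_equal(hypergeom_pvalue(u[1:5], u[1:5], u), 1 / choose(20, 5))
  # term equal to the universe: always p = 1
  expect_equal(hypergeom_pvalue(u[1:7], u, u), 1)
  # zero overlap: upper tail includes X >= 0, p = 1
  expect_equal(hypergeom_pvalue(u[1:4], u[11:15], u), 1)
  # empty bicluster after universe restriction: p = 1 by convention
  expect_equal(hypergeom_pvalue(c("absent1", "absent2"), u[1:5], u), 1)
  # random configurations against the summation oracle
  set.seed(3)
  for (rep in 1:20) {
    K <- sample(2:10, 1); n <- sample(2:10, 1)
    term <- sample(u, K); bic <- sample(u, n)
    k <- length(intersect(term, bic))
    expect_equal(hypergeom_pvalue(bic, term, u),
                 oracle_hyper_upper(k, K, 20, n))
  }
  expect_error(hypergeom_pvalue(u[1:3], c(u[1], "notinuniverse"), u),
               "subset of the universe")
})

test_that("the p-value is monotone in the overlap and the tail sums to one", {
  u <- toy_universe
  term <- u[1:8]
  p_prev <- Inf
  for (k in 0:5) {
    bic <- c(term[seq_len(k)], u[9:(13 - k)])  # 5 genes, k annotated
    p <- hypergeom_pvalue(bic, term, u)
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
  # point probabilities over the full support sum to 1
  probs <- sapply(0:5, function(k)
    choose(8, k) * choose(12, 5 - k) / choose(20, 5))
  expect_equal(sum(probs), 1)
  expect_equal(oracle_hyper_upper(0, 8, 20, 5), 1)
})

test_that("enrichment summaries count fractions exactly", {
  u <- toy_universe
  coll <- gene_set_collection(list(A = u[1:5], B = u[6:10], C = u[11:20]))
  # one bicluster exactly matching set A, one unrelated
  rec <- enrich_biclusters(list(u[1:5], c(u[4:5], u[12:14])), coll)
  expect_equal(attr(rec, "n_biclusters"), 2L)
  expect_equal(attr(rec, "n_terms"), 3L)
  pA <- 1 / choose(20, 5)
  s <- enrichment_summary(rec, thresholds = c(pA * 1.01, pA * 0.5))
  expect_equal(s$fraction_biclusters_enriched, c(0.5, 0))
  expect_equal(s$fraction_terms_enriching, c(1 / 3, 0))

  # synthetic known p-values: fractions are direct counts
  coll2 <- gene_set_collection(list(T1 = u[1:4]))
  sets <- lapply(1:10, function(i) sample(u, 4))
  rec2 <- enrich_biclusters(sets, coll2)
  minp <- tapply(rec2$p_value, rec2$bicluster, min)
  for (tau in c(1e-4, 0.05, 0.5, 1)) {
    s2 <- enrichment_summary(rec2, thresholds = tau)
    expect_equal(s2$fraction_biclusters_enriched, mean(minp <= tau))
  }
})

test_that("single bicluster, single term thresholds behave as printed", {
  u <- toy_universe
  coll <- gene_set_collection(list(T = u[1:5]), universe = u)
  # choose a bicluster whose p is about 5e-4: 3 of 4 genes annotated
  p <- hypergeom_pvalue(c(u[1:3], u[10]), u[1:5], u)
  rec <- enrich_biclusters(list(c(u[1:3], u[10])), coll)
  expect_equal(rec$p_value, p)
  above <- enrichment_summary(rec, thresholds = p * 2)
  below <- enrichment_summary(rec, thresholds = p / 2)
  expect_equal(above$fraction_biclusters_enriched, 1)
  expect_equal(above$fraction_terms_enriching, 1)
  expect_equal(below$fraction_biclusters_enriched, 0)
  expect_equal(below$fraction_terms_enriching, 0)
})

test_that("discriminative filtering applies the odds-ratio and p-value rules", {
  # a=30 cases supporting, b=128, c=20 controls supporting, d=413
  s <- make_labeled_fit(158, 433, 30, 20)
  all_stats <- discriminative_filter(s$fit, s$labels, keep_all = TRUE)
  expect_equal(all_stats$odds_ratio, (30 * 413) / (128 * 20), tolerance = 1e-12)
  expect_equal(round(all_stats$odds_ratio, 2), 4.84)
  expect_equal(all_stats$p_value,
               stats::fisher.test(matrix(c(30, 128, 20, 413), 2,
                                         byrow = TRUE))$p.value)
  kept <- discriminative_filter(s$fit, s$labels)
  expect_equal(nrow(kept), 1)

  # identical support proportions: OR = 1, never retained
  s2 <- make_labeled_fit(100, 200, 10, 20)
  st2 <- discriminative_filter(s2$fit, s2$labels, keep_all = TRUE)
  expect_equal(st2$odds_ratio, 1)
  expect_false(st2$selected)

  # zero cell: the +0.5 correction keeps the odds ratio finite
  s3 <- make_labeled_fit(50, 50, 12, 0)
  st3 <- discriminative_filter(s3$fit, s3$labels, keep_all = TRUE)
  expect_true(is.finite(st3$odds_ratio))
  expect_equal(st3$odds_ratio, (12.5 * 50.5) / (38.5 * 0.5))

  # missing labels are an error
  expect_error(discriminative_filter(s$fit, s$labels[-1]), "missing")
})

test_that("size-matched randomization yields exact exceedance arithmetic", {
  u <- toy_universe
  coll <- gene_set_collection(list(A = u[1:5], B = u[8:12]), universe = u)
  res <- randomize_gene_sets(list(u[1:5], u[c(1, 6, 11, 16)]), coll,
                             reps = 200, seed = 99)
  pb <- res$per_bicluster
  # identity: empirical p = exceedances / reps
  expect_equal(pb$empirical_p, pb$exceedances / res$reps)
  # the perfect-match bicluster has the maximal possible score: nothing beats
  # it strictly, so it reports "< 1/reps"
  expect_equal(pb$exceedances[1], 0L)
  expect_match(pb$reported[1], "^< ")
  # reproducibility is bit-for-bit under the same seed
  res2 <- randomize_gene_sets(list(u[1:5], u[c(1, 6, 11, 16)]), coll,
                              reps = 200, seed = 99)
  expect_identical(res$per_bicluster, res2$per_bicluster)
  expect_identical(res$summary, res2$summary)
  # a different seed changes the random draws
  res3 <- randomize_gene_sets(list(u[c(1, 6, 11, 16)]), coll,
                              reps = 200, seed = 100)
  expect_true(is.data.frame(res3$summary))
  # oversized bicluster rejected
  expect_error(randomize_gene_sets(list(rep(u, 2), paste0("x", 1:25)), coll,
                                   reps = 2, seed = 1),
               "universe")
})

test_that("the replicate-level summary counts exceeding random collections", {
  u <- toy_universe
  coll <- gene_set_collection(list(A = u[1:5]), universe = u)
  res <- randomize_gene_sets(list(u[1:5], u[1:5]), coll, reps = 50, seed = 7,
                             thresholds = c(1, 1e-4))
  # at threshold 1 every set in every replicate is "enriched": no replicate
  # can strictly exceed the actual fraction of 1
  expect_equal(res$summary$actual_fraction[1], 1)
  expect_equal(res$summary$n_random_exceeding[1], 0L)
  # at 1e-4 only the exact match (p = 1/C(20,5)) qualifies; the actual
  # fraction of 1 cannot be strictly exceeded
  expect_equal(res$summary$actual_fraction[2], 1)
  expect_equal(res$summary$n_random_exceeding[2], 0L)
})

test_that("per-gene shuffling preserves row multisets and breaks correlation", {
  x <- random_matrix(10, 40, seed = 21)
  sh <- shuffle_conditions(x, seed = 5)
  expect_equal(dim(sh), dim(x))
  for (i in seq_len(nrow(x)))
    expect_equal(sort(sh[i, ]), sort(unname(x[i, ])), ignore_attr = TRUE)
  # two perfectly correlated rows decorrelate on average across seeds
  y <- matrix(rep(seq(1, 4, length.out = 60), 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:60)))
  cors <- vapply(1:30, function(s) {
    z <- shuffle_conditions(y, seed = s)
    cor(z[1, ], z[2, ])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.15)
  # reproducible given the seed
  expect_identical(shuffle_conditions(x, seed = 5), sh)
})
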