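# Mean squared residue on retained cells and greedy top-bicluster selection.

# minimal hand-built fit wrapping explicit biclusters over a matrix
stub_fit <- function(x, bics) {
  structure(list(biclusters = bics, alpha = 1, epsilon = 0.25, rs = 1,
                 gene_ids = rownames(x), condition_ids = colnames(x),
                 n_genes = nrow(x), n_conditions = ncol(x),
                 level_counts = NULL, merged = FALSE, call = NULL),
            class = "et_bicluster")
}

stub_bic <- function(genes, trans, discarded = NULL, rs = 1) {
  if (is.null(discarded)) discarded <- rep(list(integer(0)), length(trans))
  list(genes = genes, transactions = trans,
       contributions = rep(1, length(trans)), discarded = discarded,
       n_errors = vapply(discarded, length, integer(1)),
       range_support = rs, level = length(genes))
}

test_that("mean squared residue is zero for constant and additive blocks", {
  x <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  x[1:2, 1:2] <- 3 # constant block
  b <- stub_bic(1:2, 1:2)
  expect_equal(mean_squared_residue(b, x), 0)

  x[1:2, 1:2] <- matrix(c(1, 3, 2, 4), 2) # rows {1,2} and {3,4}: additive
  expect_equal(mean_squared_residue(b, x), 0)
  expect_equal(mean_squared_residue(b, x), oracle_msr(x[1:2, 1:2]))
})

test_that("mean squared residue matches direct evaluation and skips error cells", {
  x <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  x[1:2, 1:2] <- matrix(c(1, 2, 2, 1), 2) # anti-diagonal block
  b <- stub_bic(1:2, 1:2)
  expect_equal(mean_squared_residue(b, x), oracle_msr(x[1:2, 1:2]))
  expect_equal(mean_squared_residue(b, x), 0.25)

  # a wild value marked as discarded does not perturb the residue
  x2 <- x
  x2[1, 1] <- 1000
  b2 <- stub_bic(1:2, 1:2, discarded = list(1L, integer(0)))
  x_clean <- x
  expect_lt(mean_squared_residue(b2, x2),
            mean_squared_residue(stub_bic(1:2, 1:2), x2))
  # single-cell bicluster scores zero
  expect_equal(mean_squared_residue(stub_bic(1L, 1L), x), 0)
})

test_that("random blocks agree with the direct residue formula", {
  set.seed(5)
  for (rep in 1:10) {
    nr <- sample(2:4, 1); nc <- sample(2:5, 1)
    x <- matrix(rnorm(nr * nc), nr,
                dimnames = list(paste0("g", 1:nr), paste0("s", 1:nc)))
    b <- stub_bic(seq_len(nr), seq_len(nc))
    expect_equal(mean_squared_residue(b, x), oracle_msr(x))
  }
})

test_that("selection ranks by gene count, breaks ties by residue, enforces overlap", {
  x <- matrix(rnorm(100), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:10)))
  # two equal-size biclusters sharing 3 of 4 genes (overlap 0.75): the one
  # with the lower residue must win and exclude the other
  x[1:4, 1:3] <- 5            # constant: residue 0
  x[5, 1:3] <- c(4, 6, 5.5)   # noisy row for the competitor
  b_clean <- stub_bic(1:4, 1:3)
  b_noisy <- stub_bic(c(1:3, 5), 1:3)
  sel <- select_top(stub_fit(x, list(b_noisy, b_clean)), x)
  expect_length(sel$biclusters, 1)
  expect_equal(sel$biclusters[[1]]$genes, 1:4)

  # pairwise-disjoint biclusters: all selected, size-sorted
  bics <- list(stub_bic(1:2, 1:3), stub_bic(5:8, 1:3), stub_bic(3:4, 4:6))
  sel <- select_top(stub_fit(x, bics), x)
  expect_length(sel$biclusters, 3)
  expect_equal(vapply(sel$biclusters, function(b) b$level, integer(1)),
               c(4L, 2L, 2L))

  # a candidate sharing 3 genes with a selected 4-gene bicluster is rejected
  bics <- list(stub_bic(1:4, 1:3), stub_bic(c(1:3, 5), 4:6))
  sel <- select_top(stub_fit(x, bics), x)
  expect_length(sel$biclusters, 1)

  # max_selected caps the output
  bics <- lapply(seq(1, 9, by = 2), function(g) stub_bic(c(g, g + 1), 1:3))
  sel <- select_top(stub_fit(x, bics), x, max_selected = 2)
  expect_length(sel$biclusters, 2)
})

test_that("selection output respects its invariants on a real mining run", {
  fit <- et_bicluster(worked_example_matrix(), alpha = 0.5, rs = 5,
                      epsilon = 0.25)
  sel <- select_top(fit, worked_example_matrix(), max_selected = 10,
                    max_overlap = 0.25)
  sizes <- vapply(sel$biclusters, function(b) b$level, integer(1))
  expect_true(all(diff(sizes) <= 0))       # non-increasing gene counts
  expect_true(all(sizes >= 2))             # singletons excluded by default
  gsets <- lapply(sel$biclusters, `[[`, "genes")
  if (length(gsets) > 1) {
    for (i in 1:(length(gsets) - 1)) {
      for (j in (i + 1):length(gsets)) {
        ov <- length(intersect(gsets[[i]], gsets[[j]])) /
          min(length(gsets[[i]]), length(gsets[[j]]))
        expect_lte(ov, 0.25 + 1e-9)
      }
    }
  }
  # determinism
  sel2 <- select_top(fit, worked_example_matrix(), max_selected = 10,
                     max_overlap = 0.25)
  expect_identical(fit_keys(sel), fit_keys(sel2))
})
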