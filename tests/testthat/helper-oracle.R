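# Independent oracles, written against the definitions only (no calls into
# the package's engine), used to cross-check the miner and the statistics.

# coherence of a value set under the sign + relative-range criteria
oracle_coherent <- function(v, alpha) {
  if (length(v) == 0L) return(FALSE)
  if (!(all(v > 0) || all(v < 0))) return(FALSE)
  a <- abs(v)
  (max(a) - min(a)) / min(a) <= alpha + 1e-9
}

# minimal number of discarded values (over ALL subsets, not just extreme
# splits) such that the retained values are coherent; length(v) if none
oracle_count_errors <- function(v, alpha) {
  n <- length(v)
  for (e in 0:(n - 1)) {
    keep_size <- n - e
    combs <- utils::combn(n, keep_size)
    for (j in seq_len(ncol(combs))) {
      if (oracle_coherent(v[combs[, j]], alpha)) return(e)
    }
  }
  n
}

# brute-force enumeration of every valid bicluster by direct application of
# the two defining conditions; exact for epsilon = 0 (every transaction is
# examined for every gene subset, no level-wise restriction)
oracle_biclusters <- function(x, alpha, rs, epsilon = 0) {
  n_genes <- nrow(x)
  out <- list()
  for (size in 1:n_genes) {
    budget <- floor(size * epsilon + 1e-9)
    combs <- utils::combn(n_genes, size)
    for (j in seq_len(ncol(combs))) {
      genes <- combs[, j]
      trans <- integer(0)
      contribs <- numeric(0)
      for (t in seq_len(ncol(x))) {
        v <- x[genes, t]
        # best contiguous retained window with at most `budget` discards
        best <- -Inf
        n <- length(v)
        sv <- sort(v)
        for (e in 0:min(budget, n - 1)) {
          for (i in 0:e) {
            ret <- sv[(i + 1):(n - (e - i))]
            if (oracle_coherent(ret, alpha)) best <- max(best, min(abs(ret)))
          }
          if (is.finite(best)) break # smallest e wins
        }
        if (is.finite(best)) {
          trans <- c(trans, t)
          contribs <- c(contribs, best)
        }
      }
      total <- if (size == 1) sum(abs(x[genes, ])) else sum(contribs)
      if (total >= rs - 1e-9) {
        out[[length(out) + 1L]] <- list(
          genes = sort(genes), transactions = trans,
          range_support = total)
      }
    }
  }
  out
}

# upper-tail hypergeometric probability by direct combinatorial summation
oracle_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  total <- 0
  for (i in k:min(K, n)) {
    total <- total + choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }
  total
}

# Cheng-Church mean squared residue on a fully retained block
oracle_msr <- function(a) {
  ri <- rowMeans(a); cj <- colMeans(a); mu <- mean(a)
  s <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      s <- s + (a[i, j] - ri[i] - cj[j] + mu)^2
  unname(s) / (nrow(a) * ncol(a))
}

# keyed comparison helpers
bic_key <- function(b) paste(b$genes, collapse = " ")

fit_keys <- function(fit) {
  vapply(fit$biclusters, bic_key, character(1))
}

find_bic <- function(fit, gene_ids) {
  idx <- sort(match(gene_ids, fit$gene_ids))
  for (b in fit$biclusters)
    if (identical(b$genes, idx)) return(b)
  NULL
}

# a one-bicluster fit over a trivial matrix with case/control labels, for
# exercising the 2x2 biomarker statistics directly
make_labeled_fit <- function(n_case, n_ctrl, case_supp, ctrl_supp) {
  n <- n_case + n_ctrl
  x <- matrix(1, 2, n, dimnames = list(c("gA", "gB"), paste0("p", 1:n)))
  labels <- stats::setNames(rep(c("case", "control"), c(n_case, n_ctrl)),
                            colnames(x))
  trans <- c(seq_len(case_supp), n_case + seq_len(ctrl_supp))
  b <- list(genes = 1:2, transactions = trans,
            contributions = rep(1, length(trans)),
            discarded = rep(list(integer(0)), length(trans)),
            n_errors = integer(length(trans)), range_support = 10, level = 2L)
  fit <- structure(list(biclusters = list(b), alpha = 0.5, epsilon = 0.25,
                        rs = 1, gene_ids = rownames(x),
                        condition_ids = colnames(x), n_genes = 2,
                        n_conditions = n, level_counts = NULL,
                        merged = FALSE, call = NULL),
                   class = "et_bicluster")
  list(fit = fit, labels = labels)
}

random_matrix <- function(n_genes, n_cond, seed, range = c(-3, 3)) {
  set.seed(seed)
  matrix(round(runif(n_genes * n_cond, range[1], range[2]), 2),
         nrow = n_genes,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_cond))))
}
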