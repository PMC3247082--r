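# Level-wise bottom-up mining of error-tolerant constant-row biclusters.
#
# Genes play the role of items and experimental conditions the role of
# transactions. Level k holds biclusters of k genes; (k+1)-level candidates are
# generated Apriori-style by joining two k-level biclusters that share a
# (k-1)-gene prefix under the matrix row order, and a candidate is kept only if
# all of its k-gene subsets are valid. The per-transaction error budget at
# level k is floor(k * epsilon); when the budget grows by one the step is an
# error-extension step and the range criterion is checked on the union of the
# subsets' supporting transactions, otherwise on their intersection.

.key <- function(genes) paste(genes, collapse = " ")

# internal bicluster record: integer gene/transaction indices into the matrix
.make_bic <- function(genes, transactions, contributions, discarded, n_errors,
                      range_support, level) {
  list(genes = genes, transactions = transactions,
       contributions = contributions, discarded = discarded,
       n_errors = n_errors, range_support = range_support, level = level)
}

#' Mine error-tolerant biclusters from a real-valued expression matrix
#'
#' Discovers constant-row biclusters bottom-up, tolerating up to
#' `floor(k * epsilon)` error values per supporting transaction of a `k`-gene
#' bicluster. With `epsilon = 0` the miner is the exact range-support pattern
#' miner (RAP mode): every value of every gene must be coherent in every
#' supporting transaction. With `epsilon > 0` biclusters fragmented by noise
#' are stitched back together; the search is then a heuristic (the range
#' criterion is not anti-monotone for error-tolerant patterns) but its output
#' always subsumes the exact-mode output at equal parameters.
#'
#' A transaction supports a gene set when, after discarding at most the
#' budgeted number of extreme values, the retained expression values share a
#' strict sign and have relative range `(max|v| - min|v|) / min|v| <= alpha`
#' (see [check_transaction()]). The contribution of a supporting transaction
#' is its minimum absolute retained value, and the RangeSupport of a bicluster
#' is the sum of contributions over its supporting transactions; a bicluster
#' is valid when its RangeSupport reaches `rs`. At level 1 every gene whose
#' summed absolute expression reaches `rs` is a valid singleton.
#'
#' All valid biclusters at every level are returned (redundancy is handled
#' later by [select_top()]), ordered by level and then lexicographically by
#' gene set under the matrix row order.
#'
#' @param x numeric expression matrix, genes as rows (rownames = identifiers),
#'   conditions as columns (colnames = labels); no missing values.
#' @param alpha non-negative relative-range threshold defining coherence
#'   within a transaction.
#' @param rs positive RangeSupport threshold.
#' @param epsilon error tolerance in `[0, 1)`: the maximum permitted fraction
#'   of discarded (error) values per supporting transaction. Default 0, the
#'   exact mode.
#' @param max_level optional cap on the bicluster level (number of genes);
#'   `Inf` mines until no candidates survive.
#' @param max_candidates optional cap on the number of candidates examined per
#'   level; when exceeded the level is truncated with a warning. Off
#'   (`Inf`) by default.
#' @param verbose logical; print per-level candidate and survivor counts.
#' @return An object of class `"et_bicluster"`: a list with the mined
#'   `biclusters`, the parameters, per-level counts and the matrix dimensions.
#'   Use [as.data.frame()][as.data.frame.et_bicluster()], `print()`,
#'   `summary()` and `plot()` on it, and [select_top()] to pick a
#'   non-redundant top set.
#' @examples
#' x <- worked_example_matrix()
#' fit <- et_bicluster(x, alpha = 0.5, rs = 5, epsilon = 0.25)
#' fit
#' subset(as.data.frame(fit), level == 5)
#' @export
et_bicluster <- function(x, alpha, rs, epsilon = 0, max_level = Inf,
                         max_candidates = Inf, verbose = FALSE) {
  validate_expression_matrix(x)
  .validate_params(alpha, epsilon, rs)
  n_genes <- nrow(x)
  n_cond <- ncol(x)
  rs_tol <- rs - .range_tol

  out <- list()
  level_counts <- data.frame(level = integer(0), candidates = integer(0),
                             valid = integer(0))

  # level 1: singletons by summed absolute expression
  current <- list()
  for (g in seq_len(n_genes)) {
    a <- abs(x[g, ])
    total <- sum(a)
    if (total >= rs_tol) {
      supp <- unname(which(a > 0))
      bic <- .make_bic(g, supp, unname(a[supp]),
                       rep(list(integer(0)), length(supp)),
                       integer(length(supp)), total, 1L)
      current[[.key(g)]] <- bic
    }
  }
  level_counts <- rbind(level_counts,
                        data.frame(level = 1L, candidates = n_genes,
                                   valid = length(current)))
  if (verbose)
    message(sprintf("level 1: %d candidates, %d valid", n_genes,
                    length(current)))
  out <- c(out, unname(current))

  k <- 1L
  while (length(current) >= 2L && k + 1L <= max_level) {
    k1 <- k + 1L
    budget <- error_budget(k1, epsilon)
    error_step <- budget != error_budget(k, epsilon)

    # prefix join under matrix row order
    keys <- names(current)
    gene_mat <- matrix(0L, nrow = length(keys), ncol = k)
    for (i in seq_along(keys)) gene_mat[i, ] <- current[[keys[i]]]$genes
    prefix <- if (k == 1L) rep("", length(keys)) else
      apply(gene_mat[, -k, drop = FALSE], 1L, paste, collapse = " ")
    candidates <- list()
    for (grp in split(seq_along(keys), prefix)) {
      if (length(grp) < 2L) next
      last <- gene_mat[grp, k]
      o <- grp[order(last)]
      for (ii in seq_len(length(o) - 1L)) {
        for (jj in (ii + 1L):length(o)) {
          candidates[[length(candidates) + 1L]] <-
            c(current[[o[ii]]]$genes, gene_mat[o[jj], k])
        }
      }
    }
    n_cand <- length(candidates)
    if (n_cand > max_candidates) {
      warning(sprintf(
        "level %d: %d candidates exceed max_candidates = %g; truncating",
        k1, n_cand, max_candidates))
      candidates <- candidates[seq_len(max_candidates)]
    }

    nxt <- list()
    for (genes in candidates) {
      # Apriori pruning: every k-subset must be a valid level-k bicluster
      subs <- vector("list", k1)
      ok <- TRUE
      for (d in seq_len(k1)) {
        sb <- current[[.key(genes[-d])]]
        if (is.null(sb)) { ok <- FALSE; break }
        subs[[d]] <- sb
      }
      if (!ok) next

      supp_sets <- lapply(subs, `[[`, "transactions")
      cand_trans <- if (error_step) {
        sort(unique(unlist(supp_sets)))
      } else {
        Reduce(intersect, supp_sets)
      }
      if (length(cand_trans) == 0L) next

      trans <- integer(0)
      contribs <- numeric(0)
      discarded <- list()
      n_err <- integer(0)
      for (t in cand_trans) {
        d <- check_transaction(x[genes, t], alpha, budget)
        if (d$supports) {
          trans <- c(trans, t)
          contribs <- c(contribs, d$contribution)
          discarded <- c(discarded, list(genes[d$discarded]))
          n_err <- c(n_err, length(d$discarded))
        }
      }
      total <- sum(contribs)
      if (length(trans) > 0L && total >= rs_tol) {
        nxt[[.key(genes)]] <- .make_bic(genes, trans, contribs, discarded,
                                        n_err, total, k1)
      }
    }

    level_counts <- rbind(level_counts,
                          data.frame(level = k1, candidates = n_cand,
                                     valid = length(nxt)))
    if (verbose)
      message(sprintf("level %d (%s step, budget %d): %d candidates, %d valid",
                      k1, if (error_step) "error" else "non-error", budget,
                      n_cand, length(nxt)))
    if (length(nxt) == 0L) break
    # lexicographic order of gene sets within the level
    ord <- do.call(order, as.data.frame(do.call(rbind,
                                                lapply(nxt, `[[`, "genes"))))
    nxt <- nxt[ord]
    out <- c(out, unname(nxt))
    current <- nxt
    k <- k1
  }

  structure(
    list(biclusters = out, alpha = alpha, epsilon = epsilon, rs = rs,
         gene_ids = rownames(x), condition_ids = colnames(x),
         n_genes = n_genes, n_conditions = n_cond,
         level_counts = level_counts, merged = FALSE,
         call = match.call()),
    class = "et_bicluster")
}

#' Merge an exact and an error-tolerant mining run
#'
#' Combines the biclusters of two runs on the same matrix (typically an exact
#' run, `epsilon = 0`, at a lower RangeSupport threshold and an error-tolerant
#' run at a higher one) into a single result. The union is keyed by gene set;
#' when both runs contain the same gene set, the variant with the larger
#' supporting-transaction set is kept (ties broken by larger RangeSupport).
#'
#' @param exact an `"et_bicluster"` fit, the exact (RAP-mode) run.
#' @param tolerant an `"et_bicluster"` fit, the error-tolerant run.
#' @return an `"et_bicluster"` object holding the merged bicluster list; the
#'   parameters of both runs are retained in `$runs`.
#' @export
merge_runs <- function(exact, tolerant) {
  stopifnot(inherits(exact, "et_bicluster"), inherits(tolerant, "et_bicluster"))
  if (!identical(exact$gene_ids, tolerant$gene_ids) ||
      !identical(exact$condition_ids, tolerant$condition_ids))
    stop("the two runs must come from the same expression matrix")

  pool <- list()
  for (b in exact$biclusters) pool[[.key(b$genes)]] <- b
  for (b in tolerant$biclusters) {
    key <- .key(b$genes)
    old <- pool[[key]]
    if (is.null(old) ||
        length(b$transactions) > length(old$transactions) ||
        (length(b$transactions) == length(old$transactions) &&
         b$range_support > old$range_support)) {
      pool[[key]] <- b
    }
  }
  lev <- vapply(pool, `[[`, integer(1), "level")
  ord <- order(lev, names(pool))
  merged <- tolerant
  merged$biclusters <- unname(pool[ord])
  merged$merged <- TRUE
  merged$runs <- list(
    exact = list(alpha = exact$alpha, epsilon = exact$epsilon, rs = exact$rs),
    tolerant = list(alpha = tolerant$alpha, epsilon = tolerant$epsilon,
                    rs = tolerant$rs))
  merged$level_counts <- NULL
  merged$call <- match.call()
  merged
}

#' Verify a mined bicluster against the defining conditions
#'
#' Re-checks, from scratch and independently of the miner's bookkeeping, that
#' a bicluster satisfies the two defining conditions: RangeSupport at least
#' `rs`, and at most `floor(epsilon * |G|)` error values (counted by
#' [count_errors()]) in every supporting transaction.
#'
#' @param fit an `"et_bicluster"` object.
#' @param i index of the bicluster within `fit$biclusters`.
#' @param x the expression matrix the fit was mined from.
#' @return logical.
#' @export
verify_bicluster <- function(fit, i, x) {
  b <- fit$biclusters[[i]]
  budget <- error_budget(b$level, fit$epsilon)
  rs_sum <- 0
  for (t in b$transactions) {
    vals <- x[b$genes, t]
    if (count_errors(vals, fit$alpha) > budget) return(FALSE)
    rs_sum <- rs_sum + check_transaction(vals, fit$alpha, budget)$contribution
  }
  rs_sum >= fit$rs - .range_tol
}
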