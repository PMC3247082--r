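# Range-coherence engine: decides whether one transaction (condition) supports
# a gene set under an error budget, and counts errors in a set of values.
#
# A set of retained values is coherent when (a) all values share a strict sign
# (zeros never pass) and (b) the relative range of their absolute values,
# (max|v| - min|v|) / min|v|, is at most alpha. Errors are confined to the
# extremes of the sorted value list: discarding i smallest and j largest values
# (i + j = e) enumerates every permissible-error case for budget e.

# absolute slack for threshold comparisons so decimal fixtures compare stably
.range_tol <- 1e-9

# coherence of a retained (already sorted or unsorted) value vector
.coherent <- function(v, alpha) {
  if (all(v > 0) || all(v < 0)) {
    a <- abs(v)
    mn <- min(a)
    (max(a) - mn) / mn <= alpha + .range_tol
  } else {
    FALSE
  }
}

#' Decide whether a transaction supports a gene set under an error budget
#'
#' Given the expression values of a bicluster's genes in a single transaction
#' (experimental condition), determines whether the transaction is a supporting
#' transaction when up to `max_errors` values may be discarded as errors.
#' Candidate error values are restricted to the extremes of the sorted value
#' list: for every budget `e = 0, 1, ..., max_errors` and every split
#' `e = i + j`, the configuration discarding the `i` smallest and `j` largest
#' values is examined. A configuration passes when the retained values all
#' share a strict sign (zeros never pass) and their relative range of absolute
#' values, `(max|v| - min|v|) / min|v|`, is at most `alpha`.
#'
#' The decision returned is the first passing configuration at the smallest
#' number of discards; among passing splits at that budget, the one maximizing
#' the contribution (the minimum absolute retained value) is kept, and
#' remaining ties prefer fewer discards from the maximum end.
#'
#' @param values numeric vector, the expression values of the bicluster's genes
#'   in one transaction; must be non-empty and finite.
#' @param alpha non-negative relative-range threshold.
#' @param max_errors non-negative integer, the per-transaction error budget;
#'   must be strictly less than `length(values)` (a supporting transaction
#'   retains at least one value).
#' @return A list of class `"support_decision"` with elements
#'   `supports` (logical), `retained` (integer positions into `values` of the
#'   retained, non-error values), `discarded` (integer positions of the error
#'   values), `contribution` (minimum absolute retained value; 0 when
#'   `supports` is `FALSE`) and `n_errors` (number of discards used).
#' @examples
#' check_transaction(c(2, 2.1), alpha = 0.5, max_errors = 0)
#' check_transaction(c(2, 2.05, 2.1, 8), alpha = 0.5, max_errors = 1)
#' @seealso [count_errors()], [et_bicluster()]
#' @export
check_transaction <- function(values, alpha, max_errors = 0L) {
  n <- length(values)
  if (n == 0L) stop("'values' must be non-empty")
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("'values' must be finite numeric")
  if (alpha < 0) stop("'alpha' must be non-negative")
  max_errors <- as.integer(max_errors)
  if (max_errors < 0L) stop("'max_errors' must be non-negative")
  if (max_errors >= n)
    stop("'max_errors' must be smaller than length(values): ",
         "a transaction must retain at least one value")

  ord <- order(values)
  sv <- values[ord]

  for (e in 0:max_errors) {
    best <- NULL
    for (j in 0:e) { # j discards from the maximum end, ascending
      i <- e - j
      ret <- sv[(i + 1L):(n - j)]
      if (.coherent(ret, alpha)) {
        contrib <- min(abs(ret))
        if (is.null(best) || contrib > best$contribution) {
          keep <- ord[(i + 1L):(n - j)]
          drop <- if (e > 0L) {
            ord[c(seq_len(i), if (j > 0L) (n - j + 1L):n)]
          } else integer(0)
          best <- list(contribution = contrib, retained = sort(keep),
                       discarded = sort(drop))
        }
      }
    }
    if (!is.null(best)) {
      return(structure(
        list(supports = TRUE, retained = best$retained,
             discarded = best$discarded, contribution = best$contribution,
             n_errors = e),
        class = "support_decision"))
    }
  }
  structure(
    list(supports = FALSE, retained = integer(0),
         discarded = seq_len(n), contribution = 0, n_errors = NA_integer_),
    class = "support_decision")
}

#' @export
print.support_decision <- function(x, ...) {
  if (x$supports) {
    cat(sprintf(
      "supporting transaction: contribution %g, %d error value(s) discarded\n",
      x$contribution, length(x$discarded)))
  } else {
    cat("non-supporting transaction\n")
  }
  invisible(x)
}

#' Count the errors in a set of real values under the range criterion
#'
#' Returns the minimum number of extreme discards (as enumerated by
#' [check_transaction()]) needed for the retained values to pass the sign and
#' relative-range checks. If no retained subset of size at least one passes
#' (an all-zero input), `length(values)` is returned.
#'
#' @inheritParams check_transaction
#' @return non-negative integer count of error values.
#' @examples
#' count_errors(c(2, 2.1, 8), alpha = 0.5) # the value 8 is a single error
#' count_errors(c(5, 5, 5), alpha = 0)     # exact constant row, no errors
#' @export
count_errors <- function(values, alpha) {
  n <- length(values)
  if (n == 0L) stop("'values' must be non-empty")
  for (e in 0:(n - 1L)) {
    d <- check_transaction(values, alpha, e)
    if (d$supports) return(e)
  }
  n
}

#' Per-level error budget
#'
#' Number of permissible error values in a supporting transaction of a
#' `k`-gene bicluster at error tolerance `epsilon`: `floor(k * epsilon)`.
#'
#' @param k integer number of genes (bicluster level).
#' @param epsilon error tolerance in `[0, 1)`.
#' @return integer budget.
#' @examples
#' error_budget(4, 0.25)  # 1
#' error_budget(12, 0.25) # 3
#' @export
error_budget <- function(k, epsilon) {
  as.integer(floor(k * epsilon + .range_tol))
}
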