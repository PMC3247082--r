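# Synthetic data: matrices with planted, error-corrupted constant-row
# biclusters, and the 5-gene x 8-condition worked-example matrix.

#' The 5 x 8 worked-example matrix
#'
#' A small real-valued matrix with genes `a`-`e` and conditions `t1`-`t8`
#' constructed so that mining with `alpha = 0.5`, `rs = 5`, `epsilon = 0.25`
#' walks through every stage of the algorithm: pair `ab` supports
#' `{t1,t2,t3,t4,t7,t8}` with contributions 2, 2.1, 4, 6.5, 3, 2
#' (RangeSupport 19.6); triple `abc` supports `{t2,t4,t8}` with RangeSupport
#' 10.6; the level-4 error-extension step admits one discarded value per
#' transaction, giving `abcd` and `abce` support `{t1,t2,t3,t4,t5,t6,t8}`
#' and RangeSupport 33.6 (the error values are 8 at `t1`, 9 at `t3`, 20 at
#' `t5`); and the quintuple `abcde` is valid with the same support and
#' RangeSupport. In exact mode (`epsilon = 0`) `abcde` is not discoverable:
#' gene `d` carries an outlying value in each of `t2`, `t4`, `t8`, so no
#' single transaction is coherent across all five genes without an error
#' discard.
#'
#' Only a handful of cells are pinned down by those constraints; the
#' remaining cells are fixture choices frozen here, and the constraints
#' themselves are asserted in the test suite.
#'
#' @return a 5 x 8 numeric matrix with dimnames.
#' @examples
#' fit <- et_bicluster(worked_example_matrix(), alpha = 0.5, rs = 5,
#'                     epsilon = 0.25)
#' as.data.frame(fit)
#' @export
worked_example_matrix <- function() {
  m <- matrix(c(
    #  t1    t2    t3    t4    t5    t6    t7    t8
       2,    2.2,  4,    6.5,  8,    5,    3,    2.1,  # a
       2.1,  2.1,  4.5,  7,    20,   12,   3.2,  2,    # b
       8,    2.3,  9,    6.8,  8.5,  9,    30,   2.2,  # c
       2.05, 7,    4.2,  15,   8.2,  9.5,  0.1,  6,    # d
       2.1,  2.15, 4.4,  6.9,  8.4,  9.2,  0.2,  2.1   # e
  ), nrow = 5, byrow = TRUE,
  dimnames = list(c("a", "b", "c", "d", "e"), paste0("t", 1:8)))
  m
}

#' Generate an expression matrix with planted constant-row biclusters
#'
#' Background cells are drawn i.i.d. uniformly from `background[1]` to
#' `background[2]`. Each planted block assigns every one of its genes a base
#' magnitude; within each planted condition the cell value is
#' `base * sign * (1 + u)` with `u` uniform in `[-jitter, +jitter]`, so an
#' uncorrupted planted transaction is a near-constant row slice. A fraction
#' `error_rate` of each block's cells is then replaced by fresh background
#' draws, with at most `floor(epsilon * n_genes_in_block)` corrupted cells
#' per planted condition so that an error-tolerant miner at tolerance
#' `epsilon` can still support every planted condition.
#'
#' @param n_genes,n_conditions matrix dimensions.
#' @param planted list of planted-block descriptors; each a list with
#'   `genes` (count or explicit gene indices), `conditions` (count or
#'   indices), and optionally `base` (per-gene magnitudes; default drawn
#'   uniformly from `base_range`), `sign` (+1, -1, or a vector per planted
#'   condition; default +1), `jitter` (default 0.03) and `error_rate`
#'   (default 0.1).
#' @param epsilon error tolerance the corruption must respect per planted
#'   condition (default 0.25).
#' @param background length-2 numeric range of the background distribution
#'   (default `c(-2, 2)`, the range typical of log-ratio compendia).
#' @param base_range range the per-gene base magnitudes are drawn from when
#'   not given explicitly (default `c(2, 2.4)`, which keeps the
#'   within-transaction relative range below 0.3 at the default jitter).
#' @param seed integer seed; required.
#' @return a list of class `"planted_expression"`: `matrix` (with gene ids
#'   `g1..` and condition ids `s1..`), and `truth` — one record per planted
#'   block with its gene/condition ids and the corrupted cell coordinates.
#' @examples
#' sim <- simulate_expression(seed = 1)
#' dim(sim$matrix)
#' sim$truth[[1]]$genes
#' @export
simulate_expression <- function(n_genes = 20, n_conditions = 30,
                                planted = list(list(genes = 5,
                                                    conditions = 10)),
                                epsilon = 0.25, background = c(-2, 2),
                                base_range = c(2, 2.4), seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (n_genes < 1 || n_conditions < 1) stop("matrix dimensions must be positive")
  set.seed(seed)
  gene_ids <- paste0("g", seq_len(n_genes))
  cond_ids <- paste0("s", seq_len(n_conditions))
  x <- matrix(stats::runif(n_genes * n_conditions, background[1], background[2]),
              nrow = n_genes, dimnames = list(gene_ids, cond_ids))

  truth <- list()
  used_genes <- integer(0)
  for (bi in seq_along(planted)) {
    spec <- planted[[bi]]
    g_idx <- spec$genes
    if (length(g_idx) == 1L && is.numeric(g_idx) && g_idx == round(g_idx) &&
        is.null(spec$gene_indices)) {
      avail <- setdiff(seq_len(n_genes), used_genes)
      if (g_idx > length(avail))
        stop("planted block does not fit: not enough free genes")
      g_idx <- avail[seq_len(g_idx)]
    }
    c_idx <- spec$conditions
    if (length(c_idx) == 1L && is.numeric(c_idx) && c_idx == round(c_idx)) {
      if (c_idx > n_conditions)
        stop("planted block does not fit: too many conditions")
      c_idx <- seq_len(c_idx)
    }
    if (any(g_idx > n_genes) || any(c_idx > n_conditions))
      stop("planted block indices outside the matrix")
    used_genes <- c(used_genes, g_idx)
    ng <- length(g_idx)
    nc <- length(c_idx)

    jitter <- if (is.null(spec$jitter)) 0.03 else spec$jitter
    error_rate <- if (is.null(spec$error_rate)) 0.1 else spec$error_rate
    if (error_rate < 0 || error_rate >= 1) stop("'error_rate' must be in [0, 1)")
    base <- if (is.null(spec$base))
      stats::runif(ng, base_range[1], base_range[2]) else spec$base
    if (length(base) != ng) stop("'base' must give one magnitude per gene")
    sgn <- if (is.null(spec$sign)) rep(1, nc) else rep(spec$sign, length.out = nc)

    for (j in seq_len(nc)) {
      u <- stats::runif(ng, -jitter, jitter)
      x[g_idx, c_idx[j]] <- base * sgn[j] * (1 + u)
    }

    # corruption: error_rate of the block's cells, capped per condition (so a
    # tolerance-epsilon miner can still support every planted condition) and
    # per gene (scattered noise: no gene is disproportionately corrupted)
    n_err <- round(error_rate * ng * nc)
    cond_cap <- error_budget(ng, epsilon)
    gene_cap <- max(1L, as.integer(ceiling(error_rate * nc)))
    if (n_err > cond_cap * nc)
      stop(sprintf(
        "error_rate %.3g needs %d corrupted cells but the per-condition cap floor(epsilon * %d) = %d allows at most %d",
        error_rate, n_err, ng, cond_cap, cond_cap * nc))
    corrupted <- NULL
    if (n_err > 0) {
      cells <- expand.grid(g = g_idx, c = c_idx)
      pick <- NULL
      for (try in 1:50) { # greedy capped sampling; reshuffle if it jams
        perm <- cells[sample.int(nrow(cells)), ]
        used_c <- integer(0); used_g <- integer(0); take <- integer(0)
        for (r in seq_len(nrow(perm))) {
          gg <- perm$g[r]; cc <- perm$c[r]
          if (sum(used_c == cc) < cond_cap && sum(used_g == gg) < gene_cap) {
            used_c <- c(used_c, cc); used_g <- c(used_g, gg)
            take <- c(take, r)
            if (length(take) == n_err) break
          }
        }
        if (length(take) == n_err) { pick <- perm[take, ]; break }
      }
      if (is.null(pick))
        stop("could not place the corrupted cells under the per-gene/per-condition caps")
      for (e in seq_len(n_err)) {
        x[pick$g[e], pick$c[e]] <-
          stats::runif(1, background[1], background[2])
      }
      corrupted <- data.frame(gene = gene_ids[pick$g],
                              condition = cond_ids[pick$c],
                              stringsAsFactors = FALSE)
    }
    truth[[bi]] <- list(genes = gene_ids[g_idx],
                        conditions = cond_ids[c_idx],
                        base = base, jitter = jitter,
                        error_rate = error_rate,
                        corrupted = corrupted)
  }
  structure(list(matrix = x, truth = truth), class = "planted_expression")
}

#' @export
print.planted_expression <- function(x, ...) {
  cat(sprintf("synthetic expression matrix: %d genes x %d conditions, %d planted block(s)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$truth)))
  for (i in seq_along(x$truth)) {
    t <- x$truth[[i]]
    cat(sprintf("  block %d: %d genes x %d conditions, %d corrupted cell(s)\n",
                i, length(t$genes), length(t$conditions),
                if (is.null(t$corrupted)) 0L else nrow(t$corrupted)))
  }
  invisible(x)
}
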