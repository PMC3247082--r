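# Evaluation stack: hypergeometric gene-set enrichment, summary statistics,
# discriminative (case/control) biomarker filtering, and the two randomization
# significance tests.

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability `P(X >= k)` of drawing at least `k = |bicluster ∩ term|`
#' annotated genes when drawing `n = |bicluster ∩ universe|` genes without
#' replacement from a universe of `N` genes of which `K = |term|` are
#' annotated. Bicluster genes are intersected with the universe before
#' testing; an empty intersection gives `p = 1` by convention.
#'
#' @param bicluster_genes character vector of gene identifiers.
#' @param term_genes character vector, the gene set (must lie in `universe`).
#' @param universe character vector, the annotation universe.
#' @return p-value in `(0, 1]`.
#' @examples
#' u <- paste0("g", 1:20)
#' hypergeom_pvalue(u[1:5], u[1:5], u) # 1 / choose(20, 5)
#' @export
hypergeom_pvalue <- function(bicluster_genes, term_genes, universe) {
  universe <- unique(universe)
  term <- unique(term_genes)
  if (!all(term %in% universe))
    stop("term genes must be a subset of the universe")
  b <- intersect(unique(bicluster_genes), universe)
  n <- length(b)
  if (n == 0L) return(1)
  k <- length(intersect(b, term))
  # P(X >= k), upper tail including k
  stats::phyper(k - 1L, length(term), length(universe) - length(term), n,
                lower.tail = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format: one gene set per line, fields are the
#' set name, a description, then the member genes. Members are deduplicated
#' within a set. The annotation universe defaults to the union of all sets.
#'
#' @param path path to a GMT file.
#' @param universe optional character vector overriding the universe.
#' @return a list of class `"gene_set_collection"` with elements `sets`
#'   (named list of character vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: expected at least 3 tab-separated fields", i))
    name <- f[1]
    if (!is.null(sets[[name]]))
      stop(sprintf("duplicate gene-set name '%s' at line %d", name, i))
    sets[[name]] <- unique(f[-(1:2)])
  }
  gene_set_collection(sets, universe)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene identifiers).
#' @param universe optional character vector; defaults to the union of all
#'   sets. Every set must be contained in the universe.
#' @return an object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) == 0L) stop("empty gene-set collection")
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("gene sets must have unique non-empty names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  all_genes <- sort(unique(unlist(sets)))
  if (is.null(universe)) {
    universe <- all_genes
  } else {
    universe <- unique(as.character(universe))
    if (!all(all_genes %in% universe))
      stop("every gene set must be contained in the universe")
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene-set collection: %d sets, %d genes in universe\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

# gene sets of an et_bicluster fit (or pass-through for a list of character
# vectors), as character vectors of gene identifiers
.gene_sets_of <- function(obj) {
  if (inherits(obj, "et_bicluster")) {
    lapply(obj$biclusters, function(b) obj$gene_ids[b$genes])
  } else if (is.list(obj)) {
    lapply(obj, as.character)
  } else {
    stop("expected an 'et_bicluster' fit or a list of gene-identifier vectors")
  }
}

# membership matrix (sets x universe) and vectorised min-p scorer used by the
# enrichment and randomization routines
.collection_index <- function(collection) {
  u <- collection$universe
  m <- matrix(FALSE, nrow = length(collection$sets), ncol = length(u),
              dimnames = list(names(collection$sets), NULL))
  for (i in seq_along(collection$sets))
    m[i, match(collection$sets[[i]], u)] <- TRUE
  list(universe = u, membership = m,
       set_sizes = vapply(collection$sets, length, integer(1)))
}

# p-values of one gene set against every term in the indexed collection
.term_pvalues <- function(genes_idx, idx) {
  n <- length(genes_idx)
  if (n == 0L)
    return(rep(1, nrow(idx$membership)))
  k <- as.integer(idx$membership[, genes_idx, drop = FALSE] %*%
                    rep(1L, n))
  stats::phyper(k - 1L, idx$set_sizes,
                length(idx$universe) - idx$set_sizes, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of biclusters against a gene-set collection
#'
#' Computes the upper-tail hypergeometric p-value for every
#' (bicluster, gene set) pair. Bicluster genes are restricted to the
#' collection's universe first. No multiple-testing correction is applied;
#' the p-values are used comparatively.
#'
#' @param fit an `"et_bicluster"` object (typically after [select_top()]), or
#'   a list of character vectors of gene identifiers.
#' @param collection a `"gene_set_collection"`.
#' @return a `data.frame` with columns `bicluster` (index), `term`,
#'   `overlap_count` and `p_value`, plus attributes `n_biclusters`,
#'   `n_terms` and `scores` (per-bicluster enrichment score
#'   `-log10(min p)` over all terms).
#' @export
enrich_biclusters <- function(fit, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_sets <- .gene_sets_of(fit)
  idx <- .collection_index(collection)
  n_terms <- nrow(idx$membership)
  records <- vector("list", length(gene_sets))
  scores <- numeric(length(gene_sets))
  for (i in seq_along(gene_sets)) {
    gi <- match(intersect(gene_sets[[i]], idx$universe), idx$universe)
    p <- .term_pvalues(gi, idx)
    k <- if (length(gi)) as.integer(idx$membership[, gi, drop = FALSE] %*%
                                      rep(1L, length(gi))) else
      integer(n_terms)
    records[[i]] <- data.frame(bicluster = i,
                               term = rownames(idx$membership),
                               overlap_count = k, p_value = p,
                               stringsAsFactors = FALSE)
    scores[i] <- -log10(min(p))
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "n_biclusters") <- length(gene_sets)
  attr(out, "n_terms") <- n_terms
  attr(out, "scores") <- scores
  out
}

#' Fraction of biclusters enriched and of terms enriching, per threshold
#'
#' For each p-value threshold, computes the fraction of biclusters whose best
#' (minimum) p-value over all terms reaches the threshold, and the fraction of
#' terms whose best p-value over all biclusters reaches it. P-values are not
#' corrected for multiple testing.
#'
#' @param records output of [enrich_biclusters()].
#' @param thresholds numeric vector of p-value thresholds.
#' @return a `data.frame` with columns `threshold`,
#'   `fraction_biclusters_enriched` and `fraction_terms_enriching`.
#' @export
enrichment_summary <- function(records,
                               thresholds = c(5e-2, 1e-2, 5e-3, 1e-3, 1e-5)) {
  nb <- attr(records, "n_biclusters")
  nt <- attr(records, "n_terms")
  if (is.null(nb) || is.null(nt))
    stop("'records' must come from enrich_biclusters()")
  min_b <- tapply(records$p_value, records$bicluster, min)
  min_t <- tapply(records$p_value, records$term, min)
  data.frame(
    threshold = thresholds,
    fraction_biclusters_enriched =
      vapply(thresholds, function(th) sum(min_b <= th) / nb, numeric(1)),
    fraction_terms_enriching =
      vapply(thresholds, function(th) sum(min_t <= th) / nt, numeric(1)))
}

#' Read a two-column condition-label file
#'
#' Tab-separated, no header: condition label, then `case` or `control`.
#'
#' @param path file path.
#' @return named character vector of `"case"`/`"control"` keyed by condition.
#' @export
read_condition_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != 2L)
    stop("label file must have exactly two tab-separated columns")
  labels <- tolower(trimws(df[[2]]))
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'; offending row ",
         which(!labels %in% c("case", "control"))[1])
  if (anyDuplicated(df[[1]]))
    stop("duplicate condition label in label file")
  stats::setNames(labels, trimws(df[[1]]))
}

#' Filter biclusters that discriminate cases from controls
#'
#' For each bicluster, builds the 2x2 table of (case/control) x
#' (supporting / not supporting) conditions, computes the odds ratio
#' `OR = (a*d)/(b*c)` (with the Haldane-Anscombe +0.5 correction applied to
#' all four cells when any cell is zero) and a two-sided Fisher exact
#' p-value, and retains the biclusters with `p < p_threshold` and
#' `OR > or_high` (over-represented in cases) or `OR < or_low`
#' (over-represented in controls).
#'
#' @param fit an `"et_bicluster"` object (typically after [select_top()]).
#' @param labels named character vector mapping every condition label of the
#'   fit to `"case"` or `"control"` (see [read_condition_labels()]).
#' @param p_threshold significance cut-off (default 0.05).
#' @param or_low,or_high odds-ratio cut-offs (defaults 0.5 and 2.0).
#' @param keep_all logical; when `TRUE` return the statistics for every
#'   bicluster with a `selected` flag instead of filtering.
#' @return a `data.frame` with one row per retained bicluster: index, genes,
#'   2x2 cell counts, odds ratio and p-value.
#' @export
discriminative_filter <- function(fit, labels, p_threshold = 0.05,
                                  or_low = 0.5, or_high = 2.0,
                                  keep_all = FALSE) {
  stopifnot(inherits(fit, "et_bicluster"))
  missing_lab <- setdiff(fit$condition_ids, names(labels))
  if (length(missing_lab))
    stop("missing case/control label for condition(s): ",
         paste(utils::head(missing_lab, 5), collapse = ", "))
  lab <- labels[fit$condition_ids]
  if (!all(lab %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  n_case <- sum(lab == "case")
  n_ctrl <- sum(lab == "control")

  rows <- lapply(seq_along(fit$biclusters), function(i) {
    b <- fit$biclusters[[i]]
    supp_lab <- lab[b$transactions]
    a <- sum(supp_lab == "case")
    cc <- sum(supp_lab == "control")
    bb <- n_case - a
    d <- n_ctrl - cc
    tab <- matrix(c(a, bb, cc, d), nrow = 2)
    if (any(tab == 0)) {
      or <- ((a + 0.5) * (d + 0.5)) / ((bb + 0.5) * (cc + 0.5))
    } else {
      or <- (a * d) / (bb * cc)
    }
    p <- stats::fisher.test(tab)$p.value
    data.frame(bicluster = i,
               genes = paste(fit$gene_ids[b$genes], collapse = ";"),
               cases_supporting = a, cases_not = bb,
               controls_supporting = cc, controls_not = d,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$selected <- out$p_value < p_threshold &
    (out$odds_ratio > or_high | out$odds_ratio < or_low)
  if (keep_all) out else {
    res <- out[out$selected, , drop = FALSE]
    res$selected <- NULL
    rownames(res) <- NULL
    res
  }
}

#' Randomization test with size-matched random gene sets
#'
#' For each bicluster, draws `reps` uniform random gene sets of the same size
#' (number of genes) from the universe and scores each by the same enrichment
#' analysis (enrichment score = `-log10` of the minimum hypergeometric
#' p-value over all terms). The empirical p-value of a bicluster is the
#' fraction of its random counterparts whose score strictly exceeds the
#' actual score; a bicluster with zero exceedances is reported as
#' `< 1/reps`. A replicate-level summary in the same spirit is also returned:
#' the `r`-th random counterparts of all biclusters form the `r`-th random
#' set collection, and for each p-value threshold the number of replicates
#' whose enriched fraction exceeds the actual run's fraction is reported.
#'
#' @param fit an `"et_bicluster"` object or a list of gene-identifier vectors
#'   (the actual biclusters, typically the selected top set).
#' @param collection a `"gene_set_collection"`.
#' @param reps number of random replicates (default 1000).
#' @param seed integer seed; required, for bit-for-bit reproducibility.
#' @param thresholds p-value thresholds for the replicate-level summary.
#' @return a list with `per_bicluster` (data.frame: size, actual score,
#'   exceedances, `empirical_p`, and `reported` — the `"< 1/reps"` form when
#'   no random set exceeds), `summary` (data.frame per threshold:
#'   actual enriched fraction, mean and max random fraction, number of
#'   replicates exceeding the actual fraction), and `reps`.
#' @export
randomize_gene_sets <- function(fit, collection, reps = 1000, seed,
                                thresholds = c(5e-2, 1e-2, 5e-3, 1e-3, 1e-5)) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (reps < 1) stop("'reps' must be at least 1")
  gene_sets <- .gene_sets_of(fit)
  if (length(gene_sets) == 0L) stop("no biclusters to test")
  idx <- .collection_index(collection)
  nu <- length(idx$universe)
  sizes <- vapply(gene_sets, function(g) length(unique(g)), integer(1))
  if (any(sizes > nu))
    stop("bicluster gene-size exceeds the universe: cannot draw a size-matched random set")

  actual_minp <- vapply(gene_sets, function(g) {
    min(.term_pvalues(match(intersect(g, idx$universe), idx$universe), idx))
  }, numeric(1))
  actual_score <- -log10(actual_minp)

  set.seed(seed)
  nb <- length(gene_sets)
  exceed <- integer(nb)
  rand_minp <- matrix(NA_real_, nrow = reps, ncol = nb)
  for (r in seq_len(reps)) {
    for (i in seq_len(nb)) {
      gi <- sample.int(nu, sizes[i])
      mp <- min(.term_pvalues(gi, idx))
      rand_minp[r, i] <- mp
      if (-log10(mp) > actual_score[i]) exceed[i] <- exceed[i] + 1L
    }
  }
  emp_p <- exceed / reps
  per_bicluster <- data.frame(
    bicluster = seq_len(nb), size = sizes, score = actual_score,
    exceedances = exceed, empirical_p = emp_p,
    reported = ifelse(exceed == 0L, sprintf("< %g", 1 / reps),
                      format(emp_p)),
    stringsAsFactors = FALSE)

  actual_frac <- vapply(thresholds, function(th)
    mean(actual_minp <= th), numeric(1))
  rand_frac <- vapply(thresholds, function(th)
    rowMeans(rand_minp <= th), numeric(reps))
  rand_frac <- matrix(rand_frac, nrow = reps)
  summary_df <- data.frame(
    threshold = thresholds,
    actual_fraction = actual_frac,
    random_fraction_mean = colMeans(rand_frac),
    random_fraction_max = apply(rand_frac, 2, max),
    n_random_exceeding = vapply(seq_along(thresholds), function(j)
      sum(rand_frac[, j] > actual_frac[j]), integer(1)))

  list(per_bicluster = per_bicluster, summary = summary_df, reps = reps)
}

#' Randomize an expression matrix by shuffling each gene profile
#'
#' Independently permutes each gene's values across the conditions. The
#' multiset of values in every row is conserved exactly, but correlations
#' between genes are destroyed; mining the shuffled matrix shows how much
#' bicluster structure arises by chance from the marginal value
#' distributions alone.
#'
#' @param x numeric expression matrix.
#' @param seed integer seed; required.
#' @return a matrix of the same shape and dimnames.
#' @export
shuffle_conditions <- function(x, seed) {
  validate_expression_matrix(x)
  if (missing(seed)) stop("'seed' is required for reproducibility")
  set.seed(seed)
  out <- x
  for (i in seq_len(nrow(x)))
    out[i, ] <- x[i, sample.int(ncol(x))]
  out
}
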