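# S3 methods for "et_bicluster" fits.

#' @export
print.et_bicluster <- function(x, ...) {
  cat("Error-tolerant bicluster mining\n")
  if (isTRUE(x$merged)) {
    cat(sprintf(
      "  merged runs: exact (alpha=%g, rs=%g) + tolerant (alpha=%g, epsilon=%g, rs=%g)\n",
      x$runs$exact$alpha, x$runs$exact$rs, x$runs$tolerant$alpha,
      x$runs$tolerant$epsilon, x$runs$tolerant$rs))
  } else {
    cat(sprintf("  alpha = %g, epsilon = %g, RangeSupport threshold = %g%s\n",
                x$alpha, x$epsilon, x$rs,
                if (x$epsilon == 0) " (exact/RAP mode)" else ""))
  }
  cat(sprintf("  data: %d genes x %d conditions\n", x$n_genes, x$n_conditions))
  lev <- vapply(x$biclusters, `[[`, integer(1), "level")
  cat(sprintf("  %d biclusters (levels %s)\n", length(lev),
              if (length(lev)) paste(range(lev), collapse = "-") else "-"))
  if (length(lev)) {
    tab <- table(lev)
    cat("  per level:", paste(sprintf("%s:%d", names(tab), tab),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.et_bicluster <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(params = list(alpha = object$alpha,
                               epsilon = object$epsilon, rs = object$rs),
                 n_biclusters = nrow(df),
                 size_distribution = if (nrow(df)) table(df$level) else table(integer(0)),
                 range_support = if (nrow(df)) summary(df$range_support) else NULL,
                 level_counts = object$level_counts),
            class = "summary.et_bicluster")
}

#' @export
print.summary.et_bicluster <- function(x, ...) {
  cat(sprintf("alpha = %g, epsilon = %g, RangeSupport threshold = %g\n",
              x$params$alpha, x$params$epsilon, x$params$rs))
  cat(sprintf("total biclusters: %d\n", x$n_biclusters))
  if (x$n_biclusters > 0) {
    cat("size distribution (# genes : # biclusters):\n")
    cat(" ", paste(sprintf("%s:%d", names(x$size_distribution),
                           x$size_distribution), collapse = ", "), "\n")
    cat("RangeSupport:\n")
    print(x$range_support)
  }
  if (!is.null(x$level_counts)) {
    cat("per-level candidates and survivors:\n")
    print(x$level_counts, row.names = FALSE)
  }
  invisible(x)
}

#' Tabulate mined biclusters
#'
#' One row per bicluster: gene identifiers (semicolon-separated), supporting
#' condition labels, level (number of genes), number of supporting
#' transactions, RangeSupport, and the total number of discarded (error)
#' values across supporting transactions.
#'
#' @param x an `"et_bicluster"` object.
#' @param row.names,optional,... passed on for S3 compatibility; unused.
#' @return a `data.frame`.
#' @export
as.data.frame.et_bicluster <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  bl <- x$biclusters
  if (length(bl) == 0L) {
    return(data.frame(genes = character(0), conditions = character(0),
                      level = integer(0), n_transactions = integer(0),
                      range_support = numeric(0), n_errors = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    genes = vapply(bl, function(b)
      paste(x$gene_ids[b$genes], collapse = ";"), character(1)),
    conditions = vapply(bl, function(b)
      paste(x$condition_ids[b$transactions], collapse = ";"), character(1)),
    level = vapply(bl, `[[`, integer(1), "level"),
    n_transactions = vapply(bl, function(b)
      length(b$transactions), integer(1)),
    range_support = vapply(bl, `[[`, numeric(1), "range_support"),
    n_errors = vapply(bl, function(b) sum(b$n_errors), integer(1)),
    stringsAsFactors = FALSE)
}

#' Plot bicluster size against RangeSupport
#'
#' Scatter of the number of genes per bicluster versus its RangeSupport, the
#' usual first look at a mining run (larger error-tolerant biclusters with
#' substantial RangeSupport are the interesting ones).
#'
#' @param x an `"et_bicluster"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.et_bicluster <- function(x, ...) {
  df <- as.data.frame(x)
  if (nrow(df) == 0L) {
    warning("no biclusters to plot")
    return(invisible(x))
  }
  jit <- df$level + stats::runif(nrow(df), -0.12, 0.12)
  graphics::plot(jit, df$range_support,
                 xlab = "bicluster size (# genes)",
                 ylab = "RangeSupport",
                 main = sprintf("alpha = %g, epsilon = %g, RS >= %g",
                                x$alpha, x$epsilon, x$rs), ...)
  invisible(x)
}
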