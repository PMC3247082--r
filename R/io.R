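# Readers and writers: expression TSV, bicluster reports (TSV + JSON twin).
# The GMT and condition-label readers live alongside the evaluation code.

#' Read a gene-by-condition expression matrix from TSV
#'
#' First row holds the condition labels, first column the gene identifiers,
#' all remaining cells numeric. Duplicate identifiers, missing values and
#' non-numeric cells are rejected with their location.
#'
#' @param path file path.
#' @return a validated numeric matrix (genes x conditions).
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression TSV needs a gene-id column plus at least one condition column")
  gene_ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
              dimnames = list(gene_ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf(
        "non-numeric or missing value '%s' at data row %d (gene '%s'), column '%s'",
        vals[[j]][bad[1]], bad[1], gene_ids[bad[1]], colnames(vals)[j]))
    m[, j] <- v
  }
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix with gene rownames and condition colnames.
#' @param path output path.
#' @param gene_column header of the gene-id column (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, gene_column = "gene") {
  validate_expression_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(gene_column, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mining result to a line-oriented report plus a JSON twin
#'
#' The TSV report holds one bicluster per line (gene list, supporting
#' condition labels, level, RangeSupport, per-transaction discarded error
#' genes) with the mining parameters echoed in `#`-prefixed header lines. A
#' machine-readable JSON twin at `paste0(path, ".json")` carries the full
#' structure, including per-transaction contributions and retained/discarded
#' partitions; [read_biclusters()] restores it losslessly.
#'
#' @param fit an `"et_bicluster"` object.
#' @param path path of the TSV report; the JSON twin is written next to it.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(fit, path) {
  stopifnot(inherits(fit, "et_bicluster"))
  df <- as.data.frame(fit)
  err_desc <- vapply(fit$biclusters, function(b) {
    has <- which(b$n_errors > 0L)
    if (length(has) == 0L) return("")
    paste(vapply(has, function(j)
      sprintf("%s:%s", fit$condition_ids[b$transactions[j]],
              paste(fit$gene_ids[b$discarded[[j]]], collapse = ",")),
      character(1)), collapse = ";")
  }, character(1))
  header <- c(
    "# etbicluster report",
    sprintf("# alpha=%g epsilon=%g rs=%g", fit$alpha, fit$epsilon, fit$rs),
    sprintf("# genes=%d conditions=%d biclusters=%d",
            fit$n_genes, fit$n_conditions, nrow(df)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  out <- cbind(df, discarded = err_desc)
  if (!is.null(fit$mse)) out$mse <- fit$mse
  suppressWarnings(utils::write.table(out, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  json <- list(
    params = list(alpha = fit$alpha, epsilon = fit$epsilon, rs = fit$rs),
    gene_ids = fit$gene_ids, condition_ids = fit$condition_ids,
    merged = isTRUE(fit$merged),
    biclusters = lapply(fit$biclusters, function(b) list(
      genes = fit$gene_ids[b$genes],
      transactions = fit$condition_ids[b$transactions],
      contributions = b$contributions,
      discarded = lapply(b$discarded, function(d) as.list(fit$gene_ids[d])),
      n_errors = b$n_errors,
      range_support = b$range_support,
      level = b$level)))
  jsonlite::write_json(json, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a JSON bicluster report back into an `"et_bicluster"` object
#'
#' @param path path of the JSON twin written by [write_biclusters()].
#' @return an `"et_bicluster"` object equivalent to the one written.
#' @export
read_biclusters <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  gene_ids <- unlist(j$gene_ids)
  cond_ids <- unlist(j$condition_ids)
  bics <- lapply(j$biclusters, function(b) {
    genes <- match(unlist(b$genes), gene_ids)
    .make_bic(
      genes = genes,
      transactions = match(unlist(b$transactions), cond_ids),
      contributions = as.numeric(unlist(b$contributions)),
      discarded = lapply(b$discarded, function(d)
        if (length(d) == 0L) integer(0) else match(unlist(d), gene_ids)),
      n_errors = as.integer(unlist(b$n_errors)),
      range_support = b$range_support,
      level = as.integer(b$level))
  })
  structure(
    list(biclusters = bics, alpha = j$params$alpha,
         epsilon = j$params$epsilon, rs = j$params$rs,
         gene_ids = gene_ids, condition_ids = cond_ids,
         n_genes = length(gene_ids), n_conditions = length(cond_ids),
         level_counts = NULL, merged = isTRUE(j$merged),
         call = NULL),
    class = "et_bicluster")
}
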