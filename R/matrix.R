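# Expression-matrix validation. The data container is a plain numeric matrix
# with genes as rows and experimental conditions as columns; rownames are gene
# identifiers, colnames are condition labels.

#' Validate a gene-by-condition expression matrix
#'
#' Checks that `x` is a numeric matrix with unique, non-empty row (gene) and
#' column (condition) identifiers and no missing or non-finite cells, and
#' returns it invisibly. All mining entry points call this on their input.
#'
#' @param x numeric matrix, genes in rows, conditions in columns.
#' @return `x`, invisibly.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x conditions)")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("expression matrix must have at least one gene and one condition")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene ids as rownames and condition labels as colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate condition labels: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(rownames(x) == "") || any(colnames(x) == ""))
    stop("empty gene or condition identifier")
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite expression value at gene '%s', condition '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  invisible(x)
}

.validate_params <- function(alpha, epsilon, rs) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("'alpha' must be a single non-negative number")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon >= 1)
    stop("'epsilon' must lie in [0, 1); 0 is the exact (RAP) mode")
  if (!is.numeric(rs) || length(rs) != 1L || rs <= 0)
    stop("'rs' (the RangeSupport threshold) must be a single positive number")
  invisible(NULL)
}
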