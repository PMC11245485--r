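#' Expression matrix container
#'
#' A lightweight container for a genes-by-samples expression study: an
#' integer count layer, a TPM layer (each column summing to one million),
#' per-gene transcript lengths and a per-sample metadata table.
#'
#' @param counts Nonnegative integer matrix, genes x samples, with row and
#'   column names.
#' @param gene_lengths Named numeric vector of transcript lengths (bp),
#'   aligned with `rownames(counts)`.
#' @param samples Data frame with columns `sample_id`, `variety`,
#'   `condition`, `stage`, `replicate`; `sample_id` must match
#'   `colnames(counts)`.
#' @param tpm Optional TPM matrix; computed from `counts` and
#'   `gene_lengths` when omitted.
#'
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(counts, gene_lengths, samples, tpm = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene rownames and sample colnames.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be nonnegative integers.")
  }
  if (!all(rownames(counts) %in% names(gene_lengths))) {
    abort("every gene in `counts` needs an entry in `gene_lengths`.")
  }
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(gene_lengths <= 0)) abort("`gene_lengths` must be positive.")
  samples <- as_tibble(samples)
  need <- c("sample_id", "variety", "condition", "stage", "replicate")
  if (!all(need %in% names(samples))) {
    abort(paste("`samples` must have columns:", paste(need, collapse = ", ")))
  }
  if (!identical(samples$sample_id, colnames(counts))) {
    abort("`samples$sample_id` must equal `colnames(counts)` in order.")
  }
  if (is.null(tpm)) tpm <- tpm_normalize(counts, gene_lengths)
  structure(
    list(
      counts = counts, tpm = tpm, gene_lengths = gene_lengths,
      samples = samples, gene_ids = rownames(counts)
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples\n",
    nrow(x$counts), ncol(x$counts)
  ))
  tab <- table(x$samples$condition)
  cat("  conditions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Gene-wise Z-transform
#'
#' Standardizes each row of a matrix to mean 0 and unit (n-1) standard
#' deviation; rows with zero variance are mapped to all-zero rows. Used to
#' put TPM on the scale the clustering and network stages expect.
#'
#' @param x Numeric matrix (genes x samples).
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(x) {
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
  z <- (x - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}
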