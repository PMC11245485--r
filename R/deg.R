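#' TPM normalization
#'
#' Converts raw counts to transcripts per million:
#' `tpm[g, s] = 1e6 * (counts[g, s] / length[g]) / sum_g'(counts[g', s] / length[g'])`.
#' Every column of the result sums to one million.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @param gene_lengths Positive lengths (bp), one per gene, in row order or
#'   named by gene.
#' @return TPM matrix with the dimnames of `counts`.
#' @examples
#' counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' tpm_normalize(counts, c(a = 1000, b = 2000))
#' @export
tpm_normalize <- function(counts, gene_lengths) {
  if (any(counts < 0)) abort("`counts` must be nonnegative.")
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts)) {
    abort("`gene_lengths` must supply one length per gene.")
  }
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
    abort("`gene_lengths` must be positive and finite.")
  }
  rpk <- counts / gene_lengths
  denom <- colSums(rpk)
  if (any(denom == 0)) {
    abort(sprintf(
      "TPM undefined: sample(s) %s have all-zero counts.",
      paste(colnames(counts)[denom == 0], collapse = ", ")
    ))
  }
  sweep(rpk, 2, denom, `/`) * 1e6
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, returned in
#' the input order. Input values outside \[0, 1\] are an error.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values (q-values), same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("`pvalues` must be numeric.")
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad)) {
    abort(sprintf("p-values outside [0, 1] at positions %s.",
                  toString(head(which(bad), 5))))
  }
  p.adjust(pvalues, method = "BH")
}

#' Call stress differentially expressed genes
#'
#' Screens genes for differential expression between a stress condition and
#' the control using the decision rule |log2FC| > `lfc_threshold` and
#' BH-adjusted p < `alpha` (default: more than twofold change at adjusted
#' p < 0.05). The fold change is the difference of group means of
#' `log2(TPM + pseudocount)` and the p-value a two-sided Welch t-test on
#' the same values; adjustment is over all tested genes. This is a
#' deliberately simple moderated-free test: the pipeline consumes only the
#' resulting DEG set, and recovery of planted effects is verified against
#' the generator's ground truth.
#'
#' Genes with zero variance in both groups carry no evidence and are
#' assigned p = 1 (they stay in the adjustment so the number of tests is
#' stable). Results are invariant to gene and sample ordering.
#'
#' @param expr An [expression_matrix()].
#' @param contrast Length-2 character vector `c(stress, control)` naming
#'   conditions in `expr$samples$condition`.
#' @param lfc_threshold Minimum |log2 fold change| (default 1, i.e. twofold).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param pseudocount Added to TPM before the log2 transform (default 1).
#' @param filter If `TRUE` (default) return only genes passing the rule;
#'   otherwise return the full per-gene table.
#' @return A tibble with columns `gene_id`, `contrast`, `log2fc`, `pvalue`,
#'   `padj`, `direction` ("up"/"down" in the stress group).
#' @export
call_degs <- function(expr, contrast, lfc_threshold = 1, alpha = 0.05,
                      pseudocount = 1, filter = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(contrast) != 2L) abort("`contrast` must be c(stress, control).")
  cond <- expr$samples$condition
  for (side in contrast) {
    if (sum(cond == side) < 2L) {
      abort(sprintf("contrast side \"%s\" needs >= 2 replicates in the metadata.", side))
    }
  }
  x <- log2(expr$tpm + pseudocount)
  a <- x[, cond == contrast[1], drop = FALSE]   # stress
  b <- x[, cond == contrast[2], drop = FALSE]   # control
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  log2fc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  pvalue <- ifelse(se2 > 0, 2 * pt(-abs(tstat), df), 1)
  out <- tibble(
    gene_id = rownames(x),
    contrast = paste0(contrast[1], "_vs_", contrast[2]),
    log2fc = unname(log2fc),
    pvalue = unname(pvalue),
    padj = bh_adjust(unname(pvalue)),
    direction = ifelse(log2fc >= 0, "up", "down")
  )
  if (filter) {
    out <- out %>% filter(abs(.data$log2fc) > lfc_threshold, .data$padj < alpha)
  }
  out
}

#' Pool DEG sets across stress contrasts
#'
#' Calls [call_degs()] for every stress condition against the control and
#' returns the union table (a gene qualifying in any contrast is kept),
#' mirroring the practice of pooling stress-triggered DEGs before
#' clustering.
#'
#' @inheritParams call_degs
#' @param stresses Stress condition labels; default: every non-control
#'   condition present.
#' @param control Control label (default "control").
#' @return A tibble as in [call_degs()], one row per (gene, contrast) pass.
#' @export
call_degs_all <- function(expr, stresses = NULL, control = "control",
                          lfc_threshold = 1, alpha = 0.05, pseudocount = 1) {
  if (is.null(stresses)) {
    stresses <- setdiff(unique(expr$samples$condition), control)
  }
  purrr::map_dfr(stresses, function(st) {
    call_degs(expr, c(st, control), lfc_threshold, alpha, pseudocount)
  })
}
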