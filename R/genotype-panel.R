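#' Genotype panel container
#'
#' Holds a biallelic diploid panel: a variant table, a variants-by-accessions
#' dosage matrix (counts of the alternate allele, `NA` for missing), the
#' accession table with optional population-group labels, and optionally a
#' per-regulator gene map and a geography table.
#'
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `type` ("SNP"/"InDel").
#' @param dosage Matrix variants x accessions with values in {0, 1, 2, NA};
#'   rownames = variant ids, colnames = accession ids.
#' @param accessions Tibble with columns `accession_id` and `group`.
#' @param gene_map Optional tibble with columns `gene_id`, `chrom`, `start`
#'   (region start incl. promoter), `body_start`, `body_end`.
#' @param geo Optional tibble with columns `accession_id`, `lon`, `lat`,
#'   `precip_mm`, `group`.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(variants, dosage, accessions, gene_map = NULL,
                           geo = NULL) {
  variants <- as_tibble(variants)
  accessions <- as_tibble(accessions)
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "type")
  if (!all(need %in% names(variants))) {
    abort(paste("`variants` must have columns:", paste(need, collapse = ", ")))
  }
  if (!identical(rownames(dosage), variants$variant_id)) {
    abort("`rownames(dosage)` must equal `variants$variant_id` in order.")
  }
  if (!identical(colnames(dosage), accessions$accession_id)) {
    abort("`colnames(dosage)` must equal `accessions$accession_id` in order.")
  }
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) abort("dosages must lie in {0, 1, 2} or be missing.")
  o <- order(variants$chrom, variants$pos)
  if (!identical(o, seq_len(nrow(variants)))) {
    abort("variants must be sorted by (chrom, pos).")
  }
  structure(
    list(
      variants = variants, dosage = dosage, accessions = accessions,
      gene_map = if (is.null(gene_map)) NULL else as_tibble(gene_map),
      geo = if (is.null(geo)) NULL else as_tibble(geo)
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d variants x %d accessions\n",
    nrow(x$variants), nrow(x$accessions)
  ))
  if (!all(is.na(x$accessions$group))) {
    tab <- table(x$accessions$group)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  cat(sprintf(
    "  %s:%d-%d; %d InDel(s)\n",
    x$variants$chrom[1], min(x$variants$pos), max(x$variants$pos),
    sum(x$variants$type == "InDel")
  ))
  invisible(x)
}

#' Restrict a panel to a genomic region
#'
#' @param panel A [genotype_panel()].
#' @param region `c(start, end)` in 1-based inclusive coordinates, or a
#'   string `"chrom:start-end"`.
#' @param chrom Chromosome (defaults to the panel's single chromosome when
#'   `region` is numeric).
#' @return A `genotype_panel` containing only the variants inside the region.
#' @export
panel_region <- function(panel, region, chrom = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.character(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) abort("region string must look like \"chr:start-end\".")
    chrom <- m[2]
    region <- as.numeric(m[3:4])
  }
  if (is.null(chrom)) chrom <- panel$variants$chrom[1]
  keep <- panel$variants$chrom == chrom &
    panel$variants$pos >= region[1] & panel$variants$pos <= region[2]
  genotype_panel(
    panel$variants[keep, , drop = FALSE],
    panel$dosage[keep, , drop = FALSE],
    panel$accessions,
    gene_map = panel$gene_map, geo = panel$geo
  )
}

#' Restrict a panel to a subset of accessions
#'
#' @param panel A [genotype_panel()].
#' @param accession_ids Accessions to keep, or `groups` to keep by label.
#' @param groups Optional group labels to keep instead of explicit ids.
#' @return A `genotype_panel`.
#' @export
panel_accessions <- function(panel, accession_ids = NULL, groups = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(accession_ids)) {
    if (is.null(groups)) abort("give `accession_ids` or `groups`.")
    accession_ids <- panel$accessions$accession_id[panel$accessions$group %in% groups]
  }
  keep <- panel$accessions$accession_id %in% accession_ids
  if (!any(keep)) abort("no accessions left after subsetting.")
  genotype_panel(
    panel$variants,
    panel$dosage[, keep, drop = FALSE],
    panel$accessions[keep, , drop = FALSE],
    gene_map = panel$gene_map,
    geo = if (is.null(panel$geo)) NULL else panel$geo[panel$geo$accession_id %in% accession_ids, , drop = FALSE]
  )
}
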