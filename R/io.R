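#' Write a genotype panel as VCF 4.2
#'
#' Emits a minimal valid VCF 4.2 text file: file-format and contig header
#' lines, a GT FORMAT declaration, and one diploid unphased genotype per
#' accession (`0/0`, `0/1`, `1/1`, or `./.` for missing).
#'
#' @param panel A [genotype_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  acc <- panel$accessions$accession_id
  contigs <- unique(v$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=stresshub",
    sprintf("##contig=<ID=%s,length=%d>", contigs,
            vapply(contigs, function(cc) max(v$pos[v$chrom == cc]) + 10000L, numeric(1))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", acc), collapse = "\t")
  )
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(panel$dosage), ncol(panel$dosage))
  ok <- !is.na(panel$dosage)
  gt[ok] <- gt_codes[panel$dosage[ok] + 1L]
  body <- paste(
    v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Parses a VCF 4.2 file (via the `vcfR` reader), converts diploid GT
#' fields to alternate-allele dosages, and returns a [genotype_panel()].
#' Phased separators are accepted and collapsed to dosages; multiallelic
#' records are rejected. Group labels are not part of VCF and are `NA`
#' unless supplied.
#'
#' @param path VCF file path.
#' @param groups Optional tibble (`accession_id`, `group`) to attach.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, groups = NULL) {
  vr <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(vr), stringsAsFactors = FALSE)
  if (any(grepl(",", fx$ALT))) abort("multiallelic records are not supported.")
  gt <- vcfR::extract.gt(vr, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  ids <- ifelse(is.na(fx$ID) | fx$ID == ".",
                paste0(fx$CHROM, "_", fx$POS), fx$ID)
  rownames(dos) <- ids
  variants <- tibble(
    variant_id = ids,
    chrom = fx$CHROM,
    pos = as.integer(fx$POS),
    ref = fx$REF,
    alt = fx$ALT,
    type = ifelse(nchar(fx$REF) != nchar(fx$ALT), "InDel", "SNP")
  )
  accessions <- tibble(accession_id = colnames(dos), group = NA_character_)
  if (!is.null(groups)) {
    groups <- as_tibble(groups)
    accessions$group <- groups$group[match(accessions$accession_id,
                                           groups$accession_id)]
  }
  o <- order(variants$chrom, variants$pos)
  genotype_panel(variants[o, ], dos[o, , drop = FALSE], accessions)
}

#' Write the synthetic study bundle to disk
#'
#' Writes every artifact of a simulated study in plain-text formats:
#' expression counts TSV (genes x samples) with a sample-metadata sidecar
#' and gene lengths, the genotype panel as VCF 4.2 with a group-label TSV,
#' the phenotype TSV, the geography TSV, the regulator list, and the
#' planted truth as JSON. Writing the same bundle twice produces
#' byte-identical files.
#'
#' @param bundle A bundle from [simulate_bundle()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  expr <- bundle$expression
  readr::write_tsv(
    as_tibble(expr$counts, rownames = "gene_id"), p("expression_counts.tsv")
  )
  readr::write_tsv(expr$samples, p("sample_metadata.tsv"))
  readr::write_tsv(
    tibble(gene_id = names(expr$gene_lengths),
           length_bp = unname(expr$gene_lengths)),
    p("gene_lengths.tsv")
  )
  write_vcf(bundle$panel, p("genotypes.vcf"))
  readr::write_tsv(bundle$panel$accessions, p("groups.tsv"))
  readr::write_tsv(bundle$panel$geo, p("geography.tsv"))
  readr::write_tsv(bundle$phenotypes, p("phenotypes.tsv"))
  writeLines(bundle$regulators, p("regulators.txt"))
  truth <- bundle$truth
  jsonlite::write_json(
    list(
      hub_gene_ids = truth$hub_gene_ids,
      target_map = truth$target_map,
      de_gene_ids = truth$de_gene_ids,
      causal_variant_id = truth$causal_variant_id,
      cline_variant_id = truth$cline_variant_id,
      sweep_window = truth$sweep_window
    ),
    p("truth.json"), pretty = TRUE, auto_unbox = FALSE, digits = NA
  )
  out <- c(
    counts = p("expression_counts.tsv"), metadata = p("sample_metadata.tsv"),
    lengths = p("gene_lengths.tsv"), vcf = p("genotypes.vcf"),
    groups = p("groups.tsv"), geography = p("geography.tsv"),
    phenotypes = p("phenotypes.tsv"), regulators = p("regulators.txt"),
    truth = p("truth.json")
  )
  invisible(out)
}

#' Simulate the complete synthetic study
#'
#' Runs every generator under one configuration: expression with planted
#' hub programs, the structured genotype panel with sweep/causal/cline
#' variants (sharing the hub identities), and the phenotypes. The pieces
#' are mutually consistent (shared regulator ids and accession ids) and
#' deterministic in `config$seed`.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, [write_bundle()] is called.
#' @return A list: `expression`, `panel`, `phenotypes`, `regulators`,
#'   `truth`, `config`.
#' @export
simulate_bundle <- function(config, outdir = NULL) {
  se <- simulate_expression(config)
  sg <- simulate_genotypes(config, truth = se$truth)
  pheno <- simulate_phenotypes(sg$panel, sg$truth, config)
  bundle <- list(
    expression = se$expression,
    panel = sg$panel,
    phenotypes = pheno,
    regulators = regulator_ids(config$n_regulators),
    truth = sg$truth,
    config = config
  )
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}
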