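#' Parameters of the three-step candidate filter
#'
#' Collects every tunable of [run_pipeline()] with its default. Thresholds
#' mirror the filtering rules of the underlying workflow: twofold change at
#' adjusted p < 0.05 for DEGs, a mixed-model significance threshold of
#' 1e-4, 200-bp diversity windows, and the sweep/precipitation rules of
#' [sweep_contrast()] and [precipitation_association()].
#'
#' @param lfc Minimum |log2 fold change| for a DEG (default 1).
#' @param alpha Adjusted-p cutoff for a DEG (default 0.05).
#' @param n_components Number of independent components (default 9).
#' @param z_cut Cluster-assignment threshold, see [assign_clusters()].
#' @param n_trees Trees per random forest (default 1000).
#' @param top_e Edge retention: each target's strongest `top_e` regulators.
#' @param hub_top_n A regulator counts as a hub when its degree rank is at
#'   most this (default 5).
#' @param assoc_threshold Mixed-model significance threshold (default 1e-4).
#' @param maf Minor-allele-frequency filter for the scan (default 0.05).
#' @param promoter_bp Promoter extent upstream of the gene body used to
#'   delimit each candidate's region (default 3000).
#' @param pi_window Diversity window size in bp (default 200).
#' @param sweep_ratio,sweep_frac Sweep-call cutoffs, see [sweep_contrast()].
#' @param precip_alpha Precipitation-flag threshold (default 0.01).
#' @param wild_group,cultivated_groups Population group labels.
#' @param seed Seed for the stochastic stages (ICA restarts, forests).
#' @return A named list of parameters.
#' @export
pipeline_params <- function(lfc = 1, alpha = 0.05, n_components = 9,
                            z_cut = 2, n_trees = 1000, top_e = 5,
                            hub_top_n = 5, assoc_threshold = 1e-4,
                            maf = 0.05, promoter_bp = 3000, pi_window = 200,
                            sweep_ratio = 0.5, sweep_frac = 0.5,
                            precip_alpha = 0.01, wild_group = "O.ruf",
                            cultivated_groups = c("japonica", "indica"),
                            seed = 1) {
  as.list(environment())
}

#' Run the three-step hub-candidate pipeline
#'
#' Executes the full filter on a data bundle: (1) stress DEGs are pooled
#' across contrasts, clustered by independent components, and per-cluster
#' regulator networks are inferred, ranking regulators by retained degree;
#' (2) for each regulator, the variants in its gene body + promoter are
#' tested for association with each trait under the kinship-aware mixed
#' model, requiring at least one variant below `assoc_threshold`;
#' (3) the region's windowed diversity is contrasted between wild and
#' cultivated groups (sweep), and the best-associated variant's allele
#' classes are tested for precipitation-linked distribution. The final
#' call is the conjunction: hub retained AND >= 1 significant variant for
#' >= 1 trait AND (sweep in >= 1 cultivated group AND precipitation flag).
#'
#' All regulators are reported with their per-step evidence (not only the
#' survivors), so intermediate filters can be audited; `final_pass`
#' applies the strict conjunction.
#'
#' @param bundle A list as returned by [simulate_bundle()]: `expression`,
#'   `panel` (with `gene_map` and `geo`), `phenotypes`, `regulators`.
#' @param params A [pipeline_params()] list.
#' @param verbose Emit progress messages (default `TRUE`).
#' @return A `candidate_report` tibble, one row per regulator, ordered by
#'   (`final_pass`, hub degree); attributes carry the parameter echo, the
#'   per-stage artifacts (`degs`, `ica`, `clusters`, `edges`, `hubs`,
#'   `scans`), a config hash and the package version.
#' @export
run_pipeline <- function(bundle, params = pipeline_params(), verbose = TRUE) {
  say <- function(...) if (verbose) inform(sprintf(...))
  expr <- bundle$expression
  panel <- bundle$panel
  regulators <- bundle$regulators
  if (!length(regulators)) {
    say("[stresshub] empty regulator list; nothing to score.")
    return(empty_report(params))
  }

  # Step 1a: stress DEGs, pooled across contrasts.
  degs <- call_degs_all(expr, lfc_threshold = params$lfc, alpha = params$alpha)
  deg_genes <- sort(unique(degs$gene_id))
  say("[stresshub] step 1: %d DEG rows, %d distinct genes (lfc > %g, padj < %g)",
      nrow(degs), length(deg_genes), params$lfc, params$alpha)
  if (length(deg_genes) < 3L) {
    warn("too few DEGs to cluster; returning an empty report.")
    return(empty_report(params))
  }

  # Step 1b: ICA clustering of the DEG submatrix (gene-wise Z of log TPM).
  z_all <- zscore_rows(log2(expr$tpm + 1))
  K <- min(params$n_components, length(deg_genes) - 1L, ncol(z_all) - 1L)
  ica <- fastica_decompose(z_all[deg_genes, , drop = FALSE], K = K,
                           seed = params$seed)
  clusters <- assign_clusters(ica, z_cut = params$z_cut)
  say("[stresshub] step 1: ICA K = %d, %d/%d genes assigned",
      K, sum(!is.na(clusters$cluster)), nrow(clusters))

  # Step 1c: per-cluster networks with the regulator panel; hub ranking.
  edges <- infer_grn_clusters(z_all, clusters, regulators,
                              n_trees = params$n_trees, seed = params$seed)
  hubs <- rank_hubs(edges, top_e = params$top_e)
  if (!nrow(hubs)) {
    warn("no retained edges; returning an empty report.")
    return(empty_report(params))
  }
  say("[stresshub] step 1: %d edges; top regulator %s (degree %d)",
      nrow(edges), hubs$regulator[1], hubs$degree[1])

  hub_ranks <- stats::setNames(hubs$rank, hubs$regulator)
  hub_degrees <- stats::setNames(hubs$degree, hubs$regulator)

  # Step 2 prerequisites: kinship and null fits per trait over the
  # phenotyped accessions.
  pheno <- bundle$phenotypes
  traits <- unique(pheno$trait)
  acc_ph <- unique(pheno$accession_id)
  panel_ph <- panel_accessions(panel, acc_ph)
  Kin <- kinship_matrix(panel_ph)
  nulls <- lapply(traits, function(tr) {
    pv <- pheno[pheno$trait == tr, ]
    y <- stats::setNames(pv$value, pv$accession_id)[colnames(Kin)]
    fit_null_reml(y, Kin)
  })
  names(nulls) <- traits
  say("[stresshub] step 2: null mixed model fitted for %d trait(s), n = %d",
      length(traits), ncol(Kin))

  gene_map <- panel$gene_map
  scans <- list()
  report <- purrr::map_dfr(regulators, function(reg) {
    gm <- gene_map[gene_map$gene_id == reg, ]
    degree <- unname(hub_degrees[reg])
    rank <- unname(hub_ranks[reg])
    hub_retained <- !is.na(rank) && rank <= params$hub_top_n && degree > 0
    row <- tibble(
      regulator = reg,
      hub_degree = ifelse(is.na(degree), 0L, as.integer(degree)),
      hub_rank = as.integer(rank),
      hub_retained = hub_retained,
      n_sig_variants = 0L,
      best_p = NA_real_,
      best_trait = NA_character_,
      assoc_pass = FALSE,
      sweep_japonica = NA,
      sweep_indica = NA,
      sweep_pass = FALSE,
      precip_p = NA_real_,
      precip_r = NA_real_,
      precip_pass = FALSE,
      final_pass = FALSE
    )
    if (!nrow(gm)) return(row)
    region <- c(gm$body_start - params$promoter_bp, gm$body_end)

    # Step 2: regional mixed-model association, any trait qualifies.
    best <- NULL
    for (tr in traits) {
      pv <- pheno[pheno$trait == tr, ]
      y <- stats::setNames(pv$value, pv$accession_id)[colnames(Kin)]
      sc <- scan_region(panel_ph, y, nulls[[tr]], region = region,
                        threshold = params$assoc_threshold, maf = params$maf)
      scans[[paste(reg, tr, sep = ":")]] <<- sc
      if (nrow(sc)) {
        row$n_sig_variants <- row$n_sig_variants + sum(sc$significant)
        i <- which.min(sc$pvalue)
        if (is.na(row$best_p) || sc$pvalue[i] < row$best_p) {
          row$best_p <- sc$pvalue[i]
          row$best_trait <- tr
          best <- sc[i, ]
        }
      }
    }
    row$assoc_pass <- row$n_sig_variants >= 1L

    # Step 3: sweep contrast over the region, all three groups.
    prof <- dplyr::bind_rows(lapply(
      c(params$wild_group, params$cultivated_groups),
      function(g) windowed_pi(panel, g, region = region,
                              window = params$pi_window)
    ))
    sw <- sweep_contrast(prof, wild_group = params$wild_group,
                         cultivated_groups = params$cultivated_groups,
                         ratio_cutoff = params$sweep_ratio,
                         frac_windows = params$sweep_frac)
    row$sweep_japonica <- sw$sweep[match("japonica", sw$group)]
    row$sweep_indica <- sw$sweep[match("indica", sw$group)]
    row$sweep_pass <- isTRUE(any(sw$sweep))

    # Step 3: precipitation-linked distribution of the focal variant
    # (the region's best-associated variant), classes = carriers vs not.
    if (!is.null(best) && !is.null(panel$geo)) {
      d <- panel$dosage[best$variant_id, ]
      cls <- stats::setNames(ifelse(d > 0, "carrier", "noncarrier"), names(d))
      cls <- cls[!is.na(d)]
      pa <- tryCatch(
        precipitation_association(panel$geo, cls, alpha = params$precip_alpha),
        error = function(e) NULL
      )
      if (!is.null(pa)) {
        row$precip_p <- pa$pvalue
        row$precip_r <- pa$r
        row$precip_pass <- pa$flagged
      }
    }

    row$final_pass <- row$hub_retained && row$assoc_pass &&
      row$sweep_pass && row$precip_pass
    row
  })

  report <- report %>%
    arrange(desc(.data$final_pass), desc(.data$hub_degree), .data$regulator)
  say("[stresshub] final: %d/%d regulator(s) pass all three filters",
      sum(report$final_pass), nrow(report))

  attr(report, "params") <- params
  attr(report, "config_hash") <- rlang::hash(params)
  attr(report, "version") <- as.character(packageVersion("stresshub"))
  attr(report, "artifacts") <- list(degs = degs, ica = ica,
                                    clusters = clusters, edges = edges,
                                    hubs = hubs, scans = scans)
  class(report) <- c("candidate_report", class(report))
  report
}

empty_report <- function(params) {
  report <- tibble(
    regulator = character(0), hub_degree = integer(0), hub_rank = integer(0),
    hub_retained = logical(0), n_sig_variants = integer(0),
    best_p = numeric(0), best_trait = character(0), assoc_pass = logical(0),
    sweep_japonica = logical(0), sweep_indica = logical(0),
    sweep_pass = logical(0), precip_p = numeric(0), precip_r = numeric(0),
    precip_pass = logical(0), final_pass = logical(0)
  )
  attr(report, "params") <- params
  attr(report, "config_hash") <- rlang::hash(params)
  attr(report, "version") <- as.character(packageVersion("stresshub"))
  class(report) <- c("candidate_report", class(report))
  report
}

#' Write the candidate report to disk
#'
#' Writes a machine-readable JSON report (rows plus a provenance block
#' echoing the exact parameters, their hash and the package version) and a
#' human-readable TSV summary. Output is deterministic: identical reports
#' serialize to byte-identical files.
#'
#' @param report A `candidate_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "candidate_report"))
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create output dir %s", outdir))
  tsv <- file.path(outdir, "report.tsv")
  js <- file.path(outdir, "report.json")
  readr::write_tsv(as_tibble(report), tsv)
  jsonlite::write_json(
    list(
      provenance = list(
        package = "stresshub",
        version = attr(report, "version"),
        config_hash = attr(report, "config_hash"),
        params = attr(report, "params")
      ),
      candidates = as_tibble(report)
    ),
    js, pretty = TRUE, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv = tsv, json = js))
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report> %d regulator(s), %d final pass\n",
              nrow(x), sum(x$final_pass)))
  NextMethod()
}
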