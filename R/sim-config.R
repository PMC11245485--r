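#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic multi-omic study into one validated
#' object. The defaults describe a desk-scale study: a few thousand genes
#' measured in two stress conditions plus a control, a transcription-factor
#' panel containing a small number of planted hub regulators, and a
#' three-group genotype panel (one wild, two cultivated groups) carrying a
#' causal promoter variant, a low-diversity sweep region and a
#' precipitation-linked allele cline.
#'
#' All downstream randomness flows from `seed` through a fixed splitting
#' scheme: the master seed deterministically spawns one child seed per
#' generator (expression, genotypes, phenotypes, geography), so each
#' generator is independently reproducible and an identical configuration
#' yields bit-identical outputs.
#'
#' @param seed Integer master seed.
#' @param n_genes Total number of genes (including regulators).
#' @param n_regulators Number of candidate regulator genes (the NAC-like
#'   panel; planted hubs plus decoys).
#' @param n_planted_hubs Number of regulators planted as true hubs, each
#'   driving its own co-expression program.
#' @param n_targets_per_hub Number of target genes wired to each planted hub.
#' @param n_de_background Number of additional stress-responsive genes that
#'   are differentially expressed but not wired to any hub; they dilute the
#'   hub programs the way unrelated stress regulons do in real data.
#' @param n_samples_per_condition Replicates per condition.
#' @param conditions Condition labels; the first is the control.
#' @param de_log2fc Planted stress-induction effect for hub genes, in log2
#'   units; targets inherit it scaled by their (nonzero) wiring slope.
#' @param hub_program_sd Scale of each hub program's heavy-tailed (Laplace)
#'   per-sample activity, in log2 units. Larger values make the latent
#'   programs easier to separate by independent components but add shared
#'   within-group variance to the program's genes.
#' @param expr_noise_sd Gene-level log2-expression noise standard deviation.
#' @param dispersion Negative-binomial dispersion of the count layer
#'   (variance = mu + dispersion * mu^2).
#' @param n_accessions Accessions per population group (wild, and each
#'   cultivated group).
#' @param n_variants Total variants across all regulator gene regions.
#' @param fst Balding-Nichols differentiation parameter, in (0, 1).
#' @param causal_beta Phenotype effect per alternate allele at the planted
#'   causal promoter variant, in trait units.
#' @param h2_polygenic Proportion of the non-causal phenotype variance
#'   attributable to the kinship-structured polygenic term, in \[0, 1\].
#' @param pheno_noise_sd Standard deviation of the total non-causal
#'   phenotype component (polygenic + white noise).
#' @param sweep_window Optional `c(start, end)` (bp) for the planted sweep;
#'   defaults to the gene body of the first planted hub.
#' @param precip_gradient Target correlation between the cline variant's
#'   dosage and accession mean precipitation, in \[-1, 1\].
#'
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 500)
#' cfg$n_planted_hubs
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_regulators = 20L,
                       n_planted_hubs = 2L,
                       n_targets_per_hub = 20L,
                       n_de_background = 100L,
                       n_samples_per_condition = 6L,
                       conditions = c("control", "drought", "heat"),
                       de_log2fc = 3,
                       hub_program_sd = 0.4,
                       expr_noise_sd = 0.2,
                       dispersion = 0.05,
                       n_accessions = 70L,
                       n_variants = 2000L,
                       fst = 0.3,
                       causal_beta = 1,
                       h2_polygenic = 0.3,
                       pheno_noise_sd = 1,
                       sweep_window = NULL,
                       precip_gradient = 0.6) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_regulators = as.integer(n_regulators),
    n_planted_hubs = as.integer(n_planted_hubs),
    n_targets_per_hub = as.integer(n_targets_per_hub),
    n_de_background = as.integer(n_de_background),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    conditions = as.character(conditions),
    de_log2fc = as.numeric(de_log2fc),
    hub_program_sd = as.numeric(hub_program_sd),
    expr_noise_sd = as.numeric(expr_noise_sd),
    dispersion = as.numeric(dispersion),
    n_accessions = as.integer(n_accessions),
    n_variants = as.integer(n_variants),
    fst = as.numeric(fst),
    causal_beta = as.numeric(causal_beta),
    h2_polygenic = as.numeric(h2_polygenic),
    pheno_noise_sd = as.numeric(pheno_noise_sd),
    sweep_window = if (is.null(sweep_window)) NULL else as.numeric(sweep_window),
    precip_gradient = as.numeric(precip_gradient)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(
    "n_genes", "n_regulators", "n_planted_hubs", "n_targets_per_hub",
    "n_samples_per_condition", "n_accessions", "n_variants"
  )
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L) {
      abort(sprintf("`%s` must be a single count >= 1 (got %s).", f, toString(v)))
    }
  }
  if (cfg$n_de_background < 0L) abort("`n_de_background` must be >= 0.")
  if (cfg$n_planted_hubs > cfg$n_regulators) {
    abort("`n_planted_hubs` cannot exceed `n_regulators`.")
  }
  n_wired <- cfg$n_planted_hubs * cfg$n_targets_per_hub
  if (n_wired + cfg$n_regulators + cfg$n_de_background > cfg$n_genes) {
    abort(sprintf(
      paste0(
        "Sizing error: %d hub targets + %d regulators + %d background DE genes ",
        "exceed n_genes = %d."
      ),
      n_wired, cfg$n_regulators, cfg$n_de_background, cfg$n_genes
    ))
  }
  if (!(cfg$fst > 0 && cfg$fst < 1)) abort("`fst` must lie strictly in (0, 1).")
  if (cfg$h2_polygenic < 0 || cfg$h2_polygenic > 1) {
    abort("`h2_polygenic` must lie in [0, 1].")
  }
  if (abs(cfg$precip_gradient) > 1) abort("`precip_gradient` must lie in [-1, 1].")
  if (length(cfg$conditions) < 2L || cfg$conditions[1] != "control") {
    abort("`conditions` must start with \"control\" and contain >= 1 stress condition.")
  }
  if (cfg$expr_noise_sd < 0 || cfg$dispersion < 0 || cfg$pheno_noise_sd < 0 ||
      cfg$hub_program_sd < 0) {
    abort("noise/dispersion parameters must be nonnegative.")
  }
  if (!is.null(cfg$sweep_window) &&
      (length(cfg$sweep_window) != 2L || diff(cfg$sweep_window) <= 0)) {
    abort("`sweep_window` must be c(start, end) with start < end.")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  seed %d | %d genes (%d regulators, %d planted hubs x %d targets, %d background DE)\n",
    x$seed, x$n_genes, x$n_regulators, x$n_planted_hubs, x$n_targets_per_hub,
    x$n_de_background
  ))
  cat(sprintf(
    "  %s x %d replicates | de_log2fc %.2g, noise sd %.2g\n",
    paste(x$conditions, collapse = "/"), x$n_samples_per_condition,
    x$de_log2fc, x$expr_noise_sd
  ))
  cat(sprintf(
    "  3 groups x %d accessions, %d variants, Fst %.2g, beta %.2g, h2 %.2g, cline %.2g\n",
    x$n_accessions, x$n_variants, x$fst, x$causal_beta, x$h2_polygenic,
    x$precip_gradient
  ))
  invisible(x)
}

# Deterministic child seeds: one per generator, drawn once from the master
# seed so each generator can be rerun in isolation. Kept < 2^31.
child_seeds <- function(seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  names(s) <- c("expression", "genotypes", "phenotypes", "geography",
                "layout", "spare")
  s
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Gene id helpers ------------------------------------------------------------

regulator_ids <- function(n) sprintf("NAC%03d", seq_len(n))
gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Planted ground truth of a synthetic study
#'
#' Created by the generators in this package; records which structures were
#' planted so downstream recovery can be scored.
#'
#' @name sim_truth
#' @format A `sim_truth` object: a list with elements `hub_gene_ids`,
#'   `target_map` (named list hub -> character vector of target ids),
#'   `de_gene_ids` (named list per stress condition), `causal_variant_id`,
#'   `cline_variant_id`, `sweep_window` (c(start, end)), and `gene_map`
#'   (tibble of per-regulator genomic regions).
NULL

new_sim_truth <- function(...) {
  x <- list(...)
  class(x) <- "sim_truth"
  x
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  if (!is.null(x$hub_gene_ids)) {
    cat("  hubs:", paste(x$hub_gene_ids, collapse = ", "), "\n")
  }
  if (!is.null(x$de_gene_ids)) {
    for (cond in names(x$de_gene_ids)) {
      cat(sprintf("  DE under %s: %d genes\n", cond, length(x$de_gene_ids[[cond]])))
    }
  }
  if (!is.null(x$causal_variant_id)) {
    cat("  causal/cline variant:", x$causal_variant_id, "\n")
  }
  if (!is.null(x$sweep_window)) {
    cat(sprintf("  sweep window: %d-%d\n", x$sweep_window[1], x$sweep_window[2]))
  }
  invisible(x)
}

# Merge two partially filled truth objects (expression- and genotype-side).
merge_truth <- function(a, b) {
  out <- a
  for (f in names(b)) if (is.null(out[[f]])) out[[f]] <- b[[f]]
  class(out) <- "sim_truth"
  out
}
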