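#' Simulate drought-tolerance phenotypes on a genotype panel
#'
#' Generates one image-trait value (default trait `"GPAR-R"`, a projected
#' green-area ratio used as a drought-tolerance indicator) per cultivated
#' accession:
#' `y = causal_beta * dosage + u + e`, where `dosage` is the accession's
#' alternate-allele count at the planted causal variant, the polygenic term
#' `u` has covariance `sigma_g^2 * K` with `K` the VanRaden kinship of the
#' panel, and `e` is white noise. Variances are scaled so that
#' `sigma_g^2 = h2_polygenic * pheno_noise_sd^2` and
#' `sigma_e^2 = (1 - h2_polygenic) * pheno_noise_sd^2`; with
#' `h2_polygenic = 0` the non-causal part is i.i.d. normal with standard
#' deviation `pheno_noise_sd`.
#'
#' Phenotypes are produced for the cultivated groups only (the wild group
#' is reserved for the diversity contrast), mirroring studies that
#' phenotype cultivars but not wild relatives.
#'
#' @param panel A [genotype_panel()] containing the causal variant.
#' @param truth A `sim_truth` with `causal_variant_id`.
#' @param config A [sim_config()].
#' @param trait Trait name (default `"GPAR-R"`).
#' @param groups Groups to phenotype (default the cultivated groups).
#' @return A tibble with columns `accession_id`, `trait`, `value`.
#' @export
simulate_phenotypes <- function(panel, truth, config, trait = "GPAR-R",
                                groups = c("japonica", "indica")) {
  stopifnot(inherits(panel, "genotype_panel"))
  validate_sim_config(config)
  cv <- truth$causal_variant_id
  if (is.null(cv) || !cv %in% panel$variants$variant_id) {
    abort("`truth$causal_variant_id` is not present in the panel.")
  }
  keep <- panel$accessions$group %in% groups
  if (!any(keep)) abort("no accessions overlap the requested groups.")
  acc <- panel$accessions$accession_id[keep]

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(child_seeds(config$seed)[["phenotypes"]])

  d <- panel$dosage[cv, acc]
  d[is.na(d)] <- mean(d, na.rm = TRUE)
  n <- length(acc)

  sg2 <- config$h2_polygenic * config$pheno_noise_sd^2
  se2 <- (1 - config$h2_polygenic) * config$pheno_noise_sd^2
  u <- rep(0, n)
  if (sg2 > 0) {
    K <- kinship_matrix(panel_accessions(panel, acc))
    L <- chol(K + diag(1e-6, n))
    u <- sqrt(sg2) * drop(crossprod(L, rnorm(n)))
  }
  e <- rnorm(n, sd = sqrt(se2))
  y <- config$causal_beta * as.numeric(d) + u + e
  tibble(accession_id = acc, trait = trait, value = unname(y))
}
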