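#' Simulate a structured genotype panel with a planted sweep and cline
#'
#' Generates a diploid biallelic panel over the gene regions of the
#' regulator panel, for three population groups: one wild group (`O.ruf`)
#' and two cultivated groups (`japonica`, `indica`). Population structure
#' follows the Balding-Nichols model: each variant has an ancestral
#' frequency `p ~ U(0.1, 0.9)` and each group draws its frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F = fst`, so subgroup
#' frequencies have mean `p` and variance `fst * p * (1 - p)`.
#'
#' Three structures are planted:
#' \describe{
#'   \item{sweep}{inside `sweep_window` (default: the first planted hub's
#'     gene body) cultivated-group frequencies are pushed toward fixation,
#'     so windowed nucleotide diversity of the cultivated groups falls well
#'     below the wild group's in expectation;}
#'   \item{causal variant}{one promoter InDel of the first planted hub,
#'     kept at intermediate frequency, later used by
#'     [simulate_phenotypes()];}
#'   \item{cline}{the causal variant doubles as the cline variant: its
#'     genotypes are drawn through a Gaussian threshold construction tied
#'     to each accession's mean precipitation, calibrated so that
#'     `cor(dosage, precipitation)` is approximately `precip_gradient`.}
#' }
#'
#' Every accession also receives geographic coordinates and a mean annual
#' precipitation value (geography table in `panel$geo`).
#'
#' @param config A [sim_config()].
#' @param truth Optional `sim_truth` from [simulate_expression()]; when
#'   given, hub identities are reused so the causal variant lands in a
#'   planted hub's promoter.
#' @return A list with elements `panel` (a [genotype_panel()]) and `truth`
#'   (a `sim_truth` with `causal_variant_id`, `cline_variant_id`,
#'   `sweep_window` and the `gene_map`).
#' @export
simulate_genotypes <- function(config, truth = NULL) {
  validate_sim_config(config)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  seeds <- child_seeds(config$seed)
  set.seed(seeds[["genotypes"]])

  regs <- regulator_ids(config$n_regulators)
  hubs <- if (!is.null(truth) && !is.null(truth$hub_gene_ids)) {
    truth$hub_gene_ids
  } else {
    regs[seq_len(config$n_planted_hubs)]
  }
  focal_hub <- hubs[1]

  chrom <- "chr06"
  body_len <- 4000
  spacing <- 20000
  promoter_bp <- 3000
  gene_map <- tibble(
    gene_id = regs,
    chrom = chrom,
    body_start = 10000 + (seq_along(regs) - 1L) * spacing,
  ) %>%
    mutate(
      body_end = .data$body_start + body_len - 1,
      start = .data$body_start - promoter_bp
    ) %>%
    select("gene_id", "chrom", "start", "body_start", "body_end")

  sweep_window <- config$sweep_window
  if (is.null(sweep_window)) {
    gm <- gene_map[gene_map$gene_id == focal_hub, ]
    sweep_window <- c(gm$body_start, gm$body_end)
  }
  span <- c(min(gene_map$start), max(gene_map$body_end))
  if (sweep_window[1] < span[1] || sweep_window[2] > span[2]) {
    abort(sprintf(
      "`sweep_window` [%d, %d] lies outside the simulated range [%d, %d].",
      sweep_window[1], sweep_window[2], span[1], span[2]
    ))
  }

  # Variants: an even allocation across gene regions keeps every region
  # testable, positions unique within the panel.
  per_gene <- ceiling(config$n_variants / nrow(gene_map))
  pos <- unlist(lapply(seq_len(nrow(gene_map)), function(i) {
    gm <- gene_map[i, ]
    sample(seq(gm$start, gm$body_end), min(per_gene, gm$body_end - gm$start + 1))
  }))
  pos <- sort(unique(pos))
  if (length(pos) > config$n_variants) {
    pos <- sort(sample(pos, config$n_variants))
  }
  n_v <- length(pos)

  groups <- c("O.ruf", "japonica", "indica")
  acc <- tibble(
    accession_id = sprintf("acc%03d", seq_len(3L * config$n_accessions)),
    group = rep(groups, each = config$n_accessions)
  )
  n_a <- nrow(acc)

  # Geography first: the cline variant is generated conditional on it.
  set.seed(seeds[["geography"]])
  precip <- rnorm(n_a, mean = c(1500, 1200, 1100)[match(acc$group, groups)], sd = 350)
  precip <- pmax(precip, 50)
  lat <- 32 - 10 * scale(precip)[, 1] * 0.4 + rnorm(n_a, sd = 3)
  lon <- runif(n_a, 95, 125)
  geo <- tibble(
    accession_id = acc$accession_id,
    lon = round(lon, 4), lat = round(pmin(pmax(lat, -90), 90), 4),
    precip_mm = round(precip, 1), group = acc$group
  )

  set.seed(seeds[["genotypes"]] %% .Machine$integer.max + 1L)
  anc <- runif(n_v, 0.1, 0.9)
  freq <- sapply(groups, function(g) bn_subpop_freq(anc, config$fst))

  in_sweep <- pos >= sweep_window[1] & pos <= sweep_window[2]
  shrink <- 0.05
  for (g in c("japonica", "indica")) {
    f <- freq[in_sweep, g]
    freq[in_sweep, g] <- ifelse(f < 0.5, f * shrink, 1 - (1 - f) * shrink)
  }

  # Causal promoter InDel of the focal hub, outside the sweep window.
  gm_f <- gene_map[gene_map$gene_id == focal_hub, ]
  prom_idx <- which(pos >= gm_f$start & pos < gm_f$body_start & !in_sweep)
  if (!length(prom_idx)) abort("no promoter variant available for the focal hub.")
  causal_idx <- prom_idx[which.min(abs(pos[prom_idx] - (gm_f$start + gm_f$body_start) / 2))]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_v, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  type <- rep("SNP", n_v)
  ref[causal_idx] <- "A"
  alt[causal_idx] <- "ATTGC"
  type[causal_idx] <- "InDel"

  variants <- tibble(
    variant_id = sprintf("vg06%06d", pos),
    chrom = chrom, pos = pos, ref = ref, alt = alt, type = type
  )

  dosage <- matrix(NA_integer_, n_v, n_a,
                   dimnames = list(variants$variant_id, acc$accession_id))
  for (g in groups) {
    cols <- acc$group == g
    ng <- sum(cols)
    dosage[, cols] <- matrix(
      rbinom(n_v * ng, 2L, rep(freq[, g], ng)), n_v, ng
    )
  }
  dosage[causal_idx, ] <- cline_dosage(
    precip, p = 0.45, rho = config$precip_gradient
  )

  panel <- genotype_panel(variants, dosage, acc, gene_map = gene_map, geo = geo)
  gt <- new_sim_truth(
    causal_variant_id = variants$variant_id[causal_idx],
    cline_variant_id = variants$variant_id[causal_idx],
    sweep_window = sweep_window,
    gene_map = gene_map,
    hub_gene_ids = hubs
  )
  truth <- if (is.null(truth)) gt else merge_truth(truth, gt)
  list(panel = panel, truth = truth)
}

# Balding-Nichols subpopulation frequency: Beta around the ancestral
# frequency p with E = p and Var = fst * p * (1 - p).
bn_subpop_freq <- function(p, fst) {
  rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

# Dosages tied to a covariate through a Gaussian threshold construction.
# A latent u = rho' * z + sqrt(1 - rho'^2) * eps is cut at the Hardy-
# Weinberg quantiles of frequency p; rho' is inflated analytically to
# compensate for the attenuation of thresholding, so cor(dosage, covariate)
# is close to `rho`.
cline_dosage <- function(covariate, p, rho) {
  z <- as.numeric(scale(covariate))
  c1 <- qnorm((1 - p)^2)     # below: dosage 0
  c2 <- qnorm(1 - p^2)       # above: dosage 2
  atten <- (dnorm(c1) + dnorm(c2)) / sqrt(2 * p * (1 - p))
  rho_lat <- max(min(rho / atten, 0.99), -0.99)
  u <- rho_lat * z + sqrt(1 - rho_lat^2) * rnorm(length(z))
  as.integer((u > c1) + (u > c2))
}
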