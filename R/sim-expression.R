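#' Simulate a stress-response expression study with planted hub programs
#'
#' Generates a genes-by-samples count and TPM study emulating a stress
#' transcriptome experiment: a control condition plus stress conditions,
#' a regulator panel in which a few regulators are planted as hubs, and a
#' hub-driven wiring of target genes. Each planted hub carries a latent
#' activity per sample (its stress induction plus a heavy-tailed
#' sample-specific component), each of its targets tracks that activity
#' through a nonzero wiring slope plus independent noise, and additional
#' background stress-responsive genes shift under stress without belonging
#' to any hub program. The differentially expressed submatrix therefore has
#' a low-rank-plus-noise structure with at least one super-Gaussian source
#' per hub, which is what the downstream independent component analysis
#' assumes.
#'
#' Counts are drawn negative-binomially around length-weighted log-normal
#' means (Poisson when `dispersion = 0`), so the differential expression
#' stage is exercised on overdispersed data.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (an [expression_matrix()]) and
#'   `truth` (a `sim_truth` recording hubs, the hub-to-target map and the
#'   per-condition DE gene sets).
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 300,
#'   n_regulators = 8, n_planted_hubs = 2, n_targets_per_hub = 10,
#'   n_de_background = 20))
#' sim$expression
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(child_seeds(config$seed)[["expression"]])

  stresses <- setdiff(config$conditions, "control")
  regs <- regulator_ids(config$n_regulators)
  others <- gene_ids(config$n_genes - config$n_regulators)
  genes <- c(regs, others)

  hubs <- regs[seq_len(config$n_planted_hubs)]
  # Each hub's program is tied to a single stress (cycling through the
  # stress conditions), so programs are condition-separable and the DEG
  # submatrix carries one distinguishable latent source per hub.
  hub_response <- lapply(seq_along(hubs), function(i) {
    stresses[(i - 1L) %% length(stresses) + 1L]
  })
  names(hub_response) <- hubs

  pool <- sample(others)
  n_wired <- config$n_planted_hubs * config$n_targets_per_hub
  target_map <- split(
    pool[seq_len(n_wired)],
    rep(hubs, each = config$n_targets_per_hub)
  )[hubs]
  bg_de <- if (config$n_de_background > 0) {
    pool[n_wired + seq_len(config$n_de_background)]
  } else {
    character(0)
  }

  samples <- tidyr::expand_grid(
    condition = config$conditions,
    replicate = seq_len(config$n_samples_per_condition)
  ) %>%
    mutate(
      variety = "ZH11", stage = "seedling",
      sample_id = sprintf("ZH11_%s_r%d", .data$condition, .data$replicate)
    ) %>%
    select("sample_id", "variety", "condition", "stage", "replicate")
  n_s <- nrow(samples)

  base_mu <- rnorm(length(genes), mean = 5, sd = 1.5)
  names(base_mu) <- genes
  log_expr <- matrix(0, length(genes), n_s, dimnames = list(genes, samples$sample_id))

  # Hub latent activities: condition shift + Laplace sample effect.
  hub_activity <- matrix(0, length(hubs), n_s, dimnames = list(hubs, samples$sample_id))
  for (h in hubs) {
    shift <- config$de_log2fc * as.numeric(samples$condition %in% hub_response[[h]])
    hub_activity[h, ] <- shift + rlaplace(n_s, scale = config$hub_program_sd)
  }

  slopes <- list()
  for (h in hubs) {
    tg <- target_map[[h]]
    sl <- sample(c(-1, 1), length(tg), replace = TRUE) * runif(length(tg), 0.75, 1.25)
    names(sl) <- tg
    slopes[[h]] <- sl
  }

  bg_effect <- matrix(0, length(bg_de), n_s, dimnames = list(bg_de, samples$sample_id))
  bg_response <- stats::setNames(vector("list", length(bg_de)), bg_de)
  for (g in bg_de) {
    resp <- sample(stresses, sample.int(length(stresses), 1L))
    mag <- sample(c(-1, 1), 1L) * config$de_log2fc * runif(1, 0.5, 1)
    bg_effect[g, ] <- mag * as.numeric(samples$condition %in% resp)
    bg_response[[g]] <- if (abs(mag) > 0) resp else character(0)
  }

  for (g in genes) log_expr[g, ] <- base_mu[[g]]
  log_expr[hubs, ] <- log_expr[hubs, , drop = FALSE] + hub_activity
  for (h in hubs) {
    tg <- target_map[[h]]
    log_expr[tg, ] <- log_expr[tg, , drop = FALSE] +
      outer(slopes[[h]], hub_activity[h, ])
  }
  if (length(bg_de)) log_expr[bg_de, ] <- log_expr[bg_de, , drop = FALSE] + bg_effect
  log_expr <- log_expr + matrix(rnorm(length(log_expr), sd = config$expr_noise_sd),
                                nrow(log_expr))

  gene_lengths <- sample(500:3000, length(genes), replace = TRUE)
  names(gene_lengths) <- genes

  abundance <- 2^log_expr
  rate <- abundance * gene_lengths          # reads proportional to length
  lib_size <- 2e6 * runif(n_s, 0.85, 1.15)
  mu <- sweep(rate, 2, lib_size / colSums(rate), `*`)
  counts <- if (config$dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion), nrow(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow(mu))
  }
  dimnames(counts) <- dimnames(mu)

  expr <- expression_matrix(counts, gene_lengths, samples)

  de_gene_ids <- lapply(stresses, function(st) {
    from_hubs <- unlist(lapply(hubs, function(h) {
      if (st %in% hub_response[[h]] && config$de_log2fc != 0) {
        c(h, target_map[[h]])
      } else {
        character(0)
      }
    }))
    from_bg <- bg_de[vapply(bg_response[bg_de], function(r) st %in% r, logical(1))]
    sort(unique(c(from_hubs, from_bg)))
  })
  names(de_gene_ids) <- stresses

  truth <- new_sim_truth(
    hub_gene_ids = hubs,
    target_map = target_map,
    hub_response = hub_response,
    de_gene_ids = de_gene_ids,
    background_de_ids = bg_de
  )
  list(expression = expr, truth = truth)
}

# Laplace (double-exponential) noise; variance = 2 * scale^2.
rlaplace <- function(n, scale = 1) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}
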