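#' Infer a regulator-to-target network by tree-ensemble importance
#'
#' GENIE3-style network inference: for every target gene, a random-forest
#' regression of its (gene-wise Z-transformed) expression on the candidate
#' regulators is fitted, and the importance of the edge regulator -> target
#' is the regulator's share of the forest's total impurity reduction,
#' normalized per target to sum to one. A regulator never predicts itself
#' (no self-edges). Forest hyperparameters follow the original tree-ensemble
#' procedure's defaults: 1000 trees and `mtry = ceiling(sqrt(R))` for `R`
#' candidate regulators.
#'
#' Constant (zero-variance) targets are skipped with a message. Child seeds
#' are derived per target from `seed` and the sorted target names, so runs
#' are reproducible and insensitive to regulator/target input order (up to
#' row order of the edge list).
#'
#' @param expr_z Numeric matrix, genes x samples, typically Z-transformed
#'   TPM (see [zscore_rows()]).
#' @param regulators Character vector of candidate regulator gene ids; at
#'   least two must be present in `expr_z`.
#' @param targets Target gene ids (default: all genes in `expr_z`).
#' @param n_trees Trees per forest (default 1000).
#' @param mtry Predictors sampled per split (default `ceiling(sqrt(R))`).
#' @param seed Integer seed.
#' @param cluster Optional cluster label stored with the edges.
#' @return A tibble with columns `cluster`, `regulator`, `target`,
#'   `importance`; attributes `n_trees` and `seed`.
#' @export
infer_grn <- function(expr_z, regulators, targets = NULL, n_trees = 1000,
                      mtry = NULL, seed = 1, cluster = NA_character_) {
  expr_z <- as.matrix(expr_z)
  if (ncol(expr_z) < 5L) abort("network inference needs >= 5 samples.")
  regulators <- intersect(regulators, rownames(expr_z))
  if (length(regulators) < 2L) {
    abort("need >= 2 regulators present in the expression matrix.")
  }
  if (is.null(targets)) targets <- rownames(expr_z)
  targets <- intersect(targets, rownames(expr_z))
  targets_sorted <- sort(targets)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  tseeds <- sample.int(.Machine$integer.max - 1L, length(targets_sorted))
  names(tseeds) <- targets_sorted

  regulators <- sort(regulators)   # canonical predictor order
  edges <- purrr::map_dfr(targets, function(tg) {
    preds <- setdiff(regulators, tg)
    if (!length(preds)) return(NULL)
    y <- expr_z[tg, ]
    if (var(y) == 0) {
      inform(sprintf("target %s is constant; skipped.", tg))
      return(NULL)
    }
    dat <- as.data.frame(t(expr_z[preds, , drop = FALSE]))
    names(dat) <- preds
    dat$.y <- y
    m <- if (is.null(mtry)) max(1L, ceiling(sqrt(length(preds)))) else
      min(mtry, length(preds))
    rf <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = n_trees, mtry = m, importance = "impurity",
      seed = tseeds[[tg]], num.threads = 1
    )
    imp <- pmax(rf$variable.importance[preds], 0)
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
    tibble(cluster = cluster, regulator = preds, target = tg,
           importance = unname(imp))
  })
  attr(edges, "n_trees") <- n_trees
  attr(edges, "seed") <- seed
  edges
}

#' Infer per-cluster sub-networks
#'
#' Runs [infer_grn()] once per cluster, with the cluster's genes as targets
#' and the full regulator panel as candidate regulators, and pools the
#' edges.
#'
#' @param expr_z Genes x samples matrix (Z-transformed TPM), containing
#'   both the clustered genes and the regulators.
#' @param assignments Tibble from [assign_clusters()] (columns `gene_id`,
#'   `cluster`); unassigned genes are ignored.
#' @inheritParams infer_grn
#' @return Pooled edge tibble as in [infer_grn()].
#' @export
infer_grn_clusters <- function(expr_z, assignments, regulators,
                               n_trees = 1000, mtry = NULL, seed = 1) {
  assignments <- assignments %>% filter(!is.na(.data$cluster))
  if (!nrow(assignments)) abort("no assigned genes to build sub-networks from.")
  cl <- sort(unique(assignments$cluster))
  purrr::map_dfr(cl, function(k) {
    tg <- assignments$gene_id[assignments$cluster == k]
    infer_grn(expr_z, regulators, targets = tg, n_trees = n_trees,
              mtry = mtry, seed = seed + as.integer(k),
              cluster = paste0("C", k))
  })
}

#' Rank regulators by network degree
#'
#' Applies an edge-retention rule to a weighted edge list, counts each
#' regulator's retained out-edges (pooled across clusters), and ranks
#' regulators by degree. A retention rule is required because degree is
#' meaningless on the complete weighted graph; the default keeps each
#' target's `top_e` strongest regulators.
#'
#' @param edges Edge tibble from [infer_grn()]/[infer_grn_clusters()].
#' @param top_e Retain each target's `top_e` most important regulators
#'   (default 5). Ignored when `importance_threshold` is given.
#' @param importance_threshold Alternative rule: retain edges with
#'   importance at or above this value.
#' @return A tibble with columns `regulator`, `degree`, `total_importance`,
#'   `rank`, `retention` (rule used), sorted by rank. Ties in degree are
#'   broken by total retained importance, then lexical id. Per-cluster
#'   degrees are attached as attribute `"by_cluster"`.
#' @export
rank_hubs <- function(edges, top_e = 5, importance_threshold = NULL) {
  if (!nrow(edges)) {
    return(tibble(regulator = character(0), degree = integer(0),
                  total_importance = numeric(0), rank = integer(0),
                  retention = character(0)))
  }
  if (is.null(importance_threshold)) {
    retained <- edges %>%
      group_by(.data$cluster, .data$target) %>%
      arrange(desc(.data$importance), .data$regulator, .by_group = TRUE) %>%
      dplyr::slice_head(n = top_e) %>%
      ungroup()
    rule <- sprintf("top_%d_per_target", top_e)
  } else {
    retained <- edges %>% filter(.data$importance >= importance_threshold)
    rule <- sprintf("importance>=%g", importance_threshold)
  }
  if (!nrow(retained)) {
    return(tibble(regulator = character(0), degree = integer(0),
                  total_importance = numeric(0), rank = integer(0),
                  retention = character(0)))
  }
  by_cluster <- retained %>%
    group_by(.data$cluster, .data$regulator) %>%
    summarise(degree = n(), total_importance = sum(.data$importance),
              .groups = "drop")
  out <- retained %>%
    group_by(.data$regulator) %>%
    summarise(degree = n(), total_importance = sum(.data$importance),
              .groups = "drop") %>%
    arrange(desc(.data$degree), desc(.data$total_importance), .data$regulator) %>%
    mutate(rank = dplyr::row_number(), retention = rule)
  attr(out, "by_cluster") <- by_cluster
  out
}

#' Plot regulator degrees
#'
#' @param x A hub table from [rank_hubs()].
#' @param top Show at most this many regulators (default 20).
#' @return A ggplot bar chart of retained out-degree per regulator.
#' @export
plot_hub_degrees <- function(x, top = 20) {
  df <- head(x, top)
  ggplot2::ggplot(df, ggplot2::aes(
    stats::reorder(.data$regulator, .data$degree), .data$degree
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "retained out-degree")
}
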