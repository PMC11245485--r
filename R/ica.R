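#' FastICA decomposition of a gene-by-sample expression matrix
#'
#' Decomposes a Z-transformed expression matrix into statistically
#' independent components for co-expression clustering: genes are treated
#' as observations of a sample-dimensional signal, the sample covariance is
#' whitened by eigendecomposition, and the fixed-point FastICA iteration
#' with the logcosh contrast extracts `K` maximally non-Gaussian
#' directions. The symmetric (parallel) update is tried first over several
#' random orthogonal initializations; if it stalls, a deflation (one
#' component at a time) fallback runs. Components are canonicalized for
#' reproducibility: ordered by explained variance and sign-fixed so each
#' component's largest-magnitude gene loading is positive; loading columns
#' are scaled to unit norm with the compensating scale moved into the
#' sources.
#'
#' @param X Numeric matrix, genes x samples. For expression input this
#'   should already be gene-wise Z-transformed (see [zscore_rows()]); the
#'   function itself only centers columns before whitening.
#' @param K Number of components (default 9, a typical cluster count for
#'   stress DEG sets); must not exceed `min(dim(X))`.
#' @param seed Integer seed for the random initializations.
#' @param tol Convergence tolerance on the fixed-point update.
#' @param max_iter Iteration cap per restart.
#' @param n_restarts Random restarts of the symmetric iteration before the
#'   deflation fallback.
#' @return An `ica_model`: list with `loadings` (genes x K, unit-norm
#'   columns), `sources` (K x samples), `whitening`, `unmixing`,
#'   `eigenvalues`, `n_components`, `converged`, `iterations`, `method`,
#'   `tol`, `seed`.
#' @examples
#' X <- matrix(rnorm(600), 60, 10)
#' fit <- fastica_decompose(X, K = 3, seed = 1)
#' dim(fit$loadings)
#' @export
fastica_decompose <- function(X, K = 9, seed = 1, tol = 1e-6, max_iter = 500,
                              n_restarts = 5) {
  X <- as.matrix(X)
  G <- nrow(X); S <- ncol(X)
  if (K > min(G, S)) {
    abort(sprintf("K = %d exceeds min(dim(X)) = %d.", K, min(G, S)))
  }
  Xc <- sweep(X, 2, colMeans(X))

  cv <- crossprod(Xc) / (G - 1)
  eg <- eigen(cv, symmetric = TRUE)
  d <- eg$values[seq_len(K)]
  if (any(d < 1e-12)) {
    abort("covariance is rank-deficient at the requested K; lower K.")
  }
  E <- eg$vectors[, seq_len(K), drop = FALSE]
  V <- E %*% diag(1 / sqrt(d), K)        # whitening: Xw = Xc V
  Xw <- Xc %*% V

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  fit <- NULL
  for (r in seq_len(n_restarts)) {
    W0 <- random_orthogonal(K)
    res <- fastica_symmetric(Xw, W0, tol, max_iter)
    if (res$converged) {
      fit <- res
      fit$method <- "symmetric"
      break
    }
    if (is.null(fit) || res$lim < fit$lim) {
      fit <- res
      fit$method <- "symmetric"
    }
  }
  if (!fit$converged) {
    res <- fastica_deflation(Xw, tol, max_iter)
    if (res$converged) {
      fit <- res
      fit$method <- "deflation"
    } else {
      abort(sprintf(
        paste0("FastICA failed to converge: best residual %.3e after %d ",
               "symmetric restarts (max_iter %d) and a deflation pass."),
        min(fit$lim, res$lim), n_restarts, max_iter
      ))
    }
  }
  W <- fit$W

  loadings <- Xw %*% t(W)                         # genes x K, unit variance
  sources <- W %*% diag(sqrt(d), K) %*% t(E)      # K x samples

  # Canonical order and signs.
  ord <- order(rowSums(sources^2), decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  sources <- sources[ord, , drop = FALSE]
  W <- W[ord, , drop = FALSE]
  for (k in seq_len(K)) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      sources[k, ] <- -sources[k, ]
      W[k, ] <- -W[k, ]
    }
  }
  nrm <- sqrt(colSums(loadings^2))
  loadings <- sweep(loadings, 2, nrm, `/`)
  sources <- sweep(sources, 1, nrm, `*`)

  rownames(loadings) <- rownames(X)
  colnames(loadings) <- paste0("IC", seq_len(K))
  rownames(sources) <- paste0("IC", seq_len(K))
  colnames(sources) <- colnames(X)

  structure(
    list(
      loadings = loadings, sources = sources, whitening = V, unmixing = W,
      eigenvalues = eg$values, n_components = K, converged = fit$converged,
      iterations = fit$iterations, method = fit$method, tol = tol, seed = seed
    ),
    class = "ica_model"
  )
}

random_orthogonal <- function(K) {
  qr.Q(qr(matrix(rnorm(K * K), K)))
}

# Symmetric fixed-point iteration, logcosh contrast (alpha = 1).
fastica_symmetric <- function(Xw, W, tol, max_iter) {
  G <- nrow(Xw)
  lim <- Inf
  for (it in seq_len(max_iter)) {
    Y <- Xw %*% t(W)
    gy <- tanh(Y)
    gpy <- 1 - gy^2
    W1 <- crossprod(gy, Xw) / G - diag(colMeans(gpy), ncol(W)) %*% W
    W1 <- sym_decorrelate(W1)
    lim <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (lim < tol) {
      return(list(W = W, converged = TRUE, iterations = it, lim = lim))
    }
  }
  list(W = W, converged = FALSE, iterations = max_iter, lim = lim)
}

# Deflation: extract components one at a time with Gram-Schmidt.
fastica_deflation <- function(Xw, tol, max_iter) {
  K <- ncol(Xw); G <- nrow(Xw)
  W <- matrix(0, K, K)
  total_it <- 0L
  for (k in seq_len(K)) {
    w <- rnorm(K); w <- w / sqrt(sum(w^2))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      y <- drop(Xw %*% w)
      gy <- tanh(y)
      w1 <- drop(crossprod(Xw, gy)) / G - mean(1 - gy^2) * w
      if (k > 1) {
        Wp <- W[seq_len(k - 1), , drop = FALSE]
        w1 <- w1 - drop(crossprod(Wp, Wp %*% w1))
      }
      w1 <- w1 / sqrt(sum(w1^2))
      lim <- abs(abs(sum(w1 * w)) - 1)
      w <- w1
      total_it <- total_it + 1L
      if (lim < tol) { ok <- TRUE; break }
    }
    if (!ok) return(list(W = W, converged = FALSE, iterations = total_it, lim = lim))
    W[k, ] <- w
  }
  list(W = W, converged = TRUE, iterations = total_it, lim = 0)
}

sym_decorrelate <- function(W) {
  sv <- eigen(W %*% t(W), symmetric = TRUE)
  K <- nrow(W)
  sv$vectors %*% diag(1 / sqrt(pmax(sv$values, 1e-12)), K) %*%
    t(sv$vectors) %*% W
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf(
    "<ica_model> K = %d over %d genes x %d samples; %s, %s in %d iterations\n",
    x$n_components, nrow(x$loadings), ncol(x$sources), x$method,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Assign genes to independent components
#'
#' Each gene goes to the component with its largest absolute loading,
#' provided that loading is an outlier within its component: the absolute
#' loadings of each component are standardized (mean 0, sd 1 within the
#' column) and the gene is assigned only when the standardized value at its
#' argmax exceeds `z_cut`; otherwise it stays unassigned (`NA`). Ties take
#' the lowest component index. The rule is declared, threshold-exposed and
#' logged in the result rather than inferred from any reference analysis.
#'
#' @param model An `ica_model` from [fastica_decompose()].
#' @param z_cut Threshold on the column-standardized absolute loading
#'   (default 2).
#' @return A tibble with columns `gene_id`, `cluster` (integer or `NA`),
#'   `loading` (signed loading at the assigned/argmax component),
#'   `abs_loading`, `z` (standardized |loading| at the argmax).
#' @export
assign_clusters <- function(model, z_cut = 2) {
  stopifnot(inherits(model, "ica_model"))
  L <- model$loadings
  A <- abs(L)
  Z <- scale(A)
  k_star <- max.col(A, ties.method = "first")
  idx <- cbind(seq_len(nrow(A)), k_star)
  z_at <- Z[idx]
  tibble(
    gene_id = rownames(L),
    cluster = ifelse(z_at > z_cut, k_star, NA_integer_),
    loading = L[idx],
    abs_loading = A[idx],
    z = as.numeric(z_at)
  )
}

#' @exportS3Method generics::tidy
tidy.ica_model <- function(x, ...) {
  as_tibble(x$loadings, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "component", values_to = "loading")
}

#' @exportS3Method generics::glance
glance.ica_model <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    n_genes = nrow(x$loadings),
    n_samples = ncol(x$sources),
    converged = x$converged,
    iterations = x$iterations,
    method = x$method,
    tol = x$tol,
    seed = x$seed
  )
}

#' Plot component source activities across samples
#'
#' @param object An `ica_model`.
#' @param ... Unused.
#' @return A ggplot: per-component source value by sample.
#' @exportS3Method ggplot2::autoplot
autoplot.ica_model <- function(object, ...) {
  df <- as_tibble(object$sources, rownames = "component") %>%
    tidyr::pivot_longer(-"component", names_to = "sample", values_to = "activity")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$activity, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "source activity")
}
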