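#' VanRaden kinship matrix
#'
#' Estimates accession-by-accession genetic relatedness from a dosage
#' matrix: dosages are mean-imputed per variant, centered by twice the
#' allele frequency, and `K = W'W / (2 * sum(p * (1 - p)))` over the
#' polymorphic variants. The result is symmetric and positive
#' semi-definite by construction, with diagonal near `1 + f` (inbreeding).
#'
#' @param panel A [genotype_panel()] or a variants x accessions dosage
#'   matrix.
#' @return A `kinship_matrix` (numeric matrix with accession dimnames and
#'   attribute `construction = "vanraden"`).
#' @export
kinship_matrix <- function(panel) {
  dos <- if (inherits(panel, "genotype_panel")) panel$dosage else as.matrix(panel)
  if (ncol(dos) < 2L) abort("kinship needs >= 2 accessions.")
  dos <- impute_row_means(dos)
  p <- rowMeans(dos) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("no polymorphic variants; kinship undefined.")
  Z <- dos[poly, , drop = FALSE] - 2 * p[poly]
  K <- crossprod(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  K <- (K + t(K)) / 2
  attr(K, "construction") <- "vanraden"
  class(K) <- c("kinship_matrix", class(K))
  K
}

impute_row_means <- function(dos) {
  miss <- is.na(dos)
  if (any(miss)) {
    rm <- rowMeans(dos, na.rm = TRUE)
    rm[is.nan(rm)] <- 0
    dos[miss] <- rm[row(dos)[miss]]
  }
  dos
}

#' Fit the null polygenic mixed model by REML
#'
#' Fits `y = X b + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood, using the
#' spectral trick: one eigendecomposition of `S K S` (with `S` the
#' projection removing the fixed effects) reduces the restricted likelihood
#' to a one-dimensional profile in `delta = sigma_e^2 / sigma_g^2`, which
#' is maximized over `log(delta)` in \[-10, 10\] by golden-section search
#' plus an endpoint check. The eigendecomposition of `K` itself is cached
#' for the fixed-ratio association scan.
#'
#' @param y Numeric phenotype vector (complete), length n >= 10, named by
#'   accession when `K` carries dimnames.
#' @param K A [kinship_matrix()] (n x n, aligned with `y`).
#' @param X Fixed-effect design matrix (default: intercept only).
#' @return A `null_model_fit`: list with `sigma_g2`, `sigma_e2`, `delta`,
#'   `h2` (= sigma_g2 / (sigma_g2 + sigma_e2)), `loglik` (restricted),
#'   `eig_K` (values/vectors of K), `X`, `y`, `n`, `p`, `accessions`.
#' @export
fit_null_reml <- function(y, K, X = NULL) {
  n <- length(y)
  if (n < 10L) abort("null model needs >= 10 phenotyped accessions.")
  if (any(!is.finite(y))) abort("`y` must be complete and finite.")
  K <- as.matrix(K)
  if (!all(dim(K) == n)) abort("`K` must be n x n aligned with `y`.")
  if (max(abs(K - t(K))) > 1e-10) abort("`K` must be symmetric.")
  if (!is.null(names(y)) && !is.null(colnames(K)) &&
      !identical(names(y), colnames(K))) {
    abort("names(y) and dimnames(K) disagree; align accessions first.")
  }
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)

  eig_K <- eigen(K, symmetric = TRUE)
  if (min(eig_K$values) < -1e-6 * max(abs(eig_K$values))) {
    abort("`K` is not positive semi-definite (large negative eigenvalue).")
  }
  eig_K$values <- pmax(eig_K$values, 1e-9)

  # Restricted profile on the eigenbasis of S K S.
  XtXi <- solve(crossprod(X))
  SK <- K - X %*% (XtXi %*% crossprod(X, K))
  SKS <- SK - (SK %*% X) %*% (XtXi %*% t(X))
  SKS <- (SKS + t(SKS)) / 2
  eg <- eigen(SKS, symmetric = TRUE)
  m <- n - p
  xi <- pmax(eg$values[seq_len(m)], 0)
  U <- eg$vectors[, seq_len(m), drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2

  rll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- xi + delta
    0.5 * (m * (log(m / (2 * pi)) - 1 - log(sum(eta2 / w))) - sum(log(w)))
  }
  opt <- optimize(rll, interval = c(-10, 10), maximum = TRUE, tol = 1e-8)
  cands <- rbind(
    c(opt$maximum, opt$objective),
    c(-10, rll(-10)),
    c(10, rll(10))
  )
  best <- cands[which.max(cands[, 2]), ]
  delta <- exp(best[1])
  loglik <- best[2]
  if (!is.finite(loglik)) abort("non-finite restricted likelihood.")
  sigma_g2 <- sum(eta2 / (xi + delta)) / m
  sigma_e2 <- delta * sigma_g2

  structure(
    list(
      sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
      h2 = 1 / (1 + delta), loglik = loglik,
      eig_K = eig_K, X = X, y = y, n = n, p = p,
      accessions = names(y)
    ),
    class = "null_model_fit"
  )
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf(
    "<null_model_fit> n = %d | sigma_g2 = %.4g, sigma_e2 = %.4g (h2 = %.3f), REML LL = %.3f\n",
    x$n, x$sigma_g2, x$sigma_e2, x$h2, x$loglik
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.null_model_fit <- function(x, ...) {
  tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, delta = x$delta,
         h2 = x$h2, loglik = x$loglik, n = x$n)
}

#' Region-based mixed-model association scan
#'
#' Tests each variant in a region for association with the phenotype under
#' the polygenic mixed model, holding the variance ratio `delta` fixed at
#' its null-model estimate (the fixed-ratio "P3D/EMMAX" approximation, the
#' default behavior of standard MLM software). Phenotype, covariates and
#' genotypes are rotated into the eigenbasis of `K`, whitened by
#' `(lambda_i + delta)^(-1/2)`, and the genotype term is tested by an
#' F-test with `(1, n - p - 1)` degrees of freedom. P-values are invariant
#' to location/scale changes of the phenotype.
#'
#' Monomorphic variants are reported with p = 1 and never flagged;
#' variants with minor-allele frequency below `maf` (but > 0) are dropped.
#' With `exact = TRUE` the variance ratio is re-estimated per variant by
#' REML with the genotype as an extra fixed effect (slow; intended for
#' cross-checks).
#'
#' @param panel A [genotype_panel()].
#' @param pheno Tibble with `accession_id` and `value` columns (or a named
#'   numeric vector).
#' @param null A [fit_null_reml()] fit on the same accessions, in order.
#' @param region Optional `c(start, end)` or `"chrom:start-end"` to
#'   restrict the scan (gene body + promoter of a candidate, typically).
#' @param threshold Significance threshold on the p-value (default 1e-4).
#' @param maf Minor-allele-frequency filter (default 0.05).
#' @param exact Re-estimate the variance ratio per variant (default FALSE).
#' @return An `association_scan` tibble: `variant_id`, `chrom`, `pos`,
#'   `maf`, `beta`, `Fstat`, `pvalue`, `significant`; attributes
#'   `threshold`, `delta`, `n`.
#' @export
scan_region <- function(panel, pheno, null, region = NULL, threshold = 1e-4,
                        maf = 0.05, exact = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(null, "null_model_fit"))
  if (is.data.frame(pheno)) {
    y <- stats::setNames(pheno$value, pheno$accession_id)
  } else {
    y <- pheno
  }
  acc <- names(y)
  if (is.null(acc)) abort("`pheno` must name its accessions.")
  if (!all(acc %in% panel$accessions$accession_id)) {
    abort("phenotyped accessions missing from the panel.")
  }
  if (!is.null(null$accessions) && !identical(acc, null$accessions)) {
    abort("null model was fitted on different accessions (or a different order).")
  }
  sub <- if (is.null(region)) panel else panel_region(panel, region)
  if (!nrow(sub$variants)) {
    out <- tibble(variant_id = character(0), chrom = character(0),
                  pos = numeric(0), maf = numeric(0), beta = numeric(0),
                  Fstat = numeric(0), pvalue = numeric(0),
                  significant = logical(0))
    return(annotate_scan(out, threshold, null$delta, length(y)))
  }
  G <- impute_row_means(sub$dosage[, acc, drop = FALSE])
  p_freq <- rowMeans(G) / 2
  mafs <- pmin(p_freq, 1 - p_freq)
  novar <- apply(G, 1, function(g) var(g) == 0)
  keep <- novar | mafs >= maf     # no-variance rows kept, reported with p = 1
  vs <- sub$variants[keep, , drop = FALSE]
  G <- G[keep, , drop = FALSE]
  mafs <- mafs[keep]
  mono <- novar[keep]

  n <- length(y)
  U <- null$eig_K$vectors
  w <- 1 / sqrt(null$eig_K$values + null$delta)
  ys <- w * drop(crossprod(U, y))
  Xs <- w * crossprod(U, null$X)
  Q <- qr.Q(qr(Xs))
  ry <- ys - Q %*% crossprod(Q, ys)
  df2 <- n - null$p - 1

  beta <- Fstat <- pvalue <- rep(NA_real_, nrow(vs))
  if (any(!mono)) {
    Ts <- w * crossprod(U, t(G[!mono, , drop = FALSE]))   # n x V
    RG <- Ts - Q %*% crossprod(Q, Ts)
    gg <- colSums(RG^2)
    gy <- drop(crossprod(RG, ry))
    b <- gy / gg
    rss0 <- sum(ry^2)
    rss1 <- pmax(rss0 - gy^2 / gg, 0)
    Fv <- (rss0 - rss1) / (rss1 / df2)
    pv <- pf(Fv, 1, df2, lower.tail = FALSE)
    beta[!mono] <- b
    Fstat[!mono] <- Fv
    pvalue[!mono] <- pv
  }
  beta[mono] <- 0
  Fstat[mono] <- 0
  pvalue[mono] <- 1

  if (exact && any(!mono)) {
    K <- U %*% (null$eig_K$values * t(U))
    for (i in which(!mono)) {
      fx <- fit_null_reml(y, K, X = cbind(null$X, G[i, ]))
      wi <- 1 / sqrt(null$eig_K$values + fx$delta)
      ysi <- wi * drop(crossprod(U, y))
      Xsi <- wi * crossprod(U, cbind(null$X, G[i, ]))
      X0i <- wi * crossprod(U, null$X)
      r1 <- stats::lsfit(Xsi, ysi, intercept = FALSE)$residuals
      r0 <- stats::lsfit(X0i, ysi, intercept = FALSE)$residuals
      rss1 <- sum(r1^2); rss0 <- sum(r0^2)
      Fstat[i] <- (rss0 - rss1) / (rss1 / df2)
      pvalue[i] <- pf(Fstat[i], 1, df2, lower.tail = FALSE)
      beta[i] <- stats::lsfit(Xsi, ysi, intercept = FALSE)$coefficients[null$p + 1]
    }
  }

  out <- tibble(
    variant_id = vs$variant_id, chrom = vs$chrom, pos = vs$pos,
    maf = unname(mafs), beta = beta, Fstat = Fstat, pvalue = pvalue,
    significant = pvalue < threshold
  )
  annotate_scan(out, threshold, null$delta, n)
}

annotate_scan <- function(out, threshold, delta, n) {
  attr(out, "threshold") <- threshold
  attr(out, "delta") <- delta
  attr(out, "n") <- n
  class(out) <- c("association_scan", class(out))
  out
}

#' Manhattan-style plot of an association scan
#'
#' @param object An `association_scan` from [scan_region()].
#' @param ... Unused.
#' @return A ggplot of -log10 p by position, with the significance
#'   threshold drawn as a dashed line.
#' @exportS3Method ggplot2::autoplot
autoplot.association_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(.data$pos, -log10(.data$pvalue))) +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant), show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10] * " p"))
}

#' Pairwise linkage disequilibrium (R-squared)
#'
#' Composite LD on unphased genotypes: `R^2(i, j)` is the squared Pearson
#' correlation of the two variants' dosage vectors, missing entries
#' dropped pairwise. Monomorphic variants have undefined LD and are
#' reported as `NA`; polymorphic diagonals are 1.
#'
#' @param panel A [genotype_panel()] or dosage matrix (variants x
#'   accessions).
#' @param region Optional region restriction as in [panel_region()].
#' @return A symmetric `ld_matrix` (variants x variants) of R-squared
#'   values in \[0, 1\].
#' @export
ld_r2 <- function(panel, region = NULL) {
  if (inherits(panel, "genotype_panel")) {
    if (!is.null(region)) panel <- panel_region(panel, region)
    dos <- panel$dosage
  } else {
    dos <- as.matrix(panel)
  }
  if (nrow(dos) < 2L) abort("LD needs >= 2 variants.")
  sds <- apply(dos, 1, sd, na.rm = TRUE)
  r <- suppressWarnings(cor(t(dos), use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[sds == 0, ] <- NA_real_
  r2[, sds == 0] <- NA_real_
  diag(r2)[sds > 0] <- 1
  class(r2) <- c("ld_matrix", class(r2))
  r2
}
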