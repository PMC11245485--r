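# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no data files.

# Tiny genotype panel from a dosage matrix (variants x accessions).
toy_panel <- function(dosage, pos = NULL, groups = NULL, chrom = "chr06") {
  n_v <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(n_v) * 10L
  ids <- sprintf("vg06%06d", pos)
  dimnames(dosage) <- list(ids, sprintf("acc%03d", seq_len(ncol(dosage))))
  variants <- tibble::tibble(
    variant_id = ids, chrom = chrom, pos = as.integer(pos),
    ref = "A", alt = "C", type = "SNP"
  )
  accessions <- tibble::tibble(
    accession_id = colnames(dosage),
    group = if (is.null(groups)) NA_character_ else groups
  )
  genotype_panel(variants, dosage, accessions)
}

# Brute-force BH step-up: explicit enumeration of the rule.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force windowed pi: explicit enumeration of all allele pairs.
# Each diploid contributes two alleles; per site, pi is the mean pairwise
# difference over all C(n, 2) allele pairs; the window value is the site
# sum over the window length.
pi_oracle <- function(dosage, window_len) {
  per_site <- apply(dosage, 1, function(g) {
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 2) return(0)
    diffs <- 0
    for (i in seq_len(n - 1)) {
      diffs <- diffs + sum(alleles[i] != alleles[(i + 1):n])
    }
    diffs / choose(n, 2)
  })
  sum(per_site) / window_len
}

# All permutations of 1..k (k small).
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]))
  }))
}

# Best min |Pearson r| between estimated and true sources over
# permutations (sign handled by the absolute value).
matched_min_cor <- function(est, tru) {
  K <- ncol(tru)
  P <- all_perms(seq_len(K))
  best <- 0
  for (i in seq_len(nrow(P))) {
    r <- vapply(seq_len(K), function(k) {
      abs(stats::cor(est[, k], tru[, P[i, k]]))
    }, numeric(1))
    best <- max(best, min(r))
  }
  best
}

# Naive generalized-least-squares F-test: builds V = sg2 K + se2 I and
# tests the genotype term by explicit matrix inversion. Oracle for the
# spectral association scan on small n.
gls_oracle_p <- function(y, X, g, K, sg2, se2) {
  n <- length(y)
  V <- sg2 * K + se2 * diag(n)
  Vi <- solve(V)
  X1 <- cbind(X, g)
  b1 <- solve(t(X1) %*% Vi %*% X1, t(X1) %*% Vi %*% y)
  r1 <- y - X1 %*% b1
  rss1 <- drop(t(r1) %*% Vi %*% r1)
  b0 <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r0 <- y - X %*% b0
  rss0 <- drop(t(r0) %*% Vi %*% r0)
  df2 <- n - ncol(X1)
  f <- (rss0 - rss1) / (rss1 / df2)
  stats::pf(f, 1, df2, lower.tail = FALSE)
}

# Small expression study with planted DE genes for DEG power checks:
# two groups of n reps, `n_de` genes shifted by lfc in log2 space.
toy_de_study <- function(seed, n_genes = 2000, n_de = 50, lfc = 3,
                         noise_sd = 0.2, n_rep = 6) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  de <- sample(genes, n_de)
  samples <- tibble::tibble(
    sample_id = c(sprintf("s_control_%d", seq_len(n_rep)),
                  sprintf("s_drought_%d", seq_len(n_rep))),
    variety = "ZH11",
    condition = rep(c("control", "drought"), each = n_rep),
    stage = "seedling",
    replicate = rep(seq_len(n_rep), 2)
  )
  mu <- stats::rnorm(n_genes, 6, 1)
  logx <- matrix(mu, n_genes, 2 * n_rep) +
    matrix(stats::rnorm(n_genes * 2 * n_rep, sd = noise_sd), n_genes)
  logx[match(de, genes), samples$condition == "drought"] <-
    logx[match(de, genes), samples$condition == "drought"] + lfc
  lens <- sample(500:2000, n_genes, replace = TRUE)
  counts <- matrix(stats::rpois(length(logx), lambda = 2^logx), n_genes,
                   dimnames = list(genes, samples$sample_id))
  expr <- expression_matrix(counts, stats::setNames(lens, genes), samples)
  list(expr = expr, de = de)
}
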