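test_that("TPM normalization matches hand-computed values", {
  # single expressed gene takes the whole million
  one <- matrix(5L, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(unname(tpm_normalize(one, c(g1 = 800))[1, 1]), 1e6)
  # two genes, equal counts, 2x length ratio -> 2:1 TPM split
  two <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- tpm_normalize(two, c(a = 1000, b = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # all-zero sample is undefined
  z <- matrix(c(1L, 0L, 0L, 0L), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(tpm_normalize(z, c(a = 100, b = 100)), "all-zero")
})

test_that("bh_adjust equals the explicit step-up enumeration", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone when re-sorted by p
  p <- runif(100)
  q <- bh_adjust(p)
  expect_false(is.unsorted(q[order(p)]))
  expect_error(bh_adjust(c(0.2, 1.4)), "outside")
})

test_that("DEG calling is near-silent under a seeded global null", {
  study <- toy_de_study(seed = 41, n_genes = 2000, n_de = 0)
  degs <- call_degs(study$expr, c("drought", "control"))
  expect_lte(nrow(degs) / 2000, 0.01)
})

test_that("planted twofold+ effects are recovered with controlled FDR", {
  # power checked against the generating model: lfc 3 >> threshold 1,
  # noise sd 0.2 with 6v6 replicates
  study <- toy_de_study(seed = 42, n_genes = 2000, n_de = 50, lfc = 3,
                        noise_sd = 0.2, n_rep = 6)
  degs <- call_degs(study$expr, c("drought", "control"))
  sens <- mean(study$de %in% degs$gene_id)
  fdp <- mean(!degs$gene_id %in% study$de)
  expect_gte(sens, 0.95)
  expect_lte(fdp, 0.05)
  expect_true(all(abs(degs$log2fc) > 1))
  expect_true(all(degs$padj < 0.05))
  expect_true(all(degs$direction == ifelse(degs$log2fc >= 0, "up", "down")))
})

test_that("DEG calling is invariant to gene and sample ordering", {
  study <- toy_de_study(seed = 43, n_genes = 300, n_de = 20)
  expr <- study$expr
  g_perm <- sample(nrow(expr$counts))
  s_perm <- sample(ncol(expr$counts))
  expr2 <- expression_matrix(
    expr$counts[g_perm, s_perm], expr$gene_lengths[g_perm],
    expr$samples[s_perm, ]
  )
  a <- dplyr::arrange(call_degs(expr, c("drought", "control")), gene_id)
  b <- dplyr::arrange(call_degs(expr2, c("drought", "control")), gene_id)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("degenerate DEG inputs are handled as documented", {
  study <- toy_de_study(seed = 44, n_genes = 50, n_de = 0)
  expect_error(call_degs(study$expr, c("salt", "control")), "salt")
  # zero variance in both groups -> p = 1, still adjusted
  counts <- matrix(100L, 4, 8,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:8), variety = "v", stage = "st",
    condition = rep(c("control", "drought"), each = 4),
    replicate = rep(1:4, 2)
  )
  expr <- expression_matrix(counts, stats::setNames(rep(1000, 4), paste0("g", 1:4)),
                            samples)
  tab <- call_degs(expr, c("drought", "control"), filter = FALSE)
  expect_true(all(tab$pvalue == 1))
})
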