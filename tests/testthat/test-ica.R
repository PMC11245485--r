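test_that("whitening produces identity covariance and a faithful reconstruction", {
  set.seed(51)
  X <- matrix(rnorm(500 * 12), 500, 12,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:12)))
  fit <- fastica_decompose(X, K = 5, seed = 1)
  Xc <- sweep(X, 2, colMeans(X))
  Xw <- Xc %*% fit$whitening
  expect_lt(max(abs(crossprod(Xw) / (nrow(X) - 1) - diag(5))), 1e-8)
  # loadings %*% sources equals the projection of Xc on the top-K PC space
  E <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)$vectors[, 1:5]
  proj <- Xc %*% E %*% t(E)
  expect_lt(max(abs(fit$loadings %*% fit$sources - proj)), 1e-6)
  expect_equal(unname(sqrt(colSums(fit$loadings^2))), rep(1, 5), tolerance = 1e-9)
})

test_that("K = 1 degenerates to the first principal direction", {
  set.seed(52)
  X <- matrix(rnorm(300 * 8), 300, 8)
  X[, 1:4] <- X[, 1:4] + rnorm(300) * 2   # dominant direction
  fit <- fastica_decompose(X, K = 1, seed = 3)
  Xc <- sweep(X, 2, colMeans(X))
  pc1 <- prcomp(Xc, center = FALSE)$x[, 1]
  expect_gt(abs(cor(fit$loadings[, 1], pc1)), 0.999)
  asg <- assign_clusters(fit, z_cut = -Inf)
  expect_true(all(asg$cluster == 1))
})

test_that("planted Laplacian sources are recovered up to permutation and sign", {
  ok <- 0
  for (s in 1:8) {
    set.seed(600 + s)
    S <- matrix(rexp(2000 * 3) * sample(c(-1, 1), 6000, TRUE), 2000, 3)
    A <- matrix(rnorm(3 * 10), 3, 10)
    X <- S %*% A + matrix(rnorm(20000, sd = 0.05), 2000)
    fit <- fastica_decompose(X, K = 3, seed = s)
    if (matched_min_cor(fit$loadings, S) > 0.95) ok <- ok + 1
  }
  expect_gte(ok, 7)
})

test_that("decomposition is seed-deterministic and stable across seeds", {
  set.seed(53)
  S <- matrix(rexp(1500 * 3) * sample(c(-1, 1), 4500, TRUE), 1500, 3)
  X <- S %*% matrix(rnorm(24), 3, 8) + matrix(rnorm(1500 * 8, sd = 0.05), 1500)
  a <- fastica_decompose(X, K = 3, seed = 9)
  b <- fastica_decompose(X, K = 3, seed = 9)
  expect_identical(a$loadings, b$loadings)
  c <- fastica_decompose(X, K = 3, seed = 10)
  expect_gt(matched_min_cor(a$loadings, c$loadings), 0.9)
})

test_that("cluster assignment follows the thresholded argmax rule", {
  set.seed(54)
  L <- matrix(rnorm(200 * 3, sd = 0.02), 200, 3)
  L[1, ] <- c(0, 0, 0.9)      # clear member of component 3
  L[2, ] <- c(0, 0, 0)        # featureless row
  fake <- structure(list(loadings = L), class = "ica_model")
  rownames(fake$loadings) <- paste0("g", 1:200)
  asg <- assign_clusters(fake, z_cut = 2)
  expect_identical(asg$cluster[1], 3L)
  expect_true(is.na(asg$cluster[2]))
})

test_that("hub-module expression yields pure co-assigned clusters", {
  cfg <- sim_config(seed = 55, n_genes = 2000, n_regulators = 10,
                    n_planted_hubs = 2, n_targets_per_hub = 20,
                    n_de_background = 300, hub_program_sd = 1)
  sim <- simulate_expression(cfg)
  degs <- call_degs_all(sim$expression)
  deg_genes <- unique(degs$gene_id)
  z <- zscore_rows(log2(sim$expression$tpm + 1))[deg_genes, ]
  fit <- fastica_decompose(z, K = 4, seed = 1)
  asg <- assign_clusters(fit, z_cut = 2)
  for (h in sim$truth$hub_gene_ids) {
    tg <- intersect(sim$truth$target_map[[h]], deg_genes)
    cl <- asg$cluster[match(tg, asg$gene_id)]
    cl <- cl[!is.na(cl)]
    expect_gte(length(cl) / length(tg), 0.9)         # targets are assigned
    expect_gte(max(table(cl)) / length(tg), 0.9)     # and to one component
  }
})

test_that("rank-deficient requests and tidiers behave", {
  X <- matrix(rnorm(40 * 6), 40, 6)
  expect_error(fastica_decompose(X, K = 7, seed = 1), "exceeds")
  fit <- fastica_decompose(X, K = 2, seed = 1)
  td <- tidy(fit)
  expect_named(td, c("gene_id", "component", "loading"))
  expect_equal(nrow(td), 80)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_components, 2)
})
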