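test_that("kinship identifies duplicates and is symmetric PSD", {
  set.seed(71)
  dos <- matrix(rbinom(200 * 6, 2, 0.4), 200, 6)
  dos[, 2] <- dos[, 1]   # duplicated accession
  dimnames(dos) <- list(paste0("v", 1:200), paste0("a", 1:6))
  K <- kinship_matrix(dos)
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-10)
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # unrelated accessions at HWE: off-diagonals shrink to zero
  set.seed(72)
  big <- matrix(rbinom(3000 * 40, 2, rep(runif(3000, 0.1, 0.9), 40)), 3000, 40)
  dimnames(big) <- list(paste0("v", 1:3000), paste0("a", 1:40))
  K2 <- kinship_matrix(big)
  # sample-frequency centering leaves a small negative O(1/n) bias
  expect_lt(abs(mean(K2[upper.tri(K2)])), 1.5 / 39)
  expect_lt(mean(abs(K2[upper.tri(K2)])), 0.05)
  expect_error(kinship_matrix(matrix(2, 5, 3)), "polymorphic")
})

test_that("with identity kinship the mixed model reduces to OLS", {
  set.seed(73)
  n <- 60
  dos <- matrix(rbinom(40 * n, 2, 0.3), 40, n)
  panel <- toy_panel(dos)
  y <- stats::setNames(rnorm(n), colnames(panel$dosage))
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  nf <- fit_null_reml(y, K)
  expect_equal(nf$sigma_g2 + nf$sigma_e2, var(y), tolerance = 0.05 * var(y))
  sc <- scan_region(panel, y, nf, maf = 0.01)
  ols <- vapply(sc$variant_id, function(v) {
    g <- panel$dosage[v, ]
    if (sd(g) == 0) return(1)
    stats::anova(stats::lm(y ~ g))[1, "Pr(>F)"]
  }, numeric(1))
  expect_lt(max(abs(sc$pvalue - ols)), 1e-8)
})

test_that("REML optimum beats every grid value of the variance ratio", {
  set.seed(74)
  n <- 80
  dos <- matrix(rbinom(300 * n, 2, rep(runif(300, .1, .9), n)), 300, n)
  dimnames(dos) <- list(paste0("v", 1:300), paste0("a", 1:n))
  K <- kinship_matrix(dos)
  eK <- eigen(K, symmetric = TRUE)
  L <- eK$vectors %*% diag(sqrt(pmax(eK$values, 0)))
  y <- stats::setNames(drop(L %*% rnorm(n)) + rnorm(n, sd = 0.7), colnames(K))
  nf <- fit_null_reml(y, K)
  X <- matrix(1, n, 1)
  XtXi <- solve(crossprod(X))
  SK <- K - X %*% (XtXi %*% crossprod(X, K))
  SKS <- SK - (SK %*% X) %*% (XtXi %*% t(X))
  eg <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
  xi <- pmax(eg$values[seq_len(n - 1)], 0)
  eta2 <- drop(crossprod(eg$vectors[, seq_len(n - 1)], y))^2
  rll <- function(ld) {
    w <- xi + exp(ld)
    0.5 * ((n - 1) * (log((n - 1) / (2 * pi)) - 1 - log(sum(eta2 / w))) - sum(log(w)))
  }
  grid <- vapply(seq(-10, 10, length.out = 50), rll, numeric(1))
  expect_gte(nf$loglik + 1e-6, max(grid))
})

test_that("the spectral scan agrees with naive GLS on small instances", {
  set.seed(75)
  n <- 40
  dos <- matrix(rbinom(25 * n, 2, rep(runif(25, .2, .8), n)), 25, n)
  panel <- toy_panel(dos)
  Kfull <- kinship_matrix(matrix(rbinom(500 * n, 2, rep(runif(500, .1, .9), n)),
                                 500, n,
                                 dimnames = list(paste0("w", 1:500),
                                                 colnames(panel$dosage))))
  y <- stats::setNames(rnorm(n), colnames(panel$dosage))
  nf <- fit_null_reml(y, Kfull)
  sc <- scan_region(panel, y, nf, maf = 0.01)
  X <- matrix(1, n, 1)
  for (i in seq_len(nrow(sc))) {
    if (sc$maf[i] == 0) next
    g <- panel$dosage[sc$variant_id[i], ]
    p_oracle <- gls_oracle_p(y, X, g, Kfull, nf$sigma_g2, nf$sigma_e2)
    expect_equal(sc$pvalue[i], p_oracle, tolerance = 1e-8)
  }
})

test_that("scan p-values ignore phenotype location and scale", {
  set.seed(76)
  n <- 50
  dos <- matrix(rbinom(30 * n, 2, 0.4), 30, n)
  panel <- toy_panel(dos)
  Kd <- kinship_matrix(matrix(rbinom(400 * n, 2, rep(runif(400, .1, .9), n)),
                              400, n,
                              dimnames = list(paste0("w", 1:400),
                                              colnames(panel$dosage))))
  y <- stats::setNames(rnorm(n), colnames(panel$dosage))
  a <- scan_region(panel, y, fit_null_reml(y, Kd), maf = 0.01)
  y2 <- 5 * y + 11
  b <- scan_region(panel, y2, fit_null_reml(y2, Kd), maf = 0.01)
  expect_lt(max(abs(a$pvalue - b$pvalue)), 1e-10)
})

test_that("monomorphic variants report p = 1 and never flag", {
  dos <- rbind(rep(2, 20), rbinom(20, 2, 0.5))
  panel <- toy_panel(dos)
  dosK <- matrix(rbinom(200 * 20, 2, rep(runif(200, .1, .9), 20)), 200, 20,
                 dimnames = list(paste0("w", 1:200), colnames(panel$dosage)))
  y <- stats::setNames(rnorm(20), colnames(panel$dosage))
  nf <- fit_null_reml(y, kinship_matrix(dosK))
  sc <- scan_region(panel, y, nf, maf = 0.01)
  i <- which(sc$maf == 0)
  expect_length(i, 1)
  expect_equal(sc$pvalue[i], 1)
  expect_false(sc$significant[i])
})

test_that("LD matrix matches its closed forms", {
  set.seed(77)
  g <- rbinom(100, 2, 0.4)
  dup <- rbind(g, g, 2 - g, rbinom(100, 2, 0.5))
  r2 <- ld_r2(dup)
  expect_equal(r2[1, 2], 1, tolerance = 1e-12)   # duplicate
  expect_equal(r2[1, 3], 1, tolerance = 1e-12)   # perfect repulsion
  expect_true(all(diag(r2) == 1))
  # monomorphic variants are undefined
  mono <- rbind(rep(2, 30), rbinom(30, 2, .5), rbinom(30, 2, .5))
  r2m <- ld_r2(mono)
  expect_true(all(is.na(r2m[1, ])))
  expect_false(anyNA(r2m[2:3, 2:3]))
  # independence: mean off-diagonal R2 ~ 1/(n-1)
  set.seed(78)
  n <- 500
  ind <- matrix(rbinom(30 * n, 2, rep(runif(30, .2, .8), n)), 30, n)
  r2i <- ld_r2(ind)
  off <- r2i[upper.tri(r2i)]
  expect_lt(abs(mean(off) - 1 / (n - 1)), 0.35 / (n - 1))
})
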