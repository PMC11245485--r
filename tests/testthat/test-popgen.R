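test_that("windowed pi matches the hand example and the pairwise oracle", {
  # one site, two diploids with dosages (0, 2): p = .5, n = 4 alleles,
  # pi_site = (4/3) * 2 * .5 * .5 = 2/3; per 200-bp window: 1/300
  dos <- matrix(c(0L, 2L), 1, 2)
  panel <- toy_panel(dos, pos = 50, groups = c("g1", "g1"))
  prof <- windowed_pi(panel, "g1", region = c(1, 200), window = 200)
  expect_equal(prof$pi, (4 / 3) * 0.5 / 200, tolerance = 1e-12)
  expect_equal(prof$n_sites, 1L)

  # random toy windows against explicit allele-pair enumeration, exact
  set.seed(81)
  for (i in 1:100) {
    n_d <- sample(2:10, 1)
    n_s <- sample(1:20, 1)
    dos <- matrix(rbinom(n_s * n_d, 2, runif(1, .05, .95)), n_s, n_d)
    if (runif(1) < 0.3) dos[sample(length(dos), 2)] <- NA
    panel <- toy_panel(dos, pos = sort(sample(1:200, n_s)),
                       groups = rep("g1", n_d))
    prof <- windowed_pi(panel, "g1", region = c(1, 200), window = 200)
    expect_equal(prof$pi, pi_oracle(dos, 200), tolerance = 1e-12)
  }
})

test_that("pi is invariant under allele relabeling and zero when monomorphic", {
  set.seed(82)
  dos <- matrix(rbinom(10 * 8, 2, 0.3), 10, 8)
  panel <- windowed_pi(toy_panel(dos, groups = rep("g1", 8)), "g1",
                       region = c(1, 200), window = 200)
  flipped <- windowed_pi(toy_panel(2L - dos, groups = rep("g1", 8)), "g1",
                         region = c(1, 200), window = 200)
  expect_equal(panel$pi, flipped$pi, tolerance = 1e-12)
  mono <- toy_panel(matrix(0L, 5, 6), groups = rep("g1", 6))
  expect_equal(windowed_pi(mono, "g1", region = c(1, 200))$pi, 0)
  expect_error(windowed_pi(mono, "absent"), "absent")
})

test_that("sweep contrast flags pushed regions, not identical groups", {
  set.seed(83)
  n <- 30
  wild <- matrix(rbinom(60 * n, 2, rep(runif(60, .2, .8), n)), 60, n)
  groups3 <- c(rep("O.ruf", 10), rep("japonica", 10), rep("indica", 10))
  # identical distributions -> no sweep
  panel <- toy_panel(wild, pos = sort(sample(1:2000, 60)), groups = groups3)
  prof <- dplyr::bind_rows(lapply(c("O.ruf", "japonica", "indica"), function(g) {
    windowed_pi(panel, g, region = c(1, 2000))
  }))
  sw <- sweep_contrast(prof)
  expect_false(any(sw$sweep))
  # cultivated columns pushed to fixation -> sweep in both groups
  pushed <- wild
  pushed[, groups3 != "O.ruf"] <- 0L
  panel2 <- toy_panel(pushed, pos = sort(sample(1:2000, 60)), groups = groups3)
  prof2 <- dplyr::bind_rows(lapply(c("O.ruf", "japonica", "indica"), function(g) {
    windowed_pi(panel2, g, region = c(1, 2000))
  }))
  sw2 <- sweep_contrast(prof2)
  expect_true(all(sw2$sweep))
  # monotonicity: the pushed panel's flagged fraction dominates
  expect_true(all(sw2$frac_below >= sw$frac_below))
})

test_that("uninformative windows are excluded and can make the call indeterminate", {
  dos <- matrix(0L, 4, 9)   # wild invariant everywhere
  dos[, 4:9] <- rbinom(24, 2, .5)
  panel <- toy_panel(dos, pos = c(10, 50, 120, 180),
                     groups = c(rep("O.ruf", 3), rep("japonica", 3),
                                rep("indica", 3)))
  prof <- dplyr::bind_rows(lapply(c("O.ruf", "japonica", "indica"), function(g) {
    windowed_pi(panel, g, region = c(1, 200))
  }))
  sw <- sweep_contrast(prof)
  expect_true(all(is.na(sw$sweep)))
  expect_true(all(sw$n_informative == 0))
})

test_that("genotype-class trait test matches t.test and its limits", {
  set.seed(84)
  y <- stats::setNames(rnorm(40), paste0("a", 1:40))
  cl <- stats::setNames(rep(c("InDel+", "InDel-"), 20), names(y))
  res <- genotype_group_test(y, cl)
  ref <- t.test(y[cl == "InDel+"], y[cl == "InDel-"])
  expect_equal(res$pvalue, ref$p.value, tolerance = 1e-12)
  # separation limit: distinct means, vanishing variance
  y2 <- stats::setNames(c(rep(0, 5), rep(1, 5)) + rnorm(10, sd = 1e-4),
                        paste0("a", 1:10))
  cl2 <- stats::setNames(rep(c("A", "B"), each = 5), names(y2))
  expect_lt(genotype_group_test(y2, cl2)$pvalue, 1e-10)
  expect_error(genotype_group_test(y[1:3], cl[1:3]), ">= 2")
})

test_that("null class labels give uniform group-test p-values", {
  set.seed(85)
  ps <- replicate(400, {
    y <- stats::setNames(rnorm(30), paste0("a", 1:30))
    cl <- stats::setNames(sample(rep(c("A", "B"), 15)), names(y))
    genotype_group_test(y, cl)$pvalue
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("z-score normalization is exact and guarded", {
  expect_equal(zscore_normalize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(86)
  x <- rnorm(50, 10, 3)
  z <- zscore_normalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore_normalize(5), ">= 2")
  expect_error(zscore_normalize(rep(2, 4)), "variance")
})

test_that("precipitation association flags planted clines, not nulls", {
  set.seed(87)
  # null: class independent of precipitation; flag rate ~ alpha
  flags <- replicate(300, {
    geo <- tibble::tibble(accession_id = paste0("a", 1:60),
                          precip_mm = rnorm(60, 1200, 300))
    cl <- stats::setNames(sample(rep(c("C", "N"), 30)), geo$accession_id)
    precipitation_association(geo, cl, alpha = 0.05)$flagged
  })
  expect_lt(abs(mean(flags) - 0.05), 0.04)
  # planted gradient through the generator: flag true, carriers wetter
  cfg <- sim_config(seed = 88, n_accessions = 60, n_variants = 600,
                    precip_gradient = 0.6)
  sg <- simulate_genotypes(cfg)
  d <- sg$panel$dosage[sg$truth$cline_variant_id, ]
  cl <- stats::setNames(ifelse(d > 0, "carrier", "noncarrier"), names(d))
  pa <- precipitation_association(sg$panel$geo, cl, alpha = 0.01)
  expect_true(pa$flagged)
  wet_carrier <- ifelse(pa$class1 == "carrier", pa$mean_precip1, pa$mean_precip2)
  dry_non <- ifelse(pa$class1 == "carrier", pa$mean_precip2, pa$mean_precip1)
  expect_gt(wet_carrier, dry_non)
  # degenerate: one class only
  cl1 <- stats::setNames(rep("carrier", length(d)), names(d))
  expect_error(precipitation_association(sg$panel$geo, cl1), "two classes")
})
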