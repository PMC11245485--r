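test_that("a perfect predictor dominates its target's importances", {
  set.seed(61)
  n_s <- 30
  regs <- matrix(rnorm(5 * n_s), 5, n_s,
                 dimnames = list(paste0("NAC00", 1:5), paste0("s", 1:n_s)))
  target <- regs["NAC003", ] + rnorm(n_s, sd = 1e-6)
  X <- rbind(regs, t1 = target)
  edges <- infer_grn(X, rownames(regs), targets = "t1", n_trees = 300, seed = 1)
  top <- edges$regulator[which.max(edges$importance)]
  expect_identical(top, "NAC003")
  imp <- sort(edges$importance, decreasing = TRUE)
  expect_gt(imp[1], 0.5)
  expect_gt(imp[1], 3 * imp[2])
})

test_that("per-target importances are normalized shares", {
  set.seed(62)
  X <- matrix(rnorm(8 * 25), 8, 25,
              dimnames = list(c(paste0("NAC00", 1:4), paste0("g", 1:4)),
                              paste0("s", 1:25)))
  edges <- infer_grn(X, paste0("NAC00", 1:4), n_trees = 200, seed = 2)
  sums <- tapply(edges$importance, edges$target, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_false(any(edges$regulator == edges$target))   # no self-edges
})

test_that("identical seeds reproduce importances; regulator order is irrelevant", {
  set.seed(63)
  X <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(c(paste0("NAC00", 1:5), paste0("g", 1:3)),
                              paste0("s", 1:20)))
  regs <- paste0("NAC00", 1:5)
  a <- infer_grn(X, regs, targets = paste0("g", 1:3), n_trees = 200, seed = 5)
  b <- infer_grn(X, regs, targets = paste0("g", 1:3), n_trees = 200, seed = 5)
  expect_identical(a$importance, b$importance)
  c <- infer_grn(X, rev(regs), targets = paste0("g", 1:3), n_trees = 200, seed = 5)
  key <- function(e) e[order(e$regulator, e$target), c("regulator", "target", "importance")]
  expect_equal(key(a), key(c), tolerance = 1e-12)
})

test_that("hub ranking counts retained out-edges with documented tie-breaks", {
  edges <- tibble::tibble(
    cluster = "C1",
    regulator = c("A", "A", "B"),
    target = c("t1", "t2", "t1"),
    importance = c(0.6, 0.7, 0.4)
  )
  hubs <- rank_hubs(edges, top_e = 5)
  expect_identical(hubs$regulator, c("A", "B"))
  expect_identical(hubs$degree, c(2L, 1L))
  # retention: only each target's top-1 regulator
  hubs1 <- rank_hubs(edges, top_e = 1)
  expect_identical(hubs1$degree[hubs1$regulator == "A"], 2L)
  expect_false("B" %in% hubs1$regulator)
  # empty edge lists give an empty table
  expect_equal(nrow(rank_hubs(edges[0, ])), 0)
})

test_that("a planted hub earns the top degree against decoys", {
  wins <- 0
  for (s in 1:6) {
    set.seed(700 + s)
    n_s <- 30
    hub_act <- rnorm(n_s)
    regs <- rbind(hub_act, matrix(rnorm(5 * n_s), 5))
    rownames(regs) <- paste0("NAC00", 1:6)
    slopes <- runif(20, 0.75, 1.25) * sample(c(-1, 1), 20, TRUE)
    tg <- outer(slopes, hub_act) + matrix(rnorm(20 * n_s, sd = 0.5), 20)
    rownames(tg) <- paste0("g", 1:20)
    X <- zscore_rows(rbind(regs, tg))
    edges <- infer_grn(X, rownames(regs), targets = rownames(tg),
                       n_trees = 500, seed = s)
    hubs <- rank_hubs(edges, top_e = 2)
    if (hubs$regulator[1] == "NAC001") wins <- wins + 1
  }
  expect_gte(wins, 5)
})

test_that("degenerate networks are rejected or skipped as documented", {
  X <- matrix(rnorm(4 * 10), 4, 10,
              dimnames = list(c("NAC001", "NAC002", "g1", "g2"), paste0("s", 1:10)))
  expect_error(infer_grn(X, "NAC001"), ">= 2 regulators")
  expect_error(infer_grn(X[, 1:3], c("NAC001", "NAC002")), ">= 5 samples")
  Xc <- X
  Xc["g1", ] <- 1   # constant target is skipped
  expect_message(
    edges <- infer_grn(Xc, c("NAC001", "NAC002"), targets = c("g1", "g2"),
                       n_trees = 100, seed = 1),
    "constant"
  )
  expect_false("g1" %in% edges$target)
})
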