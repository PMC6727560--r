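test_that("similarity is the absolute Pearson correlation", {
  set.seed(1)
  v <- rnorm(20)
  X <- rbind(a = v, b = v, c = -v, d = rnorm(20))
  colnames(X) <- paste0("s", 1:20)
  S <- similarity(X)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], 1)          # unsigned network
  expect_true(all(S >= 0 & S <= 1 + 1e-12))
  expect_equal(S, t(S))
  X2 <- rbind(X, e = rep(2, 20))
  expect_error(similarity(X2), "zero-variance.*e")
})

test_that("null similarity matches the folded-normal expectation", {
  set.seed(42)
  n <- 1000
  X <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(paste0("g", 1:40), NULL))
  S <- similarity(X)
  null_mean <- mean(S[upper.tri(S)])
  expect_equal(null_mean, sqrt(2 / pi) / sqrt(n), tolerance = 0.2)
})

test_that("scale_free_fit returns exactly 1 on analytically constructed degrees", {
  # ten log-spaced degree clusters whose counts follow an exact power law:
  # points at 3 * 2^(j-1) with counts 2^(10-j) are colinear in log-log
  k <- rep(3 * 2^(0:9), times = 2^(10:1))
  fit <- scale_free_fit(k, nbins = 10)
  expect_equal(fit$r2, 1.0, tolerance = 1e-9)
  expect_lt(fit$slope, 0)
  expect_error(scale_free_fit(rep(2, 50)), "degenerate")
})

test_that("pick_soft_threshold is deterministic and rejects flat networks", {
  sim <- simulate_bulk_panel(n_genes = 150, module_size = 40, seed = 8)
  S <- similarity(sim$matrix)
  p1 <- suppressWarnings(pick_soft_threshold(S))
  p2 <- suppressWarnings(pick_soft_threshold(S))
  expect_identical(p1$beta, p2$beta)
  expect_identical(dim(p1$fit_table), c(20L, 4L))
  ident <- matrix(1, 30, 30)
  expect_error(pick_soft_threshold(ident), "identical")
  expect_error(pick_soft_threshold(S, powers = 5), ">= 2 candidate")
})

test_that("adjacency is the elementwise power with zero diagonal", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  A <- adjacency(S, 10)
  expect_equal(A[1, 2], 0.0009765625)    # 0.5^10
  expect_equal(diag(A), c(0, 0))
  expect_equal(adjacency(S, 1)[1, 2], 0.5)
  Sc <- matrix(1, 3, 3)
  expect_equal(adjacency(Sc, 7)[1, 2], 1)
  expect_error(adjacency(S, 0), "beta")
})

test_that("tom reproduces hand-computed cases", {
  A3 <- matrix(0.5, 3, 3); diag(A3) <- 0
  expect_equal(tom(A3)[1, 2], 0.5)       # (0.25 + 0.5) / (1 + 1 - 0.5)
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(tom(A2)[1, 2], 1)         # (0 + 1) / (1 + 1 - 1)
  A0 <- matrix(0, 4, 4)
  expect_true(all(tom(A0)[upper.tri(A0)] == 0))
})

test_that("tom equals the brute-force oracle on random matrices", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    A <- matrix(runif(n * n), n, n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    T1 <- tom(A)
    expect_equal(T1, tom_oracle(A), tolerance = 1e-12)
    expect_lt(max(abs(T1 - t(T1))), 1e-10)   # symmetry preserved
    expect_true(all(T1 >= 0 & T1 <= 1 + 1e-12))
  }
})

test_that("average-linkage clustering separates clean blocks at the top", {
  T <- matrix(0.1, 6, 6)
  T[1:3, 1:3] <- 0.9; T[4:6, 4:6] <- 0.9; diag(T) <- 1
  dimnames(T) <- list(paste0("g", 1:6), paste0("g", 1:6))
  dend <- cluster_genes(T)
  expect_true(all(diff(dend$height) >= -1e-12))
  top <- cutree(dend, k = 2)
  expect_identical(unname(top), rep(1:2, each = 3))
  # two genes: single merge at 1 - T12
  T2 <- matrix(c(1, 0.7, 0.7, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(cluster_genes(T2)$height, 0.3)
  expect_error(cluster_genes(T2[1, 1, drop = FALSE]), ">= 2 genes")
})

test_that("cut_modules honours min_size and labels small clusters unassigned", {
  block_tom <- function(sizes) {
    n <- sum(sizes)
    T <- matrix(0.1, n, n)
    at <- cumsum(c(0, sizes))
    for (i in seq_along(sizes)) {
      idx <- (at[i] + 1):at[i + 1]
      T[idx, idx] <- 0.9
    }
    diag(T) <- 1
    dimnames(T) <- list(paste0("g", 1:n), paste0("g", 1:n))
    T
  }
  labels <- cut_modules(cluster_genes(block_tom(c(60, 60))), min_size = 50)
  expect_identical(as.integer(sort(table(labels))), c(60L, 60L))
  expect_false("unassigned" %in% labels)
  labels2 <- cut_modules(cluster_genes(block_tom(c(60, 40))), min_size = 50)
  expect_identical(sum(labels2 == "unassigned"), 40L)
  expect_identical(sum(labels2 != "unassigned"), 60L)
  expect_warning(
    l3 <- cut_modules(cluster_genes(block_tom(c(10, 10))), min_size = 50),
    "min_size")
  expect_true(all(l3 == "unassigned"))
  expect_error(cut_modules(cluster_genes(block_tom(c(10, 10))), min_size = 1),
               "min_size")
})

test_that("module eigengene is the oriented first principal component", {
  set.seed(2)
  v <- rnorm(10)
  X <- rbind(a = 2 * v + 1, b = -3 * v, c = v + rnorm(10, sd = 1e-6))
  colnames(X) <- paste0("s", 1:10)
  e <- module_eigengene(X, c("a", "b", "c"))
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
  expect_equal(abs(cor(e, v)), 1, tolerance = 1e-4)
  # orientation: mean correlation with members is nonnegative even with
  # anti-correlated members
  Z <- t(scale(t(X)))
  expect_gte(mean(cor(e, t(Z))), 0)
  expect_error(module_eigengene(X, c("a", "zz")), "missing: zz")
})

test_that("eigengene recovers the planted latent factor", {
  rec <- sapply(1:20, function(s) {
    sim <- simulate_bulk_panel(n_genes = 150, n_biased = 0, module_size = 50,
                               r_module = 0.85, seed = s)
    e <- module_eigengene(sim$matrix, sim$truth$module_genes)
    abs(cor(e, sim$truth$latent))
  })
  expect_true(all(rec >= 0.9))
})

test_that("merge_close_modules merges duplicates and respects the cut", {
  set.seed(6)
  u <- rnorm(12); v <- rnorm(12)
  X <- rbind(matrix(rep(u, 4), 4, byrow = TRUE) + rnorm(48, sd = 0.01),
             matrix(rep(u, 4), 4, byrow = TRUE) + rnorm(48, sd = 0.01),
             matrix(rep(v, 4), 4, byrow = TRUE) + rnorm(48, sd = 0.01))
  rownames(X) <- paste0("g", 1:12); colnames(X) <- paste0("s", 1:12)
  labels <- setNames(rep(c("m1", "m2", "m3"), each = 4), rownames(X))
  merged <- merge_close_modules(X, labels, merge_cut = 0.25)
  expect_identical(length(unique(merged)), 2L)          # m1 and m2 collapse
  expect_identical(unname(merged[1:8]), rep(merged[[1]], 8))
  expect_identical(unique(merged[9:12]), "m3")
  expect_error(merge_close_modules(X, labels, merge_cut = 0), "\\(0, 1\\)")
})

test_that("module-trait correlation handles exact and orthogonal eigengenes", {
  sex <- rep(c(0, 1), each = 6)
  e1 <- as.numeric(scale(sex)); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(rep(c(-1, 1), 3), rep(c(1, -1), 3)); e2 <- e2 / sqrt(sum(e2^2))
  E <- cbind(m1 = e1, m2 = e2)
  tc <- module_trait_correlation(E, sex)
  expect_equal(tc$r, c(1, 0), tolerance = 1e-12)
  expect_lt(tc$p[1], 1e-10)
  expect_error(module_trait_correlation(E, rep(1, 12)), "constant")
})

test_that("planted module-sex correlation is recovered near its target", {
  rs <- sapply(1:50, function(s) {
    sim <- simulate_bulk_panel(n_genes = 60, n_biased = 0, module_size = 30,
                               r_module = 0.85, seed = 100 + s)
    e <- module_eigengene(sim$matrix, sim$truth$module_genes)
    abs(cor(e, as.numeric(sim$matrix$samples$sex == "female")))
  })
  expect_lt(abs(median(rs) - 0.85), 0.15)
})

test_that("significance computes GS and MS with the p = 0 cap", {
  p <- c(g1 = 0.01, g2 = 1, g3 = 0.1, g4 = 0.001, g5 = 0)
  labels <- setNames(c("blue", "blue", "red", "red", "red"), names(p))
  res <- significance(p, labels)
  expect_equal(res$gs$gs[1:2], c(2, 0))
  expect_equal(res$ms$ms[res$ms$module == "red"], mean(c(1, 3, 300)))
  expect_true(res$gs$capped[5])
  expect_error(significance(c(g = -0.1), labels), "\\[0, 1\\]")
})

test_that("permuting the trait destroys module-trait correlation", {
  sim <- simulate_bulk_panel(n_genes = 80, n_biased = 0, module_size = 30,
                             r_module = 0, seed = 17)
  e <- module_eigengene(sim$matrix, sim$truth$module_genes)
  sex <- as.numeric(sim$matrix$samples$sex == "female")
  obs <- abs(cor(e, sex))
  set.seed(99)
  perm <- replicate(199, abs(cor(e, sample(sex))))
  p_perm <- (1 + sum(perm >= obs)) / 200
  expect_gt(p_perm, 0.05)
})
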