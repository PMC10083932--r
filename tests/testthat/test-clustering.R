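test_that("Bray-Curtis matches hand calculations and handles edge cases", {
  expect_equal(bray_curtis(rbind(c(1, 0, 1), c(0, 1, 1)))[1, 2], 0.5)
  expect_equal(bray_curtis(rbind(c(0.3, 0.7), c(0.3, 0.7)))[1, 2], 0)
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 1)))[1, 2], 1)
  Z <- rbind(c(0, 0), c(0, 0), c(1, 1))
  DZ <- bray_curtis(Z)
  expect_equal(DZ[1, 2], 0)          # both profiles empty
  expect_equal(DZ[1, 3], 1)
  expect_error(bray_curtis(rbind(c(-1, 0), c(0, 1))), "non-negative")
  set.seed(2)
  X <- matrix(runif(40), 8)
  D <- bray_curtis(X)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 8))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("UPGMA merges at size-weighted average distances", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- upgma(D2)
  expect_equal(h2$height, 0.4)

  D3 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  D3["A", "B"] <- D3["B", "A"] <- 0.1
  D3["A", "C"] <- D3["C", "A"] <- 0.4
  D3["B", "C"] <- D3["C", "B"] <- 0.6
  h3 <- upgma(D3)
  expect_equal(h3$height, c(0.1, 0.5))   # (0.4 + 0.6) / 2

  # exact recovery of ultrametric distances
  DU <- manual_ultrametric()
  CU <- as.matrix(stats::cophenetic(upgma(DU)))
  expect_equal(CU[rownames(DU), colnames(DU)], DU, tolerance = 1e-10)

  # monotone heights for arbitrary random distance matrices
  set.seed(29)
  for (i in 1:20) {
    m <- sample(4:12, 1)
    M <- matrix(runif(m * m), m); M <- (M + t(M)) / 2; diag(M) <- 0
    expect_true(all(diff(upgma(M)$height) >= -1e-12))
  }
})

test_that("cutting the dendrogram yields the connected components", {
  D3 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  D3["A", "B"] <- D3["B", "A"] <- 0.1
  D3["A", "C"] <- D3["C", "A"] <- 0.4
  D3["B", "C"] <- D3["C", "B"] <- 0.6
  h3 <- upgma(D3)
  cl <- cut_dendrogram(h3, height = 0.3)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_false(cl[["A"]] == cl[["C"]])
  expect_equal(length(unique(cut_dendrogram(h3, height = 0))), 3)
  expect_equal(length(unique(cut_dendrogram(h3, height = 1))), 1)
})

test_that("the elbow rule recovers planted cluster counts", {
  set.seed(1)
  X2 <- rbind(matrix(rnorm(40, 0, 0.01), 20), matrix(rnorm(40, 1, 0.01), 20))
  expect_equal(select_k(X2, 1:6, seed = 5)$k, 2)
  X1 <- matrix(1, 10, 3)
  expect_equal(select_k(X1, 1:5, seed = 5)$k, 1)
  set.seed(2)
  X3 <- rbind(matrix(rnorm(40, 0, 0.05), 20), matrix(rnorm(40, 1, 0.05), 20),
              matrix(rnorm(40, 2, 0.05), 20))
  ks <- select_k(X3, 1:8, seed = 6)
  expect_equal(ks$k, 3)
  expect_length(ks$wss, length(ks$k_range))
  expect_true(all(diff(ks$wss) <= 1e-8))
})

test_that("PERMANOVA pseudo-F matches its definition and brute-force enumeration", {
  # 4 points, 2 groups, hand-made distances
  D <- matrix(c(0, 1, 4, 4,
                1, 0, 4, 4,
                4, 4, 0, 1,
                4, 4, 1, 0), 4, 4)
  lab <- c("g1", "g1", "g2", "g2")
  res <- permanova(D, lab, n_perm = 499, seed = 1)
  m <- 4; g <- 2
  ss_total <- sum(D[upper.tri(D)]^2) / m
  ss_within <- (1^2) / 2 + (1^2) / 2
  f_hand <- ((ss_total - ss_within) / (g - 1)) / (ss_within / (m - g))
  expect_equal(res$pseudo_F, f_hand, tolerance = 1e-12)

  # exact p by enumerating all 4! label permutations
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(z) length(unique(z)) == 4), ]
  f_of <- function(ord) {
    dl <- lab[order(ord)]
    grp <- split(1:4, dl)
    ssw <- sum(vapply(grp, function(ix)
      sum(D[ix, ix]^2) / (2 * length(ix)), numeric(1)))
    ((ss_total - ssw) / (g - 1)) / (ssw / (m - g))
  }
  fs <- apply(perms, 1, f_of)
  p_exact <- mean(fs >= f_hand - 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 0.05)

  # reproducible under a fixed seed; invariant to relabeling group identities
  res2 <- permanova(D, lab, n_perm = 499, seed = 1)
  expect_identical(res$p_value, res2$p_value)
  res3 <- permanova(D, c("x", "x", "y", "y"), n_perm = 499, seed = 1)
  expect_equal(res3$pseudo_F, res$pseudo_F)
  expect_identical(res3$p_value, res$p_value)
  expect_error(permanova(D, rep("g", 4)), "2 groups")
})

test_that("PERMANOVA agrees with an independent implementation", {
  set.seed(31)
  Y <- matrix(runif(60), 12)
  lab <- rep(c("a", "b", "c"), each = 4)
  D <- as.matrix(dist(Y))
  mine <- permanova(D, lab, n_perm = 199, seed = 2)
  ref <- vegan::adonis2(stats::as.dist(D) ~ grp,
                        data = data.frame(grp = factor(lab)),
                        permutations = 499)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-9)
  expect_lt(abs(mine$p_value - ref$`Pr(>F)`[1]), 0.25)
})

test_that("pairwise PERMANOVA reports raw and step-down adjusted p per pair", {
  set.seed(37)
  Y <- rbind(matrix(rnorm(20, 0, 0.2), 10), matrix(rnorm(20, 2, 0.2), 10),
             matrix(rnorm(20, 4, 0.2), 10))
  lab <- rep(1:3, each = 10)
  pw <- pairwise_permanova(dist(Y), lab, n_perm = 199, seed = 3)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-12))
  expect_true(all(pw$p_raw <= 0.05))   # strongly separated groups
})

test_that("PCA explains variance with sign-fixed orthonormal loadings", {
  set.seed(41)
  a <- rnorm(30)
  X <- cbind(a, a, rnorm(30, sd = 1e-8))
  p <- pca_traits(X)
  expect_gt(p$variance_explained[1], 99.99)

  b <- rnorm(500)
  Y <- cbind(b + rnorm(500, sd = 0.02), b + rnorm(500, sd = 0.02))
  p2 <- pca_traits(Y)
  expect_equal(abs(p2$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 0.01)

  Z <- matrix(rnorm(100), 20)
  p3 <- pca_traits(Z)
  expect_true(all(p3$variance_explained >= 0))
  expect_true(all(diff(p3$variance_explained) <= 1e-10))
  expect_equal(sum(p3$variance_explained), 100)
  expect_equal(t(p3$loadings) %*% p3$loadings, diag(ncol(Z)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(vapply(seq_len(ncol(Z)), function(j) {
    l <- p3$loadings[, j]; l[which.max(abs(l))] > 0
  }, TRUE)))
})
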