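test_that("trimming preserves root-to-tip path lengths", {
  tr <- yule_tree(12, seed = 51)
  expect_equal(ape::Ntip(trim_tree(tr, tr$tip.label)), 12)
  expect_error(trim_tree(tr, c("sp1", "nothere")), "nothere")

  two <- trim_tree(tr, c("sp1", "sp7"))
  full_d <- ape::cophenetic.phylo(tr)["sp1", "sp7"]
  expect_equal(ape::cophenetic.phylo(two)["sp1", "sp7"], full_d,
               tolerance = 1e-9)
  expect_true(ape::is.ultrametric(trim_tree(tr, paste0("sp", 1:6)), tol = 1e-8))
})

test_that("grafting attaches at the sister midpoint and keeps tips contemporaneous", {
  tr <- yule_tree(10, seed = 53)
  height <- max(ape::node.depth.edgelength(tr))
  g <- graft_missing(tr, "newsp", "sp4")
  expect_true("newsp" %in% g$tip.label)
  d <- ape::node.depth.edgelength(g)
  expect_equal(d[match("newsp", g$tip.label)], height, tolerance = 1e-8)
  expect_true(ape::is.ultrametric(g, tol = 1e-6))

  # new tip joins sp4 halfway down sp4's subtending branch
  bl <- tr$edge.length[tr$edge[, 2] == match("sp4", tr$tip.label)]
  expect_equal(ape::cophenetic.phylo(g)["newsp", "sp4"],
               bl / 2 + (height - (ape::node.depth.edgelength(tr)[
                 match("sp4", tr$tip.label)] - bl / 2)), tolerance = 1e-8)

  # pre-existing pairwise distances untouched
  old <- ape::cophenetic.phylo(tr)
  new <- ape::cophenetic.phylo(g)[rownames(old), colnames(old)]
  expect_equal(new, old, tolerance = 1e-9)

  # graft then trim restores the original tree's distances
  back <- trim_tree(g, tr$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[rownames(old), colnames(old)], old,
               tolerance = 1e-9)
})

test_that("lambda scales only the shared path lengths", {
  tr <- yule_tree(8, seed = 57)
  C1 <- phylo_covariance(tr, 1)
  expect_equal(C1, ape::vcv(tr))
  C0 <- phylo_covariance(tr, 0)
  expect_equal(C0[upper.tri(C0)], rep(0, sum(upper.tri(C0))))
  expect_equal(diag(C0), diag(C1))
  Ch <- phylo_covariance(tr, 0.5)
  expect_equal(Ch[upper.tri(Ch)], C1[upper.tri(C1)] / 2)
})

test_that("BM log-likelihood factorizes and matches a direct computation", {
  expect_equal(bm_loglik(2.5, matrix(3, 1, 1), sigma2 = 0.7, mu = 1),
               dnorm(2.5, 1, sqrt(0.7 * 3), log = TRUE))

  tr <- yule_tree(9, seed = 59)
  y <- simulate_bm(tr, 1, 0, 1, seed = 60)
  C0 <- phylo_covariance(tr, 0)
  expect_equal(bm_loglik(y, C0, 1.3, 0.2),
               sum(dnorm(y, 0.2, sqrt(1.3 * diag(C0)), log = TRUE)),
               tolerance = 1e-9)

  # general lambda: independent dense-solve route
  C <- phylo_covariance(tr, 0.6)
  direct <- -0.5 * (length(y) * log(2 * pi * 1.1) +
                      determinant(C)$modulus[1] +
                      t(y - 0.3) %*% solve(C) %*% (y - 0.3) / 1.1)
  expect_equal(bm_loglik(y, C, 1.1, 0.3), as.numeric(direct), tolerance = 1e-8)

  # permutation invariance
  p <- sample(length(y))
  expect_equal(bm_loglik(unname(y)[p], C[p, p], 1.1, 0.3),
               bm_loglik(unname(y), unname(C), 1.1, 0.3), tolerance = 1e-9)

  # continuity across the lambda range, and exact independence at 0
  lls <- vapply(seq(0, 1, by = 0.1), function(l)
    bm_loglik(y, phylo_covariance(tr, l), 1, 0), numeric(1))
  expect_true(all(is.finite(lls)))
  expect_lt(max(abs(diff(lls))), 10)
})

test_that("effective sample size matches iid and AR(1) benchmarks", {
  set.seed(61)
  iid <- rnorm(10000)
  expect_equal(ess(iid), 10000, tolerance = 0.1)

  x <- numeric(100000)
  for (i in 2:length(x)) x[i] <- 0.9 * x[i - 1] + rnorm(1)
  expect_equal(ess(x), length(x) * (1 - 0.9) / (1 + 0.9), tolerance = 0.15)

  expect_equal(ess(rep(1, 100)), 1)
  expect_error(ess(1:5), "10")
})

test_that("the lambda sampler recovers signal and flags convergence by ESS", {
  tr <- yule_tree(60, seed = 63)
  y <- simulate_bm(tr, sigma2 = 1, mu = 0, lambda_pagel = 1, seed = 64)
  fit <- pagel_mcmc(tr, y, n_gen = 3e4, thin = 30, seed = 65)
  expect_gt(fit$eta, 0.6)
  expect_true(fit$eta >= fit$ci95[1] && fit$eta <= fit$ci95[2])
  expect_gt(fit$ess, 0)
  expect_identical(fit$converged, fit$ess >= 200)

  ys <- y; names(ys) <- sample(names(y))
  fit0 <- pagel_mcmc(tr, ys, n_gen = 3e4, thin = 30, seed = 66)
  expect_lt(fit0$eta, 0.4)

  strict <- pagel_mcmc(tr, y, n_gen = 2e4, thin = 20, seed = 67,
                       ess_threshold = 1e7)
  expect_false(strict$converged)

  # determinism under a fixed seed
  fit2 <- pagel_mcmc(tr, y, n_gen = 3e4, thin = 30, seed = 65)
  expect_identical(fit$chain, fit2$chain)
})

test_that("posterior median lambda tracks the maximum-likelihood estimate", {
  tr <- yule_tree(80, seed = 71)
  y <- simulate_bm(tr, sigma2 = 1, mu = 0, lambda_pagel = 0.7, seed = 72)
  fit <- pagel_mcmc(tr, y, n_gen = 4e4, thin = 40, seed = 73)
  ml <- phytools::phylosig(tr, y, method = "lambda")
  expect_lt(abs(fit$eta - min(ml$lambda, 1)), 0.25)
})
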