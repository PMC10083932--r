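#' Trim a phylogeny to a set of species
#'
#' Induced subtree on the kept tips: pruned internal nodes of degree 2 are
#' suppressed with their branch lengths summed, so root-to-tip path lengths
#' of the kept tips are preserved (an ultrametric tree stays ultrametric).
#'
#' @param tree An [ape::phylo] tree (rooted, with branch lengths).
#' @param keep Character vector of tip labels to retain.
#' @return The trimmed `phylo` tree.
#' @export
trim_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("species not in the tree: ", paste(unknown, collapse = ", "))
  }
  ape::keep.tip(tree, keep)
}

#' Graft a missing species onto a phylogeny
#'
#' Adds `species` as a terminal branch attached at the midpoint of the
#' subtending branch of its sister lineage (a tip label or an internal node
#' label naming a clade). On ultrametric trees the new tip's branch length
#' is chosen so its root-to-tip depth equals the tree height (tips stay
#' contemporaneous); otherwise the new branch length is half the sister's
#' subtending branch.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param species New tip label.
#' @param sister Tip label, or internal node label, of the sister lineage.
#' @return The augmented `phylo` tree.
#' @export
graft_missing <- function(tree, species, sister) {
  stopifnot(inherits(tree, "phylo"))
  node <- match(sister, tree$tip.label)
  if (is.na(node) && !is.null(tree$node.label)) {
    j <- match(sister, tree$node.label)
    if (!is.na(j)) node <- ape::Ntip(tree) + j
  }
  if (is.na(node)) stop("sister lineage not found in tree: ", sister)
  root <- ape::Ntip(tree) + 1L
  if (node == root) stop("sister is the root: no subtending branch to attach to")
  e <- which(tree$edge[, 2] == node)
  bl <- tree$edge.length[e]
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(ape::Ntip(tree))])
  attach_depth <- depths[node] - bl / 2
  len <- if (ape::is.ultrametric(tree, tol = 1e-8)) height - attach_depth else bl / 2
  phytools::bind.tip(tree, species, edge.length = len, where = node,
                     position = bl / 2)
}

#' Phylogenetic trait covariance under Pagel's lambda
#'
#' Brownian-motion covariance of tip trait values with the off-diagonal
#' entries (shared root-to-MRCA path lengths) scaled by `lambda_pagel`;
#' diagonals (root-to-tip path lengths) are left unscaled. `lambda = 1` is
#' plain Brownian motion, `lambda = 0` independent tips.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param lambda_pagel Scaling in `[0, 1]`.
#' @return m x m covariance matrix (dimnames = tip labels).
#' @export
phylo_covariance <- function(tree, lambda_pagel = 1) {
  stopifnot(lambda_pagel >= 0, lambda_pagel <= 1)
  C <- ape::vcv(tree)
  Cl <- C * lambda_pagel
  diag(Cl) <- diag(C)
  Cl
}

#' Brownian-motion log-likelihood
#'
#' Multivariate normal log-density of tip trait values with mean `mu` and
#' covariance `sigma2 * C`, computed through a Cholesky factorization (no
#' explicit matrix inverse).
#'
#' @param y Trait values (aligned with the rows of `C`; when `y` is named
#'   and `C` has dimnames, `y` is reordered to match).
#' @param C Phylogenetic covariance structure, see [phylo_covariance()].
#' @param sigma2 Brownian rate (> 0).
#' @param mu Root state / mean.
#' @return Log-likelihood (numeric scalar).
#' @export
bm_loglik <- function(y, C, sigma2, mu) {
  C <- as.matrix(C)
  if (!is.null(names(y)) && !is.null(rownames(C))) y <- y[rownames(C)]
  n <- length(y)
  stopifnot(n == nrow(C), sigma2 > 0)
  R <- tryCatch(chol(C), error = function(e)
    stop("covariance structure is not positive definite"))
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) + sum(z^2) / sigma2)
}

#' Effective sample size of an MCMC chain
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated
#' by Geyer's initial-positive-sequence rule: pairwise sums
#' `rho_{2m} + rho_{2m+1}` are accumulated until the first non-positive
#' pair. Floored at 1; a constant chain returns 1.
#'
#' @param chain Numeric vector of at least 10 samples.
#' @return Effective sample size (numeric scalar >= 1).
#' @export
ess <- function(chain) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 10L) stop("chain must hold at least 10 samples")
  if (stats::var(chain) <= .Machine$double.eps) return(1)
  lag_max <- min(n - 1L, 5000L)
  rho <- as.numeric(stats::acf(chain, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)   # rho[1] is lag 0
  tau <- -1   # Geyer: tau = -rho_0 + 2 * sum of initial positive pair sums
  m <- 0L
  repeat {
    i1 <- 2L * m + 1L; i2 <- 2L * m + 2L
    if (i2 > length(rho)) break
    gam <- rho[i1] + rho[i2]
    if (gam <= 0) break
    tau <- tau + 2 * gam
    m <- m + 1L
  }
  max(n / max(tau, 1e-12), 1)
}

#' Bayesian estimation of Pagel's lambda by MCMC
#'
#' Metropolis-Hastings sampling of `(lambda, sigma2, mu)` under the
#' lambda-transformed Brownian-motion model: target = prior x [bm_loglik()].
#' Priors: `lambda ~ Uniform(0, 1)`, `log(sigma2) ~ Uniform(-10, 10)`,
#' `mu ~ Normal(mean(y), (10 sd(y))^2)`. Proposals: reflective Gaussian walk
#' for lambda on `[0, 1]`, Gaussian walk on `log(sigma2)`, Gaussian walk for
#' `mu`; one randomly chosen parameter is updated per generation. Step sizes
#' adapt toward 20-40% acceptance during burn-in only and are frozen
#' afterwards, preserving detailed balance for the retained samples. The
#' first `burn_in_frac` of generations is discarded and the rest thinned.
#' The point estimate `eta` is the posterior median of the lambda chain;
#' convergence is flagged by the effective sample size of that chain.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param y Named trait values (names matched to tip labels).
#' @param n_gen Number of MCMC generations.
#' @param burn_in_frac Fraction of generations discarded as burn-in.
#' @param thin Store every `thin`-th generation.
#' @param seed Seed (NULL leaves the RNG alone).
#' @param ess_threshold ESS below which the result is flagged not converged.
#' @return Object of class `pagel_mcmc`: `chain` (data.frame with columns
#'   `lambda`, `sigma2`, `mu`, post burn-in), `eta` (posterior median
#'   lambda), `ci95`, `ess`, `converged`, `acceptance`, `n_gen`, `seed`.
#' @export
pagel_mcmc <- function(tree, y, n_gen = 1e6, burn_in_frac = 0.2, thin = 100L,
                       seed = NULL, ess_threshold = 200) {
  stopifnot(inherits(tree, "phylo"))
  C1 <- ape::vcv(tree)
  if (!is.null(names(y))) {
    miss <- setdiff(rownames(C1), names(y))
    if (length(miss)) stop("trait values missing for tips: ", paste(miss, collapse = ", "))
    y <- y[rownames(C1)]
  }
  n <- length(y)
  stopifnot(n == nrow(C1))
  if (!is.null(seed)) set.seed(seed)
  dC <- diag(C1)
  ones <- rep(1, n)
  mu_prior_mean <- mean(y); mu_prior_sd <- 10 * stats::sd(y)

  # cached pieces for the current lambda: chol, whitened y and 1
  make_cache <- function(lam) {
    C <- C1 * lam; diag(C) <- dC
    R <- chol(C)
    list(a = backsolve(R, y, transpose = TRUE),
         b = backsolve(R, ones, transpose = TRUE),
         logdet = 2 * sum(log(diag(R))))
  }
  ll <- function(cache, mu, s2) {
    -0.5 * (n * log(2 * pi * s2) + cache$logdet +
              sum((cache$a - mu * cache$b)^2) / s2)
  }
  reflect01 <- function(x) {
    while (x < 0 || x > 1) x <- if (x < 0) -x else 2 - x
    x
  }

  lam <- 0.5; theta <- log(stats::var(y)); mu <- mean(y)
  cache <- make_cache(lam)
  cur_ll <- ll(cache, mu, exp(theta))
  step <- c(lam = 0.2, theta = 0.5, mu = stats::sd(y))
  n_burn <- floor(n_gen * burn_in_frac)
  prop_ct <- acc_ct <- c(lam = 0, theta = 0, mu = 0)
  win_prop <- win_acc <- c(lam = 0, theta = 0, mu = 0)

  keep_idx <- seq(thin, n_gen, by = thin)
  out <- matrix(NA_real_, length(keep_idx), 3,
                dimnames = list(NULL, c("lambda", "sigma2", "mu")))
  ki <- 1L
  for (g in seq_len(n_gen)) {
    p <- sample.int(3L, 1L)
    if (p == 1L) {
      lam_new <- reflect01(lam + stats::rnorm(1, 0, step["lam"]))
      cache_new <- make_cache(lam_new)
      new_ll <- ll(cache_new, mu, exp(theta))
      win_prop["lam"] <- win_prop["lam"] + 1
      if (log(stats::runif(1)) < new_ll - cur_ll) {
        lam <- lam_new; cache <- cache_new; cur_ll <- new_ll
        win_acc["lam"] <- win_acc["lam"] + 1
      }
    } else if (p == 2L) {
      theta_new <- theta + stats::rnorm(1, 0, step["theta"])
      win_prop["theta"] <- win_prop["theta"] + 1
      if (abs(theta_new) <= 10) {          # uniform prior on log sigma2
        new_ll <- ll(cache, mu, exp(theta_new))
        if (log(stats::runif(1)) < new_ll - cur_ll) {
          theta <- theta_new; cur_ll <- new_ll
          win_acc["theta"] <- win_acc["theta"] + 1
        }
      }
    } else {
      mu_new <- mu + stats::rnorm(1, 0, step["mu"])
      new_ll <- ll(cache, mu_new, exp(theta))
      lpr <- stats::dnorm(mu_new, mu_prior_mean, mu_prior_sd, log = TRUE) -
        stats::dnorm(mu, mu_prior_mean, mu_prior_sd, log = TRUE)
      win_prop["mu"] <- win_prop["mu"] + 1
      if (log(stats::runif(1)) < new_ll - cur_ll + lpr) {
        mu <- mu_new; cur_ll <- new_ll
        win_acc["mu"] <- win_acc["mu"] + 1
      }
    }
    if (g <= n_burn && g %% 150L == 0L) {  # adapt during burn-in only
      for (nm in names(step)) {
        if (win_prop[nm] >= 10) {
          rate <- win_acc[nm] / win_prop[nm]
          if (rate < 0.2) step[nm] <- step[nm] * 0.7
          if (rate > 0.4) step[nm] <- step[nm] * 1.4
        }
      }
      prop_ct <- prop_ct + win_prop; acc_ct <- acc_ct + win_acc
      win_prop[] <- 0; win_acc[] <- 0
    }
    if (ki <= length(keep_idx) && g == keep_idx[ki]) {
      out[ki, ] <- c(lam, exp(theta), mu)
      ki <- ki + 1L
    }
  }
  prop_ct <- prop_ct + win_prop; acc_ct <- acc_ct + win_acc
  post <- out[keep_idx > n_burn, , drop = FALSE]
  lam_chain <- post[, "lambda"]
  e <- ess(lam_chain)
  structure(list(
    chain = as.data.frame(post),
    eta = stats::median(lam_chain),
    ci95 = stats::quantile(lam_chain, c(0.025, 0.975), names = FALSE),
    ess = e,
    converged = e >= ess_threshold,
    acceptance = ifelse(prop_ct > 0, acc_ct / prop_ct, NA_real_),
    n_gen = n_gen, burn_in_frac = burn_in_frac, thin = thin, seed = seed),
    class = "pagel_mcmc")
}

#' @export
print.pagel_mcmc <- function(x, ...) {
  cat("<pagel_mcmc> posterior median lambda (eta) =", format(x$eta, digits = 3),
      "\n  95% CI: [", format(x$ci95[1], digits = 3), ",",
      format(x$ci95[2], digits = 3), "]  ESS =", round(x$ess),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.pagel_mcmc <- function(object, ...) {
  ch <- object$chain
  data.frame(
    parameter = c("lambda", "sigma2", "mu"),
    median = vapply(ch, stats::median, numeric(1)),
    lower95 = vapply(ch, stats::quantile, numeric(1), probs = 0.025),
    upper95 = vapply(ch, stats::quantile, numeric(1), probs = 0.975),
    row.names = NULL)
}
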