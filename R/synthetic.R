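#' Generate archetypal life-history projection matrix records
#'
#' Builds synthetic records spanning the fast-slow continuum of plant life
#' histories. Each archetype is one base Lefkovitch life cycle — `"fast"`
#' (annual/near-semelparous: 3 stages by default, stasis 0.06, progression
#' 0.65, fertility 3-10 from the second stage onward, maturity within about
#' one year), `"intermediate"` (iteroparous perennial: 4 stages, stasis
#' 0.45, progression 0.3, fertility 1-5 in the last two stages) and
#' `"slow"` (long-lived, late-maturing: 6 stages, stasis rising 0.7-0.9
#' with stage, progression 0.125, fertility 0.1-1 in the last two stages) —
#' and each record is that base with every nonzero entry perturbed
#' multiplicatively by a lognormal factor (`noise_sd` on the log scale),
#' emulating between-study sampling variation around a shared life history.
#' Any `T` column whose sum exceeds 0.99 is renormalized back to 0.99, so
#' every generated record passes [validate_record()] by construction.
#'
#' @param archetype `"fast"`, `"intermediate"` or `"slow"`.
#' @param count Number of records to generate.
#' @param n_stages Stage count; default is the archetype's own (3/4/6).
#'   Base rates are interpolated over stages for other values.
#' @param noise_sd Lognormal perturbation scale on nonzero entries.
#' @param listed_prop Proportion of records labeled as ESA-listed.
#' @param seed Seed (NULL leaves the RNG alone).
#' @return List of [pm_record()] objects.
#' @export
make_archetype <- function(archetype = c("fast", "intermediate", "slow"),
                           count = 1L, n_stages = NULL, noise_sd = 0.1,
                           listed_prop = 0.3, seed = NULL) {
  archetype <- match.arg(archetype)
  if (!is.null(seed)) set.seed(seed)
  par <- switch(archetype,
    fast = list(n = 3L, stasis = c(0.06, 0.06), prog = 0.65,
                fert = c(3, 10), n_repro = NA),
    intermediate = list(n = 4L, stasis = c(0.45, 0.45), prog = 0.3,
                        fert = c(1, 5), n_repro = 2L),
    slow = list(n = 6L, stasis = c(0.7, 0.9), prog = 0.125,
                fert = c(0.1, 1), n_repro = 2L))
  n <- if (is.null(n_stages)) par$n else as.integer(n_stages)
  stopifnot(n >= 2L)
  repro_from <- if (is.na(par$n_repro)) 2L else max(n - par$n_repro + 1L, 2L)
  base_T <- matrix(0, n, n)
  diag(base_T) <- seq(par$stasis[1], par$stasis[2], length.out = n)
  for (j in seq_len(n - 1L)) base_T[j + 1L, j] <- par$prog
  base_F <- matrix(0, n, n)
  base_F[1L, repro_from:n] <- seq(par$fert[1], par$fert[2],
                                  length.out = n - repro_from + 1L)
  lapply(seq_len(count), function(i) {
    # multiplicative lognormal noise on nonzero entries
    jig <- function(M) {
      nz <- M > 0
      M[nz] <- M[nz] * exp(stats::rnorm(sum(nz), 0, noise_sd))
      M
    }
    Tm <- jig(base_T); Fm <- jig(base_F)
    cs <- colSums(Tm)
    over <- cs > 0.99
    if (any(over)) Tm[, over] <- sweep(Tm[, over, drop = FALSE], 2,
                                       0.99 / cs[over], `*`)
    pm_record(sprintf("%s_%02d", archetype, i), matT = Tm, matF = Fm,
              listed = stats::runif(1) < listed_prop)
  })
}

#' Random valid projection matrix record
#'
#' Rejection-samples a random record guaranteed to pass the eligibility
#' filter: `T` entries are drawn on a random sparsity mask with column sums
#' scaled strictly below 1; `F` places random fertilities in its first row
#' (newborns enter the first stage, the Lefkovitch convention, which keeps
#' the scalar Euler-Lotka identity exact for the derived age schedules);
#' draws are repeated until `A = T + F` is irreducible and reproduction is
#' present.
#'
#' @param n_stages Matrix dimension (>= 2).
#' @param density Expected proportion of nonzero entries in `(0, 1]`.
#' @param seed Seed (NULL leaves the RNG alone).
#' @param max_tries Rejection cap.
#' @return A [pm_record()].
#' @export
random_valid_matrix <- function(n_stages = 3L, density = 0.5, seed = NULL,
                                max_tries = 1000L) {
  stopifnot(n_stages >= 2L, density > 0, density <= 1)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    n <- n_stages
    Tm <- matrix(stats::runif(n * n) * (stats::runif(n * n) < density), n, n)
    cs <- colSums(Tm)
    target <- stats::runif(n, 0.2, 0.9)
    pos <- cs > 0
    Tm[, pos] <- sweep(Tm[, pos, drop = FALSE], 2, target[pos] / cs[pos], `*`)
    Fm <- matrix(0, n, n)
    Fm[1, ] <- stats::runif(n, 0, 3) * (stats::runif(n) < density)
    if (sum(Fm) == 0) next
    tag <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed
    rec <- pm_record(sprintf("rand_n%d_s%d", n_stages, tag),
                     matT = Tm, matF = Fm)
    if (length(validate_record(rec)) == 0L) return(rec)
  }
  stop("rejection cap exceeded; try a higher density")
}

#' Cohort-simulation oracle for the age-from-stage quantities
#'
#' Individual-based simulation of a birth cohort through the survival
#' process `T`: each individual starts in a stage drawn from `w0` and each
#' year moves from stage j to stage i with probability `T[i, j]`, dying with
#' the complement `1 - sum(T[, j])`. Returns empirical survivorship, mean
#' life expectancy (years lived, counting the birth step), longevity (first
#' age with survivorship below `crit`), and the mean age at first
#' reproduction (first year occupying a stage whose `F` column sum is
#' positive, averaged over individuals that reproduce), with Monte-Carlo
#' standard errors. Used to cross-check the analytic Markov-chain results.
#'
#' @param T,F Transition and fertility matrices.
#' @param w0 Birth-stage distribution (default: all mass on stage 1).
#' @param n_individuals Cohort size.
#' @param seed Seed (NULL leaves the RNG alone).
#' @param crit Longevity criterion on the empirical survivorship.
#' @return List: `lx`, `lx_se` (ages 0-based), `Lmean`, `Lmean_se`, `Lmax`,
#'   `Lalpha`, `Lalpha_se` (NA when no individual reproduces), `n`.
#' @export
cohort_oracle <- function(T, F, w0 = NULL, n_individuals = 1e5, seed = NULL,
                          crit = 0.01) {
  T <- as.matrix(T); F <- as.matrix(F)
  n <- nrow(T)
  if (is.null(w0)) { w0 <- numeric(n); w0[1] <- 1 }
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(n_individuals)
  repro_stage <- colSums(F) > 0
  state <- sample.int(n, N, replace = TRUE, prob = w0)
  lifespan <- rep(NA_integer_, N)
  first_rep <- rep(NA_integer_, N)
  alive <- seq_len(N)
  age <- 0L
  lx <- numeric(0)
  while (length(alive)) {
    lx <- c(lx, length(alive) / N)
    newly <- alive[repro_stage[state[alive]] & is.na(first_rep[alive])]
    first_rep[newly] <- age
    nxt <- integer(length(alive))
    st <- state[alive]
    for (j in seq_len(n)) {
      sel <- which(st == j)
      if (!length(sel)) next
      pj <- T[, j]
      nxt[sel] <- sample.int(n + 1L, length(sel), replace = TRUE,
                             prob = c(pj, max(1 - sum(pj), 0)))
    }
    died <- nxt == n + 1L
    lifespan[alive[died]] <- age + 1L
    state[alive] <- nxt
    alive <- alive[!died]
    age <- age + 1L
    if (age > 100000L) stop("cohort simulation did not terminate")
  }
  lx_se <- sqrt(lx * (1 - lx) / N)
  emp_lmax <- {
    hit <- which(lx < crit)
    if (length(hit)) hit[1] - 1 else length(lx) - 1
  }
  fr <- first_rep[!is.na(first_rep)]
  list(lx = lx, lx_se = lx_se,
       Lmean = mean(lifespan), Lmean_se = stats::sd(lifespan) / sqrt(N),
       Lmax = emp_lmax,
       Lalpha = if (length(fr)) mean(fr) else NA_real_,
       Lalpha_se = if (length(fr) > 1) stats::sd(fr) / sqrt(length(fr)) else NA_real_,
       n = N)
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Seed (NULL leaves the RNG alone).
#' @param birth Speciation rate.
#' @return An ultrametric [ape::phylo] tree with tips `sp1..spN`.
#' @export
yule_tree <- function(n_tips, seed = NULL, birth = 1) {
  stopifnot(n_tips >= 2L)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  tr$tip.label <- paste0("sp", seq_len(n_tips))
  tr
}

#' Simulate trait values under lambda-scaled Brownian motion
#'
#' Draws one trait vector from the multivariate normal with mean `mu` and
#' covariance `sigma2 * phylo_covariance(tree, lambda_pagel)`.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param sigma2 Brownian rate (>= 0).
#' @param mu Root state.
#' @param lambda_pagel Phylogenetic-signal scaling in `[0, 1]`.
#' @param seed Seed (NULL leaves the RNG alone).
#' @return Named numeric vector of tip trait values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, mu = 0, lambda_pagel = 1,
                        seed = NULL) {
  stopifnot(sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_covariance(tree, lambda_pagel)
  z <- stats::rnorm(nrow(C))
  y <- mu + sqrt(sigma2) * as.numeric(t(chol(C)) %*% z)
  names(y) <- rownames(C)
  y
}
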