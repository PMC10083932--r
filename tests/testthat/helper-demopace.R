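# Shared fixtures, all built in code.

# 2-stage semelparous worked life cycle: seed -> flowering plant -> death.
# lambda = sqrt(2), Ro = 2, Lmean = 1.5, Lalpha = 1, S = 0, H = 0.23105.
worked_record <- function() {
  pm_record("semelparous_2stage",
            matT = matrix(c(0, 0.5, 0, 0), 2, 2),
            matF = matrix(c(0, 0, 4, 0), 2, 2))
}

# minimal hand-built life table (class constructed directly, for the scalar
# trait operations that only read ages/lx/mx)
manual_life_table <- function(lx, mx, w0 = c(1)) {
  structure(list(ages = seq_along(lx) - 1L, lx = lx, mx = mx, w0 = w0,
                 truncated_at_cap = FALSE), class = "life_table")
}

# brute-force irreducibility: (I + A)^(n-1) strictly positive
reachability_irreducible <- function(A) {
  n <- nrow(A)
  M <- diag(n) + (A > 0)
  P <- diag(n)
  for (i in seq_len(n - 1)) P <- P %*% M
  all(P > 0)
}

# an ultrametric distance matrix (cophenetic distances of a dendrogram are
# ultrametric by construction)
manual_ultrametric <- function(m = 8, seed = 99) {
  set.seed(seed)
  X <- matrix(stats::rnorm(3 * m), m)
  rownames(X) <- paste0("s", seq_len(m))
  h <- stats::hclust(stats::dist(X), method = "average")
  as.matrix(stats::cophenetic(h))
}

# batch of random valid records with reproducible seeds
random_records <- function(n_records, dims = 2:6, seed0 = 1000) {
  lapply(seq_len(n_records), function(i) {
    random_valid_matrix(n_stages = sample(dims, 1),
                        density = stats::runif(1, 0.4, 0.9),
                        seed = seed0 + i)
  })
}
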