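#' Bray-Curtis dissimilarity between species trait profiles
#'
#' `D[a, b] = sum(|x_a - x_b|) / sum(x_a + x_b)` over non-negative trait
#' profiles (min-max normalized traits). A pair of all-zero profiles is
#' assigned distance 0.
#'
#' @param X Non-negative numeric matrix (species x traits); rownames carry
#'   species ids.
#' @return Symmetric matrix with zero diagonal and entries in `[0, 1]`.
#' @export
bray_curtis <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0)) {
    stop("Bray-Curtis requires non-negative profiles; normalize the traits ",
         "first (see normalize_trait_table)")
  }
  D <- as.matrix(suppressWarnings(vegan::vegdist(X, method = "bray")))
  D[!is.finite(D)] <- 0   # both profiles all-zero
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering: at each step the closest pair
#' of nodes is merged at a height equal to their distance, and the distance
#' from the merged node to the others is the size-weighted arithmetic mean
#' of the member distances. Average linkage is monotone, so merge heights
#' never decrease.
#'
#' @param D Symmetric distance matrix (or `dist`).
#' @return An [stats::hclust] object (`method = "average"`).
#' @export
upgma <- function(D) {
  d <- stats::as.dist(D)
  if (attr(d, "Size") < 2L) stop("need at least 2 leaves")
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into clusters
#'
#' Removes all merges above the cut height (or cuts into exactly `k`
#' groups); the connected components that remain are the clusters.
#'
#' @param dend An [stats::hclust] object.
#' @param height Cut height (default 0.3). Ignored when `k` is given.
#' @param k Optional number of clusters.
#' @return Integer vector of cluster labels in `1..k`, named by leaf label.
#' @export
cut_dendrogram <- function(dend, height = 0.3, k = NULL) {
  if (!is.null(k)) stats::cutree(dend, k = k) else stats::cutree(dend, h = height)
}

#' Export a dendrogram as Newick
#'
#' @param dend An [stats::hclust] object.
#' @param path Optional file path; when NULL the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend)
  s <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}

#' K-means guided choice of the number of clusters
#'
#' Runs centroid partitioning for each candidate `k` (with `n_init` random
#' restarts) and recommends the `k` at the maximum-curvature ("elbow") point
#' of the within-cluster sum-of-squares profile, located as the point of the
#' profile (rescaled to the unit square, which makes the rule invariant to
#' the scale of either axis) lying furthest below the chord joining its
#' endpoints. The full profile is returned so the recommendation can be
#' inspected rather than trusted blindly.
#'
#' @param X Numeric matrix (species x traits).
#' @param k_range Candidate cluster counts (capped at `nrow(X) - 1` and at
#'   the number of distinct rows).
#' @param n_init Random restarts per `k`.
#' @param seed Seed for the restarts.
#' @return List of class `kselect`: `k` (recommended), `k_range`, `wss`.
#' @export
select_k <- function(X, k_range = 1:10, n_init = 25L, seed = 1L) {
  X <- as.matrix(X)
  m <- nrow(X)
  n_distinct <- nrow(unique(X))
  k_range <- sort(unique(pmin(k_range, max(m - 1L, 1L), n_distinct)))
  k_range <- k_range[k_range >= 1L]
  set.seed(seed)
  wss <- vapply(k_range, function(k) {
    if (k == 1L) sum(scale(X, scale = FALSE)^2)
    else stats::kmeans(X, centers = k, nstart = n_init, iter.max = 50L)$tot.withinss
  }, numeric(1))
  k <- if (wss[1] < 1e-12 || length(k_range) < 3L) {
    k_range[which(wss <= wss[1] * 1e-9 + 1e-12)[1]]
  } else {
    x <- (k_range - min(k_range)) / diff(range(k_range))
    y <- (wss - min(wss)) / diff(range(wss))
    chord <- y[1] + x * (y[length(y)] - y[1])
    k_range[which.max(chord - y)]
  }
  structure(list(k = k, k_range = k_range, wss = wss), class = "kselect")
}

#' @export
print.kselect <- function(x, ...) {
  cat("<kselect> recommended k =", x$k, "\n")
  print(data.frame(k = x$k_range, wss = signif(x$wss, 5)), row.names = FALSE)
  invisible(x)
}

# Within-group sum of squared distances for a grouping of indices.
.ss_within <- function(D2, idx_by_group) {
  s <- 0
  for (idx in idx_by_group) {
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared dissimilarities among and within
#' groups and tests the pseudo-F statistic
#' `F = ((SS_total - SS_within)/(g - 1)) / (SS_within/(m - g))` by random
#' permutation of the group labels:
#' `p = (1 + #(F_perm >= F_obs)) / (n_perm + 1)`.
#' The p-value is reported only when every group has at least 2 members.
#'
#' @param D Distance matrix (or `dist`).
#' @param labels Group labels (length m, at least 2 distinct values).
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutation stream (NULL leaves the RNG alone).
#' @return List of class `permanova`: `pseudo_F`, `p_value`, `ss_total`,
#'   `ss_within`, `df`, `n_perm`, group sizes.
#' @export
permanova <- function(D, labels, n_perm = 999L, seed = NULL) {
  D <- as.matrix(D)
  m <- nrow(D)
  labels <- as.factor(labels)
  stopifnot(length(labels) == m)
  g <- nlevels(droplevels(labels))
  if (g < 2L) stop("PERMANOVA needs at least 2 groups")
  labels <- droplevels(labels)
  D2 <- D^2
  ss_total <- sum(D2) / (2 * m)
  grp <- split(seq_len(m), labels)
  ss_within <- .ss_within(D2, grp)
  f_obs <- ((ss_total - ss_within) / (g - 1)) / (ss_within / (m - g))
  sizes <- lengths(grp)
  p <- NA_real_
  if (all(sizes >= 2L)) {
    if (!is.null(seed)) set.seed(seed)
    fac <- rep.int(seq_along(sizes), sizes)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- split(sample.int(m), fac)
      ssw <- .ss_within(D2, idx)
      fp <- ((ss_total - ssw) / (g - 1)) / (ssw / (m - g))
      if (fp >= f_obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(pseudo_F = f_obs, p_value = p, ss_total = ss_total,
                 ss_within = ss_within, df = c(between = g - 1L, within = m - g),
                 n_perm = n_perm, sizes = sizes),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("<permanova> pseudo-F =", format(x$pseudo_F, digits = 5),
      " df =", x$df[1], "/", x$df[2],
      " p =", if (is.na(x$p_value)) "NA (a group has < 2 members)"
      else format(x$p_value, digits = 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' @rdname permanova
#' @param adjust Multiple-testing adjustment for the pairwise table
#'   (step-down Holm by default; raw p-values always reported alongside).
#' @return `pairwise_permanova` returns a data.frame with one row per label
#'   pair: `group1`, `group2`, `pseudo_F`, `p_raw`, `p_adj`.
#' @export
pairwise_permanova <- function(D, labels, n_perm = 999L, seed = NULL,
                               adjust = "holm") {
  D <- as.matrix(D)
  labels <- as.factor(labels)
  levs <- levels(droplevels(labels))
  if (length(levs) < 2L) stop("PERMANOVA needs at least 2 groups")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  if (!is.null(seed)) seeds <- seed + seq_along(pairs) else seeds <- vector("list", length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    keep <- labels %in% pr
    res <- permanova(D[keep, keep, drop = FALSE], droplevels(labels[keep]),
                     n_perm = n_perm, seed = if (is.null(seed)) NULL else seeds[[i]])
    data.frame(group1 = pr[1], group2 = pr[2], pseudo_F = res$pseudo_F,
               p_raw = res$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = adjust)
  out
}

#' Principal components analysis of normalized traits
#'
#' PCA on the column-centered (not re-standardized: min-max normalization
#' already equalizes trait ranges) trait matrix. Component signs are fixed
#' so that each loading vector's largest-magnitude entry is positive.
#'
#' @param X Numeric matrix (species x traits), normalized traits.
#' @return List of class `trait_pca`: `loadings` (orthonormal columns),
#'   `scores`, `variance_explained` (percentages summing to 100).
#' @export
pca_traits <- function(X) {
  X <- as.matrix(X)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  L <- pr$rotation
  S <- pr$x
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  ve <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  structure(list(loadings = L, scores = S, variance_explained = ve),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("<trait_pca>\n  variance explained (%):",
      paste(round(x$variance_explained, 1), collapse = ", "), "\n")
  invisible(x)
}
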