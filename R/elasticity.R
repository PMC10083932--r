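#' Eigenvalue elasticity matrix
#'
#' Elasticities are the proportional response of the population growth rate
#' to a proportional change in each matrix element:
#' `e_ij = (a_ij / lam) * d lam / d a_ij`. The sensitivity is
#' `s_ij = v_i * w_j / <v, w>` from the dominant eigen-pair, so with the
#' scaling used by [dominant_eigen()] (`<v, w> = 1`) the elasticity matrix
#' is `E = (A / lam) * (v w')`. Entries where `a_ij = 0` are exactly 0, and
#' the elasticities of an irreducible matrix sum to 1 (de Kroon's property).
#'
#' @param rec A [pm_record()] with irreducible `A`, or a bare square matrix.
#' @return Object of class `elasticity_decomp`: list with the elasticity
#'   matrix `E`, `lam`, and `groups` (NULL until [group_elasticities()] is
#'   applied).
#' @export
elasticity_matrix <- function(rec) {
  A <- if (inherits(rec, "pm_record")) rec$A else as.matrix(rec)
  eig <- dominant_eigen(A)
  S <- outer(eig$v, eig$w)           # <v, w> = 1 by construction
  E <- (A / eig$lam) * S
  E[A == 0] <- 0
  structure(list(E = E, lam = eig$lam, groups = NULL),
            class = "elasticity_decomp")
}

#' @export
print.elasticity_decomp <- function(x, ...) {
  cat("<elasticity_decomp> lambda =", format(x$lam, digits = 5),
      " sum(E) =", format(sum(x$E), digits = 6), "\n")
  print(round(x$E, 4))
  if (!is.null(x$groups)) {
    cat("groups:\n"); print(round(unlist(x$groups), 4))
  }
  invisible(x)
}

#' Group elasticities into survival, growth and fertility processes
#'
#' Partitions the elasticity total (1) across the three demographic
#' processes: fertility = positions with `F > 0`; growth = sub-diagonal `T`
#' positions (progression to later stages, row > col); survival = diagonal
#' and super-diagonal `T` positions (stasis and retrogression, row <= col).
#' Positions positive in both `T` and `F` have their elasticity split in
#' proportion `T[i,j] : F[i,j]`, preserving the sum-to-one property. Whether
#' retrogression belongs with survival (the default) or with growth is
#' configurable, since published groupings vary.
#'
#' @param E Elasticity matrix, or an `elasticity_decomp`.
#' @param T,F The record's transition and fertility matrices.
#' @param retrogression `"survival"` (stasis + retrogression, default) or
#'   `"growth"` (retrogression counted as a growth transition).
#' @return Named list `(survival, growth, fertility)`; when `E` is an
#'   `elasticity_decomp` the object is returned with its `groups` filled.
#' @export
group_elasticities <- function(E, T, F, retrogression = c("survival", "growth")) {
  retrogression <- match.arg(retrogression)
  decomp <- NULL
  if (inherits(E, "elasticity_decomp")) { decomp <- E; E <- decomp$E }
  T <- as.matrix(T); F <- as.matrix(F)
  stopifnot(all(dim(E) == dim(T)), all(dim(E) == dim(F)))
  tot <- T + F
  wF <- ifelse(tot > 0, F / ifelse(tot > 0, tot, 1), 0)
  wT <- ifelse(tot > 0, T / ifelse(tot > 0, tot, 1), 0)
  rows <- row(E); cols <- col(E)
  if (retrogression == "survival") {
    surv_mask <- rows <= cols          # stasis + retrogression
    grow_mask <- rows > cols           # progression
  } else {
    surv_mask <- rows == cols          # stasis only
    grow_mask <- rows != cols          # progression + retrogression
  }
  groups <- list(
    survival = sum(E * wT * surv_mask),
    growth = sum(E * wT * grow_mask),
    fertility = sum(E * wF))
  if (!is.null(decomp)) { decomp$groups <- groups; return(decomp) }
  groups
}

#' Per-species elasticity table
#'
#' Runs [elasticity_matrix()] + [group_elasticities()] on every record.
#'
#' @param records List of [pm_record()] objects.
#' @param cluster Optional integer cluster labels aligned with `records`.
#' @param retrogression Passed to [group_elasticities()].
#' @return data.frame with columns `species_id`, `listed`, `cluster`,
#'   `e_survival`, `e_growth`, `e_fertility`.
#' @export
elasticity_table <- function(records, cluster = NA_integer_,
                             retrogression = "survival") {
  cluster <- rep_len(cluster, length(records))
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    g <- group_elasticities(elasticity_matrix(r), r$T, r$F,
                            retrogression = retrogression)$groups
    data.frame(species_id = r$species_id, listed = r$listed,
               cluster = cluster[i], e_survival = g$survival,
               e_growth = g$growth, e_fertility = g$fertility)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kernel-density summaries of grouped elasticities by stratum
#'
#' For each stratum (cluster x listing status x process) of an elasticity
#' table, reports the median and range and a Gaussian kernel density on
#' `[0, 1]` with boundary reflection (elasticities are bounded, so an
#' unreflected kernel would leak mass past 0 and 1). Bandwidth follows
#' Silverman's rule; degenerate strata (zero spread) fall back to a narrow
#' fixed bandwidth so a point mass shows as a sharp peak. Strata outside
#' `clusters_keep` are excluded; densities are skipped (medians still
#' reported) for strata with fewer than 2 species.
#'
#' @param etab Output of [elasticity_table()] (columns `cluster`, `listed`,
#'   `e_survival`, `e_growth`, `e_fertility`).
#' @param clusters_keep Integer vector of cluster labels to summarize
#'   (default: all present).
#' @param n_grid Number of grid points on `[0, 1]`.
#' @return List with `summary` (data.frame: cluster, listed, process, n,
#'   median, min, max) and `densities` (named list of data.frames with
#'   columns `x`, `density`, or NULL for skipped strata).
#' @export
elasticity_density_summary <- function(etab, clusters_keep = NULL,
                                       n_grid = 256L) {
  if (is.null(clusters_keep)) clusters_keep <- sort(unique(etab$cluster))
  etab <- etab[etab$cluster %in% clusters_keep, , drop = FALSE]
  grid <- seq(0, 1, length.out = n_grid)
  procs <- c(survival = "e_survival", growth = "e_growth",
             fertility = "e_fertility")
  summary_rows <- list(); densities <- list()
  for (cl in sort(unique(etab$cluster))) {
    for (li in sort(unique(etab$listed))) {
      sub <- etab[etab$cluster == cl & etab$listed == li, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (pn in names(procs)) {
        x <- sub[[procs[pn]]]
        key <- paste0("cluster", cl, "_", if (li) "listed" else "nonlisted",
                      "_", pn)
        summary_rows[[key]] <- data.frame(
          cluster = cl, listed = li, process = pn, n = length(x),
          median = stats::median(x), min = min(x), max = max(x))
        densities[[key]] <- if (length(x) >= 2L) {
          .reflected_density(x, grid)
        } else NULL
      }
    }
  }
  list(summary = do.call(rbind, c(summary_rows, list(make.row.names = FALSE))),
       densities = densities)
}

# Gaussian KDE on [0, 1] with reflection at both bounds.
.reflected_density <- function(x, grid) {
  h <- if (stats::sd(x) > 0) stats::bw.nrd0(x) else 0.01  # point-mass stratum
  if (!is.finite(h) || h <= 0) h <- 0.01
  f <- vapply(grid, function(g) {
    mean(stats::dnorm(g - x, sd = h) + stats::dnorm(g + x, sd = h) +
           stats::dnorm(2 - g - x, sd = h))
  }, numeric(1))
  data.frame(x = grid, density = f)
}
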