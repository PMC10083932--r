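#' Pipeline configuration
#'
#' Assembles the full configuration for [run_pipeline()]. Defaults follow
#' the analysis conventions hard-wired throughout the package: all nine
#' eligibility conditions on, birth mass on the first stage, survivorship
#' truncation at 1e-7 (cap 1000 years), longevity criterion 0.01,
#' dendrogram cut height 0.3, 999 PERMANOVA permutations, MCMC with 1
#' million generations, 20% burn-in, thinning 100 and ESS convergence
#' threshold 200. A single master seed fans out deterministically to
#' per-stage seeds.
#'
#' @param records_path Path to a records file (JSON or CSV), or NULL when
#'   `records` are passed to [run_pipeline()] directly.
#' @param tree_path Optional Newick tree path (phylogenetic-signal stage is
#'   skipped, with a logged notice, when absent).
#' @param conditions Logical vector of length 9: which eligibility
#'   conditions to enforce.
#' @param w0_method Birth-stage convention, see [birth_distribution()].
#' @param lx_tol,x_cap,lmax_crit Trait-extraction settings.
#' @param cut_height Dendrogram cut height.
#' @param k_range Candidate cluster counts for [select_k()].
#' @param n_perm PERMANOVA permutations.
#' @param retrogression Elasticity grouping option, see
#'   [group_elasticities()].
#' @param min_cluster_size Minimum species per cluster for inclusion in the
#'   elasticity density summaries (undersized clusters are skipped, as when
#'   comparisons are restricted to the few largest clusters).
#' @param mcmc List: `n_gen`, `burn_in_frac`, `thin`, `ess_threshold`.
#' @param seed Master seed.
#' @param outdir Output directory for artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(records_path = NULL, tree_path = NULL,
                            conditions = rep(TRUE, 9), w0_method = "first_stage",
                            lx_tol = 1e-7, x_cap = 1000L, lmax_crit = 0.01,
                            cut_height = 0.3, k_range = 1:10, n_perm = 999L,
                            retrogression = "survival", min_cluster_size = 5L,
                            mcmc = list(), seed = 1L, outdir = "demopace_out") {
  mc <- list(n_gen = 1e6, burn_in_frac = 0.2, thin = 100L, ess_threshold = 200)
  bad <- setdiff(names(mcmc), names(mc))
  if (length(bad)) stop("unknown mcmc key(s): ", paste(bad, collapse = ", "))
  mc[names(mcmc)] <- mcmc
  stopifnot(length(conditions) == 9L, is.logical(conditions))
  structure(list(records_path = records_path, tree_path = tree_path,
                 conditions = conditions, w0_method = w0_method,
                 lx_tol = lx_tol, x_cap = x_cap, lmax_crit = lmax_crit,
                 cut_height = cut_height, k_range = k_range, n_perm = n_perm,
                 retrogression = retrogression,
                 min_cluster_size = min_cluster_size, mcmc = mc,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Load / save a pipeline configuration file
#'
#' YAML configuration files: unspecified fields take the defaults of
#' [pipeline_config()]; unknown keys are rejected by name; type mismatches
#' are reported with their key path.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- pipeline_config()
  known <- setdiff(names(unclass(defaults)), character(0))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$mcmc)) {
    badm <- setdiff(names(raw$mcmc), names(defaults$mcmc))
    if (length(badm)) stop("unknown config key(s): ",
                           paste(paste0("mcmc.", badm), collapse = ", "))
  }
  .check_type <- function(val, ref, key) {
    if (is.null(val)) return(invisible())
    if (is.numeric(ref) && !is.numeric(val))
      stop("config key ", key, ": expected a number, got ", class(val)[1])
    if (is.character(ref) && !is.character(val))
      stop("config key ", key, ": expected a string, got ", class(val)[1])
    if (is.logical(ref) && !is.logical(val))
      stop("config key ", key, ": expected a logical, got ", class(val)[1])
  }
  for (k in intersect(names(raw), known)) {
    if (k == "mcmc") next
    .check_type(raw[[k]], defaults[[k]], k)
  }
  if (!is.null(raw$mcmc)) {
    for (k in names(raw$mcmc)) .check_type(raw$mcmc[[k]], defaults$mcmc[[k]],
                                           paste0("mcmc.", k))
  }
  args <- raw
  if (!is.null(args$conditions)) args$conditions <- as.logical(args$conditions)
  do.call(pipeline_config, args)
}

#' @rdname load_config
#' @param config A `pipeline_config` to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# deterministic fan-out of the master seed to named per-stage substreams
.stage_seed <- function(master, stage) {
  stages <- c(simulate = 1L, kselect = 2L, permanova = 3L, mcmc = 4L,
              oracle = 5L)
  (as.integer(master) * 101L + stages[[stage]]) %% .Machine$integer.max
}

#' Run the full comparative-demography pipeline
#'
#' One call runs: eligibility filtering -> trait extraction -> min-max
#' normalization -> Bray-Curtis + UPGMA clustering (with a K-means
#' cluster-count profile) -> PERMANOVA (global and pairwise) -> PCA ->
#' elasticity decomposition and density summaries stratified by cluster x
#' listing status -> per-trait Pagel's-lambda phylogenetic signal (when a
#' tree is supplied). All artifacts are written to `config$outdir` as
#' plain-text CSV/JSON/Newick files plus a run manifest, and the main
#' results are also returned invisibly.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param records Optional list of [pm_record()] objects, overriding
#'   `config$records_path`.
#' @param tree Optional [ape::phylo], overriding `config$tree_path`.
#' @return (Invisibly) list with the filtered records, trait tables,
#'   clustering, PERMANOVA, PCA, elasticity and phylogenetic-signal results.
#' @export
run_pipeline <- function(config, records = NULL, tree = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on.exit({
    if (!identical(stage, "done")) {
      writeLines(paste("FAILED at stage:", stage), file.path(out, "FAILED"))
    }
  })
  res <- list(config = config)

  stage <- "filter"
  if (is.null(records)) {
    if (is.null(config$records_path)) stop("stage filter: no records supplied")
    records <- read_records(config$records_path)
  }
  viol <- lapply(records, validate_record)
  enforced <- which(config$conditions)
  keep <- vapply(viol, function(v) !any(v %in% enforced), TRUE)
  counts <- vapply(1:9, function(i) sum(vapply(viol, function(v) i %in% v, TRUE)),
                   numeric(1))
  rejection <- data.frame(condition = 1:9, enforced = config$conditions,
                          n_failing = counts)
  utils::write.csv(rejection, file.path(out, "rejection_report.csv"),
                   row.names = FALSE)
  message("filter: ", sum(keep), "/", length(records), " records retained")
  records <- records[keep]
  res$records <- records
  if (length(records) == 0L) {
    empty <- data.frame(species_id = character(0), listed = logical(0),
                        lam = numeric(0), Lmax = numeric(0), H = numeric(0),
                        Lalpha = numeric(0), Lmean = numeric(0),
                        S = numeric(0), Ro = numeric(0))
    utils::write.csv(empty, file.path(out, "traits_raw.csv"),
                     row.names = FALSE)
    message("no records retained; downstream stages skipped")
    stage <- "done"
    return(invisible(res))
  }

  stage <- "traits"
  traits <- trait_table(records, w0_method = config$w0_method,
                        lx_tol = config$lx_tol, x_cap = config$x_cap,
                        crit = config$lmax_crit)
  norm <- normalize_trait_table(traits)
  write_trait_table(traits, file.path(out, "traits_raw.csv"))
  write_trait_table(norm, file.path(out, "traits_normalized.csv"))
  res$traits <- traits; res$traits_normalized <- norm
  X <- trait_matrix(norm)

  stage <- "cluster"
  D <- bray_curtis(X)
  utils::write.csv(D, file.path(out, "bray_curtis.csv"))
  dend <- upgma(D)
  dendrogram_newick(dend, file.path(out, "dendrogram.nwk"))
  ks <- select_k(X, k_range = config$k_range,
                 seed = .stage_seed(config$seed, "kselect"))
  utils::write.csv(data.frame(k = ks$k_range, wss = ks$wss,
                              recommended = ks$k_range == ks$k),
                   file.path(out, "kmeans_profile.csv"), row.names = FALSE)
  clusters <- cut_dendrogram(dend, height = config$cut_height)
  utils::write.csv(data.frame(species_id = traits$species_id,
                              listed = traits$listed, cluster = clusters),
                   file.path(out, "clusters.csv"), row.names = FALSE)
  message("cluster: ", length(unique(clusters)), " clusters at cut height ",
          config$cut_height, " (k-means elbow suggests k = ", ks$k, ")")
  res$distance <- D; res$dendrogram <- dend; res$kselect <- ks
  res$clusters <- clusters

  stage <- "permanova"
  if (length(unique(clusters)) >= 2L) {
    pv <- permanova(D, clusters, n_perm = config$n_perm,
                    seed = .stage_seed(config$seed, "permanova"))
    pw <- pairwise_permanova(D, clusters, n_perm = config$n_perm,
                             seed = .stage_seed(config$seed, "permanova"))
    utils::write.csv(data.frame(pseudo_F = pv$pseudo_F, p_value = pv$p_value,
                                df_between = pv$df[1], df_within = pv$df[2],
                                n_perm = pv$n_perm),
                     file.path(out, "permanova_global.csv"), row.names = FALSE)
    utils::write.csv(pw, file.path(out, "permanova_pairwise.csv"),
                     row.names = FALSE)
    res$permanova <- pv; res$permanova_pairwise <- pw
  } else {
    message("permanova: single cluster, test skipped")
  }

  stage <- "pca"
  pca <- pca_traits(X)
  utils::write.csv(pca$loadings, file.path(out, "pca_loadings.csv"))
  utils::write.csv(pca$scores, file.path(out, "pca_scores.csv"))
  utils::write.csv(data.frame(component = seq_along(pca$variance_explained),
                              variance_explained = pca$variance_explained),
                   file.path(out, "pca_variance.csv"), row.names = FALSE)
  res$pca <- pca

  stage <- "elasticity"
  etab <- elasticity_table(records, cluster = clusters,
                           retrogression = config$retrogression)
  utils::write.csv(etab, file.path(out, "elasticities.csv"), row.names = FALSE)
  sizes <- table(clusters)
  big <- as.integer(names(sizes)[sizes >= config$min_cluster_size])
  if (length(big) == 0L) big <- as.integer(names(sizes))  # keep all rather than none
  dens <- elasticity_density_summary(etab, clusters_keep = big)
  utils::write.csv(dens$summary, file.path(out, "elasticity_summary.csv"),
                   row.names = FALSE)
  for (nm in names(dens$densities)) {
    if (!is.null(dens$densities[[nm]])) {
      utils::write.csv(dens$densities[[nm]],
                       file.path(out, paste0("density_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  res$elasticities <- etab; res$elasticity_densities <- dens

  stage <- "phylosignal"
  if (is.null(tree) && !is.null(config$tree_path)) {
    tree <- ape::read.tree(config$tree_path)
  }
  if (!is.null(tree)) {
    common <- intersect(tree$tip.label, traits$species_id)
    if (length(common) >= 3L) {
      tr <- trim_tree(tree, common)
      sig <- list()
      trait_names <- c("lam", "Lmax", "H", "Lalpha", "Lmean", "S", "Ro")
      for (ti in seq_along(trait_names)) {
        tn <- trait_names[ti]
        y <- stats::setNames(traits[[tn]], traits$species_id)[common]
        fit <- pagel_mcmc(tr, y, n_gen = config$mcmc$n_gen,
                          burn_in_frac = config$mcmc$burn_in_frac,
                          thin = config$mcmc$thin,
                          seed = .stage_seed(config$seed, "mcmc") + ti,
                          ess_threshold = config$mcmc$ess_threshold)
        sig[[tn]] <- fit
        utils::write.csv(fit$chain,
                         file.path(out, paste0("chain_", tn, ".csv")),
                         row.names = FALSE)
      }
      sig_tab <- do.call(rbind, lapply(names(sig), function(tn) {
        f <- sig[[tn]]
        data.frame(trait = tn, eta = f$eta, ci_lower = f$ci95[1],
                   ci_upper = f$ci95[2], ess = f$ess, converged = f$converged,
                   n_gen = f$n_gen)
      }))
      jsonlite::write_json(sig_tab, file.path(out, "phylo_signal.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      res$phylo_signal <- sig
    } else {
      message("phylosignal: fewer than 3 species shared with the tree; skipped")
    }
  } else {
    message("phylosignal: no tree supplied; stage skipped")
  }

  stage <- "manifest"
  manifest <- list(
    package_version = as.character(utils::packageVersion("demopace")),
    master_seed = config$seed,
    stage_seeds = lapply(c("simulate", "kselect", "permanova", "mcmc"),
                         function(s) .stage_seed(config$seed, s)) |>
      stats::setNames(c("simulate", "kselect", "permanova", "mcmc")),
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage <- "done"
  invisible(res)
}
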