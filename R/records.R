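#' Stage-structured projection matrix record
#'
#' Bundles one species' annual projection matrix `A = T + F` — the survival/
#' transition component `T` (column j sums to the survival probability of
#' stage j) and the sexual-reproduction component `F` (offspring per
#' individual per year) — together with the record-level metadata used by the
#' eligibility filter ([validate_record()]).
#'
#' @param species_id Character scalar identifying the species.
#' @param matT Square numeric matrix of survival/growth transition
#'   probabilities (entries in `[0, ~1]`, substochastic columns).
#' @param matF Square numeric matrix of per-capita sexual fertilities
#'   (non-negative).
#' @param matA Optional projection matrix; reconstructed as `matT + matF`
#'   when omitted. When supplied it is kept as given and checked against
#'   `T + F` by [validate_record()].
#' @param listed Logical; is the species listed as threatened or endangered
#'   under the US Endangered Species Act?
#' @param stages Optional character vector of stage labels.
#' @param metadata List of record-level annotations: `treatment`
#'   (`"unmanipulated"` or `"manipulated"`), `periodicity_years`,
#'   `stage_criterion` (`"stage"`, `"size"`, `"age"`, `"other"`),
#'   `composition` (`"mean"`, `"pooled"`, `"individual"`), `duration_years`.
#'   Missing entries default to conforming values.
#' @return An object of class `pm_record`.
#' @examples
#' rec <- pm_record("sp1",
#'   matT = matrix(c(0, 0.5, 0, 0), 2, 2),
#'   matF = matrix(c(0, 0, 4, 0), 2, 2))
#' validate_record(rec)
#' @export
pm_record <- function(species_id, matT, matF, matA = NULL, listed = FALSE,
                      stages = NULL, metadata = list()) {
  matT <- as.matrix(matT)
  matF <- as.matrix(matF)
  .check_square(matT, "T")
  .check_square(matF, "F")
  if (!all(dim(matT) == dim(matF))) {
    stop("structural error: T and F have mismatched dimensions (",
         nrow(matT), "x", ncol(matT), " vs ", nrow(matF), "x", ncol(matF), ")")
  }
  if (is.null(matA)) {
    matA <- matT + matF
  } else {
    matA <- as.matrix(matA)
    .check_square(matA, "A")
    if (!all(dim(matA) == dim(matT))) {
      stop("structural error: A dimension does not match T/F")
    }
  }
  n <- nrow(matT)
  if (is.null(stages)) stages <- paste0("stage", seq_len(n))
  md <- .default_metadata()
  bad <- setdiff(names(metadata), names(md))
  if (length(bad)) stop("unknown metadata field(s): ", paste(bad, collapse = ", "))
  md[names(metadata)] <- metadata
  md$periodicity_years <- as.numeric(md$periodicity_years)
  md$duration_years <- as.numeric(md$duration_years)
  structure(
    list(species_id = as.character(species_id), listed = isTRUE(listed),
         n_stages = n, A = unname(matA), T = unname(matT), F = unname(matF),
         stages = stages, metadata = md),
    class = "pm_record")
}

.default_metadata <- function() {
  list(treatment = "unmanipulated", periodicity_years = 1,
       stage_criterion = "stage", composition = "mean", duration_years = 1)
}

.check_square <- function(M, name) {
  if (!is.numeric(M) || length(dim(M)) != 2L || nrow(M) != ncol(M)) {
    stop("structural error: matrix ", name, " is not square numeric")
  }
  if (anyNA(M)) stop("structural error: matrix ", name, " contains NA")
  invisible(M)
}

#' @export
print.pm_record <- function(x, ...) {
  cat("<pm_record> ", x$species_id,
      if (x$listed) " [ESA-listed]" else "", "\n", sep = "")
  cat("  stages: ", x$n_stages,
      "  lambda: ", tryCatch(format(dominant_eigen(x$A)$lam, digits = 4),
                             error = function(e) "n/a"), "\n", sep = "")
  cat("  survival issue (max column sum of T): ",
      format(survival_issue(x$T), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Eligibility filter for projection matrix records
#'
#' Applies the nine record-eligibility conditions used to screen projection
#' matrices before trait extraction: (1) unmanipulated treatment; (2) `T` and
#' `F` present with `A = T + F` (within 1e-9); (3) study duration of at least
#' one year; (4) annual periodicity; (5) individuals classified by stage or
#' size; (6) matrix composition one of mean / pooled / individual; (7) at
#' least 2x2 stages; (8) survival issue (max column sum of `T`) strictly less
#' than 1.05; (9) `A` irreducible. Conditions 1 and 3-6 are metadata flags and
#' are taken on trust from the record annotations.
#'
#' @param rec A [pm_record()].
#' @return Integer vector of failed condition numbers (empty when the record
#'   is eligible), with a `description` attribute naming each failure.
#' @export
validate_record <- function(rec) {
  stopifnot(inherits(rec, "pm_record"))
  md <- rec$metadata
  fails <- integer(0)
  why <- character(0)
  add <- function(i, msg) {
    fails <<- c(fails, i)
    why <<- c(why, msg)
  }
  if (!identical(md$treatment, "unmanipulated"))
    add(1L, "treatment is not unmanipulated")
  if (is.null(rec$T) || is.null(rec$F) ||
      max(abs(rec$A - (rec$T + rec$F))) > 1e-9)
    add(2L, "A does not equal T + F")
  if (!is.numeric(md$duration_years) || md$duration_years < 1)
    add(3L, "study duration under one year")
  if (!is.numeric(md$periodicity_years) || abs(md$periodicity_years - 1) > 1e-9)
    add(4L, "matrix periodicity is not annual")
  if (!md$stage_criterion %in% c("stage", "size"))
    add(5L, "individuals not classified by stage or size")
  if (!md$composition %in% c("mean", "pooled", "individual"))
    add(6L, "matrix composition not mean/pooled/individual")
  if (rec$n_stages < 2L)
    add(7L, "matrix smaller than 2 x 2")
  if (!(survival_issue(rec$T) < 1.05))
    add(8L, "survival issue >= 1.05")
  if (!is_irreducible(rec$A))
    add(9L, "A is reducible")
  attr(fails, "description") <- why
  fails
}

#' Survival issue of a transition matrix
#'
#' The maximum column sum of `T`. Stage-specific survival probabilities are
#' the column sums of `T`; values above 1 indicate estimation error, tolerated
#' up to (but excluding) 1.05 by the eligibility filter.
#'
#' @param T Non-negative square transition matrix.
#' @return The maximum column sum (numeric scalar).
#' @export
survival_issue <- function(T) {
  T <- as.matrix(T)
  if (length(T) == 0L) stop("empty matrix")
  if (any(T < 0)) stop("T has negative entries")
  max(colSums(T))
}

#' Test irreducibility of a projection matrix
#'
#' A projection matrix is irreducible when every stage can contribute,
#' directly or through intermediate stages, to every other stage: the
#' directed graph with an edge j -> i whenever `A[i, j] > 0` is strongly
#' connected.
#'
#' @param A Square non-negative matrix.
#' @return Logical scalar.
#' @export
is_irreducible <- function(A) {
  A <- as.matrix(A)
  .check_square(A, "A")
  if (nrow(A) == 1L) return(TRUE)  # single-node graph is strongly connected
  g <- igraph::graph_from_adjacency_matrix(t(A) > 0, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

#' Dominant eigenvalue and stable stage structure
#'
#' Dominant eigen-analysis of a non-negative projection matrix: the dominant
#' eigenvalue is the asymptotic per-year population growth rate, its right
#' eigenvector `w` the stable stage distribution (scaled to sum to 1), and
#' its left eigenvector `v` the stage-specific reproductive values (scaled so
#' that `sum(v * w) == 1`). For irreducible non-negative matrices
#' Perron-Frobenius guarantees a real dominant eigenvalue with a non-negative
#' eigenvector; signs are flipped accordingly.
#'
#' @param A Square non-negative matrix (irreducible for the guarantees above).
#' @return A list of class `eigen_triple` with elements `lam`, `w`, `v`.
#' @export
dominant_eigen <- function(A) {
  A <- as.matrix(A)
  .check_square(A, "A")
  er <- eigen(A)
  i <- which.max(Re(er$values))
  lam <- er$values[i]
  if (abs(Im(lam)) > 1e-10) stop("dominant eigenvalue is complex beyond tolerance")
  lam <- Re(lam)
  w <- .perron_vector(Re(er$vectors[, i]))
  el <- eigen(t(A))
  j <- which.max(Re(el$values))
  v <- .perron_vector(Re(el$vectors[, j]))
  w <- w / sum(w)
  v <- v / sum(v * w)
  structure(list(lam = lam, w = w, v = v), class = "eigen_triple")
}

.perron_vector <- function(x) {
  if (sum(x) < 0) x <- -x
  if (min(x) < -1e-8) stop("dominant eigenvector has mixed signs; matrix may be reducible")
  pmax(x, 0)
}

#' Read and write projection matrix records
#'
#' Exchange format for projection matrix records. JSON files hold one object
#' per record with keys `species_id`, `listed`, `stages`, `matT`, `matF`,
#' `matA` (row-major lists of lists) and `metadata`. The CSV variant is a
#' long table with columns `species_id`, `matrix` (`T`|`F`|`A`), `row`,
#' `col`, `value`, plus a metadata sidecar (same path with a `_metadata.csv`
#' suffix) carrying one row per species. A write followed by a read restores
#' all fields.
#'
#' @param path File path. For CSV, the sidecar path is derived from `path`.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   missing.
#' @param records List of [pm_record()] objects (for `write_records`).
#' @return `read_records` returns a list of `pm_record` objects.
#' @export
read_records <- function(path, format = c("auto", "json", "csv")) {
  format <- .resolve_format(match.arg(format), path)
  if (format == "json") .read_records_json(path) else .read_records_csv(path)
}

#' @rdname read_records
#' @export
write_records <- function(records, path, format = c("auto", "json", "csv")) {
  format <- .resolve_format(match.arg(format), path)
  stopifnot(is.list(records), all(vapply(records, inherits, TRUE, "pm_record")))
  if (format == "json") .write_records_json(records, path)
  else .write_records_csv(records, path)
  invisible(path)
}

.resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) ext else
    stop("cannot infer format from extension: ", path)
}

.sidecar_path <- function(path) sub("\\.csv$", "_metadata.csv", path)

.write_records_json <- function(records, path) {
  objs <- lapply(records, function(r) {
    list(species_id = r$species_id, listed = r$listed, stages = r$stages,
         matT = .mat_to_rows(r$T), matF = .mat_to_rows(r$F),
         matA = .mat_to_rows(r$A), metadata = r$metadata)
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
}

.mat_to_rows <- function(M) lapply(seq_len(nrow(M)), function(i) unname(M[i, ]))

.rows_to_mat <- function(rows, what, idx) {
  if (is.null(rows)) stop("record ", idx, ": missing field \"", what, "\"")
  if (is.matrix(rows)) return(rows)  # jsonlite simplifies regular arrays
  n <- length(rows)
  out <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  if (!is.matrix(out) || ncol(out) != n) {
    stop("record ", idx, ": field \"", what, "\" is not a square row-major matrix")
  }
  out
}

.read_records_json <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    for (f in c("species_id", "matT", "matF")) {
      if (is.null(o[[f]])) stop("record ", i, ": missing field \"", f, "\"")
    }
    pm_record(o$species_id,
              matT = .rows_to_mat(o$matT, "matT", i),
              matF = .rows_to_mat(o$matF, "matF", i),
              matA = if (!is.null(o$matA)) .rows_to_mat(o$matA, "matA", i),
              listed = isTRUE(o$listed),
              stages = unlist(o$stages),
              metadata = o$metadata)
  })
}

.write_records_csv <- function(records, path) {
  long <- do.call(rbind, lapply(records, function(r) {
    do.call(rbind, lapply(c("T", "F", "A"), function(m) {
      M <- r[[m]]
      data.frame(species_id = r$species_id, matrix = m,
                 row = rep(seq_len(nrow(M)), ncol(M)),
                 col = rep(seq_len(ncol(M)), each = nrow(M)),
                 value = as.vector(M))
    }))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  meta <- do.call(rbind, lapply(records, function(r) {
    data.frame(species_id = r$species_id, listed = r$listed,
               stages = paste(r$stages, collapse = ";"),
               treatment = r$metadata$treatment,
               periodicity_years = r$metadata$periodicity_years,
               stage_criterion = r$metadata$stage_criterion,
               composition = r$metadata$composition,
               duration_years = r$metadata$duration_years)
  }))
  utils::write.csv(meta, .sidecar_path(path), row.names = FALSE)
}

.read_records_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "matrix", "row", "col", "value")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("records CSV missing column(s): ", paste(miss, collapse = ", "))
  meta <- utils::read.csv(.sidecar_path(path), stringsAsFactors = FALSE)
  ids <- unique(long$species_id)
  lapply(seq_along(ids), function(i) {
    id <- ids[i]
    sub <- long[long$species_id == id, ]
    grab <- function(m) {
      s <- sub[sub$matrix == m, ]
      if (nrow(s) == 0L) stop("record ", i, " (", id, "): missing field \"", m, "\"")
      n <- max(s$row)
      M <- matrix(0, n, n)
      M[cbind(s$row, s$col)] <- s$value
      M
    }
    mrow <- meta[meta$species_id == id, ]
    if (nrow(mrow) != 1L) stop("record ", i, " (", id, "): metadata sidecar row missing")
    pm_record(id, matT = grab("T"), matF = grab("F"), matA = grab("A"),
              listed = as.logical(mrow$listed),
              stages = strsplit(mrow$stages, ";", fixed = TRUE)[[1]],
              metadata = list(treatment = mrow$treatment,
                              periodicity_years = mrow$periodicity_years,
                              stage_criterion = mrow$stage_criterion,
                              composition = mrow$composition,
                              duration_years = mrow$duration_years))
  })
}
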