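#' Fundamental matrix of the survival/transition process
#'
#' `N = (I - T)^-1`. Entry `N[i, j]` is the expected number of yearly time
#' steps an individual starting in stage j spends in stage i before death.
#' Requires every individual to die eventually, i.e. the spectral radius of
#' `T` below 1.
#'
#' @param T Substochastic transition matrix (column sums < 1 allows death).
#' @return The fundamental matrix `N` (plain numeric matrix).
#' @export
fundamental_matrix <- function(T) {
  T <- as.matrix(T)
  .check_square(T, "T")
  rho <- max(Mod(eigen(T, only.values = TRUE)$values))
  if (rho >= 1) {
    stop("immortal stage structure: spectral radius of T is ",
         format(rho, digits = 6), " (>= 1)")
  }
  solve(diag(nrow(T)) - T)
}

#' Birth-stage distribution conventions
#'
#' Stage mixing at birth used to collapse the stage-structured model onto an
#' age axis. `"first_stage"` places all newborn mass on stage 1 (the dominant
#' convention for these matrices); `"offspring"` distributes mass according
#' to where `F` actually deposits offspring (row sums of `F`, normalized).
#'
#' @param rec A [pm_record()] (or any list with an `F` matrix).
#' @param method `"first_stage"` or `"offspring"`.
#' @return Numeric vector summing to 1.
#' @export
birth_distribution <- function(rec, method = c("first_stage", "offspring")) {
  method <- match.arg(method)
  Fm <- if (inherits(rec, "pm_record")) rec$F else as.matrix(rec)
  n <- nrow(Fm)
  if (method == "first_stage") {
    w0 <- numeric(n); w0[1] <- 1
  } else {
    rs <- rowSums(Fm)
    if (sum(rs) <= 0) stop("F has no positive entries; offspring distribution undefined")
    w0 <- rs / sum(rs)
  }
  w0
}

#' Age-from-stage survivorship and fertility schedules
#'
#' Markov-chain decomposition of a stage-structured model onto an age axis:
#' a birth cohort with stage mixing `w0` is projected through `T`, giving
#' survivorship `lx(x) = sum(T^x w0)` (the cumulative probability of being
#' alive at age x, `l0 = 1`) and per-capita fertility
#' `mx(x) = sum(F T^x w0) / lx(x)` (0 where `lx` is 0). The schedule is
#' truncated at the first age where `lx` drops below `lx_tol`, or at `x_cap`.
#'
#' @param T,F Transition and fertility matrices.
#' @param w0 Birth-stage distribution (sums to 1); see [birth_distribution()].
#' @param lx_tol Survivorship level at which the schedule is truncated.
#' @param x_cap Hard cap on the oldest tabulated age.
#' @return An object of class `life_table`: list with `ages` (0-based), `lx`,
#'   `mx`, `w0` and logical `truncated_at_cap` (TRUE when `x_cap` was hit
#'   before `lx` reached `lx_tol`).
#' @export
age_schedules <- function(T, F, w0 = NULL, lx_tol = 1e-7, x_cap = 1000L) {
  T <- as.matrix(T); F <- as.matrix(F)
  .check_square(T, "T"); .check_square(F, "F")
  n <- nrow(T)
  if (is.null(w0)) { w0 <- numeric(n); w0[1] <- 1 }
  if (abs(sum(w0) - 1) > 1e-8) stop("w0 must sum to 1")
  lx <- numeric(0); mx <- numeric(0)
  p <- as.numeric(w0)
  x <- 0L
  truncated_at_cap <- FALSE
  repeat {
    l <- sum(p)
    lx <- c(lx, l)
    mx <- c(mx, if (l > 0) sum(F %*% p) / l else 0)
    if (l < lx_tol) break
    if (x >= x_cap) { truncated_at_cap <- TRUE; break }
    p <- as.numeric(T %*% p)
    x <- x + 1L
  }
  if (truncated_at_cap) {
    warning("age schedule truncated at x_cap = ", x_cap,
            " before lx reached ", lx_tol)
  }
  mx[lx <= 0] <- 0
  structure(list(ages = seq_along(lx) - 1L, lx = lx, mx = mx,
                 w0 = as.numeric(w0), truncated_at_cap = truncated_at_cap),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> ages 0..", max(x$ages),
      if (x$truncated_at_cap) " (truncated at cap)", "\n", sep = "")
  print(utils::head(data.frame(age = x$ages, lx = x$lx, mx = x$mx), 10))
  if (length(x$ages) > 10) cat("  ... ", length(x$ages) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Longevity from the survivorship schedule
#'
#' The age at which survivorship first drops below a critical level
#' (default 0.01). When the tabulated schedule never reaches the criterion,
#' the truncation age is returned with a warning.
#'
#' @param lt A `life_table` (or a bare numeric `lx` vector, ages 0-based).
#' @param crit Critical survivorship level in `(0, 1]`.
#' @return Age in years (numeric scalar).
#' @export
longevity_lmax <- function(lt, crit = 0.01) {
  if (!is.numeric(crit) || length(crit) != 1L || crit <= 0 || crit > 1) {
    stop("crit must lie in (0, 1]")
  }
  lx <- if (inherits(lt, "life_table")) lt$lx else as.numeric(lt)
  hit <- which(lx < crit)
  if (length(hit) == 0L) {
    warning("survivorship never drops below ", crit,
            "; returning the truncation age")
    return(length(lx) - 1)
  }
  hit[1] - 1
}

#' Mean life expectancy
#'
#' Expected number of yearly time steps lived (counting the birth step) for
#' an individual born with stage mixing `w0`: the total of `N %*% w0`.
#'
#' @param N Fundamental matrix from [fundamental_matrix()].
#' @param w0 Birth-stage distribution.
#' @return Years (numeric scalar).
#' @export
mean_life_expectancy <- function(N, w0) {
  N <- as.matrix(N)
  if (abs(sum(w0) - 1) > 1e-8) stop("w0 must sum to 1")
  sum(N %*% as.numeric(w0))
}

#' Age at first reproduction
#'
#' Expected age at which an individual first occupies a reproductive stage
#' (a stage whose `F` column has positive sum), computed on the absorbing
#' Markov chain in which reproductive stages absorb. Death is a competing
#' absorbing state, so the default estimate conditions on ever reproducing —
#' matching what a cohort simulation records when it averages the
#' first-reproduction ages of the individuals that do reproduce. Birth mass
#' already on a reproductive stage contributes age 0.
#'
#' @param T,F Transition and fertility matrices.
#' @param w0 Birth-stage distribution.
#' @param method `"absorbing"` (expected age, default) or `"first_mx"` (the
#'   first tabulated age with positive `mx` — a coarser classical variant).
#' @param ... Passed to [age_schedules()] when `method = "first_mx"`.
#' @return Years (numeric scalar).
#' @export
age_at_first_reproduction <- function(T, F, w0, method = c("absorbing", "first_mx"),
                                      ...) {
  method <- match.arg(method)
  T <- as.matrix(T); F <- as.matrix(F)
  repro <- colSums(F) > 0
  if (!any(repro)) stop("non-reproducing life cycle: F has no positive column")
  if (method == "first_mx") {
    lt <- age_schedules(T, F, w0, ...)
    pos <- which(lt$mx > 0)
    if (length(pos) == 0L) stop("non-reproducing life cycle: mx is zero at every tabulated age")
    return(lt$ages[pos[1]])
  }
  w0 <- as.numeric(w0)
  if (all(repro)) return(0)
  Q <- which(!repro)
  U <- T[Q, Q, drop = FALSE]
  b <- colSums(T[repro, Q, drop = FALSE])          # P(next step enters a reproductive stage)
  IU <- diag(length(Q)) - t(U)
  h <- as.numeric(solve(IU, b))                    # P(ever reproduce | start in Q stage)
  m <- as.numeric(solve(IU, b + as.numeric(t(U) %*% h)))  # E[age * 1{reproduce}]
  wQ <- w0[Q]; wR <- sum(w0[repro])
  denom <- wR + sum(wQ * h)
  if (denom <= 0) stop("non-reproducing life cycle: no reproductive stage reachable from w0")
  sum(wQ * m) / denom
}

#' Keyfitz entropy of a survivorship schedule
#'
#' Shape statistic of the survivorship curve,
#' `H = (-sum(lx * log(lx))) / sum(lx)` with natural logs, summed over the
#' tabulated ages (zero-survivorship entries are excluded). Constant-hazard
#' (log-linear, "Type II") survivorship gives H = 1; survivorship curves
#' dying off late give smaller H, early-mortality curves larger H.
#'
#' @param lx A `life_table` or a numeric survivorship vector with `l0 = 1`.
#' @return Dimensionless entropy (numeric scalar, >= 0).
#' @export
keyfitz_entropy <- function(lx) {
  if (inherits(lx, "life_table")) lx <- lx$lx
  lx <- as.numeric(lx)
  if (length(lx) == 0L || abs(lx[1] - 1) > 1e-8) stop("lx must start at l0 = 1")
  lx <- lx[lx > 0]
  s <- sum(lx)
  if (s <= 0) return(0)
  -sum(lx * log(lx)) / s
}

#' Net reproductive rate
#'
#' Expected lifetime offspring per individual: the dominant eigenvalue of
#' `F %*% N`, where `N` is the fundamental matrix.
#'
#' @param F Fertility matrix.
#' @param N Fundamental matrix.
#' @return Ro (numeric scalar, >= 0).
#' @export
net_reproductive_rate <- function(F, N) {
  R <- as.matrix(F) %*% as.matrix(N)
  ev <- eigen(R, only.values = TRUE)$values
  i <- which.max(Re(ev))
  if (abs(Im(ev[i])) > 1e-10) stop("dominant eigenvalue of F N is complex beyond tolerance")
  max(Re(ev[i]), 0)
}

#' Degree of iteroparity (reproductive entropy)
#'
#' Shannon entropy of the distribution of reproduction over age. Ages are
#' weighted by `lam^-(x+1) * lx(x) * mx(x)` (discounted net-fertility terms of
#' the Euler-Lotka identity), renormalized to a probability vector `p`, and
#' `S = -sum(p * log(p))` (natural logs). `S = 0` is strict semelparity
#' (all reproduction at a single age); larger S means reproduction spread
#' over more ages.
#'
#' @param lt A `life_table`.
#' @param lam Population growth rate (dominant eigenvalue of `A`).
#' @return S in nats (numeric scalar, >= 0).
#' @export
iteroparity_entropy <- function(lt, lam) {
  stopifnot(inherits(lt, "life_table"))
  w <- lam^(-(lt$ages + 1)) * lt$lx * lt$mx
  tot <- sum(w)
  if (tot <= 0) stop("no reproduction: lx * mx is zero at every tabulated age")
  p <- w[w > 0] / tot
  s <- -sum(p * log(p))
  if (s <= 0) 0 else s
}

#' Life-history trait vector for one record
#'
#' Composes the eigen-analysis and the age-from-stage machinery into the
#' seven per-species quantities: population growth rate `lam`, longevity
#' `Lmax`, survivorship-curve shape `H`, age at first reproduction `Lalpha`,
#' mean life expectancy `Lmean`, degree of iteroparity `S`, and net
#' reproductive rate `Ro`. All components share the same birth-stage
#' distribution and truncation settings.
#'
#' @param rec A [pm_record()] that passed [validate_record()].
#' @param w0_method Birth-stage convention, see [birth_distribution()].
#' @param lx_tol,x_cap Truncation settings, see [age_schedules()].
#' @param crit Longevity criterion, see [longevity_lmax()].
#' @param lalpha_method See [age_at_first_reproduction()].
#' @return Named numeric vector of class `trait_vector` with elements
#'   `lam`, `Lmax`, `H`, `Lalpha`, `Lmean`, `S`, `Ro`.
#' @export
trait_vector <- function(rec, w0_method = "first_stage", lx_tol = 1e-7,
                         x_cap = 1000L, crit = 0.01,
                         lalpha_method = "absorbing") {
  stopifnot(inherits(rec, "pm_record"))
  out <- tryCatch({
    eig <- dominant_eigen(rec$A)
    N <- fundamental_matrix(rec$T)
    w0 <- birth_distribution(rec, w0_method)
    lt <- age_schedules(rec$T, rec$F, w0, lx_tol = lx_tol, x_cap = x_cap)
    c(lam = eig$lam,
      Lmax = longevity_lmax(lt, crit = crit),
      H = keyfitz_entropy(lt),
      Lalpha = age_at_first_reproduction(rec$T, rec$F, w0, method = lalpha_method),
      Lmean = mean_life_expectancy(N, w0),
      S = iteroparity_entropy(lt, eig$lam),
      Ro = net_reproductive_rate(rec$F, N))
  }, error = function(e) {
    stop("trait extraction failed for species \"", rec$species_id, "\": ",
         conditionMessage(e), call. = FALSE)
  })
  class(out) <- c("trait_vector", class(out))
  out
}

#' @export
print.trait_vector <- function(x, ...) {
  cat("<trait_vector>\n")
  print(round(unclass(x), 5))
  invisible(x)
}

#' Trait table for a set of records
#'
#' Runs [trait_vector()] on every record and assembles the species x trait
#' table used downstream by the clustering, elasticity and phylogenetic
#' signal analyses.
#'
#' @param records List of [pm_record()] objects.
#' @param ... Passed to [trait_vector()].
#' @return A `data.frame` of class `trait_table` with columns `species_id`,
#'   `listed`, `lam`, `Lmax`, `H`, `Lalpha`, `Lmean`, `S`, `Ro`.
#' @export
trait_table <- function(records, ...) {
  stopifnot(length(records) >= 1L)
  rows <- lapply(records, function(r) {
    tv <- trait_vector(r, ...)
    cbind(data.frame(species_id = r$species_id, listed = r$listed),
          as.data.frame(as.list(unclass(tv))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trait_table", class(out))
  out
}

#' Min-max normalization of a trait table
#'
#' Rescales each trait column to `[0, 1]` by `(y - min(y)) / (max(y) -
#' min(y))`, so that traits on very different scales (years, nats, offspring
#' counts) contribute comparably to the Bray-Curtis dissimilarity. A constant
#' column maps to all zeros.
#'
#' @param tab A `trait_table` (or any data frame; non-numeric columns are
#'   passed through unchanged) or a bare numeric matrix.
#' @return Same shape as the input with numeric columns rescaled to `[0, 1]`.
#' @export
normalize_trait_table <- function(tab) {
  mm <- function(y) {
    r <- range(y)
    if (diff(r) == 0) return(rep(0, length(y)))
    (y - r[1]) / diff(r)
  }
  if (is.matrix(tab)) {
    if (nrow(tab) < 2L) stop("need at least 2 species to normalize")
    return(apply(tab, 2, mm))
  }
  if (nrow(tab) < 2L) stop("need at least 2 species to normalize")
  num <- vapply(tab, is.numeric, TRUE) & !names(tab) %in% c("species_id", "listed")
  tab[num] <- lapply(tab[num], mm)
  tab
}

#' Numeric trait matrix from a trait table
#'
#' @param tab A `trait_table` data frame.
#' @return Numeric matrix (rownames = species_id) of the trait columns.
#' @export
trait_matrix <- function(tab) {
  num <- vapply(tab, is.numeric, TRUE) & !names(tab) %in% c("species_id", "listed")
  m <- as.matrix(tab[num])
  rownames(m) <- tab$species_id
  m
}

#' @rdname trait_table
#' @param tab Trait table to write.
#' @param path Output CSV path.
#' @export
write_trait_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trait_table
#' @export
read_trait_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("trait_table", class(out))
  out
}
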