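## Spatial weights and local/global autocorrelation statistics on the
## hexagonal lattice.  Weights are first-order edge contiguity; Moran and
## LISA use row-standardized weights without self, Gi* uses binary weights
## with self included (the classic hot-spot formulation with analytic
## mean and variance).

#' First-order contiguity weights on a hexagonal grid
#'
#' Edge-sharing hexagons are neighbors (at most six).  Cells with no
#' retained neighbor are flagged as islands; their weights row is empty.
#'
#' @param grid a [hex_grid()].
#' @param cell_ids retained cell ids (e.g. after [filter_min_count()]);
#'   default all grid cells.
#' @param style `"W"` row-standardized (each neighbor weight `1/k_i`) or
#'   `"B"` binary.
#' @return Object of class `spatial_weights`: `ids` (sorted cell ids),
#'   `neighbors` (list of integer *positions* into `ids`), `weights`
#'   (parallel list of numeric weights), `style`, `islands` (ids).
#' @export
contiguity_weights <- function(grid, cell_ids = NULL, style = c("W", "B")) {
  style <- match.arg(style)
  nb <- hex_neighbors(grid, cell_ids)
  ids <- as.integer(names(nb))
  ord <- order(ids)
  ids <- ids[ord]; nb <- nb[ord]
  pos <- match(ids, ids)  # identity; neighbor ids -> positions below
  neighbors <- lapply(nb, function(v) match(v, ids))
  weights <- lapply(neighbors, function(v) {
    k <- length(v)
    if (k == 0L) return(numeric(0))
    if (style == "W") rep(1 / k, k) else rep(1, k)
  })
  islands <- ids[lengths(neighbors) == 0L]
  structure(list(ids = ids, neighbors = unname(neighbors),
                 weights = unname(weights), style = style, islands = islands),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d cells, style %s, %d island(s), avg %.2f neighbors\n",
              length(x$ids), x$style, length(x$islands),
              mean(lengths(x$neighbors))))
  invisible(x)
}

# spatial lag of a vector under a weights object
spatial_lag <- function(w, x) {
  vapply(seq_along(x), function(i) {
    nb <- w$neighbors[[i]]
    if (length(nb) == 0L) return(0)
    sum(w$weights[[i]] * x[nb])
  }, numeric(1))
}

check_values <- function(x, w) {
  if (length(x) != length(w$ids)) {
    stop("values and weights refer to different cell sets", call. = FALSE)
  }
  if (anyNA(x)) stop("values contain NA", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 cells", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance: all values equal", call. = FALSE)
  invisible(x)
}

# raw cross-product Moran's I for given deviations (internal core)
moran_stat <- function(x, w) {
  n <- length(x)
  zd <- x - mean(x)
  s0 <- sum(unlist(w$weights))
  num <- sum(zd * spatial_lag(w, zd))
  (n / s0) * num / sum(zd^2)
}

#' Global Moran's I with permutation inference
#'
#' The standard cross-product statistic
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with expectation `E[I] = -1/(n-1)` under spatial randomness, and a
#' pseudo p-value from random relabeling of the values across cells.
#'
#' @param x numeric values, one per cell, in the order of `w$ids`.
#' @param w a [contiguity_weights()] object (row-standardized recommended).
#' @param n_perm number of permutations (0 to skip inference).
#' @param seed optional integer seed for the permutations.
#' @return List with `I`, `expected`, `p_value` (two-sided pseudo p, `NA`
#'   when `n_perm = 0`), `n`, `n_perm`.
#' @export
global_morans_i <- function(x, w, n_perm = 999L, seed = NULL) {
  check_values(x, w)
  n <- length(x)
  obs <- moran_stat(x, w)
  expected <- -1 / (n - 1)
  p <- NA_real_
  if (n_perm > 0L) {
    perm <- function() {
      vapply(seq_len(n_perm), function(k) moran_stat(x[sample.int(n)], w),
             numeric(1))
    }
    sims <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())
    extreme <- if (obs >= expected) sum(sims >= obs) else sum(sims <= obs)
    p <- (extreme + 1) / (n_perm + 1)
  }
  list(I = obs, expected = expected, p_value = p, n = n, n_perm = n_perm)
}

quadrant_codes <- function(z, lag) {
  own <- ifelse(z > 0, "H", "L")
  nbr <- ifelse(lag > 0, "H", "L")
  paste0(own, nbr)
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' Per cell: `z_i = (x_i - xbar) / s` (population sd), spatial lag
#' `lag_i = sum_j w_ij z_j`, local statistic `I_i = z_i * lag_i`, and the
#' Moran-scatter quadrant from the signs of `(z_i, lag_i)`.  With
#' row-standardized weights and the population sd, `sum_i I_i = n * I`
#' (the global-local identity).  Pseudo p-values come from conditional
#' permutation: cell i's value is held fixed while its neighbors' values
#' are redrawn from the remaining cells.
#'
#' @inheritParams global_morans_i
#' @return Object of class `lisa_result`: data.frame with `cell_id`,
#'   `value`, `z`, `lag`, `Ii`, `quadrant`, `p_value`; attribute `global_I`.
#' @export
local_morans_i <- function(x, w, n_perm = 999L, seed = NULL) {
  check_values(x, w)
  n <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / n)
  z <- (x - mean(x)) / s
  lag <- spatial_lag(w, z)
  Ii <- z * lag
  p <- rep(NA_real_, n)
  if (n_perm > 0L) {
    run <- function() {
      for (i in seq_len(n)) {
        nb <- w$neighbors[[i]]
        k <- length(nb)
        if (k == 0L) next
        pool <- z[-i]
        # n_perm draws of k neighbor values without replacement
        draws <- matrix(pool[replicate(n_perm, sample.int(n - 1L, k))],
                        nrow = k)
        wts <- w$weights[[i]]
        sims <- z[i] * colSums(draws * wts)
        extreme <- if (Ii[i] >= 0) sum(sims >= Ii[i]) else sum(sims <= Ii[i])
        p[i] <<- (extreme + 1) / (n_perm + 1)
      }
    }
    if (is.null(seed)) run() else withr::with_seed(seed, run())
  }
  out <- data.frame(cell_id = w$ids, value = x, z = z, lag = lag, Ii = Ii,
                    quadrant = quadrant_codes(z, lag), p_value = p)
  attr(out, "global_I") <- moran_stat(x, w)
  class(out) <- c("lisa_result", class(out))
  out
}

#' Getis-Ord Gi* hot/cold-spot statistic
#'
#' The self-inclusive local concentration z-score with binary contiguity
#' weights and analytic mean and variance:
#' `Gi* = (sum_j w_ij x_j - xbar W_i) / (S sqrt((n W_i - W_i^2)/(n-1)))`
#' where `W_i` counts cell i plus its neighbors, `xbar` and `S` are the
#' global mean and population sd.  Cells are `hot` when the z-score exceeds
#' the two-sided critical value at `alpha`, `cold` when below its negative.
#'
#' @param x numeric values, one per cell, in the order of `w$ids`.
#' @param w a [contiguity_weights()] object; its neighbor sets are used,
#'   weights are taken as binary with self included.
#' @param alpha two-sided significance level for the hot/cold labels.
#' @return Object of class `gistar_result`: data.frame with `cell_id`,
#'   `value`, `gistar` (z-score), `category` in
#'   `{hot, cold, not_significant}`.
#' @export
getis_ord_gistar <- function(x, w, alpha = 0.05) {
  check_values(x, w)
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  zstat <- vapply(seq_len(n), function(i) {
    nb <- c(i, w$neighbors[[i]])
    Wi <- length(nb)  # binary, self included
    if (Wi == n) return(0)  # neighborhood spans the whole area: num and var both 0
    num <- sum(x[nb]) - xbar * Wi
    den <- S * sqrt((n * Wi - Wi^2) / (n - 1))
    num / den
  }, numeric(1))
  crit <- stats::qnorm(1 - alpha / 2)
  category <- ifelse(zstat > crit, "hot",
                     ifelse(zstat < -crit, "cold", "not_significant"))
  out <- data.frame(cell_id = w$ids, value = x, gistar = zstat,
                    category = category)
  class(out) <- c("gistar_result", class(out))
  out
}
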