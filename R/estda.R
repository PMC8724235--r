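## Exploratory space-time data analysis on the Moran scatter plane.
##
## Each regime slice places every cell at a LISA coordinate (z, lag): the
## per-slice standardized emotion proportion and its spatial lag.  The
## dynamics layer measures how cells move between slices: relative
## time-path lengths T_i, the five-type quadrant-transition taxonomy, and
## the flow (F) / cohesion (C) summary indices.

REGIME_PAIRS <- list(day_night = c("day", "night"),
                     weekday_weekend = c("weekday", "weekend"))

#' LISA coordinates of one panel slice
#'
#' Standardizes the per-cell proportion of `emotion` within the `regime`
#' slice (mean 0, population sd 1 over cells) and computes its spatial lag.
#' Cells with no messages in the slice (proportion `NA`) are imputed at the
#' slice mean, i.e. placed at z = 0, a neutral Moran-scatter position.
#'
#' @param panel a (filtered) [aggregate_panel()] output.
#' @param emotion one of [emotion_levels()].
#' @param regime one of `all`, `day`, `night`, `weekday`, `weekend`.
#' @param w row-standardized [contiguity_weights()] on the panel's cells.
#' @return data.frame `(cell_id, z, lag, quadrant)` in `w$ids` order.
#' @export
lisa_coordinates <- function(panel, emotion, regime, w) {
  assert_emotion(emotion)
  x <- panel_slice(panel, emotion, regime, cells = w$ids)
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  n <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / n)
  if (s == 0) {
    stop(sprintf("zero variance in slice (%s, %s)", emotion, regime),
         call. = FALSE)
  }
  z <- as.numeric((x - mean(x)) / s)
  lag <- spatial_lag(w, z)
  data.frame(cell_id = w$ids, z = z, lag = lag,
             quadrant = quadrant_codes(z, lag))
}

#' Relative LISA time-path length
#'
#' For ordered slices t = 1..T, each cell traces a path through the Moran
#' scatter plane; with Euclidean step distance d the relative length is
#' `T_i = n * sum_t d(L_i,t, L_i,t+1) / sum_i sum_t d(L_i,t, L_i,t+1)`,
#' so the mean of `T_i` over cells is exactly 1 whenever anything moves.
#' Larger `T_i` marks a cell whose local spatial structure is more dynamic.
#'
#' @param coords list of [lisa_coordinates()] data.frames, one per ordered
#'   slice, all over the same cell set.
#' @return data.frame `(cell_id, path_length, T_i)` with attributes `n`
#'   (cells) and `T` (slices).
#' @export
time_path_relative_length <- function(coords) {
  if (length(coords) < 2L) stop("need at least 2 slices", call. = FALSE)
  ids <- coords[[1]]$cell_id
  for (cc in coords[-1]) {
    if (!identical(cc$cell_id, ids)) {
      stop("cell sets differ between slices", call. = FALSE)
    }
  }
  n <- length(ids)
  steps <- vapply(seq_len(length(coords) - 1L), function(t) {
    a <- coords[[t]]; b <- coords[[t + 1L]]
    sqrt((b$z - a$z)^2 + (b$lag - a$lag)^2)
  }, numeric(n))
  own <- if (is.matrix(steps)) rowSums(steps) else steps
  total <- sum(own)
  if (total == 0) stop("degenerate: no dynamics (total movement is zero)",
                       call. = FALSE)
  out <- data.frame(cell_id = ids, path_length = own, T_i = n * own / total)
  attr(out, "n") <- n
  attr(out, "T") <- length(coords)
  out
}

TRANSITION_TYPES <- c("I", "II", "III", "IV(a)", "IV(b)")

#' Classify a Moran-scatter quadrant transition
#'
#' Between two time slices a cell's two-letter state (own letter = sign of
#' z, neighbor letter = sign of lag) either persists or changes:
#' * Type I — no change (e.g. HH to HH);
#' * Type II — own letter changes, neighborhood letter fixed
#'   (HH to LH, HL to LL, LH to HH, LL to HL);
#' * Type III — own fixed, neighborhood changes
#'   (HH to HL, HL to HH, LH to LL, LL to LH);
#' * Type IV(a) — both flip concordantly (HH to LL, LL to HH);
#' * Type IV(b) — both flip discordantly (HL to LH, LH to HL).
#'
#' @param quadrant_t,quadrant_t1 character vectors of quadrant codes in
#'   `{HH, HL, LH, LL}` at the earlier and later slice.
#' @return Factor over the five transition types.
#' @export
classify_transition <- function(quadrant_t, quadrant_t1) {
  valid <- c("HH", "HL", "LH", "LL")
  bad <- setdiff(unique(c(quadrant_t, quadrant_t1)), valid)
  if (length(bad) > 0L) {
    stop(sprintf("malformed quadrant code(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (length(quadrant_t) != length(quadrant_t1)) {
    stop("quadrant vectors differ in length", call. = FALSE)
  }
  own0 <- substr(quadrant_t, 1, 1); nbr0 <- substr(quadrant_t, 2, 2)
  own1 <- substr(quadrant_t1, 1, 1); nbr1 <- substr(quadrant_t1, 2, 2)
  own_chg <- own0 != own1; nbr_chg <- nbr0 != nbr1
  type <- ifelse(!own_chg & !nbr_chg, "I",
          ifelse(own_chg & !nbr_chg, "II",
          ifelse(!own_chg & nbr_chg, "III",
          ifelse(quadrant_t %in% c("HH", "LL"), "IV(a)", "IV(b)"))))
  factor(type, levels = TRANSITION_TYPES)
}

#' Flow and cohesion from transition-type shares
#'
#' Given shares (counts divided by the number of cells m) of the five
#' transition types, the spatiotemporal flow is `F = share_II + share_III`
#' (cells where exactly one of the two letters moved) and the cohesion is
#' `C = share_I + share_IV(a)` (cells that stayed put or moved with their
#' neighborhood).  `F + C + share_IV(b) = 1`.
#'
#' @param shares numeric vector of 5 shares, in type order I, II, III,
#'   IV(a), IV(b) (names optional).
#' @return List with `flow` and `cohesion`.
#' @export
#' @examples
#' flow_cohesion(c(0.41, 0.23, 0.22, 0.07, 0.07))
flow_cohesion <- function(shares) {
  if (length(shares) != 5L) stop("need 5 transition-type shares", call. = FALSE)
  s <- as.numeric(shares)
  list(flow = s[2] + s[3], cohesion = s[1] + s[4])
}

#' Spatiotemporal transition summary for one emotion and regime pair
#'
#' Computes LISA coordinates for both slices of the regime pair, classifies
#' every retained cell's quadrant transition, and summarizes counts, shares,
#' flow and cohesion.
#'
#' @param panel a (filtered) [aggregate_panel()] output.
#' @param emotion one of [emotion_levels()].
#' @param pair `"day_night"` or `"weekday_weekend"`, or a length-2
#'   character vector of regimes.
#' @param w row-standardized [contiguity_weights()] on the panel's cells.
#' @return One-row data.frame: `emotion`, `pair`, `m`, counts `S_I`..`S_IVb`,
#'   shares `I`..`IV(b)`, `SF` (flow), `SC` (cohesion).  The per-cell
#'   classification is attached as attribute `cells`.
#' @export
transition_summary <- function(panel, emotion, pair = "day_night", w) {
  regimes <- if (length(pair) == 2L) pair else REGIME_PAIRS[[pair]]
  if (is.null(regimes)) stop("unknown regime pair", call. = FALSE)
  c0 <- lisa_coordinates(panel, emotion, regimes[1], w)
  c1 <- lisa_coordinates(panel, emotion, regimes[2], w)
  if (!identical(c0$cell_id, c1$cell_id)) {
    stop("cell sets differ between slices", call. = FALSE)
  }
  type <- classify_transition(c0$quadrant, c1$quadrant)
  counts <- table(type)
  m <- length(type)
  shares <- as.numeric(counts) / m
  fc <- flow_cohesion(shares)
  out <- data.frame(emotion = emotion,
                    pair = paste(regimes, collapse = "_"), m = m,
                    S_I = as.integer(counts[1]), S_II = as.integer(counts[2]),
                    S_III = as.integer(counts[3]),
                    S_IVa = as.integer(counts[4]),
                    S_IVb = as.integer(counts[5]),
                    `I` = shares[1], `II` = shares[2], `III` = shares[3],
                    `IV(a)` = shares[4], `IV(b)` = shares[5],
                    SF = fc$flow, SC = fc$cohesion,
                    check.names = FALSE)
  attr(out, "cells") <- data.frame(cell_id = c0$cell_id,
                                   from = c0$quadrant, to = c1$quadrant,
                                   type = type)
  out
}

#' Transition table over all six emotions
#'
#' @inheritParams transition_summary
#' @return data.frame with one [transition_summary()] row per emotion:
#'   shares of types I..IV(b) plus SF and SC.
#' @export
transition_table <- function(panel, pair = "day_night", w) {
  do.call(rbind, lapply(EMOTIONS, function(emo) {
    transition_summary(panel, emo, pair, w)
  }))
}

#' Per-emotion LISA time-path lengths for a regime pair
#'
#' @inheritParams transition_summary
#' @return data.frame `(cell_id, <one T_i column per emotion>, total)`
#'   where `total` is the per-cell sum over the six emotions.
#' @export
time_path_by_emotion <- function(panel, pair = "day_night", w) {
  regimes <- if (length(pair) == 2L) pair else REGIME_PAIRS[[pair]]
  if (is.null(regimes)) stop("unknown regime pair", call. = FALSE)
  cols <- lapply(EMOTIONS, function(emo) {
    coords <- lapply(regimes, function(rg) lisa_coordinates(panel, emo, rg, w))
    time_path_relative_length(coords)$T_i
  })
  out <- data.frame(cell_id = w$ids)
  for (i in seq_along(EMOTIONS)) out[[EMOTIONS[i]]] <- cols[[i]]
  out$total <- rowSums(out[, EMOTIONS])
  out
}

#' Hot and cold spots of emotional volatility
#'
#' Sums the six per-emotion relative time-path lengths per cell and applies
#' the Gi* hot-spot statistic to the sum: hot cells are where the local
#' spatial structure of emotion is most dynamic between the two regimes.
#'
#' @inheritParams transition_summary
#' @param alpha two-sided significance level for hot/cold labels.
#' @return List with `ti` (the [time_path_by_emotion()] table) and
#'   `gistar` (a [getis_ord_gistar()] result on the per-cell sums).
#' @export
volatility_hotspots <- function(panel, pair = "day_night", w, alpha = 0.05) {
  ti <- time_path_by_emotion(panel, pair, w)
  list(ti = ti, gistar = getis_ord_gistar(ti$total, w, alpha = alpha))
}
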