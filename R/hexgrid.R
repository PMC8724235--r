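## Regular hexagonal tessellation in geographic degrees.
##
## Axial (q, r) integer addressing anchored at the bbox lower-left corner.
## cell_size is the hexagon circumradius (center-to-vertex), in degrees.
## Pointy-top: center = origin + (sqrt(3)*s*(q + r/2), 1.5*s*r)
## Flat-top:   center = origin + (1.5*s*q, sqrt(3)*s*(r + q/2))
## Cells are retained when their center lies inside the bbox; ids are
## assigned in row-major (r, then q) order so they are stable across runs.

AXIAL_DIRS <- matrix(c(1L, 0L, 1L, -1L, 0L, -1L, -1L, 0L, -1L, 1L, 0L, 1L),
                     ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("q", "r")))

axial_center <- function(q, r, size, orientation, origin) {
  if (orientation == "pointy") {
    cbind(origin[1] + size * sqrt(3) * (q + r / 2),
          origin[2] + size * 1.5 * r)
  } else {
    cbind(origin[1] + size * 1.5 * q,
          origin[2] + size * sqrt(3) * (r + q / 2))
  }
}

#' Build a hexagonal grid over a bounding box
#'
#' Tessellates the bounding box with regular hexagons of circumradius
#' `cell_size` (degrees).  Whole hexagons are retained when their center
#' lies inside the bbox; nothing is clipped.  Cell ids are deterministic:
#' row-major over axial coordinates (r, then q).
#'
#' @param bbox numeric `(min_lon, min_lat, max_lon, max_lat)` in degrees.
#' @param cell_size hexagon circumradius in degrees; must be positive and
#'   smaller than the bbox extent.
#' @param orientation `"pointy"` (vertex up) or `"flat"` (edge up).
#' @return Object of class `hex_grid`: list with `cells` (data.frame of
#'   `cell_id`, `q`, `r`, `lon`, `lat`), `cell_size`, `orientation`, `bbox`.
#' @export
#' @examples
#' g <- hex_grid(c(0, 0, 1, 1), cell_size = 0.1)
#' nrow(g$cells)
hex_grid <- function(bbox, cell_size, orientation = c("pointy", "flat")) {
  orientation <- match.arg(orientation)
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4L || bbox[1] >= bbox[3] || bbox[2] >= bbox[4]) {
    stop("bbox must be (min_lon, min_lat, max_lon, max_lat) with positive extent",
         call. = FALSE)
  }
  w <- bbox[3] - bbox[1]; hgt <- bbox[4] - bbox[2]
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (cell_size > min(w, hgt)) {
    stop("cell_size larger than the bounding-box extent", call. = FALSE)
  }
  origin <- bbox[1:2]
  s <- cell_size
  tol <- 1e-9 * max(1, abs(bbox))

  if (orientation == "pointy") {
    rmax <- floor(hgt / (1.5 * s) + tol)
    rows <- 0:rmax
    cells <- do.call(rbind, lapply(rows, function(r) {
      # q range with x = sqrt(3)*s*(q + r/2) in [0, w]
      qlo <- ceiling(-r / 2 - tol)
      qhi <- floor(w / (sqrt(3) * s) - r / 2 + tol)
      if (qhi < qlo) return(NULL)
      data.frame(q = qlo:qhi, r = r)
    }))
  } else {
    qmax <- floor(w / (1.5 * s) + tol)
    cols <- 0:qmax
    cells <- do.call(rbind, lapply(cols, function(q) {
      rlo <- ceiling(-q / 2 - tol)
      rhi <- floor(hgt / (sqrt(3) * s) - q / 2 + tol)
      if (rhi < rlo) return(NULL)
      data.frame(q = q, r = rlo:rhi)
    }))
    # reorder to row-major on (r, q)
    cells <- cells[order(cells$r, cells$q), , drop = FALSE]
  }
  if (is.null(cells) || nrow(cells) == 0L) {
    stop("cell_size larger than the bounding-box extent", call. = FALSE)
  }
  ctr <- axial_center(cells$q, cells$r, s, orientation, origin)
  cells <- data.frame(cell_id = seq_len(nrow(cells)), q = cells$q, r = cells$r,
                      lon = ctr[, 1], lat = ctr[, 2])
  rownames(cells) <- NULL
  structure(list(cells = cells, cell_size = s, orientation = orientation,
                 bbox = bbox, origin = origin),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("hex_grid: %d cells, circumradius %g deg, %s-top, bbox [%g, %g] x [%g, %g]\n",
              nrow(x$cells), x$cell_size, x$orientation,
              x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

#' Hexagon vertex coordinates for one cell
#'
#' @param grid a [hex_grid()].
#' @param cell_id cell identifier.
#' @return 6 x 2 matrix of (lon, lat) vertices, counter-clockwise.
#' @export
hex_vertices <- function(grid, cell_id) {
  row <- grid$cells[grid$cells$cell_id == cell_id, ]
  if (nrow(row) != 1L) stop("unknown cell_id", call. = FALSE)
  ang0 <- if (grid$orientation == "pointy") -30 else 0
  ang <- (ang0 + 60 * 0:5) * pi / 180
  cbind(lon = row$lon + grid$cell_size * cos(ang),
        lat = row$lat + grid$cell_size * sin(ang))
}

# key-based lookup of (q, r) -> cell_id
axial_key <- function(q, r) paste(q, r, sep = ",")

#' Neighboring cells on the hexagonal lattice
#'
#' First-order edge contiguity: the up to six hexagons sharing an edge with
#' each cell, restricted to cells present in the grid (or in `cell_ids`).
#'
#' @param grid a [hex_grid()].
#' @param cell_ids optional subset of retained cell ids.
#' @return Named list mapping each cell id to an integer vector of
#'   neighboring cell ids.
#' @export
hex_neighbors <- function(grid, cell_ids = NULL) {
  cells <- grid$cells
  if (!is.null(cell_ids)) {
    if (!all(cell_ids %in% cells$cell_id)) {
      stop("cell_ids not all present in grid", call. = FALSE)
    }
    cells <- cells[cells$cell_id %in% cell_ids, , drop = FALSE]
  }
  lut <- stats::setNames(cells$cell_id, axial_key(cells$q, cells$r))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    keys <- axial_key(cells$q[i] + AXIAL_DIRS[, "q"],
                      cells$r[i] + AXIAL_DIRS[, "r"])
    unname(sort(lut[keys[keys %in% names(lut)]]))
  })
  stats::setNames(out, cells$cell_id)
}

#' Assign points to hexagonal cells
#'
#' Maps each message to the unique hexagon containing it.  Boundary points
#' (equidistant from two or more centers) go to the nearest center, ties
#' broken by the lowest cell id.  Points outside every retained hexagon get
#' `NA` as a sentinel and are excluded downstream.
#'
#' @param grid a [hex_grid()].
#' @param messages data.frame with `lon` and `lat` columns.
#' @return `messages` with an integer `cell_id` column appended.
#' @export
assign_points <- function(grid, messages) {
  stopifnot(all(c("lon", "lat") %in% names(messages)))
  s <- grid$cell_size
  x <- messages$lon - grid$origin[1]
  y <- messages$lat - grid$origin[2]
  if (grid$orientation == "pointy") {
    qf <- (sqrt(3) / 3 * x - 1 / 3 * y) / s
    rf <- (2 / 3 * y) / s
  } else {
    qf <- (2 / 3 * x) / s
    rf <- (-1 / 3 * x + sqrt(3) / 3 * y) / s
  }
  # cube rounding
  xs <- qf; zs <- rf; ys <- -xs - zs
  rx <- round(xs); ry <- round(ys); rz <- round(zs)
  dx <- abs(rx - xs); dy <- abs(ry - ys); dz <- abs(rz - zs)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  q0 <- as.integer(rx); r0 <- as.integer(rz)

  lut <- stats::setNames(grid$cells$cell_id,
                         axial_key(grid$cells$q, grid$cells$r))
  n <- length(q0)
  # candidates: the rounded cell and its six lattice neighbors
  nd <- nrow(AXIAL_DIRS) + 1L
  cq <- outer(q0, c(0L, AXIAL_DIRS[, "q"]), `+`)
  cr <- outer(r0, c(0L, AXIAL_DIRS[, "r"]), `+`)
  ctr_x <- matrix(0, n, nd); ctr_y <- matrix(0, n, nd)
  for (j in seq_len(nd)) {
    cc <- axial_center(cq[, j], cr[, j], s, grid$orientation, c(0, 0))
    ctr_x[, j] <- cc[, 1]; ctr_y[, j] <- cc[, 2]
  }
  d2 <- (ctr_x - x)^2 + (ctr_y - y)^2
  dmin <- do.call(pmin, as.data.frame(d2))
  tol <- (1e-9 * s)^2 + 1e-12 * s^2
  cell_id <- rep(NA_integer_, n)
  ids <- matrix(NA_integer_, n, nd)
  for (j in seq_len(nd)) {
    m <- lut[axial_key(cq[, j], cr[, j])]
    ids[, j] <- ifelse(is.na(m), NA_integer_, as.integer(m))
  }
  # among in-grid candidates within tolerance of the minimum distance,
  # take the lowest id; none -> sentinel NA
  eligible <- (d2 <= dmin + tol) & !is.na(ids)
  ids[!eligible] <- NA_integer_
  cell_id <- suppressWarnings(apply(ids, 1L, min, na.rm = TRUE))
  cell_id[!is.finite(cell_id)] <- NA_integer_
  messages$cell_id <- as.integer(cell_id)
  messages
}

# regime indicator helpers ---------------------------------------------------

parse_timestamps <- function(ts) {
  out <- as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out
}

regime_flags <- function(ts, day_window = c(6, 18),
                         weekend_days = c("6", "7")) {
  t <- parse_timestamps(ts)
  if (anyNA(t)) stop("unparseable timestamp(s)", call. = FALSE)
  hour <- as.numeric(format(t, "%H")) + as.numeric(format(t, "%M")) / 60 +
    as.numeric(format(t, "%S")) / 3600
  list(day = hour >= day_window[1] & hour < day_window[2],
       weekend = format(t, "%u") %in% weekend_days)
}

REGIMES <- c("all", "day", "night", "weekday", "weekend")

#' Aggregate assigned messages into a cell-emotion panel
#'
#' Counts messages per (cell, regime, emotion) and derives within-cell
#' proportions.  Regimes are `all`, `day`/`night` (by local hour against
#' `day_window`), and `weekday`/`weekend`.  Messages with the `NA` sentinel
#' cell id (outside the grid) are dropped.
#'
#' @param messages data.frame with `cell_id`, `timestamp`, `emotion`.
#' @param day_window hours `c(start, end)` defining "day".
#' @return Long data.frame `(cell_id, regime, emotion, count, proportion)`,
#'   complete over the cross of observed cells x 5 regimes x 6 emotions;
#'   `proportion` is `NA` where a (cell, regime) stratum has no messages.
#' @export
aggregate_panel <- function(messages, day_window = c(6, 18)) {
  stopifnot(all(c("cell_id", "timestamp", "emotion") %in% names(messages)))
  assert_emotion(messages$emotion)
  msg <- messages[!is.na(messages$cell_id), , drop = FALSE]
  if (nrow(msg) == 0L) stop("no messages fall inside the grid", call. = FALSE)
  fl <- regime_flags(msg$timestamp, day_window)
  cells <- sort(unique(msg$cell_id))
  emo <- factor(msg$emotion, levels = EMOTIONS)
  cid <- factor(msg$cell_id, levels = cells)

  slice_counts <- function(keep) {
    tab <- table(cid[keep], emo[keep])
    as.vector(t(tab))  # cell-major, emotion within cell
  }
  keeps <- list(all = rep(TRUE, nrow(msg)), day = fl$day, night = !fl$day,
                weekday = !fl$weekend, weekend = fl$weekend)
  out <- do.call(rbind, lapply(REGIMES, function(rg) {
    cnt <- slice_counts(keeps[[rg]])
    data.frame(cell_id = rep(cells, each = 6L),
               regime = rg,
               emotion = rep(EMOTIONS, times = length(cells)),
               count = as.integer(cnt))
  }))
  tot <- stats::ave(out$count, out$cell_id, out$regime, FUN = sum)
  out$proportion <- ifelse(tot > 0, out$count / tot, NA_real_)
  rownames(out) <- NULL
  out
}

#' Apply the minimum-message filter to a panel
#'
#' Removes cells whose all-regime total falls below `min_n` (default 20
#' messages): sparse cells make per-cell emotion proportions unreliable.
#' The retained-cell count is the `n` used by all downstream spatial
#' statistics.
#'
#' @param panel output of [aggregate_panel()].
#' @param min_n minimum all-regime message count for a cell to be kept.
#' @return The panel restricted to retained cells.
#' @export
filter_min_count <- function(panel, min_n = 20L) {
  stopifnot(all(c("cell_id", "regime", "emotion", "count") %in% names(panel)))
  allp <- panel[panel$regime == "all", , drop = FALSE]
  tot <- tapply(allp$count, allp$cell_id, sum)
  keep <- as.numeric(names(tot))[tot >= min_n]
  if (length(keep) == 0L) stop("no cells survive filter", call. = FALSE)
  out <- panel[panel$cell_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# cells present in a panel, sorted
panel_cells <- function(panel) sort(unique(panel$cell_id))

# extract one (regime, emotion) slice of proportions in cell-id order
panel_slice <- function(panel, emotion, regime, cells = panel_cells(panel)) {
  sl <- panel[panel$regime == regime & panel$emotion == emotion, , drop = FALSE]
  sl <- sl[match(cells, sl$cell_id), , drop = FALSE]
  if (anyNA(sl$cell_id)) stop("panel is missing cells for this slice", call. = FALSE)
  stats::setNames(sl$proportion, cells)
}

#' Cells whose centers fall inside a disk
#'
#' Convenience for locating planted structures: returns the ids of cells
#' whose center lies within `radius` (degrees) of `center`.
#'
#' @param grid a [hex_grid()].
#' @param center `(lon, lat)` of the disk center.
#' @param radius disk radius in degrees.
#' @param cell_ids optional subset to search within.
#' @return Integer vector of cell ids.
#' @export
cells_in_disk <- function(grid, center, radius, cell_ids = NULL) {
  cells <- grid$cells
  if (!is.null(cell_ids)) cells <- cells[cells$cell_id %in% cell_ids, ]
  d2 <- (cells$lon - center[1])^2 + (cells$lat - center[2])^2
  cells$cell_id[d2 <= radius^2]
}
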