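test_that("grid matches a pen-and-paper tiling of a 3-cell-wide bbox", {
  s <- 0.1
  # pointy-top: cell width sqrt(3)*s, row height 1.5*s.
  # bbox width = 3 cell widths, height = 0.3:
  #   row r=0 (y=0):    x = sqrt(3)*s*q,       q = 0..3  -> 4 centers
  #   row r=1 (y=0.15): x = sqrt(3)*s*(q+1/2), q = 0..2  -> 3 centers
  #   row r=2 (y=0.30): x = sqrt(3)*s*(q+1),   q = -1..2 -> 4 centers
  g <- hex_grid(c(0, 0, 3 * sqrt(3) * s, 0.3), s, "pointy")
  expect_equal(nrow(g$cells), 11L)
  expect_equal(sum(g$cells$r == 0), 4L)
  expect_equal(sum(g$cells$r == 1), 3L)
  expect_equal(sum(g$cells$r == 2), 4L)
})

test_that("grid construction is deterministic and interior cells have 6 neighbors", {
  g1 <- hex_grid(c(0, 0, 1, 1), 0.07)
  g2 <- hex_grid(c(0, 0, 1, 1), 0.07)
  expect_identical(g1, g2)
  nb <- hex_neighbors(g1)
  # interior cells: all six lattice neighbors present
  counts <- lengths(nb)
  expect_true(any(counts == 6L))
  expect_true(all(counts <= 6L))
  # adjacency is symmetric
  ids <- as.integer(names(nb))
  for (i in seq_along(nb)) {
    for (j in nb[[i]]) {
      expect_true(ids[i] %in% nb[[as.character(j)]])
    }
  }
})

test_that("degenerate grids are rejected", {
  expect_error(hex_grid(c(0, 0, 1, 1), 2), "cell_size larger")
  expect_error(hex_grid(c(0, 0, 1, 1), 0), "positive")
  expect_error(hex_grid(c(1, 0, 0, 1), 0.1), "bbox")
})

test_that("points map to the containing hexagon; conservation holds", {
  g <- hex_grid(c(0, 0, 1, 1), 0.08)
  # cell centers map to their own cell
  probe <- data.frame(lon = g$cells$lon, lat = g$cells$lat)
  a <- assign_points(g, probe)
  expect_identical(a$cell_id, g$cells$cell_id)
  # random interior points: every one assigned (conservation)
  set.seed(1)
  pts <- data.frame(lon = runif(500, 0.2, 0.8), lat = runif(500, 0.2, 0.8))
  a <- assign_points(g, pts)
  expect_false(anyNA(a$cell_id))
  expect_true(all(a$cell_id %in% g$cells$cell_id))
  # and each point is nearest to its assigned center
  d_assigned <- sqrt((pts$lon - g$cells$lon[a$cell_id])^2 +
                     (pts$lat - g$cells$lat[a$cell_id])^2)
  expect_true(all(d_assigned <= g$cell_size + 1e-12))
})

test_that("a far-outside point gets the sentinel id", {
  g <- hex_grid(c(0, 0, 1, 1), 0.1)
  a <- assign_points(g, data.frame(lon = 5, lat = 5))
  expect_true(is.na(a$cell_id))
})

test_that("shared-edge midpoints resolve to the lower cell id", {
  s <- 0.1
  g <- hex_grid(c(0, 0, 1, 1), s, "pointy")
  # cells 1 (q=0,r=0, center (0,0)) and 2 (q=1,r=0, center (sqrt(3)s, 0))
  # share the vertical edge at x = sqrt(3)s/2; its midpoint is equidistant
  expect_identical(g$cells$cell_id[g$cells$q == 0 & g$cells$r == 0], 1L)
  expect_identical(g$cells$cell_id[g$cells$q == 1 & g$cells$r == 0], 2L)
  mid <- data.frame(lon = sqrt(3) * s / 2, lat = 0)
  expect_identical(assign_points(g, mid)$cell_id, 1L)
})

make_toy_messages <- function() {
  # two cells' worth of points on a small grid with fixed regimes:
  # Mon 2019-06-03 (weekday) at 10:00 (day) and 23:00 (night),
  # Sat 2019-06-08 (weekend) at 12:00 (day)
  data.frame(
    id = sprintf("m%d", 1:6),
    lon = c(0.31, 0.31, 0.31, 0.52, 0.52, 0.52),
    lat = c(0.33, 0.33, 0.33, 0.52, 0.52, 0.52),
    timestamp = c("2019-06-03T10:00:00", "2019-06-03T23:00:00",
                  "2019-06-08T12:00:00", "2019-06-03T10:30:00",
                  "2019-06-08T13:00:00", "2019-06-08T23:30:00"),
    emotion = c("happy", "happy", "sad", "angry", "angry", "neutral"),
    stringsAsFactors = FALSE)
}

test_that("aggregation counts by cell, regime and emotion with exact partitions", {
  g <- hex_grid(c(0, 0, 1, 1), 0.1)
  msg <- assign_points(g, make_toy_messages())
  panel <- aggregate_panel(msg)
  # proportions sum to 1 within every non-empty (cell, regime)
  sums <- stats::aggregate(proportion ~ cell_id + regime, panel, sum)
  expect_true(all(abs(sums$proportion - 1) < 1e-9))
  # day + night = all and weekday + weekend = all, per cell and emotion
  wide <- stats::reshape(panel[, c("cell_id", "regime", "emotion", "count")],
                         idvar = c("cell_id", "emotion"),
                         timevar = "regime", direction = "wide")
  expect_equal(wide$count.day + wide$count.night, wide$count.all)
  expect_equal(wide$count.weekday + wide$count.weekend, wide$count.all)
  # grand total equals the number of in-grid messages
  expect_equal(sum(panel$count[panel$regime == "all"]), 6L)
  # single-message attribution
  c1 <- msg$cell_id[1]
  one <- panel[panel$cell_id == c1 & panel$regime == "all", ]
  expect_equal(one$count[one$emotion == "happy"], 2L)
  expect_equal(one$count[one$emotion == "sad"], 1L)
  expect_equal(sum(one$count), 3L)
})

test_that("unknown emotion labels are rejected by name", {
  g <- hex_grid(c(0, 0, 1, 1), 0.1)
  msg <- make_toy_messages()
  msg$emotion[2] <- "elated"
  expect_error(aggregate_panel(assign_points(g, msg)), "elated")
})

test_that("minimum-count filter keeps exactly the cells at or above threshold", {
  toy_panel <- function(totals) {
    do.call(rbind, lapply(seq_along(totals), function(i) {
      data.frame(cell_id = i, regime = "all", emotion = emotion_levels(),
                 count = c(totals[i], 0L, 0L, 0L, 0L, 0L),
                 proportion = c(1, 0, 0, 0, 0, 0))
    }))
  }
  p <- toy_panel(c(5L, 19L, 20L, 100L))
  kept <- unique(filter_min_count(p, 20)$cell_id)
  expect_identical(kept, c(3L, 4L))          # 19 removed, 20 retained
  expect_identical(unique(filter_min_count(toy_panel(c(5L, 20L, 100L)), 20)$cell_id),
                   c(2L, 3L))
  expect_identical(filter_min_count(p, 0), p)  # min_n = 0 is the identity
  expect_error(filter_min_count(p, 1000), "no cells survive")
  # monotonicity: higher threshold never retains more cells
  retained <- vapply(c(0, 5, 19, 20, 21, 100),
                     function(m) length(unique(filter_min_count(p, m)$cell_id)),
                     numeric(1))
  expect_true(all(diff(retained) <= 0))
})
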