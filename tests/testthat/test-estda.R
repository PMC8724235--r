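test_that("LISA coordinates are standardized and lag is the neighbor mean", {
  D <- demo_panel()
  cc <- lisa_coordinates(D$panel, "happy", "day", D$w)
  n <- length(cc$z)
  expect_equal(mean(cc$z), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(cc$z^2) / n), 1, tolerance = 1e-12)
  # hand-check the lag of one cell: row-standardized neighbor mean
  i <- which(lengths(D$w$neighbors) == 6L)[1]
  expect_equal(cc$lag[i], mean(cc$z[D$w$neighbors[[i]]]), tolerance = 1e-12)
})

test_that("lag of a cell with identical neighbors equals the common value", {
  # 5-cell star: center 1 with four neighbors, hand-computable lags
  w <- structure(list(
    ids = 1:5,
    neighbors = list(2:5, 1L, 1L, 1L, 1L),
    weights = list(rep(0.25, 4), 1, 1, 1, 1),
    style = "W", islands = integer(0)), class = "spatial_weights")
  z <- c(2, 1, 1, 1, 1)
  lag <- vapply(seq_along(z), function(i) {
    sum(w$weights[[i]] * z[w$neighbors[[i]]])
  }, numeric(1))
  expect_equal(lag, c(1, 2, 2, 2, 2))  # center sees 1, leaves see 2
})

test_that("time-path relative lengths reproduce a hand-worked 3-cell example", {
  # slice 1: (0,0), (1,1), (2,0); slice 2: (1,0), (1,1), (2,2)
  # distances: 1, 0, 2 -> total 3, n = 3 -> T_i = (1, 0, 2)
  c0 <- data.frame(cell_id = 1:3, z = c(0, 1, 2), lag = c(0, 1, 0),
                   quadrant = c("LL", "HH", "HL"))
  c1 <- data.frame(cell_id = 1:3, z = c(1, 1, 2), lag = c(0, 1, 2),
                   quadrant = c("HL", "HH", "HH"))
  tp <- time_path_relative_length(list(c0, c1))
  expect_equal(tp$T_i, c(1, 0, 2), tolerance = 1e-12)
  expect_equal(mean(tp$T_i), 1, tolerance = 1e-12)
  # reversing the slice order leaves T_i unchanged (distance symmetry)
  expect_equal(time_path_relative_length(list(c1, c0))$T_i, tp$T_i,
               tolerance = 1e-12)
})

test_that("equal movement gives T_i = 1 everywhere; no movement errors", {
  c0 <- data.frame(cell_id = 1:4, z = rep(0, 4), lag = rep(0, 4),
                   quadrant = rep("LL", 4))
  c1 <- data.frame(cell_id = 1:4, z = rep(1, 4), lag = rep(0, 4),
                   quadrant = rep("HL", 4))
  expect_equal(time_path_relative_length(list(c0, c1))$T_i, rep(1, 4))
  expect_error(time_path_relative_length(list(c0, c0)), "no dynamics")
  expect_error(time_path_relative_length(list(c0)), "2 slices")
  c2 <- c1; c2$cell_id <- 5:8
  expect_error(time_path_relative_length(list(c0, c2)), "cell sets differ")
})

test_that("mean T_i is exactly 1 on random instances (algebraic identity)", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    Tn <- sample(2:4, 1)
    coords <- lapply(seq_len(Tn), function(t) {
      data.frame(cell_id = seq_len(n), z = rnorm(n), lag = rnorm(n),
                 quadrant = "HH")
    })
    tp <- time_path_relative_length(coords)
    expect_equal(mean(tp$T_i), 1, tolerance = 1e-9)
    expect_true(all(tp$T_i >= 0))
  }
})

test_that("the 16 quadrant pairs partition into types 4/4/4/2/2", {
  quads <- c("HH", "HL", "LH", "LL")
  pairs <- expand.grid(from = quads, to = quads, stringsAsFactors = FALSE)
  type <- classify_transition(pairs$from, pairs$to)
  expect_false(anyNA(type))  # total function
  expect_equal(as.integer(table(type)), c(4L, 4L, 4L, 2L, 2L))
  # spot checks of the taxonomy
  expect_identical(as.character(classify_transition("HH", "HH")), "I")
  expect_identical(as.character(classify_transition("HH", "LH")), "II")
  expect_identical(as.character(classify_transition("HH", "HL")), "III")
  expect_identical(as.character(classify_transition("HH", "LL")), "IV(a)")
  expect_identical(as.character(classify_transition("LL", "HH")), "IV(a)")
  expect_identical(as.character(classify_transition("HL", "LH")), "IV(b)")
  expect_identical(as.character(classify_transition("LH", "HL")), "IV(b)")
  expect_error(classify_transition("HH", "XX"), "malformed")
})

test_that("flow and cohesion follow their defining arithmetic", {
  fc <- flow_cohesion(c(0.60, 0.29, 0.08, 0.01, 0.01))
  expect_equal(fc$cohesion, 0.61, tolerance = 1e-12)
  fc <- flow_cohesion(c(0.41, 0.23, 0.22, 0.07, 0.07))
  expect_equal(fc$flow, 0.45, tolerance = 1e-12)
  expect_equal(fc$cohesion, 0.48, tolerance = 1e-12)
})

test_that("transition summaries are closed: shares sum to 1, F + C + IV(b) = 1", {
  D <- demo_panel()
  for (pair in c("day_night", "weekday_weekend")) {
    tab <- transition_table(D$panel, pair, D$w)
    shares <- as.matrix(tab[, c("I", "II", "III", "IV(a)", "IV(b)")])
    expect_equal(rowSums(shares), rep(1, 6), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(tab$SF + tab$SC + tab$`IV(b)`, rep(1, 6), tolerance = 1e-9)
    expect_equal(tab$SF, tab$II + tab$III, tolerance = 1e-12)
    expect_equal(tab$SC, tab$I + tab$`IV(a)`, tolerance = 1e-12)
    counts <- as.matrix(tab[, c("S_I", "S_II", "S_III", "S_IVa", "S_IVb")])
    expect_true(all(rowSums(counts) == tab$m))
  }
})

test_that("a static field is all Type I with F = 0, C = 1", {
  # panel where day and night slices are identical -> no movement
  D <- demo_panel()
  p <- D$panel
  idx_day <- which(p$regime == "day")
  idx_night <- which(p$regime == "night")
  key <- paste(p$cell_id, p$emotion)
  map <- match(key[idx_night], key[idx_day])
  p$count[idx_night] <- p$count[idx_day][map]
  p$proportion[idx_night] <- p$proportion[idx_day][map]
  ts <- transition_summary(p, "happy", "day_night", D$w)
  expect_equal(ts$SF, 0)
  expect_equal(ts$SC, 1)
  expect_equal(ts$S_I, ts$m)
})

test_that("summed time paths feed the volatility layer linearly", {
  D <- demo_panel()
  ti <- time_path_by_emotion(D$panel, "day_night", D$w)
  expect_equal(ti$total,
               rowSums(as.matrix(ti[, emotion_levels()])), tolerance = 1e-12)
  # each emotion column has mean 1 (relative lengths)
  for (emo in emotion_levels()) {
    expect_equal(mean(ti[[emo]]), 1, tolerance = 1e-9)
  }
  vol <- volatility_hotspots(D$panel, "day_night", D$w)
  expect_identical(vol$gistar$value, ti$total)
})
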