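# Independent brute-force oracles for the spatial statistics, written as
# literal double loops over a dense weight matrix, plus small fixture
# builders.  The oracles deliberately share no code with the package
# internals they check.

# dense weight matrix from a spatial_weights object
weights_matrix <- function(w) {
  n <- length(w$ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- w$neighbors[[i]]
    if (length(nb) > 0L) W[i, nb] <- w$weights[[i]]
  }
  W
}

# global Moran's I: two nested loops over the double-sum formula
oracle_global_moran <- function(x, W) {
  n <- length(x)
  xbar <- mean(x)
  s0 <- 0; num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s0 <- s0 + W[i, j]
      num <- num + W[i, j] * (x[i] - xbar) * (x[j] - xbar)
    }
  }
  (n / s0) * num / sum((x - xbar)^2)
}

# local Moran's I_i with population-sd standardization
oracle_local_moran <- function(x, W) {
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum((x - xbar)^2) / n)
  z <- (x - xbar) / s
  Ii <- numeric(n)
  for (i in seq_len(n)) {
    lag <- 0
    for (j in seq_len(n)) lag <- lag + W[i, j] * z[j]
    Ii[i] <- z[i] * lag
  }
  Ii
}

# Gi* z-scores: self-included binary weights, analytic mean/variance
oracle_gistar <- function(x, Wbin) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    wi <- Wbin[i, ]
    wi[i] <- 1
    sw <- 0; sx <- 0; sw2 <- 0
    for (j in seq_len(n)) {
      sw <- sw + wi[j]
      sw2 <- sw2 + wi[j]^2
      sx <- sx + wi[j] * x[j]
    }
    out[i] <- if (sw == n) 0 else {
      (sx - xbar * sw) / (S * sqrt((n * sw2 - sw^2) / (n - 1)))
    }
  }
  out
}

# chi-square test statistic for a 2x2 table, from the textbook formula
oracle_chisq_2x2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# small hexagonal lattice with weights, shared by the oracle tests
small_lattice <- function(bbox = c(0, 0, 1, 1), cell_size = 0.22,
                          style = "W") {
  g <- hex_grid(bbox, cell_size)
  list(grid = g, w = contiguity_weights(g, style = style))
}

# a filtered panel + weights from the planted demo generator, small scale
demo_panel <- function(n_messages = 6000, seed = 42, cell_size = 0.05,
                       min_n = 10) {
  cfg <- planted_demo_config(n_messages = n_messages, seed = seed)
  msg <- generate_messages(cfg)
  g <- hex_grid(cfg$bbox, cell_size)
  panel <- filter_min_count(aggregate_panel(assign_points(g, msg)), min_n)
  cells <- sort(unique(panel$cell_id))
  list(config = cfg, messages = msg, grid = g, panel = panel, cells = cells,
       w = contiguity_weights(g, cells, style = "W"))
}
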