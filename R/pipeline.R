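## End-to-end orchestration: simulate or ingest messages, grid, filter,
## per-emotion spatial statistics, regime-pair dynamics, volatility
## hot spots, and word shifts between emotion strata; all artifacts land
## on disk with a machine-readable run log.

#' Build a pipeline configuration
#'
#' @param input optional path to a message CSV; when `NULL` the simulation
#'   block is used instead.
#' @param simulation a [sim_config()] (used when `input` is `NULL`).
#' @param cell_size hexagon circumradius in degrees.
#' @param orientation hexagon orientation, `"pointy"` or `"flat"`.
#' @param min_n minimum messages per retained cell.
#' @param day_window local hours `c(start, end)` defining "day".
#' @param n_perm permutations for Moran/LISA inference.
#' @param alpha two-sided significance level for hot/cold labels.
#' @param reference_emotion reference stratum for the word shifts.
#' @param top_k contributors kept in word-shift outputs.
#' @param stoplist optional tokens dropped before word-shift computation.
#' @param seed master seed for permutation inference.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            simulation = sim_config(),
                            cell_size = 0.02,
                            orientation = "pointy",
                            min_n = 20L,
                            day_window = c(6, 18),
                            n_perm = 999L,
                            alpha = 0.05,
                            reference_emotion = "neutral",
                            top_k = 20L,
                            stoplist = character(0),
                            seed = 1L) {
  assert_emotion(reference_emotion)
  if (min_n < 0L) stop("min_n must be non-negative", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(input = input, simulation = simulation,
                 cell_size = cell_size, orientation = orientation,
                 min_n = as.integer(min_n), day_window = day_window,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 reference_emotion = reference_emotion,
                 top_k = as.integer(top_k), stoplist = stoplist,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; the `simulation` block is passed to
#' [sim_config()] and validated there.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(raw$input) && is.null(raw$simulation)) {
    stop("configuration must provide 'input' or 'simulation'", call. = FALSE)
  }
  if (!is.null(raw$simulation)) {
    sim_known <- names(formals(sim_config))
    sim_unknown <- setdiff(names(raw$simulation), sim_known)
    if (length(sim_unknown) > 0L) {
      stop(sprintf("unknown simulation key(s): %s",
                   paste(sim_unknown, collapse = ", ")), call. = FALSE)
    }
    if (!is.null(raw$simulation$bbox)) {
      raw$simulation$bbox <- as.numeric(raw$simulation$bbox)
    }
    raw$simulation <- do.call(sim_config, raw$simulation)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or read) messages, build the hexagonal grid, assign
#' points, aggregate the cell-emotion panel, apply the minimum-count
#' filter, build contiguity weights, run per-emotion global Moran's I,
#' LISA and Gi* on the all-regime proportions, compute transition tables
#' and volatility hot spots for both regime pairs, and word shifts of each
#' emotion stratum against the reference stratum.  All artifacts plus a
#' machine-readable run log (seed, parameters, package version) are
#' written under `outdir`.  A stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if absent).
#' @return Invisibly, a list with the grid, panel, weights, per-emotion
#'   ESDA results, transition tables, volatility layers and word shifts.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  log_msg <- function(...) message(sprintf(...))

  messages <- stage("ingest", {
    if (!is.null(config$input)) {
      log_msg("reading messages from %s", config$input)
      read_messages(config$input)
    } else {
      log_msg("simulating %d messages (seed %d)",
              config$simulation$n_messages, config$simulation$seed)
      generate_messages(config$simulation)
    }
  })
  write_messages(messages, file.path(outdir, "messages.csv"))

  bbox <- if (!is.null(config$input)) {
    c(min(messages$lon), min(messages$lat), max(messages$lon), max(messages$lat))
  } else config$simulation$bbox

  grid <- stage("grid", hex_grid(bbox, config$cell_size, config$orientation))
  log_msg("grid: %d cells of circumradius %g deg", nrow(grid$cells),
          config$cell_size)
  assigned <- stage("assign", assign_points(grid, messages))
  panel <- stage("aggregate", aggregate_panel(assigned, config$day_window))
  panel <- stage("filter", filter_min_count(panel, config$min_n))
  cells <- panel_cells(panel)
  log_msg("retained %d cells with >= %d messages", length(cells), config$min_n)
  utils::write.csv(panel, file.path(outdir, "panel.csv"), row.names = FALSE)

  w <- stage("weights", contiguity_weights(grid, cells, style = "W"))

  esda <- stage("esda", {
    lapply(stats::setNames(EMOTIONS, EMOTIONS), function(emo) {
      x <- panel_slice(panel, emo, "all", cells)
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      list(moran = global_morans_i(x, w, config$n_perm, seed = config$seed),
           lisa = local_morans_i(x, w, config$n_perm, seed = config$seed),
           gistar = getis_ord_gistar(x, w, alpha = config$alpha))
    })
  })
  for (emo in EMOTIONS) {
    props <- data.frame(cell_id = cells,
                        proportion = esda[[emo]]$lisa$value,
                        Ii = esda[[emo]]$lisa$Ii,
                        quadrant = esda[[emo]]$lisa$quadrant,
                        lisa_p = esda[[emo]]$lisa$p_value,
                        gistar = esda[[emo]]$gistar$gistar,
                        category = esda[[emo]]$gistar$category)
    write_grid_geojson(grid, file.path(outdir, sprintf("esda_%s.geojson", emo)),
                       cell_ids = cells, properties = props)
  }

  estda <- stage("estda", {
    lapply(stats::setNames(names(REGIME_PAIRS), names(REGIME_PAIRS)),
           function(pr) {
             list(transitions = transition_table(panel, pr, w),
                  volatility = volatility_hotspots(panel, pr, w,
                                                   alpha = config$alpha))
           })
  })
  for (pr in names(REGIME_PAIRS)) {
    write_transition_csv(estda[[pr]]$transitions,
                         file.path(outdir, sprintf("transitions_%s.csv", pr)))
    vol <- estda[[pr]]$volatility
    props <- data.frame(cell_id = cells, ti_total = vol$ti$total,
                        gistar = vol$gistar$gistar,
                        category = vol$gistar$category)
    write_grid_geojson(grid,
                       file.path(outdir, sprintf("volatility_%s.geojson", pr)),
                       cell_ids = cells, properties = props)
  }

  shifts <- stage("wordshift", {
    strata <- split(messages$tokens, messages$emotion)
    corpora <- lapply(strata, function(tl) {
      tk <- unlist(tl, use.names = FALSE)
      tk[!tk %in% config$stoplist]
    })
    ref <- corpora[[config$reference_emotion]]
    others <- setdiff(names(corpora), config$reference_emotion)
    lapply(stats::setNames(others, others),
           function(emo) entropy_shift(ref, corpora[[emo]]))
  })
  for (emo in names(shifts)) {
    write_shift_tsv(shifts[[emo]],
                    file.path(outdir, sprintf("shift_%s_vs_%s.tsv",
                                              emo, config$reference_emotion)))
  }

  run_log <- list(
    package = "emospat",
    version = as.character(utils::packageVersion("emospat")),
    seed = config$seed,
    parameters = list(cell_size = config$cell_size,
                      orientation = config$orientation, min_n = config$min_n,
                      day_window = config$day_window, n_perm = config$n_perm,
                      alpha = config$alpha,
                      reference_emotion = config$reference_emotion),
    simulation_seed = if (is.null(config$input)) config$simulation$seed else NULL,
    n_messages = nrow(messages),
    n_cells = length(cells))
  jsonlite::write_json(run_log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(messages = messages, grid = grid, panel = panel, weights = w,
                 esda = esda, estda = estda, shifts = shifts,
                 run_log = run_log))
}
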