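## Readers and writers: message tables as CSV (tokens space-joined), grids
## and per-cell statistics as GeoJSON FeatureCollections, panels and
## transition summaries as long/wide CSV, word shifts as TSV.

#' Write a message table to CSV
#'
#' Columns `id,lon,lat,timestamp,emotion,tokens` with tokens space-joined.
#'
#' @param messages a message table (as [generate_messages()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_messages <- function(messages, path) {
  out <- data.frame(id = messages$id, lon = messages$lon, lat = messages$lat,
                    timestamp = messages$timestamp, emotion = messages$emotion,
                    tokens = vapply(messages$tokens, paste, character(1),
                                    collapse = " "),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a message table from CSV
#'
#' Validates each row (parseable timestamp, numeric coordinates, known
#' emotion label, unique id).  Malformed rows are counted, skipped and
#' reported with their line numbers; more than `max_bad_frac` malformed
#' rows is an error.
#'
#' @param path CSV written by [write_messages()] (or matching its schema).
#' @param max_bad_frac hard-failure threshold on the malformed-row fraction.
#' @return A message table with a `tokens` list-column.
#' @export
read_messages <- function(path, max_bad_frac = 0.01) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (nrow(raw) == 0L) stop("empty message file", call. = FALSE)
  need <- c("id", "lon", "lat", "timestamp", "emotion", "tokens")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("message file missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- is.na(lon) | is.na(lat) | is.na(ts) |
    !(raw$emotion %in% EMOTIONS) | raw$id == "" | duplicated(raw$id)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header line offset
    warning(sprintf("skipped %d malformed row(s) at line(s): %s",
                    sum(bad), paste(utils::head(lines, 20L), collapse = ", ")))
    if (mean(bad) > max_bad_frac) {
      stop(sprintf("%.1f%% of rows malformed (limit %.1f%%)",
                   100 * mean(bad), 100 * max_bad_frac), call. = FALSE)
    }
  }
  keep <- !bad
  out <- data.frame(id = raw$id[keep], lon = lon[keep], lat = lat[keep],
                    timestamp = raw$timestamp[keep],
                    emotion = raw$emotion[keep], stringsAsFactors = FALSE)
  out$tokens <- strsplit(raw$tokens[keep], " ", fixed = TRUE)
  out
}

#' Export a grid (with optional per-cell properties) as GeoJSON
#'
#' One polygon feature per cell; `properties` rows are joined by `cell_id`.
#'
#' @param grid a [hex_grid()].
#' @param path output file ending in `.geojson` or `.json`.
#' @param cell_ids optional subset of cells to export.
#' @param properties optional data.frame with a `cell_id` column whose other
#'   columns become feature properties.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path, cell_ids = NULL, properties = NULL) {
  cells <- grid$cells
  if (!is.null(cell_ids)) cells <- cells[cells$cell_id %in% cell_ids, ]
  features <- lapply(seq_len(nrow(cells)), function(i) {
    id <- cells$cell_id[i]
    v <- hex_vertices(grid, id)
    ring <- rbind(v, v[1, , drop = FALSE])
    props <- list(cell_id = id, q = cells$q[i], r = cells$r[i])
    if (!is.null(properties)) {
      row <- properties[properties$cell_id == id, , drop = FALSE]
      if (nrow(row) == 1L) {
        for (nm in setdiff(names(row), "cell_id")) props[[nm]] <- row[[nm]]
      }
    }
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) unname(ring[k, ])))),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a transition table in the standard column order
#'
#' Columns: emotion, shares of types I, II, III, IV(a), IV(b), SF, SC.
#'
#' @param tab a [transition_table()] result.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(tab, path) {
  cols <- c("emotion", "I", "II", "III", "IV(a)", "IV(b)", "SF", "SC")
  utils::write.csv(tab[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a word shift as TSV
#'
#' Columns: token, p1, p2, delta, rank.
#'
#' @param shift an [entropy_shift()] result.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_shift_tsv <- function(shift, path) {
  utils::write.table(shift$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
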