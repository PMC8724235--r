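#' Default background emotion mixture
#'
#' Marginal emotion proportions typical of a large urban microblog corpus:
#' happy and sad dominate, fear and surprise are rare.  Derived from
#' category counts (65766, 37876, 54984, 1611, 9073, 42216 over 211526
#' messages), so the vector sums to 1 exactly up to floating point.
#'
#' @return Named numeric probability vector over the six emotions.
#' @export
default_background_mixture <- function() {
  counts <- c(happy = 65766, angry = 37876, sad = 54984,
              fear = 1611, surprise = 9073, neutral = 42216)
  counts / sum(counts)
}

#' Default per-emotion token vocabulary
#'
#' Disjoint-core plus shared-stopword design: each emotion owns
#' `n_core` exclusive tokens with Zipf-decaying probabilities carrying
#' `1 - stop_mass` of the distribution, and all emotions share `n_stop`
#' uniform stopword tokens carrying `stop_mass`.  The disjoint cores give
#' word-shift and lexicon-classifier tests a known signed structure.
#'
#' @param n_core exclusive tokens per emotion.
#' @param n_stop shared stopword tokens.
#' @param stop_mass total probability of the shared stopwords.
#' @return Named list (by emotion) of named probability vectors.
#' @export
default_vocab <- function(n_core = 15L, n_stop = 10L, stop_mass = 0.4) {
  stopifnot(n_core >= 1L, n_stop >= 0L, stop_mass >= 0, stop_mass < 1)
  stops <- if (n_stop > 0L) {
    stats::setNames(rep(stop_mass / n_stop, n_stop),
                    sprintf("stop%02d", seq_len(n_stop)))
  } else numeric(0)
  out <- lapply(EMOTIONS, function(emo) {
    zipf <- 1 / seq_len(n_core)
    core <- stats::setNames((1 - stop_mass) * zipf / sum(zipf),
                            sprintf("%s_core%02d", emo, seq_len(n_core)))
    c(core, stops)
  })
  stats::setNames(out, EMOTIONS)
}

#' Build and validate a simulation configuration
#'
#' Describes a synthetic geotagged-emotion corpus: a bounding box, a
#' background emotion mixture, optional Gaussian spatial hotspots that boost
#' one emotion, optional regime-dependent mixture multipliers, optional
#' volatile regions whose dominant emotion flips between the two slices of a
#' regime pair, and per-emotion token vocabularies.
#'
#' @param bbox numeric `(min_lon, min_lat, max_lon, max_lat)` in degrees.
#' @param n_messages number of messages to draw.
#' @param background_mixture probability vector over the six emotions
#'   (named or in [emotion_levels()] order).
#' @param hotspots list of hotspots, each a list with `center` (lon, lat),
#'   `sd` (isotropic Gaussian spread, degrees), `emotion`, `boost` in (0, 1]
#'   (weight of the one-hot target mixed into the background), and `share`
#'   (fraction of all points drawn from this hotspot).
#' @param regime_multipliers optional named list with any of `day`, `night`,
#'   `weekday`, `weekend`, each a length-6 non-negative multiplier vector
#'   applied to the mixture (then renormalized) for messages in that regime.
#' @param volatile_regions list of disks whose dominant emotion flips between
#'   regimes: each a list with `center`, `radius` (degrees), `dimension`
#'   (`"daynight"` or `"weekweekend"`), `emotion_a` (dominant in day /
#'   weekday), `emotion_b` (dominant in night / weekend), `boost` in (0, 1].
#' @param vocab per-emotion token distributions, as [default_vocab()].
#' @param tokens_per_message integer range `c(min, max)`.
#' @param date_range two dates (coercible by `as.Date`) spanned uniformly by
#'   the timestamps; the default covers four full Monday-to-Sunday weeks.
#' @param day_window local hours `c(start, end)`; a message is "day" when
#'   `start <= hour < end`.
#' @param seed integer seed; all generator randomness flows from it.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(bbox = c(115.7, 28.4, 116.2, 28.9),
                       n_messages = 20000L,
                       background_mixture = default_background_mixture(),
                       hotspots = list(),
                       regime_multipliers = NULL,
                       volatile_regions = list(),
                       vocab = default_vocab(),
                       tokens_per_message = c(8L, 20L),
                       date_range = c("2019-06-03", "2019-06-30"),
                       day_window = c(6L, 18L),
                       seed = 1L) {
  cfg <- structure(
    list(bbox = as.numeric(bbox), n_messages = as.integer(n_messages),
         background_mixture = background_mixture, hotspots = hotspots,
         regime_multipliers = regime_multipliers,
         volatile_regions = volatile_regions, vocab = vocab,
         tokens_per_message = as.integer(tokens_per_message),
         date_range = as.Date(date_range), day_window = as.numeric(day_window),
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

check_prob_vector <- function(p, field, n = NULL) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    stop(sprintf("configuration error in '%s': not a valid probability vector",
                 field), call. = FALSE)
  }
  if (!is.null(n) && length(p) != n) {
    stop(sprintf("configuration error in '%s': expected length %d, got %d",
                 field, n, length(p)), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("configuration error in '%s': probabilities sum to %.12f, not 1",
                 field, sum(p)), call. = FALSE)
  }
  invisible(p)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  b <- cfg$bbox
  if (length(b) != 4L || b[1] >= b[3] || b[2] >= b[4]) {
    stop("configuration error in 'bbox': need (min_lon, min_lat, max_lon, max_lat) with positive extent",
         call. = FALSE)
  }
  if (cfg$n_messages <= 0L) {
    stop("configuration error in 'n_messages': must be positive", call. = FALSE)
  }
  mix <- cfg$background_mixture
  if (!is.null(names(mix))) {
    assert_emotion(names(mix), "background_mixture")
    mix <- mix[EMOTIONS]
  }
  check_prob_vector(mix, "background_mixture", 6L)
  cfg$background_mixture <- stats::setNames(as.numeric(mix), EMOTIONS)

  shares <- 0
  for (i in seq_along(cfg$hotspots)) {
    h <- cfg$hotspots[[i]]
    fld <- sprintf("hotspots[[%d]]", i)
    if (is.null(h$center) || length(h$center) != 2L ||
        is.null(h$sd) || is.null(h$emotion) || is.null(h$boost) ||
        is.null(h$share)) {
      stop(sprintf("configuration error in '%s': needs center, sd, emotion, boost, share",
                   fld), call. = FALSE)
    }
    if (h$sd <= 0) stop(sprintf("configuration error in '%s': sd must be > 0", fld),
                        call. = FALSE)
    if (h$boost <= 0 || h$boost > 1) {
      stop(sprintf("configuration error in '%s': boost must be in (0, 1]", fld),
           call. = FALSE)
    }
    if (h$share < 0 || h$share > 1) {
      stop(sprintf("configuration error in '%s': share must be in [0, 1]", fld),
           call. = FALSE)
    }
    assert_emotion(h$emotion, fld)
    shares <- shares + h$share
  }
  if (shares > 1 + 1e-12) {
    stop("configuration error in 'hotspots': point shares sum to > 1", call. = FALSE)
  }

  if (!is.null(cfg$regime_multipliers)) {
    ok <- c("day", "night", "weekday", "weekend")
    bad <- setdiff(names(cfg$regime_multipliers), ok)
    if (length(bad) > 0L) {
      stop(sprintf("configuration error in 'regime_multipliers': unknown regime(s) %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (nm in names(cfg$regime_multipliers)) {
      m <- cfg$regime_multipliers[[nm]]
      if (!is.numeric(m) || length(m) != 6L || any(m < 0)) {
        stop(sprintf("configuration error in 'regime_multipliers$%s': need 6 non-negative multipliers",
                     nm), call. = FALSE)
      }
    }
  }

  for (i in seq_along(cfg$volatile_regions)) {
    v <- cfg$volatile_regions[[i]]
    fld <- sprintf("volatile_regions[[%d]]", i)
    if (is.null(v$center) || length(v$center) != 2L || is.null(v$radius) ||
        is.null(v$emotion_a) || is.null(v$emotion_b)) {
      stop(sprintf("configuration error in '%s': needs center, radius, emotion_a, emotion_b",
                   fld), call. = FALSE)
    }
    if (v$radius <= 0) {
      stop(sprintf("configuration error in '%s': radius must be > 0", fld),
           call. = FALSE)
    }
    if (is.null(v$dimension)) v$dimension <- "daynight"
    if (!v$dimension %in% c("daynight", "weekweekend")) {
      stop(sprintf("configuration error in '%s': dimension must be 'daynight' or 'weekweekend'",
                   fld), call. = FALSE)
    }
    if (is.null(v$boost)) v$boost <- 0.8
    if (v$boost <= 0 || v$boost > 1) {
      stop(sprintf("configuration error in '%s': boost must be in (0, 1]", fld),
           call. = FALSE)
    }
    assert_emotion(c(v$emotion_a, v$emotion_b), fld)
    cfg$volatile_regions[[i]] <- v
  }

  if (!setequal(names(cfg$vocab), EMOTIONS)) {
    stop("configuration error in 'vocab': need one token distribution per emotion",
         call. = FALSE)
  }
  for (emo in EMOTIONS) {
    p <- cfg$vocab[[emo]]
    if (is.null(names(p)) || any(names(p) == "")) {
      stop(sprintf("configuration error in 'vocab$%s': tokens must be named", emo),
           call. = FALSE)
    }
    check_prob_vector(p, sprintf("vocab$%s", emo))
  }

  tpm <- cfg$tokens_per_message
  if (length(tpm) != 2L || tpm[1] < 1L || tpm[2] < tpm[1]) {
    stop("configuration error in 'tokens_per_message': need c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (anyNA(cfg$date_range) || cfg$date_range[2] < cfg$date_range[1]) {
    stop("configuration error in 'date_range': need two ordered dates", call. = FALSE)
  }
  dw <- cfg$day_window
  if (length(dw) != 2L || dw[1] < 0 || dw[2] > 24 || dw[1] >= dw[2]) {
    stop("configuration error in 'day_window': need hours c(start, end) with start < end",
         call. = FALSE)
  }
  cfg
}

# isotropic Gaussian truncated to bbox by rejection sampling
rtrunc_gauss <- function(n, center, sd, bbox) {
  lon <- numeric(n); lat <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    m <- length(need)
    x <- stats::rnorm(m, center[1], sd)
    y <- stats::rnorm(m, center[2], sd)
    ok <- x >= bbox[1] & x <= bbox[3] & y >= bbox[2] & y <= bbox[4]
    lon[need[ok]] <- x[ok]
    lat[need[ok]] <- y[ok]
    need <- need[!ok]
  }
  cbind(lon, lat)
}

# draw one categorical outcome per row of a probability matrix
rcat_rows <- function(prob) {
  cum <- prob %*% upper.tri(diag(ncol(prob)), diag = TRUE)
  u <- stats::runif(nrow(prob)) * cum[, ncol(prob)]
  1L + rowSums(u > cum)
}

#' Generate a synthetic message table
#'
#' Draws `n_messages` geotagged, timestamped, emotion-labeled, tokenized
#' messages.  Point locations come from a uniform background over the
#' bounding box plus truncated isotropic Gaussians for each hotspot; each
#' message's emotion is drawn from a location- and regime-dependent mixture;
#' tokens are drawn i.i.d. from the emotion's vocabulary.  Fully reproducible
#' given the config seed (the caller's RNG state is untouched).
#'
#' @param config a [sim_config()] object.
#' @return A data.frame with columns `id`, `lon`, `lat`, `timestamp`
#'   (ISO-8601 character), `emotion`, and a list-column `tokens`.
#' @export
generate_messages <- function(config) {
  config <- validate_sim_config(config)
  bbox <- config$bbox
  n <- config$n_messages

  withr::with_seed(config$seed, {
    ## locations: background vs hotspot sources
    shares <- vapply(config$hotspots, function(h) h$share, numeric(1))
    src <- if (length(shares) > 0L) {
      sample.int(length(shares) + 1L, n, replace = TRUE,
                 prob = c(1 - sum(shares), shares)) - 1L
    } else rep(0L, n)
    lon <- numeric(n); lat <- numeric(n)
    bg <- src == 0L
    lon[bg] <- stats::runif(sum(bg), bbox[1], bbox[3])
    lat[bg] <- stats::runif(sum(bg), bbox[2], bbox[4])
    for (h in seq_along(config$hotspots)) {
      idx <- which(src == h)
      if (length(idx) == 0L) next
      hs <- config$hotspots[[h]]
      pts <- rtrunc_gauss(length(idx), hs$center, hs$sd, bbox)
      lon[idx] <- pts[, 1]; lat[idx] <- pts[, 2]
    }

    ## timestamps: uniform date in range, uniform second in the day
    days <- seq(config$date_range[1], config$date_range[2], by = "day")
    date <- days[sample.int(length(days), n, replace = TRUE)]
    secs <- floor(stats::runif(n, 0, 86400))
    ts <- as.POSIXct(date, tz = "UTC") + secs
    hour <- secs / 3600
    is_day <- hour >= config$day_window[1] & hour < config$day_window[2]
    is_weekend <- format(date, "%u") %in% c("6", "7")

    ## emotion mixtures per message
    M <- matrix(config$background_mixture, n, 6L, byrow = TRUE)
    for (h in seq_along(config$hotspots)) {
      idx <- which(src == h)
      if (length(idx) == 0L) next
      hs <- config$hotspots[[h]]
      tgt <- matrix(emotion_onehot(hs$emotion), length(idx), 6L, byrow = TRUE)
      M[idx, ] <- (1 - hs$boost) * M[idx, , drop = FALSE] + hs$boost * tgt
    }
    rm_apply <- function(rows, mult) {
      if (length(rows) == 0L) return()
      M[rows, ] <<- sweep(M[rows, , drop = FALSE], 2L, mult, `*`)
    }
    rmul <- config$regime_multipliers
    if (!is.null(rmul)) {
      if (!is.null(rmul$day)) rm_apply(which(is_day), rmul$day)
      if (!is.null(rmul$night)) rm_apply(which(!is_day), rmul$night)
      if (!is.null(rmul$weekday)) rm_apply(which(!is_weekend), rmul$weekday)
      if (!is.null(rmul$weekend)) rm_apply(which(is_weekend), rmul$weekend)
      M <- M / rowSums(M)
    }
    for (v in config$volatile_regions) {
      inside <- (lon - v$center[1])^2 + (lat - v$center[2])^2 <= v$radius^2
      first <- if (v$dimension == "daynight") is_day else !is_weekend
      for (slice in c(TRUE, FALSE)) {
        idx <- which(inside & (first == slice))
        if (length(idx) == 0L) next
        emo <- if (slice) v$emotion_a else v$emotion_b
        tgt <- matrix(emotion_onehot(emo), length(idx), 6L, byrow = TRUE)
        M[idx, ] <- (1 - v$boost) * M[idx, , drop = FALSE] + v$boost * tgt
      }
    }
    emotion <- EMOTIONS[rcat_rows(M)]

    ## tokens, drawn per emotion stratum for speed
    tpm <- config$tokens_per_message
    k <- if (tpm[1] == tpm[2]) rep(tpm[1], n) else
      sample(seq(tpm[1], tpm[2]), n, replace = TRUE)
    tokens <- vector("list", n)
    for (emo in EMOTIONS) {
      idx <- which(emotion == emo)
      if (length(idx) == 0L) next
      p <- config$vocab[[emo]]
      draw <- sample(names(p), sum(k[idx]), replace = TRUE, prob = p)
      tokens[idx] <- split(draw, rep(seq_along(idx), k[idx]))
    }

    out <- data.frame(
      id = sprintf("msg%07d", seq_len(n)),
      lon = lon, lat = lat,
      timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      emotion = emotion,
      stringsAsFactors = FALSE)
    out$tokens <- tokens
    out
  })
}

#' Generate a pair of multinomial token corpora
#'
#' Draws `n_tokens` i.i.d. tokens from each of two token distributions;
#' the standard fixture for word-shift computations.
#'
#' @param vocab_a,vocab_b named probability vectors (token -> probability).
#' @param n_tokens tokens per corpus; must be positive.
#' @param seed integer seed.
#' @return List with character vectors `corpus_a` and `corpus_b`.
#' @export
generate_paired_corpora <- function(vocab_a, vocab_b, n_tokens, seed = 1L) {
  if (n_tokens <= 0) stop("n_tokens must be positive", call. = FALSE)
  check_prob_vector(vocab_a, "vocab_a")
  check_prob_vector(vocab_b, "vocab_b")
  withr::with_seed(seed, {
    list(
      corpus_a = sample(names(vocab_a), n_tokens, replace = TRUE, prob = vocab_a),
      corpus_b = sample(names(vocab_b), n_tokens, replace = TRUE, prob = vocab_b))
  })
}

#' Expected emotion mixture at a location under a configuration
#'
#' Analytic (noise-free) emotion mixture for a point drawn from the given
#' source, before regime effects: used to assert planted-structure
#' recoverability on expectations rather than noisy realizations.
#'
#' @param config a [sim_config()].
#' @param hotspot index of the hotspot the point was drawn from, or `NULL`
#'   for a background point.
#' @return Named probability vector over the six emotions.
#' @export
expected_mixture <- function(config, hotspot = NULL) {
  config <- validate_sim_config(config)
  mix <- config$background_mixture
  if (!is.null(hotspot)) {
    hs <- config$hotspots[[hotspot]]
    mix <- (1 - hs$boost) * mix + hs$boost * emotion_onehot(hs$emotion)
  }
  stats::setNames(as.numeric(mix), EMOTIONS)
}

#' Demonstration configuration with planted structure
#'
#' One happy hotspot (an isotropic Gaussian holding 30% of all points, its
#' mixture boosted 0.8 toward happy) and one volatile region (a disk whose
#' dominant emotion flips from sad by day to fear by night), on the default
#' bounding box.  Used by the worked examples and the recovery checks.
#'
#' @param n_messages number of messages.
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
planted_demo_config <- function(n_messages = 20000L, seed = 1L) {
  sim_config(
    n_messages = n_messages,
    hotspots = list(list(center = c(116.05, 28.75), sd = 0.03,
                         emotion = "happy", boost = 0.8, share = 0.3)),
    volatile_regions = list(list(center = c(115.85, 28.52), radius = 0.06,
                                 dimension = "daynight",
                                 emotion_a = "sad", emotion_b = "fear",
                                 boost = 0.8)),
    seed = seed)
}
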