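# Amplitude-envelope segmentation of echemes and phrase annotation.

#' Amplitude envelope of a waveform
#'
#' Rectified (absolute-value) signal smoothed with a centred moving average
#' of width `smooth_ms` and scaled by pi/2, so that a unit-amplitude sine
#' burst has an envelope plateau near 1. The result has the same length as
#' the input and is non-negative.
#'
#' @param waveform Numeric vector (mono audio).
#' @param sample_rate Sampling rate in Hz.
#' @param smooth_ms Smoothing window in milliseconds (> 0).
#' @return Numeric vector of envelope values.
#' @export
amplitude_envelope <- function(waveform, sample_rate, smooth_ms = 2) {
  if (length(waveform) == 0L) stop("empty waveform")
  if (smooth_ms <= 0) stop("'smooth_ms' must be > 0")
  w <- max(1L, as.integer(round(smooth_ms / 1000 * sample_rate)))
  (pi / 2) * moving_average(abs(waveform), w)
}

# centred moving average via cumulative sums; shrinking window at the edges
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 1L) return(x)
  cs <- cumsum(x)
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi] - cs[lo] + x[lo]) / (hi - lo + 1L)
}

#' Segmentation configuration
#'
#' Detection operates on a block-averaged envelope (about `env_rate`
#' samples per second, i.e. sub-millisecond resolution) with a relative
#' Schmitt trigger: an event is a run of envelope samples above
#' `hysteresis_db` (relative to the 99th-percentile envelope level) that
#' contains at least one sample above `threshold_db`. Runs closer than
#' `merge_gap_s` are merged and runs shorter than `min_event_s` dropped.
#'
#' @param threshold_db Detection threshold in dB relative to the peak level.
#' @param hysteresis_db Boundary (hysteresis) threshold in dB.
#' @param min_event_s Minimum event duration in seconds.
#' @param merge_gap_s Gaps shorter than this are bridged.
#' @param smooth_ms Envelope smoothing in milliseconds.
#' @param env_rate Approximate envelope sampling rate in Hz.
#' @param peak_quantile Quantile of the envelope used as the peak reference.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_db = -20, hysteresis_db = -23,
                                min_event_s = 0.005, merge_gap_s = 0.003,
                                smooth_ms = 2, env_rate = 4000,
                                peak_quantile = 0.99) {
  stopifnot(hysteresis_db <= threshold_db, min_event_s > 0)
  structure(list(threshold_db = threshold_db, hysteresis_db = hysteresis_db,
                 min_event_s = min_event_s, merge_gap_s = merge_gap_s,
                 smooth_ms = smooth_ms, env_rate = env_rate,
                 peak_quantile = peak_quantile),
            class = "segmentation_config")
}

# block-mean rectified envelope at roughly cfg$env_rate samples/s
decimated_envelope <- function(waveform, sample_rate, cfg) {
  block <- max(1L, as.integer(sample_rate %/% cfg$env_rate))
  n <- length(waveform)
  nb <- n %/% block
  env <- if (nb >= 1L) {
    .colMeans(abs(waveform[seq_len(nb * block)]), block, nb)
  } else {
    mean(abs(waveform))
  }
  rate <- sample_rate / block
  w <- max(1L, as.integer(round(cfg$smooth_ms / 1000 * rate)))
  list(env = moving_average(env, w), rate = rate)
}

#' Segment a recording into echeme events
#'
#' Detects acoustic events on the smoothed amplitude envelope and assigns
#' each a kind from the phrase-1/phrase-2 terminology:
#' `E_L` (long echeme, duration > 0.3 s), `E_S` (short echeme 0.02-0.15 s
#' after a long echeme), `E_IN` (introductory chirps in front of a long
#' echeme, gaps < 0.5 s), and `E_L2`/`E_S2` for events inside a phrase-2
#' block (a dense run of short events with internal gaps < 0.2 s containing
#' at least two echemes of 0.1-0.5 s duration).
#'
#' All-silent input yields an empty event table (not an error).
#'
#' @param waveform Numeric vector (mono audio).
#' @param sample_rate Sampling rate in Hz.
#' @param config A [segmentation_config()].
#' @return A data.frame with columns `kind`, `onset`, `offset` (seconds),
#'   time-ordered and non-overlapping.
#' @export
segment_echemes <- function(waveform, sample_rate,
                            config = segmentation_config()) {
  if (length(waveform) == 0L) stop("empty waveform")
  de <- decimated_envelope(waveform, sample_rate, config)
  env <- de$env
  ref <- stats::quantile(env, config$peak_quantile, names = FALSE)
  if (!is.finite(ref) || ref <= 0)
    return(data.frame(kind = character(0), onset = numeric(0),
                      offset = numeric(0)))
  thr_hi <- ref * 10^(config$threshold_db / 20)
  thr_lo <- ref * 10^(config$hysteresis_db / 20)

  r <- rle(env >= thr_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  runs <- cbind(starts[keep], ends[keep])
  if (nrow(runs) == 0L)
    return(data.frame(kind = character(0), onset = numeric(0),
                      offset = numeric(0)))
  # keep only runs that reach the high threshold
  hit <- vapply(seq_len(nrow(runs)), function(i) {
    any(env[runs[i, 1]:runs[i, 2]] >= thr_hi)
  }, logical(1))
  runs <- runs[hit, , drop = FALSE]
  if (nrow(runs) == 0L)
    return(data.frame(kind = character(0), onset = numeric(0),
                      offset = numeric(0)))
  # merge runs separated by less than merge_gap_s
  gap_smp <- config$merge_gap_s * de$rate
  if (nrow(runs) > 1L) {
    merged <- list(runs[1L, ])
    for (i in 2L:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[i, 1] - last[2] - 1L < gap_smp) {
        merged[[length(merged)]][2] <- runs[i, 2]
      } else {
        merged[[length(merged) + 1L]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, merged)
  }
  onset <- (runs[, 1] - 1L) / de$rate
  offset <- runs[, 2] / de$rate
  keep <- (offset - onset) >= config$min_event_s
  ev <- data.frame(kind = NA_character_, onset = onset[keep],
                   offset = offset[keep])
  if (nrow(ev) == 0L) return(ev)
  classify_events(ev)
}

# assign event kinds by duration and context
classify_events <- function(ev) {
  n <- nrow(ev)
  dur <- ev$offset - ev$onset
  gap_next <- c(ev$onset[-1L] - ev$offset[-n], Inf)
  kind <- rep(NA_character_, n)

  # phrase-2 blocks first: maximal runs of events with duration <= 0.5 s and
  # internal gaps < 0.2 s, holding at least two 0.1-0.5 s echemes (E_L2)
  short_ok <- dur <= 0.5
  run_id <- cumsum(c(TRUE, gap_next[-n] >= 0.2 | !short_ok[-n] |
                       !short_ok[-1L]))
  for (id in unique(run_id)) {
    idx <- which(run_id == id)
    if (length(idx) < 4L || !all(short_ok[idx])) next
    if (sum(dur[idx] >= 0.1) < 2L) next
    kind[idx] <- ifelse(dur[idx] >= 0.1, "E_L2", "E_S2")
  }
  # long echemes
  kind[is.na(kind) & dur > 0.3] <- "E_L"
  # short echeme directly after a long echeme
  idx <- which(is.na(kind))
  for (i in idx) {
    if (i > 1L && identical(kind[i - 1L], "E_L")) {
      g <- ev$onset[i] - ev$offset[i - 1L]
      if (g >= 0.02 && g <= 0.15 && dur[i] <= 0.15) kind[i] <- "E_S"
    }
  }
  # introductory chirps: chains leading to a long echeme with gaps < 0.5 s
  for (i in rev(which(is.na(kind)))) {
    if (i < n && gap_next[i] < 0.5 &&
        kind[i + 1L] %in% c("E_IN", "E_L")) kind[i] <- "E_IN"
  }
  # leftovers attach forward as introductory-type chirps (tie rule)
  kind[is.na(kind)] <- "E_IN"
  ev$kind <- kind
  ev
}

#' Group echeme events into phrases
#'
#' Builds one phrase-1 group per long echeme (its introductory chirps, the
#' long echeme, the following short echeme when present, and the two
#' inter-echeme durations) and collects phrase-2 blocks (maximal runs of
#' `E_L2`/`E_S2` events with internal gaps < 0.2 s containing at least two
#' complete echeme/inter-echeme groups). A group is flagged
#' `followed_by_ph2` when a block starts between it and the next group; its
#' `ied_s_l` is then undefined (`NA`).
#'
#' @param events Data.frame with `kind`, `onset`, `offset`, time-ordered.
#' @return A list with `groups` and `ph2_blocks` data.frames.
#' @export
annotate_phrases <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("kind", "onset", "offset") %in% names(events)))
  if (nrow(events) > 1L && any(diff(events$onset) < 0))
    stop("events must be time-ordered")
  ev <- events
  n <- nrow(ev)

  blocks <- find_ph2_blocks(ev)
  il <- which(ev$kind == "E_L")
  grows <- vector("list", length(il))
  for (k in seq_along(il)) {
    i <- il[k]
    # contiguous chain of introductory chirps in front of the long echeme
    j <- i
    qualifies <- TRUE
    n_in <- 0L
    while (j > 1L && ev$kind[j - 1L] == "E_IN" &&
           ev$onset[j] - ev$offset[j - 1L] < 0.5) {
      if (ev$onset[j] - ev$offset[j - 1L] < 0.015) qualifies <- FALSE
      n_in <- n_in + 1L
      j <- j - 1L
    }
    e_s_onset <- NA_real_; e_s_offset <- NA_real_; ied_l_s <- NA_real_
    if (i < n && ev$kind[i + 1L] == "E_S") {
      e_s_onset <- ev$onset[i + 1L]; e_s_offset <- ev$offset[i + 1L]
      ied_l_s <- e_s_onset - ev$offset[i]
    }
    tail_end <- if (is.na(e_s_offset)) ev$offset[i] else e_s_offset
    nxt_onset <- if (k < length(il)) ev$onset[il[k + 1L]] else NA_real_
    ph2 <- nrow(blocks) > 0L && !is.na(nxt_onset) &&
      any(blocks$start >= tail_end & blocks$start < nxt_onset)
    if (nrow(blocks) > 0L && k == length(il))
      ph2 <- any(blocks$start >= tail_end)
    ied_s_l <- if (!ph2 && !is.na(nxt_onset) && !is.na(e_s_offset))
      nxt_onset - e_s_offset else NA_real_
    grows[[k]] <- data.frame(
      group = k, e_l_onset = ev$onset[i], e_l_offset = ev$offset[i],
      e_s_onset = e_s_onset, e_s_offset = e_s_offset,
      n_e_in = n_in, e_in_qualifies = (n_in >= 2L) && qualifies,
      ied_l_s = ied_l_s, ied_s_l = ied_s_l, followed_by_ph2 = ph2)
  }
  groups <- if (length(grows)) do.call(rbind, grows) else
    data.frame(group = integer(0), e_l_onset = numeric(0),
               e_l_offset = numeric(0), e_s_onset = numeric(0),
               e_s_offset = numeric(0), n_e_in = integer(0),
               e_in_qualifies = logical(0), ied_l_s = numeric(0),
               ied_s_l = numeric(0), followed_by_ph2 = logical(0))
  list(groups = groups, ph2_blocks = blocks)
}

# maximal runs of phrase-2 events forming at least two complete G2 units
find_ph2_blocks <- function(ev) {
  n <- nrow(ev)
  is2 <- ev$kind %in% c("E_L2", "E_S2")
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!is2[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && is2[j + 1L] && ev$onset[j + 1L] - ev$offset[j] < 0.2)
      j <- j + 1L
    kinds <- ev$kind[i:j]
    el2 <- which(kinds == "E_L2")
    complete <- length(el2) >= 2L && all(vapply(seq_along(el2), function(k) {
      to <- if (k < length(el2)) el2[k + 1L] - 1L else length(kinds)
      any(kinds[el2[k]:to] == "E_S2")
    }, logical(1)))
    if (complete)
      out[[length(out) + 1L]] <- data.frame(
        start = ev$onset[i], end = ev$offset[j], n_g2 = length(el2))
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = numeric(0), end = numeric(0), n_g2 = integer(0))
}
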