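# Per-individual acoustic variables: the standardized power staircase of
# the long echeme, durations, chirp and phrase-2 rates, syllable counts and
# carrier-frequency quartiles.

seg_power_db <- function(waveform, sample_rate, from, to) {
  i1 <- max(1L, as.integer(round(from * sample_rate)) + 1L)
  i2 <- min(length(waveform), as.integer(round(to * sample_rate)))
  if (i2 < i1) stop("empty power segment")
  10 * log10(mean(waveform[i1:i2]^2))
}

#' Standardized power staircase of a long echeme
#'
#' Splits the long echeme into the six predefined time segments
#' (0-0.05, 0.05-0.15, 0.15-0.30, 0.30-0.60, 0.60-1.50 s and 1.50 s to the
#' end, measured from the echeme onset), computes the average power of each
#' segment as \eqn{10 \log_{10}} of the mean squared amplitude, and
#' standardizes the six values so the baseline segment is 0 and the final
#' segment is 1.
#'
#' The staircase is only `valid` for echemes of at least 1.6 s (so that the
#' final segment exists) whose total power rise is at least 0.5 dB;
#' otherwise `standardized` is `NA`.
#'
#' @param waveform Numeric vector (mono audio).
#' @param sample_rate Sampling rate in Hz.
#' @param e_l A list or one-row data.frame with `onset` and `offset` (s).
#' @return A list of class `power_staircase` with `raw_db` (6 values),
#'   `standardized` (6 values, first 0 and last 1 when valid) and `valid`.
#' @export
power_staircase <- function(waveform, sample_rate, e_l) {
  onset <- as.numeric(e_l$onset[1]); offset <- as.numeric(e_l$offset[1])
  if (onset < 0 || offset * sample_rate > length(waveform) + 0.5)
    stop("echeme lies outside the waveform")
  dur <- offset - onset
  if (dur < 1.6)
    return(structure(list(raw_db = rep(NA_real_, 6),
                          standardized = rep(NA_real_, 6), valid = FALSE),
                     class = "power_staircase"))
  b <- onset + c(0, 0.05, 0.15, 0.30, 0.60, 1.50, dur)
  raw <- vapply(1:6, function(i)
    seg_power_db(waveform, sample_rate, b[i], b[i + 1]), numeric(1))
  denom <- raw[6] - raw[1]
  valid <- is.finite(denom) && denom >= 0.5
  structure(list(raw_db = raw,
                 standardized = if (valid) (raw - raw[1]) / denom
                   else rep(NA_real_, 6),
                 valid = valid),
            class = "power_staircase")
}

#' Fraction of groups meeting the introductory-chirp criterion
#'
#' A group qualifies when at least two introductory chirps stand in front of
#' the long echeme, each followed by a pause of at least 0.015 s.
#'
#' @param groups Groups data.frame from [annotate_phrases()].
#' @return Fraction in `[0, 1]`.
#' @export
e_in_rate <- function(groups) {
  if (!is.data.frame(groups) || nrow(groups) < 1L)
    stop("at least one group required")
  mean(groups$e_in_qualifies)
}

#' Fraction of phrase-1 groups followed by phrase 2
#'
#' @param groups Groups data.frame from [annotate_phrases()]; at least 10
#'   groups are required (the minimal per-individual sample size).
#' @return Fraction in `[0, 1]`.
#' @export
ph2_rate <- function(groups) {
  if (!is.data.frame(groups) || nrow(groups) < 10L)
    stop("minimum sample size violated: ", nrow(groups),
         " groups, 10 required")
  mean(groups$followed_by_ph2)
}

#' Count syllables within a short echeme
#'
#' Counts the modulation peaks of the fine (1-ms smoothed) amplitude
#' envelope inside the event, as the number of envelope runs above half the
#' local maximum. An unmodulated burst counts as one syllable.
#'
#' @param waveform Numeric vector (mono audio).
#' @param sample_rate Sampling rate in Hz.
#' @param e_s A list or one-row data.frame with `onset` and `offset`;
#'   duration must not exceed 0.3 s.
#' @return Integer syllable count.
#' @export
syllable_count <- function(waveform, sample_rate, e_s) {
  onset <- as.numeric(e_s$onset[1]); offset <- as.numeric(e_s$offset[1])
  if (offset - onset > 0.3) stop("not a short echeme (duration > 0.3 s)")
  if (onset < 0 || offset * sample_rate > length(waveform) + 0.5)
    stop("event lies outside the waveform")
  i1 <- max(1L, as.integer(round(onset * sample_rate)) + 1L)
  i2 <- min(length(waveform), as.integer(round(offset * sample_rate)))
  w <- max(1L, as.integer(round(0.001 * sample_rate)))
  env <- moving_average(abs(waveform[i1:i2]), w)
  thr <- 0.5 * max(env)
  r <- rle(env >= thr)
  # ignore sub-millisecond ripples at the threshold: bridge short dips,
  # then drop short peaks
  r$values[!r$values & r$lengths < w] <- TRUE
  r <- rle(inverse.rle(r))
  sum(r$values & r$lengths >= w)
}

#' Carrier-frequency quartiles of an event
#'
#' Quartiles of the cumulative power spectral density over the 10-20 kHz
#' band (periodogram with a Hann window; at most the first second of the
#' event is used).
#'
#' @param waveform Numeric vector (mono audio).
#' @param sample_rate Sampling rate in Hz.
#' @param event A list or one-row data.frame with `onset` and `offset`;
#'   duration must be at least 10 ms.
#' @return List with `centre_khz`, `q1_khz`, `q3_khz`.
#' @export
carrier_frequency <- function(waveform, sample_rate, event) {
  onset <- as.numeric(event$onset[1]); offset <- as.numeric(event$offset[1])
  if (offset - onset < 0.01)
    stop("event too short for a stable spectrum (< 10 ms)")
  i1 <- max(1L, as.integer(round(onset * sample_rate)) + 1L)
  i2 <- min(length(waveform), as.integer(round(offset * sample_rate)),
            i1 + sample_rate - 1L)
  x <- waveform[i1:i2]
  n <- length(x)
  han <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  p <- Mod(stats::fft(x * han))^2
  nh <- n %/% 2L
  freqs <- (seq_len(nh) - 1L) * sample_rate / n
  band <- freqs >= 10000 & freqs <= min(20000, sample_rate / 2)
  pw <- p[seq_len(nh)][band]
  fb <- freqs[band]
  if (sum(pw) <= 0) stop("no power in the 10-20 kHz band")
  cum <- cumsum(pw) / sum(pw)
  qf <- function(q) fb[which(cum >= q)[1L]]
  list(centre_khz = qf(0.5) / 1000, q1_khz = qf(0.25) / 1000,
       q3_khz = qf(0.75) / 1000)
}

#' Power contrast between phrase 2 and the following long echeme
#'
#' Mean dB difference between the final-segment average power of the long
#' echeme following a phrase-2 block and the average power of the block's
#' `E_L2` echemes. When at least two blocks with four or more
#' echeme/inter-echeme groups are available, three `E_L2` (the fourth-,
#' third- and second-last) are sampled from each of the first two blocks
#' (six groups in total); otherwise all available `E_L2` are used.
#'
#' @param waveform Numeric vector (mono audio).
#' @param sample_rate Sampling rate in Hz.
#' @param events Events data.frame (with `E_L2` kinds).
#' @param groups Groups data.frame from [annotate_phrases()].
#' @param ph2_blocks Blocks data.frame from [annotate_phrases()].
#' @return Mean contrast in dB, or `NA` if no usable block exists.
#' @export
ph2_power_contrast <- function(waveform, sample_rate, events, groups,
                               ph2_blocks) {
  if (is.null(ph2_blocks) || nrow(ph2_blocks) == 0L) return(NA_real_)
  per_block <- list()
  for (bi in seq_len(nrow(ph2_blocks))) {
    bl <- ph2_blocks[bi, ]
    nxt <- groups[groups$e_l_onset > bl$end, , drop = FALSE]
    if (nrow(nxt) == 0L) next
    el <- nxt[1L, ]
    if (el$e_l_offset - el$e_l_onset < 1.6) next
    p5 <- seg_power_db(waveform, sample_rate, el$e_l_onset + 1.5,
                       el$e_l_offset)
    el2 <- events[events$kind == "E_L2" & events$onset >= bl$start &
                    events$offset <= bl$end, , drop = FALSE]
    if (nrow(el2) == 0L) next
    pe <- vapply(seq_len(nrow(el2)), function(i)
      seg_power_db(waveform, sample_rate, el2$onset[i], el2$offset[i]),
      numeric(1))
    per_block[[length(per_block) + 1L]] <- p5 - pe
  }
  if (length(per_block) == 0L) return(NA_real_)
  big <- which(vapply(per_block, length, integer(1)) >= 4L)
  if (length(big) >= 2L) {
    sel <- unlist(lapply(per_block[big[1:2]], function(d) {
      n <- length(d); d[c(n - 3L, n - 2L, n - 1L)]
    }))
  } else {
    sel <- unlist(per_block)
  }
  mean(sel)
}

#' Compute all per-individual song features
#'
#' Segments the recording (or uses a supplied annotation), groups events
#' into phrases, and aggregates the full set of acoustic variables over the
#' first 20 detected phrase-1 groups (or all groups when 10-19 are
#' available; fewer than 10 is a minimum-sample violation). The phrase-2
#' occurrence rate uses all groups of the recording; phrase-2 structure
#' statistics follow their own sampling rule (see
#' [ph2_power_contrast()]).
#'
#' @param waveform Numeric vector (mono audio).
#' @param sample_rate Sampling rate in Hz.
#' @param temperature Perch temperature in degrees Celsius.
#' @param config A [segmentation_config()].
#' @param annotation Optional events data.frame (e.g. ground truth from the
#'   generator), bypassing envelope segmentation.
#' @return A one-row data.frame of class `song_features`.
#' @export
compute_features <- function(waveform, sample_rate, temperature,
                             config = segmentation_config(),
                             annotation = NULL) {
  events <- if (is.null(annotation)) {
    segment_echemes(waveform, sample_rate, config)
  } else {
    annotation
  }
  ann <- annotate_phrases(events)
  groups <- ann$groups
  n_all <- nrow(groups)
  if (n_all < 10L)
    stop("minimum sample size violated: ", n_all, " groups detected, ",
         "10 required")
  used <- groups[seq_len(min(20L, n_all)), , drop = FALSE]

  ed_l <- used$e_l_offset - used$e_l_onset
  ed_s <- used$e_s_offset - used$e_s_onset
  stair <- lapply(seq_len(nrow(used)), function(i)
    power_staircase(waveform, sample_rate,
                    list(onset = used$e_l_onset[i],
                         offset = used$e_l_offset[i])))
  std <- do.call(rbind, lapply(stair, function(s)
    if (s$valid) s$standardized else rep(NA_real_, 6)))
  syl <- rep(NA_real_, nrow(used))
  for (i in seq_len(nrow(used))) {
    if (!is.na(used$e_s_onset[i]))
      syl[i] <- syllable_count(waveform, sample_rate,
                               list(onset = used$e_s_onset[i],
                                    offset = used$e_s_offset[i]))
  }
  ef_l <- lapply(seq_len(nrow(used)), function(i)
    carrier_frequency(waveform, sample_rate,
                      list(onset = used$e_l_onset[i],
                           offset = used$e_l_offset[i])))
  ef_s <- lapply(which(!is.na(used$e_s_onset) & ed_s >= 0.01), function(i)
    carrier_frequency(waveform, sample_rate,
                      list(onset = used$e_s_onset[i],
                           offset = used$e_s_offset[i])))

  el2 <- events[events$kind == "E_L2", , drop = FALSE]
  es2 <- events[events$kind == "E_S2", , drop = FALSE]
  blocks <- ann$ph2_blocks
  gd2 <- NA_real_
  if (nrow(blocks) > 0L && nrow(el2) > 1L) {
    per <- unlist(lapply(seq_len(nrow(blocks)), function(bi) {
      on <- el2$onset[el2$onset >= blocks$start[bi] &
                        el2$onset <= blocks$end[bi]]
      if (length(on) > 1L) diff(on) else numeric(0)
    }))
    if (length(per)) gd2 <- mean(per)
  }

  out <- data.frame(
    ed_l_mean = mean(ed_l),
    ed_s_mean = mean(ed_s, na.rm = TRUE),
    ied_l_s_mean = mean(used$ied_l_s, na.rm = TRUE),
    ied_s_l_mean = mean(used$ied_s_l, na.rm = TRUE),
    ied_s_l_min = if (all(is.na(used$ied_s_l))) NA_real_
      else min(used$ied_s_l, na.rm = TRUE),
    e_in_number = mean(used$n_e_in),
    e_in_rate = e_in_rate(used),
    syllables_per_e_s = mean(syl, na.rm = TRUE),
    syllable_duration = mean(ed_s / syl, na.rm = TRUE),
    ep_l_1 = mean(std[, 2], na.rm = TRUE),
    ep_l_2 = mean(std[, 3], na.rm = TRUE),
    ep_l_3 = mean(std[, 4], na.rm = TRUE),
    ep_l_4 = mean(std[, 5], na.rm = TRUE),
    ef_l_centre = mean(vapply(ef_l, `[[`, numeric(1), "centre_khz")),
    ef_l_q1 = mean(vapply(ef_l, `[[`, numeric(1), "q1_khz")),
    ef_l_q3 = mean(vapply(ef_l, `[[`, numeric(1), "q3_khz")),
    ef_s = if (length(ef_s))
      mean(vapply(ef_s, `[[`, numeric(1), "centre_khz")) else NA_real_,
    ph2_rate = ph2_rate(groups),
    ph2_power_contrast_db = ph2_power_contrast(waveform, sample_rate,
                                               events, groups, blocks),
    e_2s_count_mean = if (nrow(el2)) nrow(es2) / nrow(el2) else NA_real_,
    ed_2l_mean = if (nrow(el2)) mean(el2$offset - el2$onset) else NA_real_,
    gd_2_mean = gd2,
    temperature = temperature,
    n_groups_used = nrow(used),
    n_groups_total = n_all)
  class(out) <- c("song_features", "data.frame")
  out
}
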