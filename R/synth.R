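# Seeded synthesis of calling songs with exact ground-truth annotations.
#
# The signal model is a sine carrier, amplitude-modulated by piecewise
# envelopes. The long echeme swells along a piecewise linear-in-dB curve
# whose knots are solved so that the average power of the six predefined
# time segments reproduces the preset's standardized power staircase
# exactly (see stair_knots below). Short echemes carry a raised-cosine
# syllable modulation; introductory chirps and phrase-2 echemes are flat
# bursts with 1-ms edge ramps.

# Relative amplitudes of the event types (long echeme peak = 1). The long
# echeme starts 16 dB below its final power, which keeps onsets above the
# -20 dB segmentation threshold.
.amp_e_s <- 0.9
.amp_e_in <- 0.5
.syll_depth <- 0.8   # syllable modulation depth within the short echeme
.noise_sd <- 1e-4    # additive background noise (about -80 dB re full scale)

#' Generate one synthetic calling-song recording
#'
#' Synthesizes `n_groups` phrase-1 groups (optional introductory chirps, a
#' swelling long echeme, the short pause, the syllable-structured short
#' echeme and the long inter-echeme pause) for one OTU preset, inserting a
#' phrase-2 block after a group with the preset's insertion probability.
#' Durations are drawn from truncated normal distributions with the preset
#' means and SDs, scaled linearly with perch temperature (fractional change
#' `temp_slope_per_degC` per degree away from 25 degrees C). Long-echeme
#' durations are truncated to the observed 0.7-60 s range.
#'
#' @param preset A `taxon_preset` with song data (not `bulg`).
#' @param temperature Perch temperature in degrees Celsius (17-33).
#' @param n_groups Number of phrase-1 groups (>= 1).
#' @param sample_rate Sampling rate in Hz; must exceed 2.5 x carrier.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return An object of class `song_recording`: a list with `waveform`
#'   (numeric, mono), `sample_rate`, `ground_truth` (events, groups and
#'   phrase-2 blocks as data.frames), `otu`, `temperature` and `seed`.
#' @export
generate_song <- function(preset, temperature = 25, n_groups,
                          sample_rate = 44100, seed = 1L) {
  validate_preset(preset)
  if (is.na(preset$ed_l_mean))
    stop("preset '", preset$otu_id, "' has no calling-song data")
  if (!is.numeric(n_groups) || length(n_groups) != 1L || n_groups < 1)
    stop("'n_groups' must be a single count >= 1")
  if (temperature < 17 || temperature > 33)
    stop("'temperature' outside the studied 17-33 degrees C range")
  if (sample_rate < 2.5 * preset$carrier_hz)
    stop("sample_rate ", sample_rate, " Hz too low for a ",
         preset$carrier_hz, " Hz carrier (aliasing)")
  n_groups <- as.integer(n_groups)
  tf <- temp_factor(preset, temperature)

  with_seed(seed, {
    plan <- plan_groups(preset, n_groups, tf)
    rec <- render_plan(plan, preset, sample_rate)
  })
  rec$otu <- preset$otu_id
  rec$temperature <- temperature
  rec$seed <- as.integer(seed)
  class(rec) <- "song_recording"
  rec
}

# Draw all random quantities for the song up front.
plan_groups <- function(preset, n_groups, tf) {
  chirp_step <- preset$chirp_dur + preset$e_in_pause
  groups <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    k_in <- min(stats::rpois(1, preset$e_in_count_mean), 12L)
    ph2 <- stats::runif(1) < preset$ph2_insertion_prob
    block <- NULL
    if (ph2) {
      block <- lapply(seq_len(preset$ph2_n_g2), function(i) {
        ed_2l <- rtnorm(1, preset$ed_2l_mean * tf, preset$ed_2l_sd * tf,
                        lower = 0.08, upper = 0.45)
        k2 <- max(1L, as.integer(round(stats::rnorm(1, preset$ph2_e2s_mean,
                                                    preset$ph2_e2s_sd))))
        lo <- ed_2l + k2 * preset$e2s_dur + (k2 + 1) * 0.006
        hi <- ed_2l + k2 * preset$e2s_dur + (k2 + 1) * 0.19
        gd2 <- rtnorm(1, preset$gd_2_mean * tf, preset$gd_2_sd * tf,
                      lower = lo, upper = hi)
        list(ed_2l = ed_2l, k2 = k2, gd2 = gd2)
      })
    }
    groups[[g]] <- list(
      ed_l = rtnorm(1, preset$ed_l_mean * tf, preset$ed_l_sd * tf,
                    lower = 0.7, upper = 60),
      ed_s = rtnorm(1, preset$ed_s_mean * tf, preset$ed_s_sd * tf,
                    lower = 0.02, upper = 0.3),
      ied_l_s = rtnorm(1, preset$ied_l_s_mean * tf, preset$ied_l_s_sd * tf,
                       lower = 0.03, upper = 0.14),
      ied_s_l = rtnorm(1, preset$ied_s_l_mean * tf, preset$ied_s_l_sd * tf,
                       lower = 0.05),
      k_in = k_in,
      train_s = k_in * chirp_step,
      syllables = max(1L, as.integer(round(stats::rnorm(
        1, preset$syllables_per_e_s_mean, preset$syllables_per_e_s_sd)))),
      ph2 = ph2, block = block)
  }
  groups
}

# Turn a plan into samples plus exact annotations.
render_plan <- function(plan, preset, sr) {
  n_groups <- length(plan)
  pieces <- list()
  np <- 0L
  cursor <- 0L      # samples emitted so far
  ev <- list(); nev <- 0L
  blocks <- list(); nbl <- 0L
  grows <- vector("list", n_groups)

  push <- function(x) {
    np <<- np + 1L
    pieces[[np]] <<- x
    cursor <<- cursor + length(x)
  }
  silence <- function(dur) {
    ns <- max(0L, as.integer(round(dur * sr)))
    if (ns > 0L) push(numeric(ns))
  }
  event <- function(kind, x, syllables = NA_integer_) {
    onset <- cursor / sr
    push(x)
    nev <<- nev + 1L
    ev[[nev]] <<- list(kind = kind, onset = onset, offset = cursor / sr,
                       syllables = syllables)
    c(onset, cursor / sr)
  }

  silence(0.2)
  for (g in seq_len(n_groups)) {
    gp <- plan[[g]]
    # introductory chirps sit directly in front of the long echeme
    for (j in seq_len(gp$k_in)) {
      event("E_IN", flat_burst(preset$chirp_dur, sr, preset$carrier_hz,
                               .amp_e_in))
      silence(preset$e_in_pause)
    }
    el <- event("E_L", long_echeme(gp$ed_l, sr, preset$carrier_hz,
                                   preset$ep_targets, preset$rise_db))
    silence(gp$ied_l_s)
    es <- event("E_S", short_echeme(gp$ed_s, sr, preset$carrier_hz,
                                    gp$syllables),
                syllables = gp$syllables)
    ied_s_l_out <- NA_real_
    if (gp$ph2) {
      silence(0.25)
      bstart <- cursor / sr
      # E_L2 level sits ph2_power_offset_db below the *average* power of the
      # following long echeme's final segment, which is rise_db - top below
      # the envelope peak
      amp2 <- 10^(-(attr_stair_top(preset, gp$ed_l) +
                      preset$ph2_power_offset_db) / 20)
      for (g2 in gp$block) {
        event("E_L2", flat_burst(g2$ed_2l, sr, preset$carrier_hz, amp2))
        gap <- (g2$gd2 - g2$ed_2l - g2$k2 * preset$e2s_dur) / (g2$k2 + 1)
        for (j in seq_len(g2$k2)) {
          silence(gap)
          event("E_S2", flat_burst(preset$e2s_dur, sr, preset$carrier_hz,
                                   amp2))
        }
        silence(gap)
      }
      nbl <- nbl + 1L
      blocks[[nbl]] <- list(start = bstart, end = cursor / sr,
                            n_g2 = length(gp$block))
      if (g < n_groups) {
        train_next <- plan[[g + 1L]]$train_s
        silence(max(gp$ied_s_l, train_next + 0.3) - train_next)
      }
    } else if (g < n_groups) {
      train_next <- plan[[g + 1L]]$train_s
      gap_total <- max(gp$ied_s_l, train_next + 0.1)
      ied_s_l_out <- gap_total
      silence(gap_total - train_next)
    }
    grows[[g]] <- data.frame(
      group = g, e_l_onset = el[1], e_l_offset = el[2],
      e_s_onset = es[1], e_s_offset = es[2],
      n_e_in = gp$k_in, ied_l_s = es[1] - el[2],
      ied_s_l = ied_s_l_out, followed_by_ph2 = gp$ph2,
      syllables = gp$syllables)
  }
  silence(0.2)

  x <- unlist(pieces, use.names = FALSE)
  pieces <- NULL
  x <- x + stats::rnorm(length(x), 0, .noise_sd)

  events <- do.call(rbind, lapply(ev, as.data.frame))
  groups <- do.call(rbind, grows)
  # ground-truth ied_s_l points at the next group's long echeme
  if (n_groups > 1L) {
    nxt <- groups$e_l_onset[-1L]
    upd <- !groups$followed_by_ph2[-n_groups]
    groups$ied_s_l[-n_groups][upd] <-
      (nxt - groups$e_s_offset[-n_groups])[upd]
  }
  groups$ied_s_l[n_groups] <- NA_real_
  ph2_blocks <- if (nbl > 0L) do.call(rbind, lapply(blocks, as.data.frame))
    else data.frame(start = numeric(0), end = numeric(0), n_g2 = integer(0))
  list(waveform = x, sample_rate = sr,
       ground_truth = list(events = events, groups = groups,
                           ph2_blocks = ph2_blocks))
}

#' @export
print.song_recording <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<song_recording> %s, %.1f degC, %.1f s at %d Hz\n",
              x$otu, x$temperature, length(x$waveform) / x$sample_rate,
              x$sample_rate))
  cat(sprintf("  %d events, %d phrase-1 groups, %d phrase-2 blocks\n",
              nrow(gt$events), nrow(gt$groups), nrow(gt$ph2_blocks)))
  invisible(x)
}

# ---- envelope construction ------------------------------------------------

# dB knots of the long-echeme swell. Boundaries of the six predefined power
# segments; knot levels are solved segment by segment so that the mean power
# of segment i equals target_i * rise_db (baseline segment = 0 dB, final
# segment = rise_db), making the standardized staircase of the synthetic
# echeme reproduce the preset targets exactly.
stair_knots <- function(ep_targets, rise_db, duration) {
  if (duration <= 1.55)  # too short for the staircase; plain linear-dB swell
    return(list(t = c(0, duration), db = c(0, rise_db)))
  b <- c(0, 0.05, 0.15, 0.30, 0.60, 1.50, duration)
  targ <- c(ep_targets * rise_db, rise_db)   # segments 1..5 (dB above base)
  d <- numeric(7)                            # knot levels at b[1..7]
  d[2] <- 0                                  # flat baseline 0-0.05 s
  for (i in 2:6) {
    d[i + 1] <- solve_ramp_end(d[i], 10^(targ[i - 1] / 10))
  }
  list(t = b, db = d)
}

# end level of a linear-dB ramp starting at d1 whose mean linear power is A
solve_ramp_end <- function(d1, A) {
  p1 <- 10^(d1 / 10)
  if (abs(A - p1) < 1e-12) return(d1)
  f <- function(d2) {
    if (abs(d2 - d1) < 1e-9) return(p1 - A)
    (10^(d2 / 10) - p1) / ((d2 - d1) * log(10) / 10) - A
  }
  stats::uniroot(f, lower = d1 - 30, upper = d1 + 90, tol = 1e-10)$root
}

# top knot level (dB above baseline) of the long-echeme envelope; needed to
# place phrase-2 amplitudes relative to the *average* final-segment power
attr_stair_top <- function(preset, duration) {
  kn <- stair_knots(preset$ep_targets, preset$rise_db, duration)
  kn$db[length(kn$db)] - preset$rise_db
}

long_echeme <- function(duration, sr, carrier_hz, ep_targets, rise_db) {
  ns <- max(2L, as.integer(round(duration * sr)))
  t <- (seq_len(ns) - 0.5) / sr
  kn <- stair_knots(ep_targets, rise_db, ns / sr)
  db <- stats::approx(kn$t, kn$db, xout = t, rule = 2)$y
  env <- 10^((db - kn$db[length(kn$db)]) / 20)
  sine_burst(ns, sr, carrier_hz, env)
}

short_echeme <- function(duration, sr, carrier_hz, syllables) {
  ns <- max(2L, as.integer(round(duration * sr)))
  t <- (seq_len(ns) - 0.5) / ns
  env <- .amp_e_s * (1 - .syll_depth * (1 + cos(2 * pi * syllables * t)) / 2)
  sine_burst(ns, sr, carrier_hz, env)
}

flat_burst <- function(duration, sr, carrier_hz, amp) {
  ns <- max(2L, as.integer(round(duration * sr)))
  sine_burst(ns, sr, carrier_hz, rep(amp, ns))
}

sine_burst <- function(ns, sr, carrier_hz, env) {
  nr <- min(ns %/% 2L, as.integer(round(0.001 * sr)))  # 1-ms edge ramps
  if (nr > 0L) {
    r <- (1 - cos(pi * seq_len(nr) / (nr + 1))) / 2
    env[seq_len(nr)] <- env[seq_len(nr)] * r
    env[ns + 1L - seq_len(nr)] <- env[ns + 1L - seq_len(nr)] * r
  }
  env * sin(2 * pi * carrier_hz * (seq_len(ns) - 1L) / sr)
}

# ---- composite individuals ------------------------------------------------

#' Concatenate recordings into a composite individual
#'
#' Randomly orders the input recordings (seeded) and concatenates them with
#' one second of silence in between, re-offsetting all ground-truth
#' annotations, to reach a minimal sample size of phrase-1 groups the way
#' composite individuals are assembled from several males.
#'
#' @param recordings List of `song_recording` objects with equal sample rates.
#' @param min_groups Required total number of phrase-1 groups.
#' @param seed Integer seed for the random ordering.
#' @return A `song_recording` with the combined waveform and annotations.
#' @export
concatenate_individuals <- function(recordings, min_groups, seed = 1L) {
  stopifnot(length(recordings) >= 1L,
            all(vapply(recordings, inherits, logical(1), "song_recording")))
  srs <- vapply(recordings, `[[`, numeric(1), "sample_rate")
  if (length(unique(srs)) != 1L) stop("sample rates differ across recordings")
  total <- sum(vapply(recordings, function(r) nrow(r$ground_truth$groups),
                      integer(1)))
  if (total < min_groups)
    stop("insufficient phrase-1 groups for a composite: ", total,
         " available, ", min_groups, " required")
  if (length(recordings) == 1L) return(recordings[[1L]])

  ord <- with_seed(seed, sample(length(recordings)))
  sr <- srs[1]
  gap <- numeric(as.integer(round(1.0 * sr)))
  waves <- list(); evs <- list(); grs <- list(); bls <- list()
  off <- 0
  for (i in seq_along(ord)) {
    r <- recordings[[ord[i]]]
    waves[[2 * i - 1]] <- r$waveform
    waves[[2 * i]] <- if (i < length(ord)) gap else numeric(0)
    gt <- r$ground_truth
    e <- gt$events; e$onset <- e$onset + off; e$offset <- e$offset + off
    g <- gt$groups
    for (col in c("e_l_onset", "e_l_offset", "e_s_onset", "e_s_offset"))
      g[[col]] <- g[[col]] + off
    b <- gt$ph2_blocks
    if (nrow(b)) { b$start <- b$start + off; b$end <- b$end + off }
    evs[[i]] <- e; grs[[i]] <- g; bls[[i]] <- b
    off <- off + (length(r$waveform) + length(gap)) / sr
  }
  groups <- do.call(rbind, grs)
  groups$group <- seq_len(nrow(groups))
  # the boundary gap between recordings is not a within-song pause
  last_of_piece <- cumsum(vapply(grs, nrow, integer(1)))
  groups$ied_s_l[last_of_piece] <- NA_real_
  structure(list(
    waveform = unlist(waves, use.names = FALSE), sample_rate = sr,
    ground_truth = list(events = do.call(rbind, evs), groups = groups,
                        ph2_blocks = do.call(rbind, bls)),
    otu = recordings[[1L]]$otu,
    temperature = recordings[[1L]]$temperature,
    seed = as.integer(seed)), class = "song_recording")
}

#' Synthesize a composite individual with an exact group count
#'
#' Convenience wrapper: generates as many 20-group recordings (plus one
#' remainder recording) as needed and concatenates them, yielding a
#' composite individual with exactly `total_groups` phrase-1 groups.
#'
#' @inheritParams generate_song
#' @param total_groups Exact number of phrase-1 groups in the composite.
#' @param groups_per_recording Groups per constituent recording.
#' @return A `song_recording`.
#' @export
synth_composite <- function(preset, total_groups, temperature = 25,
                            sample_rate = 44100, seed = 1L,
                            groups_per_recording = 20L) {
  stopifnot(total_groups >= 1L)
  sizes <- rep(groups_per_recording,
               total_groups %/% groups_per_recording)
  if (total_groups %% groups_per_recording)
    sizes <- c(sizes, total_groups %% groups_per_recording)
  recs <- lapply(seq_along(sizes), function(i) {
    generate_song(preset, temperature = temperature, n_groups = sizes[i],
                  sample_rate = sample_rate, seed = seed + i * 131L)
  })
  concatenate_individuals(recs, min_groups = total_groups, seed = seed)
}
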