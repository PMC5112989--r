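# Power staircase, rates, syllable counts, carrier frequency and the
# aggregated per-individual features.

sine_at <- function(dur, sr, f = 14500, env = 1) {
  env * sin(2 * pi * f * (seq_len(round(dur * sr)) - 1) / sr)
}

test_that("standardized staircase is anchored at 0 and 1", {
  rec <- cached_song("brev", n_groups = 6, seed = 4)
  g <- rec$ground_truth$groups
  n_valid <- 0L
  for (i in seq_len(nrow(g))) {
    st <- power_staircase(rec$waveform, rec$sample_rate,
                          list(onset = g$e_l_onset[i],
                               offset = g$e_l_offset[i]))
    if (!st$valid) next
    n_valid <- n_valid + 1L
    expect_identical(st$standardized[1], 0)
    expect_identical(st$standardized[6], 1)
    expect_equal(st$standardized,
                 (st$raw_db - st$raw_db[1]) / (st$raw_db[6] - st$raw_db[1]))
  }
  expect_gt(n_valid, 0L)
})

test_that("staircase of a linear amplitude ramp matches the analytic oracle", {
  sr <- 44100; dur <- 3
  t <- (seq_len(dur * sr) - 0.5) / (dur * sr) # amplitude ramp 0 -> 1
  x <- sine_at(dur, sr, env = t)
  st <- power_staircase(x, sr, list(onset = 0, offset = dur))
  # independent oracle: mean squared amplitude of a linear ramp over [a, b]
  # is (b^3 - a^3) / (3 (b - a)); standardize the dB values analytically
  b <- c(0, 0.05, 0.15, 0.30, 0.60, 1.50, dur) / dur
  p <- vapply(1:6, function(i)
    10 * log10((b[i + 1]^3 - b[i]^3) / (3 * (b[i + 1] - b[i]))), numeric(1))
  expected <- (p - p[1]) / (p[6] - p[1])
  expect_true(st$valid)
  expect_equal(st$standardized, expected, tolerance = 0.01)
})

test_that("degenerate echemes yield an invalid staircase", {
  sr <- 44100
  flat <- sine_at(3, sr)                       # constant amplitude: no rise
  st <- power_staircase(flat, sr, list(onset = 0, offset = 3))
  expect_false(st$valid)
  expect_true(all(is.na(st$standardized)))
  short <- sine_at(1.2, sr)
  expect_false(power_staircase(short, sr,
                               list(onset = 0, offset = 1.2))$valid)
  expect_error(power_staircase(flat, sr, list(onset = 1, offset = 5)),
               "outside")
})

test_that("staircase is non-decreasing for monotone envelopes", {
  for (otu in c("petr", "brev", "lito")) {
    rec <- cached_song(otu, n_groups = 4, seed = 13)
    g <- rec$ground_truth$groups
    for (i in seq_len(nrow(g))) {
      st <- power_staircase(rec$waveform, rec$sample_rate,
                            list(onset = g$e_l_onset[i],
                                 offset = g$e_l_offset[i]))
      if (st$valid) expect_true(all(diff(st$standardized) > -1e-6))
    }
  }
})

test_that("chirp and phrase-2 rates equal hand counts", {
  ev <- hand_events(10, chirps = c(2L, 3L, 2L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
  g <- annotate_phrases(ev)$groups
  expect_equal(e_in_rate(g), 0.30)
  expect_equal(e_in_rate(annotate_phrases(hand_events(4))$groups), 0)
  expect_error(e_in_rate(g[0, ]), "group")
  # a 0.014 s pause after the chirps disqualifies the group
  ev2 <- hand_events(10, chirps = c(2L, rep(0L, 9)), chirp_pause = 0.014)
  expect_equal(e_in_rate(annotate_phrases(ev2)$groups), 0)

  g$followed_by_ph2 <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(ph2_rate(g), 0.3)
  g$followed_by_ph2 <- FALSE
  expect_equal(ph2_rate(g), 0)
  expect_error(ph2_rate(g[1:9, ]), "minimum sample")
  # the observed Torreilles tally: 32 of 117 groups
  g117 <- annotate_phrases(hand_events(117))$groups
  g117$followed_by_ph2 <- c(rep(TRUE, 32), rep(FALSE, 85))
  expect_equal(ph2_rate(g117), 32 / 117)
})

test_that("syllable counts match the generator and simple oracles", {
  sr <- 44100
  # seven raised-cosine pulses with clear gaps
  pulse <- sine_at(0.006, sr, env = sin(pi * (1:265) / 265))
  x <- c(rep(0, 100), rep(c(pulse, rep(0, 100)), 7))
  expect_equal(syllable_count(x, sr, list(onset = 0, offset = length(x) / sr)),
               7)
  # unmodulated burst counts one syllable
  burst <- sine_at(0.1, sr)
  expect_equal(syllable_count(burst, sr, list(onset = 0, offset = 0.1)), 1)
  expect_error(syllable_count(burst, sr, list(onset = 0, offset = 0.4)),
               "short echeme")
  # generator ground truth is recovered exactly per short echeme
  rec <- cached_song("lito", n_groups = 4, seed = 19)
  g <- rec$ground_truth$groups
  for (i in seq_len(nrow(g))) {
    expect_equal(syllable_count(rec$waveform, rec$sample_rate,
                                list(onset = g$e_s_onset[i],
                                     offset = g$e_s_offset[i])),
                 g$syllables[i])
  }
})

test_that("carrier-frequency quartiles sit in the right band", {
  sr <- 44100
  tone <- sine_at(0.5, sr, f = 14500)
  cf <- carrier_frequency(tone, sr, list(onset = 0, offset = 0.5))
  expect_lt(abs(cf$centre_khz - 14.5), 0.01)
  expect_true(cf$q1_khz <= cf$centre_khz && cf$centre_khz <= cf$q3_khz)
  # symmetric band of sinusoids 13-16 kHz -> centre near 14.5 kHz
  set.seed(5)
  freqs <- seq(13000, 16000, by = 50)
  ph <- runif(length(freqs), 0, 2 * pi)
  t <- (0:(sr / 2)) / sr
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) sin(2 * pi * freqs[i] * t + ph[i]),
                      numeric(length(t))))
  cfb <- carrier_frequency(x, sr, list(onset = 0, offset = 0.5))
  expect_lt(abs(cfb$centre_khz - 14.5), 0.2)
  expect_true(cfb$q1_khz < cfb$centre_khz && cfb$centre_khz < cfb$q3_khz)
  expect_error(carrier_frequency(tone, sr, list(onset = 0, offset = 0.005)),
               "too short")
})

test_that("phrase-2 power contrast recovers the preset offset", {
  p <- taxon_presets()$hipp
  rec <- cached_song("hipp", n_groups = 12, temperature = 24, seed = 6)
  ev <- segment_echemes(rec$waveform, rec$sample_rate)
  ann <- annotate_phrases(ev)
  expect_gt(nrow(ann$ph2_blocks), 0)
  ctr <- ph2_power_contrast(rec$waveform, rec$sample_rate, ev,
                            ann$groups, ann$ph2_blocks)
  expect_lt(abs(ctr - p$ph2_power_offset_db), 1)
  # no phrase 2 -> not applicable
  recb <- cached_song("petr", n_groups = 6, seed = 1)
  evb <- segment_echemes(recb$waveform, recb$sample_rate)
  annb <- annotate_phrases(evb)
  expect_true(is.na(ph2_power_contrast(recb$waveform, recb$sample_rate,
                                       evb, annb$groups, annb$ph2_blocks)))
  # phrase-2 echemes at the long echeme's full level -> 0 dB contrast
  sr <- 44100
  g2 <- c(sine_at(0.2, sr), rep(0, 2205), sine_at(0.02, sr), rep(0, 2205))
  x <- c(rep(0, 4410), g2, g2, rep(0, 22050), sine_at(2, sr), rep(0, 4410))
  evz <- segment_echemes(x, sr)
  expect_setequal(unique(evz$kind), c("E_L2", "E_S2", "E_L"))
  annz <- annotate_phrases(evz)
  ctr0 <- ph2_power_contrast(x, sr, evz, annz$groups, annz$ph2_blocks)
  expect_lt(abs(ctr0), 0.5)
})

test_that("compute_features aggregates correctly and deterministically", {
  rec <- cached_song("petr", n_groups = 12, seed = 31)
  f1 <- compute_features(rec$waveform, rec$sample_rate, 25)
  f2 <- compute_features(rec$waveform, rec$sample_rate, 25)
  expect_identical(f1, f2)
  expect_lt(f1$ied_s_l_min, 0.34)             # petr diagnostic
  expect_equal(f1$n_groups_used, 12)
  expect_true(f1$syllables_per_e_s >= 5 && f1$syllables_per_e_s <= 8)
  expect_true(f1$ef_l_q1 <= f1$ef_l_centre &&
                f1$ef_l_centre <= f1$ef_l_q3)
  expect_true(f1$e_in_rate >= 0 && f1$e_in_rate <= 1)
  # mean long-echeme duration equals the arithmetic mean of the annotation
  ann_f <- compute_features(rec$waveform, rec$sample_rate, 25,
                            annotation = rec$ground_truth$events)
  g <- rec$ground_truth$groups
  expect_equal(ann_f$ed_l_mean, mean(g$e_l_offset - g$e_l_onset),
               tolerance = 1e-12)
  # scale invariance of every relative feature
  f3 <- compute_features(rec$waveform * 2.5, rec$sample_rate, 25)
  cols <- setdiff(names(f1), "ph2_power_contrast_db")
  expect_equal(as.list(f1[, cols]), as.list(f3[, cols]), tolerance = 1e-9)
  # minimum sample rule
  rec5 <- cached_song("petr", n_groups = 6, seed = 1)
  expect_error(compute_features(rec5$waveform, rec5$sample_rate, 25),
               "minimum sample")
})
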