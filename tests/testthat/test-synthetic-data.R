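# Synthetic song generator, specimen simulator and composite individuals.

test_that("presets carry the published cohort values", {
  p <- taxon_presets()
  expect_setequal(names(p), c("petr", "brev", "hipp", "lito", "bulg"))
  expect_equal(p$petr$ed_l_mean, 3.058)
  expect_equal(p$petr$ed_l_sd, 1.121)
  expect_equal(p$lito$ph2_insertion_prob, 0.27)
  expect_equal(p$hipp$ph2_insertion_prob, 0.23)
  expect_equal(p$brev$light_junction_prob, 0)
  expect_equal(p$petr$light_junction_prob, 0.94)
  expect_equal(p$hipp$ph2_power_offset_db, 10.6)
  # bulg has attributes but no song
  expect_true(is.na(p$bulg$ed_l_mean))
  expect_error(generate_song(p$bulg, n_groups = 5), "no calling-song")
  # invariants hold for every preset with song data
  for (o in c("petr", "brev", "hipp", "lito")) {
    expect_true(p[[o]]$carrier_hz > 10000 && p[[o]]$carrier_hz < 20000)
    expect_true(p[[o]]$ph2_insertion_prob >= 0 &&
                  p[[o]]$ph2_insertion_prob <= 1)
  }
})

test_that("generate_song validates its arguments", {
  p <- taxon_presets()$petr
  expect_error(generate_song(p, n_groups = 0), "n_groups")
  expect_error(generate_song(p, temperature = 10, n_groups = 2),
               "temperature")
  expect_error(generate_song(p, n_groups = 2, sample_rate = 20000),
               "aliasing")
})

test_that("identical seeds give bit-identical recordings", {
  a <- generate_song(taxon_presets()$petr, n_groups = 3, seed = 7)
  b <- generate_song(taxon_presets()$petr, n_groups = 3, seed = 7)
  expect_identical(a$waveform, b$waveform)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_song(taxon_presets()$petr, n_groups = 3, seed = 8)
  expect_false(identical(a$waveform, c$waveform))
})

test_that("ground-truth events are ordered and groups well-formed", {
  rec <- cached_song("hipp", n_groups = 10, seed = 3)
  ev <- rec$ground_truth$events
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$offset > ev$onset))
  # non-overlap
  expect_true(all(ev$onset[-1] >= ev$offset[-nrow(ev)]))
  g <- rec$ground_truth$groups
  expect_true(all(g$e_l_offset < g$e_s_onset))
  expect_true(all(g$ied_l_s > 0))
})

test_that("generated duration means match the truncated-normal targets", {
  # distributional recovery at n_groups >= 500 (petr, single recording)
  p <- taxon_presets()$petr
  rec <- generate_song(p, temperature = 25, n_groups = 500, seed = 11)
  g <- rec$ground_truth$groups
  checks <- list(
    list(g$e_l_offset - g$e_l_onset, p$ed_l_mean, p$ed_l_sd, 0.7, 60),
    list(g$e_s_offset - g$e_s_onset, p$ed_s_mean, p$ed_s_sd, 0.02, 0.3),
    list(g$ied_l_s, p$ied_l_s_mean, p$ied_l_s_sd, 0.03, 0.14))
  for (ch in checks) {
    target <- songdelim:::tnorm_mean(ch[[2]], ch[[3]], ch[[4]], ch[[5]])
    se <- ch[[3]] / sqrt(length(ch[[1]]))
    expect_lt(abs(mean(ch[[1]]) - target), 3 * se)
  }
  # ied_s_l has a floor at the chirp train; compare where no train follows
  ied <- g$ied_s_l[!is.na(g$ied_s_l)]
  expect_lt(abs(mean(ied) -
                  songdelim:::tnorm_mean(p$ied_s_l_mean, p$ied_s_l_sd,
                                         0.05, Inf)),
            4 * p$ied_s_l_sd / sqrt(length(ied)) + 0.05)
  # example check: mean E_L duration within 2 SE at n = 50
  rec50 <- generate_song(p, temperature = 25, n_groups = 50, seed = 1)
  g50 <- rec50$ground_truth$groups
  expect_lt(abs(mean(g50$e_l_offset - g50$e_l_onset) - 3.058),
            2 * 1.121 / sqrt(50) + 0.06)  # + truncation shift allowance
})

test_that("durations shrink monotonically with temperature", {
  p <- taxon_presets()$brev
  means <- vapply(c(19, 25, 31), function(tmp) {
    g <- generate_song(p, temperature = tmp, n_groups = 15,
                       seed = 21)$ground_truth$groups
    mean(g$e_l_offset - g$e_l_onset)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("phrase-2 insertions are binomial with the preset probability", {
  p <- taxon_presets()$hipp
  counts <- vapply(1:25, function(s) {
    sum(generate_song(p, n_groups = 10, seed = 100 + s,
                      temperature = 24)$ground_truth$groups$followed_by_ph2)
  }, numeric(1))
  n_tot <- 25 * 10
  bt <- stats::binom.test(sum(counts), n_tot, p = p$ph2_insertion_prob)
  expect_gt(bt$p.value, 0.001)
  # per-recording counts look binomial, not degenerate
  expect_gt(stats::var(counts), 0)
})

test_that("specimen tables follow the preset attribute frequencies", {
  p <- taxon_presets()
  s <- generate_specimens(p$petr, 1e5, seed = 3)
  expect_lt(abs(mean(s$junction_light) - 0.94), 0.005)
  all_light <- p$lito
  expect_true(all(generate_specimens(all_light, 50, seed = 1)$junction_light))
  expect_true(all(generate_specimens(p$lito, 200, seed = 2)$altitude_m <= 10))
  expect_error(generate_specimens(p$petr, 0), "n")
  expect_identical(generate_specimens(p$brev, 20, seed = 5),
                   generate_specimens(p$brev, 20, seed = 5))
})

test_that("composites concatenate with re-offset ground truth", {
  a <- cached_song("petr", n_groups = 6, seed = 41)
  b <- cached_song("petr", n_groups = 5, seed = 42)
  comp <- concatenate_individuals(list(a, b), min_groups = 10, seed = 1)
  expect_equal(nrow(comp$ground_truth$groups), 11)
  expect_true(all(diff(comp$ground_truth$events$onset) > 0))
  expect_equal(length(comp$waveform),
               length(a$waveform) + length(b$waveform) + 44100)
  # a single input is returned unchanged
  expect_identical(concatenate_individuals(list(a), min_groups = 5), a)
  # shortfall is reported with counts
  expect_error(concatenate_individuals(list(a, b), min_groups = 12),
               "11 available, 12 required")
  # synth_composite hits an exact group count
  cc <- synth_composite(taxon_presets()$petr, 13, seed = 9,
                        groups_per_recording = 5L)
  expect_equal(nrow(cc$ground_truth$groups), 13)
})
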