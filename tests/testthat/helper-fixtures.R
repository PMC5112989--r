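# Shared fixtures built in code. Small recordings are cached per test run
# so several test files can reuse them without re-synthesizing.

.fixture_cache <- new.env(parent = emptyenv())

cached_song <- function(otu, n_groups = 6L, temperature = 25, seed = 1L) {
  key <- paste(otu, n_groups, temperature, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    p <- taxon_presets()[[otu]]
    .fixture_cache[[key]] <- generate_song(p, temperature = temperature,
                                           n_groups = n_groups, seed = seed)
  }
  .fixture_cache[[key]]
}

# hand-built phrase-1 annotation: n groups of E_L/E_S alternation with
# configurable chirps in front of selected groups
hand_events <- function(n_groups, chirps = integer(n_groups),
                        chirp_pause = 0.04, ed_l = 2, ied_l_s = 0.06,
                        ed_s = 0.05, ied_s_l = 0.8) {
  rows <- list()
  t <- 0.5
  for (g in seq_len(n_groups)) {
    for (j in seq_len(chirps[g])) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "E_IN", onset = t, offset = t + 0.02)
      t <- t + 0.02 + chirp_pause
    }
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "E_L", onset = t, offset = t + ed_l)
    t <- t + ed_l + ied_l_s
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "E_S", onset = t, offset = t + ed_s)
    t <- t + ed_s + ied_s_l
  }
  do.call(rbind, rows)
}

# a full petr-like trait record matching every petr expectation
petr_record <- function() {
  list(ph2_population_rate = 0.01, ep_l_1 = 0.25, ied_s_l_min = 0.30,
       e_in_number = 1.0, junction_light = TRUE, apical8_dark_rims = TRUE,
       postclypeus_spot = FALSE, altitude_m = 400, salt_marsh = FALSE,
       coi_dist_to_cerdaniensis = 0.01)
}
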