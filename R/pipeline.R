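# End-to-end pipeline: synthesis -> feature extraction -> temperature GLMs,
# partial-residual classification and PCA -> trait diagnosis (-> p-distance
# tables when an alignment is supplied). The numbered scripts under
# analysis/ are thin drivers over this function and its stages.

#' Pipeline configuration
#'
#' @param otus OTUs to simulate (with song data).
#' @param n_individuals Individuals per OTU.
#' @param n_groups Phrase-1 groups per individual recording.
#' @param temp_range Perch-temperature range (degrees C) sampled uniformly.
#' @param sample_rate Synthesis sampling rate in Hz.
#' @param seed Master seed; all per-individual seeds derive from it.
#' @param reference_pair The two OTUs defining the GLM contrast.
#' @param segmentation A [segmentation_config()].
#' @param out_dir Output directory for the CSV/JSON artefacts (`NULL` for
#'   in-memory results only).
#' @param alignment Optional `labelled_alignment` (or list of them) for the
#'   distance stage.
#' @param write_wavs Also write each recording as WAV + JSON annotation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(otus = c("petr", "brev"), n_individuals = 8L,
                            n_groups = 12L, temp_range = c(19, 31),
                            sample_rate = 44100, seed = 1L,
                            reference_pair = c("petr", "brev"),
                            segmentation = segmentation_config(),
                            out_dir = NULL, alignment = NULL,
                            write_wavs = FALSE) {
  structure(list(otus = otus, n_individuals = n_individuals,
                 n_groups = n_groups, temp_range = temp_range,
                 sample_rate = sample_rate, seed = as.integer(seed),
                 reference_pair = reference_pair,
                 segmentation = segmentation, out_dir = out_dir,
                 alignment = alignment, write_wavs = write_wavs),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full delimitation pipeline
#'
#' Simulates per-individual recordings for each configured OTU, extracts
#' song features through envelope segmentation, fits the
#' temperature-correction models for the three diagnostic song characters
#' between the reference OTUs, classifies every individual by partial
#' residuals, runs the correlation PCA, evaluates the diagnostic trait
#' matrix, flags putative hybrids, and (optionally) computes group-mean
#' p-distance tables. Deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list with `features`, `fits`, `classifications`, `pca`,
#'   `hybrids`, `diagnosis`, `distances` and the run `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  presets <- taxon_presets()
  missing <- setdiff(config$otus, names(presets))
  if (length(missing)) stop("unknown OTU(s): ", paste(missing, collapse = ", "))

  feats <- stage("features", {
    rows <- list()
    idx <- 0L
    for (otu in config$otus) {
      for (i in seq_len(config$n_individuals)) {
        idx <- idx + 1L
        sd_i <- config$seed + idx * 977L
        temp <- with_seed(sd_i, round(stats::runif(
          1, config$temp_range[1], config$temp_range[2]), 1))
        rec <- generate_song(presets[[otu]], temperature = temp,
                             n_groups = config$n_groups,
                             sample_rate = config$sample_rate,
                             seed = sd_i + 1L)
        if (config$write_wavs && !is.null(config$out_dir)) {
          wd <- file.path(config$out_dir, "recordings")
          dir.create(wd, showWarnings = FALSE, recursive = TRUE)
          write_wav(rec$waveform, rec$sample_rate,
                    file.path(wd, sprintf("%s_%02d.wav", otu, i)))
          write_annotation(rec, file.path(wd, sprintf("%s_%02d.json",
                                                      otu, i)))
        }
        f <- compute_features(rec$waveform, rec$sample_rate, temp,
                              config$segmentation)
        rows[[idx]] <- cbind(
          data.frame(recording_id = sprintf("%s_%02d", otu, i), otu = otu,
                     stringsAsFactors = FALSE), f)
      }
    }
    do.call(rbind, rows)
  })

  rp <- config$reference_pair
  stats_out <- stage("stats", {
    inpair <- feats$otu %in% rp
    vars <- c(ep_l_1 = "gaussian_identity",
              ied_s_l_min = "gaussian_identity",
              e_in_number = "poisson_log")
    fits <- list(); cls <- list()
    for (v in names(vars)) {
      vals <- if (vars[[v]] == "poisson_log")
        as.integer(round(feats[[v]][inpair] * feats$n_groups_used[inpair]))
        else feats[[v]][inpair]
      # counts are refit on group totals; gaussian variables as measured
      fit <- fit_temperature_glm(vals, feats$temperature[inpair],
                                 feats$otu[inpair], vars[[v]],
                                 variable_name = v, reference = rp[1])
      all_vals <- if (vars[[v]] == "poisson_log")
        round(feats[[v]] * feats$n_groups_used) else feats[[v]]
      cls[[v]] <- classify_by_partial_residuals(
        fit, all_vals, feats$temperature, feats$otu)
      fits[[v]] <- fit
    }
    pca <- pca_correlation(feats[, c("ep_l_1", "ied_s_l_min",
                                     "e_in_number")])
    list(fits = fits, classifications = cls, pca = pca)
  })

  hybrids <- stage("hybrids", flag_hybrids(stats_out$classifications))

  diagnosis <- stage("diagnosis", {
    tr <- data.frame(
      record_id = feats$recording_id, otu = feats$otu,
      ph2_population_rate = stats::ave(feats$ph2_rate, feats$otu),
      ep_l_1 = feats$ep_l_1, ied_s_l_min = feats$ied_s_l_min,
      e_in_number = feats$e_in_number,
      junction_light = NA, apical8_dark_rims = NA, postclypeus_spot = NA,
      altitude_m = NA, salt_marsh = NA, coi_dist_to_cerdaniensis = NA,
      stringsAsFactors = FALSE)
    diagnose_records(tr)
  })

  distances <- NULL
  if (!is.null(config$alignment)) {
    distances <- stage("pdist", {
      al <- config$alignment
      if (inherits(al, "labelled_alignment")) al <- list(al)
      lapply(al, group_mean_distances)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("songdelim")),
    seed = config$seed, otus = config$otus,
    n_individuals = config$n_individuals, n_groups = config$n_groups,
    sample_rate = config$sample_rate,
    reference_pair = rp,
    segmentation = unclass(config$segmentation),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  out <- list(features = feats, fits = stats_out$fits,
              classifications = stats_out$classifications,
              pca = stats_out$pca, hybrids = hybrids,
              diagnosis = diagnosis, distances = distances,
              manifest = manifest)

  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(feats, file.path(config$out_dir, "features.csv"),
                       row.names = FALSE)
      ftab <- do.call(rbind, lapply(out$fits, function(f) data.frame(
        variable = f$variable_name, family = f$family, a = f$a, b = f$b,
        c = f$c, t_or_z_temp = f$t_or_z_temp, p_temp = f$p_temp,
        t_or_z_otu = f$t_or_z_otu, p_otu = f$p_otu, n = f$n)))
      utils::write.csv(ftab, file.path(config$out_dir, "glm_fits.csv"),
                       row.names = FALSE)
      utils::write.csv(cbind(recording_id = feats$recording_id,
                             out$hybrids),
                       file.path(config$out_dir, "hybrid_flags.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(recording_id = feats$recording_id,
                                  otu = feats$otu, out$pca$scores),
                       file.path(config$out_dir, "pca_scores.csv"),
                       row.names = FALSE)
      utils::write.csv(out$diagnosis,
                       file.path(config$out_dir, "diagnosis.csv"),
                       row.names = FALSE)
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
  }
  out
}
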