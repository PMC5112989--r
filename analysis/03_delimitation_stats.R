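#!/usr/bin/env Rscript
# Statistical delimitation on the extracted features: ANCOVA interaction
# screen, common-slope temperature GLMs for the three diagnostic song
# characters between petr and brev, partial-residual classification of all
# individuals, correlation PCA, hybrid flags, and the rank-sum comparison
# of phrase-2 loudness (hipp vs the rest).

suppressPackageStartupMessages(library(songdelim))

feats <- read.csv("results/features.csv", stringsAsFactors = FALSE)
pair <- feats$otu %in% c("petr", "brev")

vars <- c(ep_l_1 = "gaussian_identity",
          ied_s_l_min = "gaussian_identity",
          e_in_number = "poisson_log")
fits <- list(); cls <- list()
for (v in names(vars)) {
  an <- ancova_interaction(feats[[v]][pair], feats$temperature[pair],
                           feats$otu[pair])
  message(sprintf("%s: temperature x taxon interaction F = %.2f, p = %.3f%s",
                  v, an$f_statistic, an$p_value,
                  if (an$p_value > 0.05) " (common slopes justified)" else ""))
  vals <- if (vars[[v]] == "poisson_log")
    as.integer(round(feats[[v]][pair] * feats$n_groups_used[pair]))
    else feats[[v]][pair]
  fit <- fit_temperature_glm(vals, feats$temperature[pair],
                             feats$otu[pair], vars[[v]],
                             variable_name = v, reference = "petr")
  print(fit)
  all_vals <- if (vars[[v]] == "poisson_log")
    round(feats[[v]] * feats$n_groups_used) else feats[[v]]
  cls[[v]] <- classify_by_partial_residuals(fit, all_vals,
                                            feats$temperature, feats$otu)
  fits[[v]] <- fit
}
ftab <- do.call(rbind, lapply(fits, function(f) data.frame(
  variable = f$variable_name, family = f$family, a = f$a, b = f$b, c = f$c,
  t_or_z_temp = f$t_or_z_temp, p_temp = f$p_temp,
  t_or_z_otu = f$t_or_z_otu, p_otu = f$p_otu, n = f$n)))
write.csv(ftab, "results/glm_fits.csv", row.names = FALSE)

cl_tab <- data.frame(recording_id = feats$recording_id, otu = feats$otu)
for (v in names(cls)) cl_tab[[paste0(v, "_zone")]] <- cls[[v]]$label
write.csv(cl_tab, "results/classification.csv", row.names = FALSE)
for (v in names(cls)) {
  z <- table(feats$otu, cls[[v]]$label)
  message(v, " zones by OTU:"); print(z)
}

hyb <- flag_hybrids(cls)
write.csv(cbind(recording_id = feats$recording_id, hyb),
          "results/hybrid_flags.csv", row.names = FALSE)
message(sum(hyb$hybrid_flag), " individual(s) flagged as putative hybrids")

pc <- pca_correlation(feats[, names(vars)])
sc <- data.frame(recording_id = feats$recording_id, otu = feats$otu,
                 pc$scores)
write.csv(sc, "results/pca_scores.csv", row.names = FALSE)
message(sprintf("PCA: PC1 %.0f%%, PC2 %.0f%% of variance",
                100 * pc$explained[1], 100 * pc$explained[2]))
if (requireNamespace("ggplot2", quietly = TRUE)) {
  gp <- ggplot2::ggplot(sc, ggplot2::aes(PC1, PC2, colour = otu)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * pc$explained[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * pc$explained[2]))
  ggplot2::ggsave("results/pca_scatter.pdf", gp, width = 5, height = 4)
}

# phrase-2 relative loudness: hipp vs the other OTUs
ctr <- feats$ph2_power_contrast_db
have <- !is.na(ctr)
if (any(have & feats$otu == "hipp") && any(have & feats$otu != "hipp")) {
  w <- wilcoxon_rank_sum(ctr[have & feats$otu == "hipp"],
                         ctr[have & feats$otu != "hipp"])
  message(sprintf(
    "PH2 power contrast, hipp vs rest: W = %.1f, p = %.3g (hipp louder)",
    w$W, w$p_value))
}
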