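#!/usr/bin/env Rscript
# Apply the diagnostic trait matrix to per-OTU cohorts of simulated trait
# records (acoustics from the presets, colouration/ecology from the
# specimen model) and report the confusion between true and assigned taxa.

suppressPackageStartupMessages(library(songdelim))

presets <- taxon_presets()
records <- do.call(rbind, lapply(c("petr", "brev", "hipp", "lito"),
  function(otu) simulate_trait_records(presets[[otu]], 100, seed = 2016)))
dg <- diagnose_records(records)
write.csv(dg, "results/diagnosis.csv", row.names = FALSE)

conf <- table(true = dg$true_otu, assigned = dg$best_taxon)
print(conf)
acc <- vapply(rownames(conf), function(tx)
  mean(dg$best_taxon[dg$true_otu == tx] == tx), numeric(1))
message("per-OTU assignment accuracy: ",
        paste(sprintf("%s %.0f%%", names(acc), 100 * acc), collapse = ", "))
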