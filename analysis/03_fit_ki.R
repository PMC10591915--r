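#!/usr/bin/env Rscript
# Fit every displacement titration with the one-site saturation +
# nonspecific model, per replicate, and summarise Ki as mean +/- SD.

suppressPackageStartupMessages(library(crbpflex))
files <- list.files("results/data", pattern = "^titration_.*\\.csv$",
                    full.names = TRUE)
rows <- lapply(files, function(f) {
  s <- read_titration_csv(f)
  su <- replicate_summary(fit_replicates(s))
  data.frame(compound = sub("^titration_(.*)\\.csv$", "\\1", basename(f)),
             ki_mean_uM = su$ki_mean * 1e6, ki_sd_uM = su$ki_sd * 1e6,
             n_replicates = su$n)
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/ki_fits.csv", row.names = FALSE)
cat("fitted Ki (mean +/- SD over replicates, uM):\n")
print(tab, row.names = FALSE, digits = 3)
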