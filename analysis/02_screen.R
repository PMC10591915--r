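#!/usr/bin/env Rscript
# Score the screening plate against its positive-control signature,
# apply the optical-artifact exclusions and call hits at >= 1.5.

suppressPackageStartupMessages(library(crbpflex))
plate <- read_plate_csv("results/data/plate.csv")
res <- screen_plate(plate, threshold = 1.5)
utils::write.csv(as.data.frame(res), "results/screen_results.csv",
                 row.names = FALSE)

hits <- call_hits(res)
truth <- plate$well_id[!is.na(plate$true_class) &
                         plate$true_class == "binder"]
cat(sprintf("scored %d compound wells against the control signature\n",
            nrow(res)))
cat(sprintf("excluded %d wells (absorbance/autofluorescence)\n",
            sum(res$excluded)))
cat(sprintf("hits at score >= 1.5: %d; ground-truth binders: %d; agreement: %s\n",
            length(hits), length(truth),
            identical(sort(hits), sort(truth))))
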