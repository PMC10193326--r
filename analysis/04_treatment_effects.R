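#!/usr/bin/env Rscript
# Step 4: treatment-effect stage on the simulated three-arm cohort.
#
# Zero-filters the signatures, fits the covariate (treatment + age +
# gender) and treatment-only linear models per signature for all three
# dose contrasts, BH-adjusts within each contrast and p-type family, and
# applies the dual significance rule (both adjusted p < 0.1). Reports
# recovery of the injected effects.

suppressPackageStartupMessages(library(immunomix))

out <- "results/treatment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- utils::read.csv("results/sim/cohort.csv", stringsAsFactors = FALSE)
injected <- readLines("results/sim/injected_signatures.txt")[-1]

res <- analyze_cohort(cohort)
utils::write.csv(res, file.path(out, "effect_results.csv"), row.names = FALSE)

for (ctr in unique(res$contrast)) {
  sub <- res[res$contrast == ctr, ]
  flagged <- sub$signature_id[sub$significant]
  cat(sprintf("%s: %d/%d significant; injected recovered %d/%d; false flags %d\n",
              ctr, length(flagged), nrow(sub),
              length(intersect(flagged, injected)), length(injected),
              length(setdiff(flagged, injected))))
}
dropped <- attr(res, "dropped")
cat("Zero-filtered signatures:",
    if (length(dropped)) paste(dropped, collapse = ", ") else "none", "\n")
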