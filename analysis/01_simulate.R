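#!/usr/bin/env Rscript
# Step 1: generate the study inputs with known ground truth.
#
# Builds a 5-type signature matrix, 50 bulk mixtures at microarray-like
# noise, a matched pseudo-flow panel, and a three-arm cohort of the trial
# subset's size (57 / 62 / 70) with effects injected into five signatures.
# Everything downstream (02-04) reads from results/sim/.

suppressPackageStartupMessages(library(immunomix))

seed <- 20260929
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

B <- make_signature_matrix(n_genes = 120, n_types = 5, overlap = 0.2,
                           seed = seed)
mx <- make_mixtures(B, n_samples = 50, noise_sd = 0.05, seed = seed + 1)
flow <- make_flow(mx$truth, cv = 0.05, seed = seed + 2)

injected <- paste0("sig", 1:5)
cohort <- make_cohort(
  signatures = paste0("sig", 1:40),
  effects = do.call(rbind, lapply(injected, function(s)
    data.frame(signature = s, arm = c("low_dose", "high_dose"), delta = 0.2))),
  baseline_sd = 0.2, seed = seed + 3)

write_expression(B, file.path(out, "signature_matrix.tsv"))
write_expression(mx$expr, file.path(out, "mixtures.tsv"))
write_scores(mx$truth$fractions, file.path(out, "true_fractions.tsv"),
             method_tag = NULL, id_col = "cell_type")
write_flow(flow, file.path(out, "flow_panel.csv"))
utils::write.csv(cohort$cohort, file.path(out, "cohort.csv"), row.names = FALSE)
writeLines(c("injected_signatures", injected),
           file.path(out, "injected_signatures.txt"))

cat("Simulated:", ncol(mx$expr), "mixtures over", ncol(B), "cell types;",
    nrow(cohort$cohort), "cohort patients;",
    "effects injected into", length(injected), "of 40 signatures.\n")
cat("Outputs under", out, "\n")
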