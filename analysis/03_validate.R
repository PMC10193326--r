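#!/usr/bin/env Rscript
# Step 3: validation.
#
# (a) Classify the bundled published correlation tables (the 14 SVR-method
#     and 25 ssGSEA-method signature/flow pairs) and tabulate categories.
# (b) Validate the simulated deconvolution output of step 2 against the
#     pseudo-flow panel of step 1 with Spearman + BH, and write the static
#     per-pair report.

suppressPackageStartupMessages(library(immunomix))

out <- "results/validation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# (a) published tables through the assessment rule
for (which in c("gse93777_cibersort", "gse93777_xcell")) {
  tab <- load_correlation_table(which)
  tab$category <- classify_correlation(tab$r, tab$fdr)
  counts <- summarize_categories(tab$category)
  utils::write.csv(tab, file.path(out, paste0(which, "_classified.csv")),
                   row.names = FALSE)
  cat(which, ": ", paste(names(counts), counts, sep = "=", collapse = " "),
      "\n", sep = "")
}

# (b) simulated scores vs pseudo-flow
scores <- read_scores("results/deconv/svr_fractions.tsv")
flow <- read_flow("results/sim/flow_panel.csv")
mapping <- data.frame(signature_id = rownames(scores),
                      flow_phenotype = rownames(scores))
v <- validate_scores(scores, flow, mapping, method = "bh")
utils::write.csv(v$results, file.path(out, "simulated_validation.csv"),
                 row.names = FALSE)
write_validation_report(v, file.path(out, "simulated_validation.md"),
                        title = "Simulated SVR fractions vs pseudo-flow")
cat("Simulated validation: ",
    paste(names(unlist(v$summary)), unlist(v$summary), sep = "=",
          collapse = " "), "\n", sep = "")
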