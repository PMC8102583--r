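#!/usr/bin/env Rscript
# Synthetic trauma cohort: generate the 48/47/47 design, summarize mediator
# panels per group, and reproduce the low-MCP-1 subgroup contrast.

library(chemoswitch)
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(seed = 1L)
utils::write.csv(cohort, file.path("results", "synthetic_cohort.csv"),
                 row.names = FALSE)
gs <- group_summary(cohort)
utils::write.csv(gs, file.path("results", "cohort_group_summary.csv"),
                 row.names = FALSE)
cat(sprintf("cohort: %d patients (incl. healthy reference)\n",
            length(unique(cohort$patient_id))))

sub <- subgroup_low_mcp1(cohort, threshold = 1000)
gsub <- group_summary(sub)
utils::write.csv(gsub, file.path("results", "subgroup_low_mcp1_summary.csv"),
                 row.names = FALSE)
cat(sprintf("low-MCP-1 subgroup (first sample < 1000 pg/ml): %d patients\n",
            length(unique(sub$patient_id))))

late <- gsub[gsub$mediator == "MCP1" & gsub$time_h == 168, ]
for (g in c("moderate", "severe")) {
  cat(sprintf("  MCP-1 at 168 h, %s injury: %.0f pg/ml (SE %.0f)\n",
              g, late$mean[late$group == g], late$se[late$group == g]))
}
cat("\nFinding: among patients starting with low MCP-1, severe injury\n")
cat("sustains elevated MCP-1 through day 7 while moderate injury resolves\n")
cat("to baseline.\n")
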