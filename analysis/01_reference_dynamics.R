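#!/usr/bin/env Rscript
# Reference chemokine-switch dynamics: zero-init trajectories per injury
# severity and exhaustive-ensemble mean/SE trajectories (the simulation
# counterpart of the population mediator panels).

library(chemoswitch)
dir.create("results", showWarnings = FALSE)

model <- reference_model()
write_model(model, file.path("results", "reference_model.txt"))

cat("== Zero-init trajectories ==\n")
rows <- list()
for (inj in 0:2) {
  label <- c("mild", "moderate", "severe")[inj + 1]
  tr <- simulate_model(model, zero_state(model, inj), 12L,
                       clamps = list(I = inj))
  cat(sprintf("%s injury: IP10 %s | MCP1 %s | IL6 %s\n", label,
              paste(tr[1:8, "IP10"], collapse = ""),
              paste(tr[1:8, "MCP1"], collapse = ""),
              paste(tr[1:8, "IL6"], collapse = "")))
  df <- as.data.frame(tr)
  df$step <- as.integer(rownames(tr))
  df$injury <- label
  rows[[label]] <- df
}
utils::write.csv(do.call(rbind, rows),
                 file.path("results", "zero_init_trajectories.csv"),
                 row.names = FALSE)

cat("\n== Exhaustive 108-state ensembles ==\n")
ens_rows <- list()
for (inj in c(1L, 2L)) {
  label <- c("mild", "moderate", "severe")[inj + 1]
  states <- enumerate_initial_states(model, fixed = list(I = inj))
  s <- ensemble_summary(simulate_ensemble(model, states, 20L))
  cat(sprintf("%s: mean IL-6 by step: %s\n", label,
              paste(round(s$mean[1:8, "IL6"], 3), collapse = " ")))
  for (v in colnames(s$mean)) {
    ens_rows[[paste(label, v)]] <- data.frame(
      injury = label, variable = v, step = as.integer(rownames(s$mean)),
      mean = s$mean[, v], se = s$se[, v])
  }
}
utils::write.csv(do.call(rbind, ens_rows),
                 file.path("results", "ensemble_trajectories.csv"),
                 row.names = FALSE)
cat("\nFinding: moderate injury saturates IP-10 only; severe injury adds a\n")
cat("transient MCP-1/IL-6 peak that settles at a moderate level.\n")
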