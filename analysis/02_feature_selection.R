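#!/usr/bin/env Rscript
# Wavelet-coherence feature selection: within-AB versus between-AB movie
# coherence, cluster statistics per movie segment, and the resulting
# time-frequency templates.

library(waversa)

seed <- 1L
epochs <- read_epochs("results/epochs")
cfg <- run_config("desk", seed = seed)
design <- build_design(cfg$n_triads, cfg$n_repetitions, cfg$sample_rate_hz,
                       cfg$n_channels)
ab <- design$movies$movie_id[design$movies$role == "AB"]
pairs_within <- do.call(rbind, lapply(ab, enumerate_within_pairs, design = design))
pairs_between <- do.call(rbind, lapply(ab, enumerate_between_pairs, design = design))
cat(sprintf("averaging %d within and %d between pairs per participant\n",
            nrow(pairs_within), nrow(pairs_between)))

within_maps <- list(); between_maps <- list(); times <- NULL
for (p in sort(unique(epochs$trials$participant))) {
  rows <- which(epochs$trials$participant == p & epochs$trials$role == "AB")
  bank <- coherence_coefficients(waversa:::subset_epochs(epochs, rows),
                                 time_step_s = cfg$coherence_step_s)
  s <- participant_coherence_summary(bank, pairs_within, pairs_between)
  within_maps[[as.character(p)]] <- s$within
  between_maps[[as.character(p)]] <- s$between
  times <- s$times
}

templates <- select_template(within_maps, between_maps, design, times, 3:30,
                             n_permutations = cfg$n_permutations,
                             seed = seed + 11L)
for (tp in templates) print(tp)

summary_tab <- do.call(rbind, lapply(templates, function(tp) {
  cl <- tp$cluster$clusters
  data.frame(segment = tp$segment,
             n_selected_cells = sum(tp$mask),
             n_significant_clusters = sum(cl$significant),
             max_cluster_mass = if (nrow(cl)) max(cl$mass) else NA,
             min_p = if (nrow(cl)) min(cl$p_value, na.rm = TRUE) else NA)
}))
utils::write.table(summary_tab, "results/feature_selection.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
saveRDS(list(within = within_maps, between = between_maps, times = times,
             templates = templates), "results/feature_selection.rds")
cat("wrote results/feature_selection.tsv\n")
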