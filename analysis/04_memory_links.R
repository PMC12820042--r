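#!/usr/bin/env Rscript
# Trial-level Bayesian regressions linking window-averaged neural
# (dis)similarity to associative (AC) and source memory, plus the
# Monte-Carlo comparison of behavioural effect sizes across movie types.

library(waversa)

report <- readRDS("results/report.rds")
if (!length(report$regressions)) {
  cat("no detected windows -> no trial-level regressions to report\n")
} else {
  rows <- do.call(rbind, lapply(names(report$regressions), function(nm) {
    co <- report$regressions[[nm]]$coefficients
    co$analysis <- nm
    co
  }))
  utils::write.table(rows, "results/memory_regressions.tsv", sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (nm in names(report$regressions)) {
    co <- report$regressions[[nm]]$coefficients
    key <- co[nrow(co) - (if (grepl("source", nm)) 1 else 0), ]
    cat(sprintf("%s: beta = %+.3f, BF10 = %.2f (n = %d trials)\n",
                nm, key$beta, key$bf10, report$regressions[[nm]]$n))
  }
}
if (!is.null(report$behavior)) {
  utils::write.table(report$behavior, "results/behavior_effect_sizes.tsv",
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cat("\nMonte-Carlo effect-size comparison across movie types:\n")
  print(report$behavior)
}
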