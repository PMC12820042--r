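#!/usr/bin/env Rscript
# Univariate spectral-power contrast (BC - XY)/BC per movie segment with
# cluster permutation statistics, and the Bayesian linkage between cluster
# power and the RSA (dis)similarities.

library(waversa)

report <- readRDS("results/report.rds")
if (!length(report$univariate)) {
  cat("univariate stage was not run\n")
} else {
  tab <- do.call(rbind, lapply(names(report$univariate), function(seg) {
    cl <- report$univariate[[seg]]$clusters
    if (!nrow(cl)) return(NULL)
    cl$segment <- seg
    cl
  }))
  utils::write.table(tab, "results/univariate_clusters.tsv", sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sig <- report$significant_clusters
  cat(sprintf("%d significant power cluster(s) across segments\n",
              if (is.null(sig)) 0 else nrow(sig)))
  if (!is.null(sig) && nrow(sig)) print(sig[, c("segment", "sign", "mass",
                                                "p_value", "n_members")])
}
if (length(report$power_links)) {
  rows <- do.call(rbind, lapply(names(report$power_links), function(nm) {
    co <- report$power_links[[nm]]$coefficients
    co$link <- nm
    co
  }))
  utils::write.table(rows, "results/power_similarity_links.tsv", sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cat("\npower -> similarity linkage (standardized betas):\n")
  print(rows[rows$term == "power", c("link", "beta", "bf10")])
}
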