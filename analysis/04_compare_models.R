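#!/usr/bin/env Rscript
# Step 4 -- model comparison by DIC.
#
# Rebuilds the six-model comparison for each round from the DIC tables of
# step 3: differences against the full model M6 and the <= 5-DIC
# similarity rule.  The expected pattern on these data: the spatial
# models (M4/M5/M6 and to a lesser degree M3) clearly beat M1/M2, and the
# best few models are within 5 DIC of each other.

library(geomultinom)

for (year in c("2014", "2018")) {
  dic_tab <- read.csv(file.path("results", paste0("dic_", year, ".csv")))
  res <- lapply(seq_len(nrow(dic_tab)), function(i) {
    dic_result(dic_tab$model[i], dic_tab$mean_deviance[i], dic_tab$pD[i],
               n_obs = dic_tab$n_obs[i])
  })
  cmp <- compare_models(res, reference = "M6")
  write.csv(cmp, file.path("results", paste0("model_comparison_", year, ".csv")),
            row.names = FALSE)
  cat("== round", year, "==\n")
  print(cmp, digits = 6)
  cat("models within 5 DIC of the best:",
      paste(cmp$model[cmp$similar], collapse = ", "), "\n\n")
}
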