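#!/usr/bin/env Rscript
# Model-evaluation statistics for the simulated panels: pairs each
# predicted series with its observed counterpart and reports RMSE (absolute
# and normalized), MAE, signed bias, Willmott's index, the
# predicted-on-observed regression and Welch's test.

suppressPackageStartupMessages(library(yieldstab))
dir.create("results", showWarnings = FALSE)

reports <- list()
for (preset in c("sadore_millet", "ndiaye_rice")) {
  panel <- read_yield_table(file.path("results",
                                      paste0("panel_", preset, ".csv")))
  pairs <- align_observed_predicted(panel)
  rep_ <- evaluate_pairs(pairs)
  rep_$dataset_id <- preset
  reports[[preset]] <- rep_
  message(sprintf(
    "%s: n = %d, RMSEa = %.2f Mg/ha (RMSEn = %.1f%%), MAE = %.2f, WI = %.2f, p(Welch) = %.2f",
    preset, rep_$n, rep_$rmse_a, rep_$rmse_n, rep_$mae, rep_$wi,
    rep_$p_welch))
}
out <- "results/model_evaluation.csv"
readr::write_csv(dplyr::bind_rows(reports), out)
message("wrote ", out)
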