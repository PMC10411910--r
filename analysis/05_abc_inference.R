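#!/usr/bin/env Rscript
# How many rate-limiting steps, and how fast is export?
#
# Fits the expression model to the synthetic dataset by ABC rejection:
# first model selection over candidate (S, R) step numbers, then the
# posterior of (kA, kB, kC) under the selected S = R = 3 model. Because
# the dataset is synthetic, the posterior can be checked against the
# generating parameters — the kind of ground-truth check an experimental
# dataset never offers.

suppressPackageStartupMessages({
  library(subpoisson)
  library(dplyr)
})
if (!file.exists("results/per_cell_counts.tsv"))
  stop("run analysis/04_quantify_noise.R first")
seed <- 5150

counts <- read.delim("results/per_cell_counts.tsv") |>
  filter(method == "hybrid", n_nuclei == 1)
wide <- counts |>
  tidyr::pivot_wider(id_cols = c(cell_id, length),
                     names_from = compartment, values_from = count)
obs <- summarize_population(wide$nuclear, wide$cytoplasmic,
                            sizes = wide$length)
cat("Data summaries (size-corrected Fano factors):\n")
print(round(obs, 3))

## model selection over step numbers ----------------------------------------
cands <- expand.grid(S = 1:4, R = 1:4)
mc <- model_selection(obs, cands, n_proposals = 5000, seed = seed)
write.table(as.data.frame(mc), "results/model_selection.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nApproximate posterior model probabilities (uniform model prior):\n")
print(as.data.frame(mc[order(-mc$probability), ])[1:6, ], digits = 2,
      row.names = FALSE)
cat("\nSingle-step transcription (S = 1) cannot generate the observed",
    "sub-Poissonian Fano factors and is excluded; several multi-step",
    "variants fit comparably, as expected for moment-level summaries.\n")

## parameter posterior under S = R = 3 --------------------------------------
post <- abc_rejection(obs, S = 3, R = 3, n_proposals = 20000,
                      tolerance_quantile = 0.01, seed = seed + 1)
write_abc_posterior(post, "results/abc_posterior_S3R3.tsv")
sm <- posterior_summary(post)
write.table(as.data.frame(sm), "results/abc_posterior_summary.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

truth <- yaml::read_yaml("results/synth/synth_config.yml")$model
cat("\nPosterior medians [95% credible interval] vs generating values:\n")
for (i in seq_len(nrow(sm))) {
  tv <- switch(sm$parameter[i], k_A = truth$kA, k_B = truth$kB,
               k_C = truth$kC)
  cat(sprintf("  %s: %6.2f [%6.2f, %7.2f]   truth %.1f\n",
              sm$parameter[i], sm$median[i], sm$lower[i], sm$upper[i], tv))
}
cat("\nExport (k_C) is the best-constrained rate: it sets the nuclear",
    "fraction and the nucleus-cytoplasm Fano gap. The synthesis-cycle",
    "rates are only bounded from below, as expected when the data are",
    "summarized by first and second moments alone.\n")
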