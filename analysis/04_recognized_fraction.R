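#!/usr/bin/env Rscript
# Stage 4: sigma-factor recognition inference.
#
# (a) Converts observed GFP+ library fractions into recognized-promoter
#     fractions against the predicted maximum of 25% under full recognition:
#     a 23% readout (heterologous sigma factor expressed) implies 92%
#     recognition; the 6.5% native-host baseline implies 26%.
# (b) Validates the inference by parameter recovery on a synthetic genome:
#     for known recognition probabilities, the estimate from a simulated
#     1,000-insert library falls inside its binomial band in ~99% of runs.

suppressMessages(library(promotrap))
dir.create("results", showWarnings = FALSE)

predicted_max <- 0.25
obs <- data.frame(condition = c("heterologous sigma factor", "native host"),
                  observed_gfp = c(0.23, 0.065))
obs$recognized_fraction <- vapply(obs$observed_gfp, function(o)
  estimate_recognized_fraction(o, predicted_max)$estimate, numeric(1))
write.table(obs, "results/recognized_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Recognized-promoter fractions (predicted maximum 25%):\n")
print(obs, row.names = FALSE)

## parameter recovery -------------------------------------------------------
g <- generate_genome(synthetic_genome_params(n_units = 2000, seed = 800))
L <- 500
pred <- gfp_fraction_exact(g, vector_mode("promoterless"),
                           sigma_model("all"), L)
lm <- fragment_length_model("fixed", L)
conf <- 2 * stats::pnorm(3) - 1
runs <- 40
rec_tab <- do.call(rbind, lapply(c(0.25, 0.5, 0.9), function(p_star) {
  est <- vapply(seq_len(runs), function(run) {
    sig <- sigma_model("bernoulli", p_rec = p_star,
                       seed = 5000 + 100 * p_star * 10 + run)
    e <- estimate_gfp_fraction_mc(g, vector_mode("promoterless"), sig, lm,
                                  1000, seed = 6000 + run, conf_level = conf)
    c(est = estimate_recognized_fraction(e$fraction, pred)$estimate,
      hit = p_star >= e$ci[1] / pred && p_star <= e$ci[2] / pred)
  }, c(est = 0, hit = 0))
  data.frame(p_rec_true = p_star,
             p_rec_mean_estimate = round(mean(est["est", ]), 3),
             coverage = mean(est["hit", ]))
}))
write.table(rec_tab, "results/parameter_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nParameter recovery over %d runs per setting (3 s.e. band):\n",
            runs))
print(rec_tab, row.names = FALSE)
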