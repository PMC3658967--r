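#!/usr/bin/env Rscript
# Stage 2: fit the standard and random-intercept logistic models to the
# study sample from stage 1, compute the three risk calculations, and
# evaluate apparent performance.
#
#   Rscript analysis/02_fit_models.R
#
# Writes results/example_coefficients.tsv and results/example_performance.tsv.

suppressPackageStartupMessages(library(clustpred))

samp <- read_population("results/example_sample.tsv")
X <- as.matrix(samp[, paste0("x", 1:6)])

fits <- fit_models(samp, predictors = paste0("x", 1:6))
std <- fits$standard
re <- fits$random_intercept

cat("Standard model:\n"); print(std)
cat("\nRandom-intercept model:\n"); print(re)
ci <- ranint_variance_ci(re)
cat(sprintf("sigma2_u0 Wald 95%% CI (log scale): %.3f - %.3f\n",
            ci$lower, ci$upper))

coefs <- rbind(cbind(model = "standard", coef_table(std)),
               cbind(model = "random_intercept", coef_table(re)))
utils::write.table(coefs, "results/example_coefficients.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)

risks <- list(
  standard = predict_standard(std, X),
  marginal = predict_marginal(re, X),
  conditional = predict_conditional(re, X, samp$center_id)
)
perf <- do.call(rbind, lapply(risks, evaluate_performance,
                              y = samp$y, cluster = samp$center_id))
cat("\nApparent performance of the three risk calculations:\n")
print(as.data.frame(perf), digits = 3)
utils::write.table(perf, "results/example_performance.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
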