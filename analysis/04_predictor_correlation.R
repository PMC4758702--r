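#!/usr/bin/env Rscript
# Step 4 — does the resting-state predictor forecast feedback accuracy?
#
# Joins the predictor values (step 2) with the session accuracies
# (step 3), fits the linear prediction model, reports the Pearson
# correlation before and after 10% Mahalanobis outlier rejection, and
# demonstrates cross-cohort transfer of the fitted model to a fresh
# simulated cohort.

suppressPackageStartupMessages(library(smrbci))

pred <- read.csv("results/predictors.csv")
acc <- read.csv("results/session_accuracies.csv")
tab <- merge(pred, acc, by = "user")

model <- fit_prediction_model(tab$predictor_db, tab$feedback_accuracy)
cat(sprintf("within-cohort: r = %.3f (p = %.2g), accuracy ~ %.2f + %.2f * predictor\n",
            model$pearson_r, model$p_value, model$intercept, model$slope))

mask <- mahalanobis_outliers(cbind(tab$predictor_db, tab$feedback_accuracy),
                             0.10)
model_in <- fit_prediction_model(tab$predictor_db[!mask],
                                 tab$feedback_accuracy[!mask])
cat(sprintf("after removing %d outlier(s): r = %.3f\n",
            sum(mask), model_in$pearson_r))

# transfer to a fresh cohort (new seed, same generative population)
SEED2 <- 4052L
profiles2 <- cohort_profiles(8, seed = SEED2)
out2 <- run_cohort(profiles2, session_config(), seed = SEED2)
est <- transfer_predict(model, out2$table$predictor)
r_transfer <- cor(est, out2$table$accuracy)
cat(sprintf("cross-cohort transfer: r = %.3f over %d new users\n",
            r_transfer, nrow(out2$table)))

write.csv(cbind(tab, outlier = mask), "results/predictor_correlation.csv",
          row.names = FALSE)
write.csv(data.frame(quantity = c("r_within", "p_within", "slope",
                                  "intercept", "r_no_outliers", "r_transfer"),
                     value = c(model$pearson_r, model$p_value, model$slope,
                               model$intercept, model_in$pearson_r,
                               r_transfer)),
          "results/prediction_model.csv", row.names = FALSE)
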