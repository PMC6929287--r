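#!/usr/bin/env Rscript
# Canonical discriminant function analysis: predict the assigned
# service-use pattern from sex, age at index and the four imputed intake
# scales; sequential Wilks' lambda tests, standardized and structure
# coefficients, centroids, and classification with proportional priors
# (resubstitution and leave-one-out).

library(careclass)

tabs <- read_cohort("results/cohort")
res <- apply_filters(tabs$children, tabs$visits,
                     as.Date(c("2004-01-01", "2006-12-31")))
assignments <- read.csv("results/assignments.csv",
                        stringsAsFactors = FALSE)
covs <- read.csv("results/covariates_imputed.csv",
                 stringsAsFactors = FALSE)

kid <- match(assignments$child_id, tabs$children$child_id)
cid <- match(assignments$child_id, covs$child_id)
age <- as.numeric(res$index_dates[as.character(assignments$child_id)] -
                    as.Date(tabs$children$dob[kid])) / 365.25
pred <- cbind(sex = as.integer(tabs$children$sex[kid] == "M"), age = age,
              as.matrix(covs[cid, c("ext_t", "int_t", "imp_t", "burden_t")]))

model <- dfa_fit(pred, assignments$pattern)
ws <- wilks_sequence(model)
write.csv(ws, "results/dfa_wilks.csv", row.names = FALSE)
cat("sequential Wilks tests:\n")
print(round(ws, 4))
cat(sprintf("first two functions account for %.1f%% of explained variance\n",
            sum(ws$pct_variance[1:2])))

coefs <- data.frame(predictor = rownames(model$standardized_coefficients),
                    standardized = model$standardized_coefficients,
                    structure = model$structure_coefficients)
write.csv(coefs, "results/dfa_coefficients.csv", row.names = FALSE)
write.csv(data.frame(pattern = rownames(model$centroids), model$centroids),
          "results/dfa_centroids.csv", row.names = FALSE)

rep <- dfa_report(model, pred, assignments$pattern, loo = TRUE)
write.csv(as.data.frame(rep$table), "results/dfa_classification.csv",
          row.names = FALSE)
cat(sprintf("correctly classified: %.1f%% (%.1f%% in leave-one-out)\n",
            rep$accuracy, rep$loo_accuracy))
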