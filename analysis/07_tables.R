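#!/usr/bin/env Rscript
# Descriptive pattern tables and univariate tests: the service-use /
# demographic table by pattern, sex chi-square with adjusted residuals,
# age ANOVA with Bonferroni letters, clinical cut-offs and comorbidity.

library(careclass)

tabs <- read_cohort("results/cohort")
res <- apply_filters(tabs$children, tabs$visits,
                     as.Date(c("2004-01-01", "2006-12-31")))
assignments <- read.csv("results/assignments.csv", stringsAsFactors = FALSE)
covs <- read.csv("results/covariates_imputed.csv", stringsAsFactors = FALSE)
summaries <- summarize_cohort(res$visits, res$retained_ids)

kid <- match(assignments$child_id, tabs$children$child_id)
age <- as.numeric(res$index_dates[as.character(assignments$child_id)] -
                    as.Date(tabs$children$dob[kid])) / 365.25
sex <- tabs$children$sex[kid]

tab1 <- pattern_summary(assignments$pattern, sex, age, summaries)
write.csv(tab1, "results/table1_patterns.csv", row.names = FALSE)
cat("pattern table:\n")
print(cbind(tab1[1], round(tab1[-1], 1)))

ct <- contingency_test(factor(assignments$pattern), factor(sex))
cat(sprintf("\nsex by pattern: chi2(%d) = %.3f, p = %.3f\n",
            ct$df, ct$chi2, ct$p_value))
cat("adjusted residuals (male column):\n")
print(round(ct$adjusted_residuals[, "M"], 2))

av <- oneway_anova_bonferroni(age, assignments$pattern)
cat(sprintf("\nage by pattern: F(%d, %d) = %.1f, p = %.3g\n",
            av$df1, av$df2, av$F, av$p_value))
cat("Bonferroni letters:\n")
print(av$letters)

cid <- match(assignments$child_id, covs$child_id)
cuts <- clinical_cutoffs(covs[cid, ])
tab3 <- aggregate(cbind(ext_ge, int_ge, imp_ge, burden_ge) ~ pattern,
                  data = cbind(cuts, pattern = assignments$pattern),
                  FUN = function(x) round(100 * mean(x), 1))
write.csv(tab3, "results/table3_cutoffs.csv", row.names = FALSE)
cat("\n% at or above clinical cut-off (T >= 65) by pattern:\n")
print(tab3)
cat("\ncomorbidity categories (%):\n")
print(round(100 * prop.table(table(assignments$pattern, cuts$comorbidity),
                             1), 1))
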