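#!/usr/bin/env Rscript
# Stage 3: cohort statistics on the synthetic lesion table.
#
# Reproduces the shape of the clinical analysis: inter-reader ICCs,
# benign-vs-malignant group comparison with ROC/Youden diagnostics per
# histogram metric, prognostic-label comparisons among cancers,
# molecular-subtype Kruskal-Wallis with Bonferroni pairwise follow-up,
# and the Spearman matrix of metrics against labels.

library(frocdwi)

cohort <- read_cohort("results/cohort.csv")

icc <- icc_report(cohort)
cat("Inter-reader reproducibility, ICC(2,1):\n")
print(icc, digits = 3, row.names = FALSE)
write.csv(icc, "results/icc_report.csv", row.names = FALSE)

bm <- benign_malignant_report(cohort)
write.csv(bm, "results/benign_malignant_report.csv", row.names = FALSE)
cat(sprintf("\nBenign vs malignant: %d/%d metrics with p < 0.05\n",
            sum(bm$p < 0.05), nrow(bm)))
top <- bm[order(-bm$auc), ][1:5, c("metric", "auc", "sensitivity",
                                   "specificity", "cutoff", "p")]
cat("Top discriminators by AUC:\n")
print(top, digits = 3, row.names = FALSE)

labels <- c("ER", "PR", "HER2", "Ki67", "ALN")
lab_tables <- do.call(rbind, lapply(labels, label_report, tab = cohort))
write.csv(lab_tables, "results/label_reports.csv", row.names = FALSE)
sig <- lab_tables[lab_tables$p < 0.05, c("label", "metric", "p")]
cat(sprintf("\nPrognostic labels: %d significant label-metric pairs\n",
            nrow(sig)))
print(sig, digits = 3, row.names = FALSE)

st <- subtype_report(cohort)
write.csv(st$omnibus, "results/subtype_omnibus.csv", row.names = FALSE)
if (!is.null(st$pairwise))
  write.csv(st$pairwise, "results/subtype_pairwise.csv",
            row.names = FALSE)
cat(sprintf("\nSubtypes: %d metrics with Kruskal-Wallis p < 0.05\n",
            sum(st$omnibus$p < 0.05)))

sm <- spearman_label_matrix(cohort)
write.csv(round(sm$rho, 4), "results/spearman_rho.csv")
write.csv(round(sm$p, 4), "results/spearman_p.csv")
cat("\nStrongest metric-label correlations:\n")
idx <- order(abs(sm$rho), decreasing = TRUE)[1:5]
pos <- arrayInd(idx, dim(sm$rho))
for (k in seq_len(5))
  cat(sprintf("  %s ~ %s: rho = %+.3f (p = %.3f)\n",
              rownames(sm$rho)[pos[k, 1]], colnames(sm$rho)[pos[k, 2]],
              sm$rho[idx[k]], sm$p[idx[k]]))
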