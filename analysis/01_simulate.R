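#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Writes (a) a multi-b DWI phantom of a malignant-like lesion with known
# FROC ground truth at the malignant-lesion SNR, and (b) a synthetic
# benign/malignant lesion cohort with the published group structure
# (n = 50/109, prognostic-label prevalences, label-conditional shifts,
# two-reader duplicates). Everything downstream reads from results/.

library(frocdwi)

dir.create("results/phantom", showWarnings = FALSE, recursive = TRUE)

protocol <- default_breast_protocol()
cat("Acquisition protocol:\n")
print(protocol)

spec <- phantom_spec(seed = 20260920 %% 100000)
phantom <- make_phantom(spec, protocol)
write_dwi(phantom$dwi, protocol, "results/phantom/dwi.nii.gz")
RNifti::writeNifti(array(as.numeric(phantom$roi$mask), spec$grid),
                   "results/phantom/true_lesion.nii.gz")
for (nm in names(phantom$truth))
  RNifti::writeNifti(phantom$truth[[nm]],
                     sprintf("results/phantom/truth_%s.nii.gz", nm))

i2000 <- which.max(protocol$b_values)
snr <- mean(phantom$dwi[, , , i2000][phantom$roi$mask]) / phantom$sigma
cat(sprintf("Phantom: grid %s, lesion %d voxels, sigma = %.3f\n",
            paste(spec$grid, collapse = "x"), sum(phantom$roi$mask),
            phantom$sigma))
cat(sprintf("Measured SNR at b = 2000: %.2f (target %.2f)\n",
            snr, spec$snr_b2000))

cohort <- make_cohort(cohort_spec(seed = 101))
write_cohort(cohort, "results/cohort.csv")
cat(sprintf("Cohort: %d lesions (%d benign, %d malignant), %d metrics\n",
            nrow(cohort), sum(cohort$malignancy == "benign"),
            sum(cohort$malignancy == "malignant"),
            length(metric_columns(cohort))))
cat("ER+ prevalence among cancers:",
    round(mean(cohort$ER[cohort$malignancy == "malignant"] == "positive"),
          3), "\n")
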