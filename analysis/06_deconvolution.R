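#!/usr/bin/env Rscript

# Step 6: reference-based cell-type deconvolution of linear-scale
# mixtures built from the cohort's planted fractions, with the
# permutation fit p-value and stage-wise fraction comparisons.

library(monostage)

seed <- 606
samples <- sample_table(read.delim("results/cohort_samples.tsv"))
truth_fr <- read.delim("results/truth_fractions.tsv")
fr <- as.matrix(truth_fr[, -1])
rownames(fr) <- truth_fr$sample_id

set.seed(seed)
ref <- make_reference_profiles(n_genes = 200,
                               n_cell_types = ncol(fr))
colnames(ref) <- colnames(fr)
mix <- simulate_mixtures(ref, fr, noise_sd = 0.1 * mean(ref %*% t(fr)))

ft <- estimate_fractions(mix, ref, n_perm = 100, seed = seed)
write.table(ft, "results/cell_fractions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

est <- as.matrix(ft[, colnames(ref)])
rmse <- sqrt(colMeans((est - fr[ft$sample_id, ])^2))
cat(sprintf("fraction recovery RMSE per cell type: %s\n",
            paste(sprintf("%s=%.3f", names(rmse), rmse), collapse = " ")))
cat(sprintf("successful deconvolutions (permutation p < 0.05): %d of %d\n",
            sum(ft$perm_p < 0.05), nrow(ft)))

cmp <- compare_fractions(ft, samples)
write.table(cmp$comparisons, "results/fraction_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- cmp$comparisons[cmp$comparisons$p < 0.05, ]
cat(sprintf("stage contrasts significant at 0.05: %d of %d (planted fractions are stage-independent, so this reflects the nominal rate)\n",
            nrow(sig), nrow(cmp$comparisons)))
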