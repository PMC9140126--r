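#!/usr/bin/env Rscript

# Step 1: generate the synthetic multi-batch staged cohort the rest of
# the workflow analyzes. Conditions: 6 ordered stages (NAU baseline +
# Ta..T4) x 30 samples, 2000 genes with 100 monotone-up and 50
# monotone-down planted genes (0.5 log2 per stage), unit noise, and 12
# batches crossed with stage carrying additive shifts (SD 0.5 log2).

library(monostage)

seed <- 20260926 %% 10000
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_cohort(cfg)

write_expression_matrix(sim$matrix, "results/cohort_expression.tsv")
write.table(sim$samples, "results/cohort_samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(sim$truth$monotone_up_genes, "results/truth_up_genes.txt")
writeLines(sim$truth$monotone_down_genes, "results/truth_down_genes.txt")
set.seed(seed)
write_gmt(make_gene_sets(sim$truth, cfg, rownames(sim$matrix)),
          "results/gene_sets.gmt")
write.table(data.frame(sample_id = rownames(sim$truth$true_fractions),
                       sim$truth$true_fractions, check.names = FALSE),
            "results/truth_fractions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("cohort: %d genes x %d samples; %d batches; planted %d up + %d down\n",
            nrow(sim$matrix), ncol(sim$matrix), cfg$n_batches,
            cfg$n_monotone_up, cfg$n_monotone_down))
cat(sprintf("stage counts: %s\n",
            paste(names(table(sim$samples$stage)),
                  table(sim$samples$stage), collapse = ", ")))
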