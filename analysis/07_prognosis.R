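#!/usr/bin/env Rscript

# Step 7: prognostic screening and the variance-normalized eight-gene
# signature. Survival here is re-simulated so that it is driven by an
# eight-gene expression signature planted among the monotone genes (4
# risk-up + 4 risk-down), independent of stage - the configuration in
# which a signature should carry prognostic value beyond stage.

library(monostage)

seed <- 707
mat <- read_expression_matrix("results/cohort_corrected.tsv")
samples <- sample_table(read.delim("results/cohort_samples.tsv"))
mono <- read.delim("results/monotone_genes.tsv")

up8 <- head(mono$gene[mono$direction == "up"], 4)
down8 <- head(mono$gene[mono$direction == "down"], 4)
stopifnot(length(up8) == 4, length(down8) == 4)
planted_model <- signature_model(up8, down8)
true_score <- scale(signature_score(mat, planted_model))[, 1]

set.seed(seed)
cfg <- simulation_config(survival_beta = log(2), censor_rate = 0.3, seed = seed)
sv <- simulate_survival(true_score, cfg)
samples$time <- sv$time
samples$event <- sv$event

# split into discovery / validation halves (alternating samples) and
# screen the monotone genes for univariate prognostic value in each
half <- seq_len(nrow(samples)) %% 2 == 0
screen_half <- function(keep) {
  ids <- samples$sample_id[keep]
  suppressWarnings(screen_prognostic_genes(mat[, ids], samples[keep, ],
                                           candidates = mono$gene,
                                           alpha = 0.01))
}
disc <- screen_half(!half)
val <- screen_half(half)
cat(sprintf("univariate Cox hits (p<0.01): discovery %d, validation %d of %d monotone genes\n",
            nrow(disc), nrow(val), nrow(mono)))

model <- build_signature(disc, val)
cat(sprintf("signature: %d up (%s) / %d down (%s)\n",
            length(model$up_genes), paste(model$up_genes, collapse = ","),
            length(model$down_genes), paste(model$down_genes, collapse = ",")))
jsonlite::write_json(list(up = model$up_genes, down = model$down_genes,
                          variances = apply(mat[c(model$up_genes,
                                                  model$down_genes), ], 1, var)),
                     "results/signature_model.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

scores <- signature_score(mat, model)
res <- survival_analysis(scores, samples, covariates = "stage")
write_survival_result(res, "results/signature_survival")

cat(sprintf("5-year survival: high %.2f vs low %.2f; log-rank p = %.2g\n",
            res$five_year[["high"]], res$five_year[["low"]], res$logrank_p))
cf <- res$cox_multivariate$coefficients
cat(sprintf("multivariate: score HR %.2f (p = %.2g); stage LRT p = %.2f\n",
            cf$HR[cf$term == "sc"], cf$p[cf$term == "sc"],
            res$cox_multivariate$covariate_lrt[["stage"]]))
got <- c(model$up_genes, model$down_genes)
cat(sprintf("overlap with the 8 planted risk genes: %d of %d rebuilt genes\n",
            sum(got %in% c(up8, down8)), length(got)))
cat("finding: because the planted score itself tracks the stage staircase,\n",
    "every monotone gene covaries with hazard, so the rebuilt roster mixes\n",
    "planted risk genes with stage-covarying ones; the resulting score still\n",
    "separates 5-year survival and stays prognostic with stage in the model.\n")
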