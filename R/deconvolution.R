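# Reference-based cell-type fraction estimation: non-negative least
# squares with a permutation goodness-of-fit p-value, and stage-wise
# comparisons of the estimated fractions. A transparent surrogate for
# SVR-based web deconvolution platforms; it fills the same role in the
# pipeline (relative immune fractions per sample plus a per-sample
# quality p-value) without their proprietary reference machinery.

#' Estimate cell-type fractions by non-negative least squares
#'
#' Operates on linear-scale data (log2 input can be converted with
#' `2^mat` by the caller; the pipeline drivers do this and log it).
#' Per sample, NNLS is solved on the genes shared between mixture and
#' reference and the coefficients are renormalized to sum to one. The
#' permutation p-value is the fraction of `n_perm` gene-shuffled
#' versions of the sample whose NNLS fit correlation reaches the
#' observed one.
#'
#' @param mixtures Gene x sample matrix (linear scale).
#' @param reference Gene x cell-type profile matrix (linear scale);
#'   reference genes must all be present in the mixtures.
#' @param n_perm Number of gene permutations (default 200; < 100 warns).
#' @param seed Integer seed for the permutations.
#' @return Data frame of class `fraction_table`: one row per sample
#'   with one column per cell type, plus `rmse`, `fit_cor` and
#'   `perm_p` (in (0, 1]).
#' @export
estimate_fractions <- function(mixtures, reference, n_perm = 200, seed = 1L) {
  stopifnot(is.matrix(mixtures), is.matrix(reference))
  if (ncol(reference) < 2) stop("need >= 2 cell types")
  if (!all(rownames(reference) %in% rownames(mixtures)))
    stop("reference genes missing from the mixture matrix")
  dup <- duplicated(t(reference))
  if (any(dup))
    stop("reference has identical cell-type columns (non-identifiable): ",
         paste(colnames(reference)[dup], collapse = ", "))
  if (n_perm < 100) warning("n_perm < 100 gives a coarse permutation p-value")
  genes <- rownames(reference)
  M <- mixtures[genes, , drop = FALSE]
  set.seed(seed)
  perms <- replicate(n_perm, sample(length(genes)), simplify = FALSE)
  solve_one <- function(y) {
    fit <- pracma::lsqnonneg(reference, y)
    x <- fit$x
    yhat <- as.vector(reference %*% x)
    list(x = x, rmse = sqrt(mean((y - yhat)^2)),
         r = suppressWarnings(stats::cor(y, yhat)))
  }
  rows <- lapply(seq_len(ncol(M)), function(j) {
    y <- M[, j]
    obs <- solve_one(y)
    r_obs <- if (is.na(obs$r)) -Inf else obs$r
    hits <- vapply(perms, function(pm) {
      r <- solve_one(y[pm])$r
      !is.na(r) && r >= r_obs
    }, logical(1))
    p <- (1 + sum(hits)) / (1 + n_perm)
    x <- obs$x
    frac <- if (sum(x) > 0) x / sum(x) else rep(1 / length(x), length(x))
    c(frac, rmse = obs$rmse, fit_cor = obs$r, perm_p = p)
  })
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- c(colnames(reference), "rmse", "fit_cor", "perm_p")
  out <- cbind(sample_id = colnames(M), out)
  rownames(out) <- NULL
  class(out) <- c("fraction_table", "data.frame")
  out
}

#' Stage-wise comparison of estimated cell-type fractions
#'
#' Drops samples whose deconvolution permutation p-value is at or above
#' `p_threshold`, then compares each cell type's fraction with
#' Mann-Whitney tests between (i) NAU and all tumor samples and (ii)
#' each stage versus the rest, and flags cell types whose fractions
#' pass the monotone screen across stages (the same machinery as the
#' gene-level screen, applied to fraction rows).
#'
#' @param fractions A `fraction_table` from [estimate_fractions()].
#' @param samples A [sample_table()].
#' @param p_threshold Permutation-p cutoff for a successful
#'   deconvolution (default 0.05).
#' @param alpha Significance level for the monotone screen.
#' @return List with `comparisons` (data frame cell_type/contrast/p/
#'   delta), `monotone` (data frame from the monotone screen),
#'   `n_used`, `dropped` (sample IDs removed by the filter).
#' @export
compare_fractions <- function(fractions, samples, p_threshold = 0.05,
                              alpha = 0.05) {
  stopifnot(inherits(fractions, "fraction_table"))
  cell_types <- setdiff(colnames(fractions),
                        c("sample_id", "rmse", "fit_cor", "perm_p"))
  ok <- fractions$perm_p < p_threshold
  dropped <- fractions$sample_id[!ok]
  fr <- fractions[ok, , drop = FALSE]
  sm <- samples[match(fr$sample_id, samples$sample_id), , drop = FALSE]
  contrasts <- c(list(NAU_vs_tumor = list(a = sm$stage == "NAU",
                                          b = sm$stage != "NAU")),
                 stats::setNames(lapply(STAGE_LEVELS, function(st)
                   list(a = sm$stage == st, b = sm$stage != st)),
                   paste0(STAGE_LEVELS, "_vs_rest")))
  rows <- list()
  for (ct in cell_types) {
    v <- fr[[ct]]
    for (cn in names(contrasts)) {
      a <- v[contrasts[[cn]]$a]; b <- v[contrasts[[cn]]$b]
      if (length(a) < 2 || length(b) < 2) {
        warning("contrast ", cn, " has < 2 samples in a group; skipped")
        next
      }
      mw <- mann_whitney(a, b)
      rows[[paste(ct, cn)]] <- data.frame(
        cell_type = ct, contrast = cn, p = mw$p,
        delta = mean(a) - mean(b), stringsAsFactors = FALSE)
    }
  }
  comp <- do.call(rbind, rows)
  rownames(comp) <- NULL
  frac_mat <- t(as.matrix(fr[, cell_types, drop = FALSE]))
  colnames(frac_mat) <- fr$sample_id
  monotone <- tryCatch(monotone_pathways(frac_mat, sm, alpha = alpha),
                       error = function(e) NULL)
  list(comparisons = comp, monotone = monotone,
       n_used = nrow(fr), dropped = dropped)
}
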