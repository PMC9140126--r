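# Empirical-Bayes location/scale batch correction.
#
# The model per gene g, batch i, sample j is
#   Y_gij = alpha_g + X_j beta_g + gamma_ig + delta_ig * eps_gij
# with parametric priors gamma_ig ~ N(gamma_i, tau_i^2) and
# delta_ig^2 ~ InverseGamma(a_i, b_i), hyperparameters estimated by
# method of moments and posterior estimates obtained by iterated
# conditional updates.

.inv_gamma_moments <- function(delta_hat) {
  m <- mean(delta_hat)
  s2 <- stats::var(delta_hat)
  list(a = (2 * s2 + m^2) / s2, b = (m * s2 + m^3) / s2)
}

# Iterated conditional posterior updates for one batch.
.eb_iterate <- function(Z, gamma_hat, delta_hat, gamma_bar, tau2, a, b,
                        tol = 1e-4, max_iter = 100) {
  n <- ncol(Z)
  g_old <- gamma_hat
  d_old <- delta_hat
  for (it in seq_len(max_iter)) {
    g_new <- (n * tau2 * gamma_hat + d_old * gamma_bar) / (n * tau2 + d_old)
    sum2 <- rowSums((Z - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / abs(d_old), na.rm = TRUE)
    g_old <- g_new
    d_old <- d_new
    if (is.finite(change) && change < tol) break
  }
  list(gamma_star = g_old, delta2_star = d_old, iterations = it)
}

#' Empirical-Bayes batch correction of a log-scale expression matrix
#'
#' Standardizes each gene using covariate-adjusted means and pooled
#' variance, estimates per-batch additive (`gamma`) and multiplicative
#' (`delta^2`) effects, shrinks them toward parametric priors (normal
#' for `gamma`, inverse-gamma for `delta^2`; hyperpriors by method of
#' moments; iterated conditional updates to tolerance `tol`, at most
#' `max_iter` iterations), and back-transforms. Biological condition
#' labels passed as `covariates` are protected: their effect enters the
#' standardization mean and is restored unchanged.
#'
#' A single-batch input is returned unchanged (there is nothing to
#' correct and the hyperprior variances degenerate); this is logged via
#' `message()`.
#'
#' @param mat Gene x sample log2 expression matrix.
#' @param batches Per-sample batch labels (length `ncol(mat)`).
#' @param covariates Optional per-sample condition labels to protect
#'   (e.g. disease stage).
#' @param tol,max_iter EB iteration control.
#' @return List with `matrix` (corrected, same dimensions and dimnames)
#'   and `model` (a `batch_model`: raw and shrunken per-batch, per-gene
#'   estimates, hyperparameters, grand mean and pooled variance).
#' @export
combat <- function(mat, batches, covariates = NULL,
                   tol = 1e-4, max_iter = 100) {
  stopifnot(is.matrix(mat), length(batches) == ncol(mat))
  batch <- factor(batches)
  tab <- table(batch)
  if (any(tab < 2))
    stop("batch with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (nlevels(batch) == 1) {
    message("single batch; returning input unchanged")
    return(list(matrix = mat, model = NULL))
  }
  n_array <- ncol(mat)
  batch_design <- stats::model.matrix(~ -1 + batch)
  design <- batch_design
  if (!is.null(covariates)) {
    cov <- factor(covariates)
    if (nlevels(cov) > 1) {
      # perfect confounding check: a batch whose samples all share one
      # covariate level that occurs nowhere else
      design_cov <- stats::model.matrix(~cov)[, -1, drop = FALSE]
      design <- cbind(batch_design, design_cov)
      if (qr(design)$rank < ncol(design)) {
        ct <- table(batch, cov)
        for (b in rownames(ct)) for (l in colnames(ct)) {
          if (ct[b, l] == sum(ct[b, ]) && ct[b, l] == sum(ct[, l]))
            stop("batch '", b, "' is perfectly confounded with covariate level '", l, "'")
        }
        stop("design is rank-deficient: batches confounded with covariates")
      }
    }
  }
  n_batch <- nlevels(batch)
  n_batches <- as.vector(tab)

  B_hat <- solve(crossprod(design), t(design) %*% t(mat))
  grand_mean <- crossprod(n_batches / n_array, B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- ((mat - t(design %*% B_hat))^2) %*% rep(1 / n_array, n_array)
  if (any(var_pooled <= 0)) stop("gene with zero pooled variance")

  stand_mean <- matrix(grand_mean, nrow(mat), n_array)
  if (ncol(design) > n_batch) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  Z <- (mat - stand_mean) / sqrt(var_pooled)[, rep(1, n_array)]

  gamma_hat <- matrix(NA_real_, nrow(mat), n_batch,
                      dimnames = list(rownames(mat), levels(batch)))
  delta2_hat <- gamma_hat
  gamma_star <- gamma_hat
  delta2_star <- gamma_hat
  hyper <- list()
  corrected <- Z
  for (i in seq_len(n_batch)) {
    idx <- which(batch == levels(batch)[i])
    Zi <- Z[, idx, drop = FALSE]
    g_hat <- rowMeans(Zi)
    d_hat <- apply(Zi, 1, stats::var)
    gamma_bar <- mean(g_hat)
    tau2 <- stats::var(g_hat)
    ig <- .inv_gamma_moments(d_hat)
    if (!is.finite(tau2) || tau2 <= 0 || !is.finite(ig$a) || !is.finite(ig$b)) {
      # degenerate hyperprior (e.g. identical genes): no shrinkage
      sol <- list(gamma_star = g_hat, delta2_star = d_hat, iterations = 0L)
    } else {
      sol <- .eb_iterate(Zi, g_hat, d_hat, gamma_bar, tau2, ig$a, ig$b,
                         tol = tol, max_iter = max_iter)
    }
    gamma_hat[, i] <- g_hat
    delta2_hat[, i] <- d_hat
    gamma_star[, i] <- sol$gamma_star
    delta2_star[, i] <- sol$delta2_star
    hyper[[levels(batch)[i]]] <- list(gamma_bar = gamma_bar, tau2 = tau2,
                                      a = ig$a, b = ig$b,
                                      iterations = sol$iterations)
    corrected[, idx] <- (Zi - sol$gamma_star) / sqrt(sol$delta2_star)
  }
  out <- corrected * sqrt(var_pooled)[, rep(1, n_array)] + stand_mean
  dimnames(out) <- dimnames(mat)
  model <- structure(list(gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                          gamma_star = gamma_star, delta2_star = delta2_star,
                          hyperparameters = hyper,
                          grand_mean = as.vector(grand_mean),
                          var_pooled = as.vector(var_pooled),
                          batch = batch, design = design),
                     class = "batch_model")
  list(matrix = out, model = model)
}

#' Batch-effect QC diagnostics
#'
#' Computes (i) per-sample relative log expression (RLE: deviation of
#' each sample from the gene-wise median), summarized as median and
#' IQR; (ii) the coefficient of determination of one-way fits of each
#' of the top two principal components on batch and on condition; and
#' (iii) an optional housekeeping contrast: the between-batch
#' dispersion (variance of per-batch means, averaged over genes) of a
#' user-flagged stable-gene panel, against the same dispersion for all
#' other genes.
#'
#' @param mat Gene x sample log2 expression matrix.
#' @param batches Per-sample batch labels.
#' @param condition Per-sample condition labels (e.g. stage).
#' @param housekeeping Optional character vector of stable-gene IDs.
#' @return A `batch_qc` list: `rle` (data frame sample/median/iqr),
#'   `pc_r2` (data frame pc/var_explained/r2_batch/r2_condition), and
#'   `housekeeping` (list with `panel_dispersion`, `other_dispersion`).
#' @export
batch_qc <- function(mat, batches, condition, housekeeping = NULL) {
  batch <- factor(batches)
  if (nlevels(batch) < 2) stop("need >= 2 batches")
  cond <- factor(condition)
  med <- apply(mat, 1, stats::median)
  rle_mat <- mat - med
  rle <- data.frame(sample = colnames(mat),
                    median = apply(rle_mat, 2, stats::median),
                    iqr = apply(rle_mat, 2, stats::IQR),
                    row.names = NULL)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  r2 <- function(y, f) {
    if (nlevels(droplevels(f)) < 2) return(0)
    summary(stats::lm(y ~ f))$r.squared
  }
  pc_r2 <- data.frame(pc = c("PC1", "PC2"),
                      var_explained = ve[1:2],
                      r2_batch = c(r2(pc$x[, 1], batch), r2(pc$x[, 2], batch)),
                      r2_condition = c(r2(pc$x[, 1], cond), r2(pc$x[, 2], cond)))
  hk <- NULL
  if (!is.null(housekeeping)) {
    panel <- intersect(housekeeping, rownames(mat))
    disp <- function(rows) {
      if (length(rows) == 0) return(NA_real_)
      bm <- t(apply(mat[rows, , drop = FALSE], 1, function(v)
        tapply(v, batch, mean)))
      mean(apply(bm, 1, stats::var))
    }
    hk <- list(panel_dispersion = disp(panel),
               other_dispersion = disp(setdiff(rownames(mat), panel)),
               panel_size = length(panel))
  }
  structure(list(rle = rle, pc_r2 = pc_r2, housekeeping = hk),
            class = "batch_qc")
}

#' Serialize a QC report as JSON plus TSV tables
#'
#' @param qc A `batch_qc` object.
#' @param path_prefix Prefix for `<prefix>_rle.tsv`, `<prefix>_pc.tsv`
#'   and `<prefix>.json`.
#' @export
write_batch_qc <- function(qc, path_prefix) {
  stopifnot(inherits(qc, "batch_qc"))
  utils::write.table(qc$rle, paste0(path_prefix, "_rle.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qc$pc_r2, paste0(path_prefix, "_pc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(pc_r2 = qc$pc_r2, housekeeping = qc$housekeeping,
                            rle_median_range = range(qc$rle$median)),
                       paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path_prefix)
}
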