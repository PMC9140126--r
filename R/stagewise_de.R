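# Stage-vs-baseline differential testing and the monotonicity screen.
#
# Fold change throughout this module is the difference of log-scale
# group means, mean(stage) - mean(NAU); it is never a ratio.

# Normal-approximation two-sided p with tie correction and continuity
# correction. Vectorized over U and tiesum. sigma2 == 0 (all values
# tied) yields p = 1.
.mw_p_approx <- function(U, m, n, tiesum) {
  N <- m + n
  sigma2 <- (m * n / 12) * ((N + 1) - tiesum / (N * (N - 1)))
  d <- U - m * n / 2
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  p[sigma2 <= 0] <- 1
  p
}

# Exact two-sided p by enumeration of all C(N, k) assignments of the
# smaller group, on the pooled ranks (handles ties naturally).
.mw_p_exact <- function(r, m, n, U_obs) {
  N <- m + n
  if (m <= n) {
    idx <- utils::combn(N, m)
    U_perm <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
  } else {
    idx <- utils::combn(N, n)
    U_y <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    U_perm <- m * n - U_y
  }
  mid <- m * n / 2
  mean(abs(U_perm - mid) >= abs(U_obs - mid) - 1e-12)
}

#' Mann-Whitney U test
#'
#' Returns the U statistic for the first group and a two-sided p-value.
#' The p-value is exact (full enumeration of group labelings, which
#' handles ties) when `min(|x|,|y|) <= exact_max_n`, at most 25% of the
#' pooled values are involved in ties, and the number of labelings
#' `choose(|x|+|y|, min)` does not exceed `comb_cap`; otherwise the
#' normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max_n Largest smaller-group size for which enumeration
#'   is attempted (default 8).
#' @param tie_frac_max Maximum fraction of pooled values involved in
#'   ties for the exact branch (default 0.25).
#' @param comb_cap Enumeration budget; above it the approximation is
#'   used regardless of group size.
#' @return List with elements `U` and `p` (`p` in (0, 1]).
#' @export
mann_whitney <- function(x, y, exact_max_n = 8, tie_frac_max = 0.25,
                         comb_cap = 2e5) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample vector")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  tc <- rle(sort(pooled))$lengths
  frac_tied <- sum(tc[tc > 1]) / N
  use_exact <- min(m, n) <= exact_max_n &&
    frac_tied <= tie_frac_max &&
    choose(N, min(m, n)) <= comb_cap
  p <- if (use_exact) .mw_p_exact(r, m, n, U)
       else .mw_p_approx(U, m, n, sum(tc^3 - tc))
  list(U = U, p = p)
}

#' Per-gene, per-stage differential table against the NAU baseline
#'
#' Each tumor stage is compared to NAU gene by gene with the
#' Mann-Whitney test (the stage samples are the first group, so `U` is
#' the stage group's statistic) and the fold change
#' `fc = mean(stage) - mean(NAU)` in log2 units. Stages with fewer than
#' two samples are skipped with a warning.
#'
#' @param mat Gene x sample log2 expression matrix.
#' @param samples A [sample_table()] covering the matrix columns.
#' @param stages Tumor stages to test (default all five).
#' @return Data frame with columns `gene`, `stage`, `U`, `p`, `fc`.
#' @export
stage_differential_table <- function(mat, samples, stages = TUMOR_STAGES) {
  stopifnot(all(samples$sample_id %in% colnames(mat)))
  nau_ids <- samples$sample_id[samples$stage == "NAU"]
  if (length(nau_ids) == 0) stop("no NAU samples")
  if (length(nau_ids) < 2) stop("need >= 2 NAU samples")
  out <- list()
  for (st in stages) {
    st_ids <- samples$sample_id[samples$stage == st]
    if (length(st_ids) < 2) {
      warning("stage ", st, " has < 2 samples; skipped")
      next
    }
    sub <- mat[, c(st_ids, nau_ids), drop = FALSE]
    m <- length(st_ids); n <- length(nau_ids)
    fc <- rowMeans(sub[, seq_len(m), drop = FALSE]) -
      rowMeans(sub[, m + seq_len(n), drop = FALSE])
    if (min(m, n) <= 8) {
      res <- apply(sub, 1, function(v) {
        mw <- mann_whitney(v[seq_len(m)], v[m + seq_len(n)])
        c(mw$U, mw$p)
      })
      U <- res[1, ]; p <- res[2, ]
    } else {
      R <- t(apply(sub, 1, rank))
      U <- rowSums(R[, seq_len(m), drop = FALSE]) - m * (m + 1) / 2
      tiesum <- apply(sub, 1, function(v) {
        tc <- rle(sort(v))$lengths
        sum(tc^3 - tc)
      })
      p <- .mw_p_approx(U, m, n, tiesum)
    }
    out[[st]] <- data.frame(gene = rownames(mat), stage = st,
                            U = unname(U), p = unname(p), fc = unname(fc),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop("no stage could be tested")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Wide gene x stage matrices of p and fc from the long table.
.de_wide <- function(table) {
  stages <- intersect(TUMOR_STAGES, unique(table$stage))
  genes <- unique(table$gene)
  P <- matrix(NA_real_, length(genes), length(stages),
              dimnames = list(genes, stages))
  FC <- P
  idx <- cbind(match(table$gene, genes), match(table$stage, stages))
  P[idx] <- table$p
  FC[idx] <- table$fc
  list(P = P, FC = FC, stages = stages)
}

#' Select concordantly differentially expressed genes (CDEGs)
#'
#' A gene is a CDEG iff its Mann-Whitney p-value is below `alpha` in
#' every tested stage-vs-NAU comparison and the sign of its fold change
#' is identical in all of them. Significance is intentionally
#' unadjusted (the screen trades Type-I for Type-II control; the
#' monotonicity filter downstream is the stringent step).
#'
#' @param table Output of [stage_differential_table()].
#' @param alpha Unadjusted significance level (default 0.05).
#' @return Data frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`).
#' @export
select_cdegs <- function(table, alpha = 0.05) {
  w <- .de_wide(table)
  complete <- rowSums(is.na(w$P)) == 0
  sig <- complete & (rowSums(w$P < alpha) == ncol(w$P))
  all_up <- rowSums(w$FC > 0) == ncol(w$FC)
  all_down <- rowSums(w$FC < 0) == ncol(w$FC)
  keep <- sig & (all_up | all_down)
  data.frame(gene = rownames(w$P)[keep],
             direction = ifelse(all_up[keep], "up", "down"),
             stringsAsFactors = FALSE)
}

#' Select monotone genes from the CDEG set
#'
#' A CDEG is monotone up iff its fold-change sequence across
#' `Ta < T1 < T2 < T3 < T4` is strictly increasing with every fc > 0,
#' and monotone down iff strictly decreasing with every fc < 0.
#' Equal adjacent fold changes are excluded under the default strict
#' reading; `strict = FALSE` admits non-strict (>=/<=) sequences.
#'
#' @param table Output of [stage_differential_table()].
#' @param cdegs Output of [select_cdegs()] (or a data frame with a
#'   `gene` column that is a subset of the table's genes).
#' @param strict Require strict monotonicity (default `TRUE`).
#' @return Data frame with columns `gene`, `direction`, and the audit
#'   columns `fc_Ta`, `fc_T1`, `fc_T2`, `fc_T3`, `fc_T4`.
#' @export
select_monotone_genes <- function(table, cdegs, strict = TRUE) {
  w <- .de_wide(table)
  genes <- intersect(cdegs$gene, rownames(w$P))
  FC <- w$FC[genes, , drop = FALSE]
  cmp_up <- if (strict) function(d) all(d > 0) else function(d) all(d >= 0)
  cmp_down <- if (strict) function(d) all(d < 0) else function(d) all(d <= 0)
  is_up <- apply(FC, 1, function(fc) all(fc > 0) && cmp_up(diff(fc)))
  is_down <- apply(FC, 1, function(fc) all(fc < 0) && cmp_down(diff(fc)))
  keep <- is_up | is_down
  out <- data.frame(gene = genes[keep],
                    direction = ifelse(is_up[keep], "up", "down"),
                    stringsAsFactors = FALSE)
  fc_cols <- as.data.frame(FC[keep, , drop = FALSE])
  colnames(fc_cols) <- paste0("fc_", colnames(FC))
  rownames(fc_cols) <- NULL
  cbind(out, fc_cols)
}

#' Correlation of NMI and MI pooled log fold changes
#'
#' Pools samples into non-muscle-invasive (Ta, T1) and muscle-invasive
#' (T2, T3, T4) groups, computes each gene's fold change of the pooled
#' group against NAU, and returns the correlation between the two
#' fold-change vectors (Spearman by default, as for all correlations in
#' the pipeline).
#'
#' @param mat Gene x sample log2 expression matrix.
#' @param samples A [sample_table()].
#' @param method Correlation method passed to [stats::cor.test()].
#' @return List with `r` (correlation), `p` (its p-value), and the two
#'   fold-change vectors `fc_nmi`, `fc_mi`.
#' @export
logfc_concordance <- function(mat, samples, method = "spearman") {
  ids <- function(st) samples$sample_id[samples$stage %in% st]
  nau <- ids("NAU"); nmi <- ids(c("Ta", "T1")); mi <- ids(c("T2", "T3", "T4"))
  if (length(nau) == 0 || length(nmi) == 0 || length(mi) == 0)
    stop("need samples in NAU, NMI and MI groups")
  base <- rowMeans(mat[, nau, drop = FALSE])
  fc_nmi <- rowMeans(mat[, nmi, drop = FALSE]) - base
  fc_mi <- rowMeans(mat[, mi, drop = FALSE]) - base
  ct <- suppressWarnings(stats::cor.test(fc_nmi, fc_mi, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value,
       fc_nmi = fc_nmi, fc_mi = fc_mi)
}
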