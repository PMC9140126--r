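# Single-sample gene-set scoring and the monotone-pathway screen.

# ssGSEA running-sum score for one sample given integer/average ranks.
# ranks: named vector over all genes (higher expression -> higher rank,
# so the walk visits genes in decreasing expression order).
.ssgsea_one <- function(ranks, members, alpha) {
  ord <- order(ranks, decreasing = TRUE)
  in_set <- names(ranks)[ord] %in% members
  w <- abs(ranks[ord])^alpha
  w[!in_set] <- 0
  denom_in <- sum(w)
  n_out <- sum(!in_set)
  cdf_in <- if (denom_in > 0) cumsum(w) / denom_in else cumsum(in_set) * 0
  cdf_out <- if (n_out > 0) cumsum(!in_set) / n_out else rep(0, length(ranks))
  d <- cdf_in - cdf_out
  walk <- c(0, cumsum(d))
  rng <- max(walk) - min(walk)
  if (rng == 0) return(0)
  sum(d) / rng
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each sample, genes are ranked by expression (average ranks on
#' ties) and each set is scored by the running-sum statistic: the sum,
#' over the expression-ordered gene list, of the difference between the
#' rank-weighted in-set cumulative distribution (weights
#' `rank^alpha`) and the uniform out-of-set cumulative distribution,
#' normalized by the range (max - min) of the running walk. Scores
#' depend on a sample's values only through their ranks, so they are
#' invariant under any strictly increasing transform.
#'
#' @param mat Gene x sample expression matrix.
#' @param sets A `gene_set_collection`; members are restricted to the
#'   matrix genes, and sets with fewer than `min_size` remaining
#'   members are dropped with a warning.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param min_size Minimum post-restriction set size (default 5).
#' @return Set x sample score matrix.
#' @export
ssgsea <- function(mat, sets, alpha = 0.25, min_size = 5) {
  stopifnot(inherits(sets, "gene_set_collection"))
  restricted <- lapply(sets$sets, intersect, rownames(mat))
  keep <- lengths(restricted) >= min_size
  if (!any(keep)) stop("no gene set with >= min_size genes in the matrix")
  if (any(!keep))
    warning("dropping ", sum(!keep), " set(s) below min_size: ",
            paste(names(restricted)[!keep], collapse = ", "))
  restricted <- restricted[keep]
  rank_mat <- apply(mat, 2, rank)
  rownames(rank_mat) <- rownames(mat)
  scores <- matrix(NA_real_, length(restricted), ncol(mat),
                   dimnames = list(names(restricted), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    r <- rank_mat[, j]
    for (s in seq_along(restricted))
      scores[s, j] <- .ssgsea_one(r, restricted[[s]], alpha)
  }
  scores
}

#' Monotone-pathway screen
#'
#' Applies the stage-vs-NAU machinery of the gene-level screen to
#' pathway score rows: Mann-Whitney per stage against NAU, fold change
#' as difference of score means, the concordance filter, then the
#' strict monotonicity filter. This is definitionally
#' [select_monotone_genes()] applied to score rows (shared code path).
#'
#' @param scores Set x sample score matrix (e.g. from [ssgsea()]).
#' @param samples A [sample_table()].
#' @param alpha Per-comparison significance level (default 0.05).
#' @param strict Strict monotonicity (default `TRUE`).
#' @return Data frame as from [select_monotone_genes()], with pathway
#'   names in the `gene` column.
#' @export
monotone_pathways <- function(scores, samples, alpha = 0.05, strict = TRUE) {
  tab <- stage_differential_table(scores, samples)
  cdegs <- select_cdegs(tab, alpha = alpha)
  select_monotone_genes(tab, cdegs, strict = strict)
}

#' Signed regulon activity
#'
#' Per sample and regulon: the mean over target genes of
#' `sign * z`, where `z` is the gene's z-score across samples. The
#' activity is linear in the z-score matrix; flipping all signs negates
#' the activity row exactly, and a single-target regulon's activity is
#' that gene's signed z-score.
#'
#' @param mat Gene x sample expression matrix.
#' @param regulons A signed `gene_set_collection` (every member carries
#'   a +1/-1 sign).
#' @param min_size Minimum number of targets present in the matrix;
#'   regulons below it are dropped with a warning.
#' @return Regulon x sample activity matrix with a `"n_targets"`
#'   attribute (per-regulon target counts used).
#' @export
regulon_activity <- function(mat, regulons, min_size = 1) {
  stopifnot(inherits(regulons, "gene_set_collection"))
  signed <- !vapply(regulons$signs, is.null, logical(1))
  if (!all(signed)) stop("all regulons must carry signs")
  z <- t(scale(t(mat)))
  if (anyNA(z)) z[is.na(z)] <- 0  # constant genes carry no signal
  act <- list(); n_targets <- integer()
  for (nm in names(regulons$sets)) {
    s <- regulons$signs[[nm]]
    targets <- intersect(names(s), rownames(mat))
    if (length(targets) < max(1, min_size)) {
      warning("regulon '", nm, "' has ", length(targets),
              " overlapping target(s); dropped")
      next
    }
    act[[nm]] <- colMeans(z[targets, , drop = FALSE] * s[targets])
    n_targets[nm] <- length(targets)
  }
  if (length(act) == 0) stop("no regulon with overlapping targets")
  out <- do.call(rbind, act)
  colnames(out) <- colnames(mat)
  attr(out, "n_targets") <- n_targets
  out
}

#' Stromal infiltration score
#'
#' An ssGSEA score of a user-supplied stromal gene panel, one row per
#' input set (an ESTIMATE-style surrogate: the score ranks samples by
#' the relative rank enrichment of stromal transcripts, not by the
#' ESTIMATE tumor-purity equation).
#'
#' @param mat Gene x sample expression matrix.
#' @param stromal_set A `gene_set_collection` holding the stromal
#'   panel(s).
#' @param ... Passed to [ssgsea()].
#' @return Single-row (per panel) score matrix.
#' @export
stromal_score <- function(mat, stromal_set, ...) {
  ssgsea(mat, stromal_set, ...)
}
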