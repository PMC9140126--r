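# Variance-normalized prognostic signature and survival validation.
#
# The signature score for sample i over four risk-up genes A..D and
# four risk-down genes E..H is
#   S_i = A_i/VarA + B_i/VarB + C_i/VarC + D_i/VarD
#       - E_i/VarE - F_i/VarF - G_i/VarG - H_i/VarH
# where Var* is the gene's variance across the scoring dataset. The
# division is by the variance, exactly as defined (which makes the
# score scale-dependent); an SD-normalized variant is available behind
# a flag.

.truncate_surv <- function(time, event, horizon) {
  over <- time > horizon
  time[over] <- horizon
  event[over] <- 0
  list(time = time, event = event)
}

#' Construct a prognostic signature model
#'
#' @param up_genes Risk-up gene symbols (higher expression, worse
#'   survival); canonical roster size is 4.
#' @param down_genes Risk-down gene symbols; canonical roster size 4.
#' @param variances Optional named per-gene variances frozen from a
#'   training matrix; when `NULL`, [signature_score()] computes sample
#'   variances (n-1 denominator) on the scoring matrix.
#' @return Object of class `signature_model`.
#' @export
signature_model <- function(up_genes, down_genes, variances = NULL) {
  genes <- c(up_genes, down_genes)
  if (anyDuplicated(genes)) stop("signature genes must be distinct")
  if (!is.null(variances)) {
    if (!all(genes %in% names(variances)))
      stop("variances must cover every signature gene")
    if (any(variances[genes] <= 0))
      stop("zero or negative variance for gene: ",
           paste(genes[variances[genes] <= 0], collapse = ", "))
  }
  structure(list(up_genes = up_genes, down_genes = down_genes,
                 variances = variances), class = "signature_model")
}

#' Variance-normalized signature scores
#'
#' Computes `S_i` as the sum of risk-up gene values each divided by its
#' variance, minus the same for risk-down genes. Scoring is linear in
#' each gene's expression: adding a constant `c` to gene `A` shifts
#' every score by exactly `c / VarA`.
#'
#' @param mat Gene x sample log2 expression matrix containing all
#'   signature genes.
#' @param model A [signature_model()]. If it carries no frozen
#'   variances, sample variances (n-1) across `mat` are used.
#' @param use_sd Normalize by the standard deviation instead of the
#'   variance (non-canonical variant; default `FALSE`).
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(mat, model, use_sd = FALSE) {
  stopifnot(inherits(model, "signature_model"))
  genes <- c(model$up_genes, model$down_genes)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop("signature gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  v <- model$variances
  if (is.null(v)) v <- apply(mat[genes, , drop = FALSE], 1, stats::var)
  v <- v[genes]
  zero <- genes[v <= 0 | !is.finite(v)]
  if (length(zero))
    stop("zero variance for signature gene: ", paste(zero, collapse = ", "))
  if (use_sd) v <- sqrt(v)
  sgn <- c(rep(1, length(model$up_genes)), rep(-1, length(model$down_genes)))
  colSums((mat[genes, , drop = FALSE] / v) * sgn)
}

#' Univariate Cox screen of candidate prognostic genes
#'
#' Fits a univariate Cox proportional-hazards model (Efron ties) per
#' candidate gene on survival administratively truncated at `horizon`
#' months (the 5-year endpoint by default) and retains genes with Wald
#' `p < alpha`.
#'
#' @param mat Gene x sample expression matrix.
#' @param samples A [sample_table()] with `time`/`event`.
#' @param candidates Candidate genes (default all matrix genes).
#' @param alpha Retention threshold (default 0.01).
#' @param horizon Truncation time in months (default 60).
#' @return Data frame `gene`, `beta`, `HR`, `p`, `risk_direction`
#'   (`"up"` if beta > 0) for the retained genes, sorted by `p`. The
#'   full (unfiltered) table is attached as attribute `"all"`.
#' @export
screen_prognostic_genes <- function(mat, samples, candidates = rownames(mat),
                                    alpha = 0.01, horizon = 60) {
  stopifnot(all(candidates %in% rownames(mat)),
            all(c("time", "event") %in% names(samples)))
  sm <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  keep <- !is.na(sm$time) & !is.na(sm$event)
  tr <- .truncate_surv(sm$time[keep], sm$event[keep], horizon)
  if (sum(tr$event) == 0) stop("no events within the horizon")
  y <- survival::Surv(tr$time, tr$event)
  ids <- sm$sample_id[keep]
  rows <- lapply(candidates, function(g) {
    x <- mat[g, ids]
    if (stats::var(x) == 0) {
      warning("constant gene skipped: ", g)
      return(NULL)
    }
    fit <- survival::coxph(y ~ x, ties = "efron")
    s <- summary(fit)$coefficients
    data.frame(gene = g, beta = s[1, "coef"], HR = s[1, "exp(coef)"],
               p = s[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  all_tab <- do.call(rbind, rows)
  all_tab$risk_direction <- ifelse(all_tab$beta > 0, "up", "down")
  out <- all_tab[all_tab$p < alpha, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_tab
  out
}

#' Build a signature model from discovery and validation screens
#'
#' Intersects the two hit tables, requiring a concordant risk
#' direction; genes with conflicting directions are excluded with a
#' warning. Risk-up genes become the signature's up role, risk-down
#' genes the down role.
#'
#' @param discovery_hits,validation_hits Data frames with columns
#'   `gene` and `risk_direction` (or `beta`, from which the direction
#'   is taken as its sign) — e.g. outputs of
#'   [screen_prognostic_genes()].
#' @param strict Error when fewer than 2 genes land in either role
#'   (default `TRUE`).
#' @return A [signature_model()] (without frozen variances).
#' @export
build_signature <- function(discovery_hits, validation_hits, strict = TRUE) {
  dir_of <- function(df) {
    if (!"risk_direction" %in% names(df)) {
      stopifnot("beta" %in% names(df))
      df$risk_direction <- ifelse(df$beta > 0, "up", "down")
    }
    stats::setNames(df$risk_direction, df$gene)
  }
  d <- dir_of(discovery_hits)
  v <- dir_of(validation_hits)
  shared <- intersect(names(d), names(v))
  conflict <- shared[d[shared] != v[shared]]
  if (length(conflict))
    warning("direction conflict between cohorts; excluded: ",
            paste(conflict, collapse = ", "))
  shared <- setdiff(shared, conflict)
  up <- shared[d[shared] == "up"]
  down <- shared[d[shared] == "down"]
  if (strict && (length(up) < 2 || length(down) < 2))
    stop("fewer than 2 concordant genes per role (", length(up), " up, ",
         length(down), " down)")
  signature_model(up, down)
}

#' Survival analysis of a per-sample score
#'
#' Dichotomizes the score at the cohort median (ties to the low group),
#' computes Kaplan-Meier curves per group with administrative
#' truncation at `horizon` months and the log-rank p-value, fits a
#' univariate Cox model on the continuous score, and, when covariates
#' are given, a multivariate Cox model with per-term Wald p-values plus
#' a likelihood-ratio p for each covariate as a whole (the
#' independent-prognostic-value check).
#'
#' @param scores Named per-sample numeric scores.
#' @param samples A [sample_table()] with `time`/`event` covering the
#'   scored samples.
#' @param covariates Character vector of `samples` columns to adjust
#'   for (e.g. `"stage"`).
#' @param stage_coding `"categorical"` (factor; default) or
#'   `"ordinal"` (integer rank) encoding for the stage covariate.
#' @param horizon Truncation in months (default 60, the 5-year
#'   endpoint).
#' @return List of class `survival_result`: `group` (factor high/low),
#'   `km` (product-limit table per group), `five_year` (survival at
#'   `horizon` per group), `logrank_p`, `cox_univariate` (beta, HR, CI,
#'   p), `cox_multivariate` (coefficient table plus `covariate_lrt`),
#'   `median_cutoff`.
#' @export
survival_analysis <- function(scores, samples, covariates = NULL,
                              stage_coding = c("categorical", "ordinal"),
                              horizon = 60) {
  stage_coding <- match.arg(stage_coding)
  stopifnot(all(c("time", "event") %in% names(samples)))
  sm <- samples[match(names(scores), samples$sample_id), , drop = FALSE]
  keep <- !is.na(sm$time) & !is.na(sm$event)
  sm <- sm[keep, , drop = FALSE]
  sc <- scores[keep]
  tr <- .truncate_surv(sm$time, sm$event, horizon)
  med <- stats::median(sc)
  group <- factor(ifelse(sc > med, "high", "low"), levels = c("low", "high"))
  fit_km <- survival::survfit(survival::Surv(tr$time, tr$event) ~ group)
  km <- summary(fit_km)
  strata <- if (is.null(km$strata)) rep(levels(group)[1], length(km$time))
            else sub("^group=", "", as.character(km$strata))
  km_tab <- data.frame(group = strata, time = km$time,
                       n_risk = km$n.risk, n_event = km$n.event,
                       surv = km$surv)
  at_h <- summary(fit_km, times = horizon, extend = TRUE)
  five_year <- stats::setNames(at_h$surv,
                               sub("^group=", "", as.character(at_h$strata)))
  ev_by_group <- tapply(tr$event, group, sum)
  logrank_p <- NA_real_
  if (nlevels(droplevels(group)) < 2) {
    warning("single score group; log-rank skipped")
  } else if (any(ev_by_group == 0, na.rm = TRUE) || sum(tr$event) == 0) {
    warning("a group has zero events; log-rank skipped")
  } else {
    sd_ <- survival::survdiff(survival::Surv(tr$time, tr$event) ~ group)
    logrank_p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1,
                               lower.tail = FALSE)
  }
  cox_uni <- NULL
  cox_multi <- NULL
  if (stats::var(sc) == 0) {
    warning("constant score; Cox models skipped")
  } else if (sum(tr$event) > 0) {
    y <- survival::Surv(tr$time, tr$event)
    fit_u <- survival::coxph(y ~ sc, ties = "efron")
    su <- summary(fit_u)
    cox_uni <- data.frame(term = "score", beta = su$coefficients[1, "coef"],
                          HR = su$coefficients[1, "exp(coef)"],
                          lower95 = su$conf.int[1, "lower .95"],
                          upper95 = su$conf.int[1, "upper .95"],
                          p = su$coefficients[1, "Pr(>|z|)"])
    if (!is.null(covariates)) {
      df <- data.frame(sc = sc)
      for (cv in covariates) {
        v <- sm[[cv]]
        if (cv == "stage")
          v <- if (stage_coding == "ordinal") as.integer(v)
               else factor(as.character(v), levels = STAGE_LEVELS)
        df[[cv]] <- if (is.factor(v)) droplevels(v) else v
      }
      fit_m <- survival::coxph(y ~ ., data = df, ties = "efron")
      sm_ <- summary(fit_m)
      coef_tab <- data.frame(term = rownames(sm_$coefficients),
                             beta = sm_$coefficients[, "coef"],
                             HR = sm_$coefficients[, "exp(coef)"],
                             p = sm_$coefficients[, "Pr(>|z|)"],
                             row.names = NULL)
      lrt <- vapply(covariates, function(cv) {
        fit_red <- survival::coxph(y ~ ., data = df[, setdiff(names(df), cv),
                                                    drop = FALSE],
                                   ties = "efron")
        stats::pchisq(2 * (fit_m$loglik[2] - fit_red$loglik[2]),
                      df = length(stats::coef(fit_m)) - length(stats::coef(fit_red)),
                      lower.tail = FALSE)
      }, numeric(1))
      cox_multi <- list(coefficients = coef_tab, covariate_lrt = lrt)
    }
  } else {
    warning("no events; Cox models skipped")
  }
  structure(list(group = stats::setNames(group, sm$sample_id), km = km_tab,
                 five_year = five_year, logrank_p = logrank_p,
                 cox_univariate = cox_uni, cox_multivariate = cox_multi,
                 median_cutoff = med),
            class = "survival_result")
}

#' Serialize a survival result as JSON plus a KM table TSV
#'
#' @param result A `survival_result`.
#' @param path_prefix Prefix for `<prefix>_km.tsv` and `<prefix>.json`.
#' @export
write_survival_result <- function(result, path_prefix) {
  stopifnot(inherits(result, "survival_result"))
  utils::write.table(result$km, paste0(path_prefix, "_km.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(five_year = as.list(result$five_year), logrank_p = result$logrank_p,
         cox_univariate = result$cox_univariate,
         cox_multivariate = result$cox_multivariate,
         median_cutoff = result$median_cutoff),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  invisible(path_prefix)
}
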