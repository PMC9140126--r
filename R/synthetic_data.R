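#' Configuration for the synthetic staged-cohort generator
#'
#' The generator emulates a multi-batch, stage-ordered expression cohort
#' (baseline NAU plus five tumor stages) with planted monotone genes,
#' additive (optionally multiplicative) batch effects, gene-set
#' structure, cell-type mixtures and signature-linked survival. Defaults
#' are the study conditions used throughout the test suite: 30 samples
#' per condition, 2000 genes with 100 monotone-up and 50 monotone-down
#' planted genes, a per-stage mean increment of 0.5 log2 units, unit
#' Gaussian noise, and 12 batches crossed with stage.
#'
#' @param n_per_stage Named integer vector of samples per condition
#'   (names in `STAGE_LEVELS`), or a single count recycled to all six.
#' @param n_genes Total number of genes.
#' @param n_monotone_up,n_monotone_down Number of planted genes whose
#'   stage means increase (decrease) by `step` per stage.
#' @param step Per-stage mean increment in log2 units.
#' @param n_batches Number of batches; batches are crossed with stage
#'   unless `confounded = TRUE`.
#' @param batch_shift_sd SD (log2 units) of the per-batch additive shift.
#' @param batch_scale_sd SD of the per-batch log multiplicative (scale)
#'   component applied to the noise; 0 disables it.
#' @param noise_sd Residual Gaussian SD in log2 units.
#' @param confounded If `TRUE`, batches are nested within stage (a
#'   pathological fixture in which correction is not identifiable).
#' @param n_gene_sets,set_size Decoy gene-set count and size for
#'   [make_gene_sets()].
#' @param n_cell_types Number of cell types for the deconvolution
#'   fixtures (planted mixing fractions).
#' @param survival_beta Log-hazard per unit of the planted prognostic
#'   score.
#' @param censor_rate Expected fraction of independently censored
#'   subjects (before administrative censoring at 120 months).
#' @param base_mean,base_sd Distribution of baseline gene means (log2).
#' @param seed Integer seed; the same config yields byte-identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_stage = 30,
                              n_genes = 2000,
                              n_monotone_up = 100,
                              n_monotone_down = 50,
                              step = 0.5,
                              n_batches = 12,
                              batch_shift_sd = 0.5,
                              batch_scale_sd = 0,
                              noise_sd = 1.0,
                              confounded = FALSE,
                              n_gene_sets = 10,
                              set_size = 50,
                              n_cell_types = 5,
                              survival_beta = log(2),
                              censor_rate = 0.3,
                              base_mean = 7,
                              base_sd = 1.5,
                              seed = 1L) {
  if (length(n_per_stage) == 1)
    n_per_stage <- stats::setNames(rep(n_per_stage, 6), STAGE_LEVELS)
  if (!setequal(names(n_per_stage), STAGE_LEVELS))
    stop("n_per_stage must be named by the six stage levels")
  n_per_stage <- n_per_stage[STAGE_LEVELS]
  if (any(n_per_stage < 0) || n_genes < 0 || n_monotone_up < 0 || n_monotone_down < 0)
    stop("all counts must be >= 0")
  if (n_monotone_up + n_monotone_down > n_genes)
    stop("more planted genes than n_genes")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  structure(list(n_per_stage = n_per_stage, n_genes = n_genes,
                 n_monotone_up = n_monotone_up, n_monotone_down = n_monotone_down,
                 step = step, n_batches = n_batches,
                 batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
                 noise_sd = noise_sd, confounded = confounded,
                 n_gene_sets = n_gene_sets, set_size = set_size,
                 n_cell_types = n_cell_types,
                 survival_beta = survival_beta, censor_rate = censor_rate,
                 base_mean = base_mean, base_sd = base_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-batch staged cohort with planted ground truth
#'
#' Planted monotone-up genes have population stage means
#' `mu, mu + step, ..., mu + 5*step` across `NAU, Ta, ..., T4` (down
#' genes mirrored); all other genes share one mean across stages.
#' Gaussian noise with SD `noise_sd` is added, then a per-batch additive
#' location shift drawn from `N(0, batch_shift_sd)` is applied after the
#' biology (with an optional per-batch scale component on the noise).
#' Survival is tied to a planted standard-normal score, independent of
#' stage, via [simulate_survival()].
#'
#' @param config A [simulation_config()].
#' @return List with elements `matrix` (gene x sample log2 expression),
#'   `samples` (a [sample_table()] incl. survival) and `truth` (lists of
#'   planted up/down genes, batch assignment, per-sample planted score,
#'   planted cell-type fractions, and the per-batch shifts).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_stage <- config$n_per_stage
  stages <- rep(STAGE_LEVELS, times = n_stage)
  n <- length(stages)
  sample_ids <- sprintf("S%04d", seq_len(n))
  genes <- sprintf("G%05d", seq_len(config$n_genes))

  planted <- sample(genes, config$n_monotone_up + config$n_monotone_down)
  up <- planted[seq_len(config$n_monotone_up)]
  down <- setdiff(planted, up)

  # batches crossed with stage: round-robin within each stage, shuffled
  batch <- integer(n)
  for (s in STAGE_LEVELS) {
    i <- which(stages == s)
    batch[i] <- if (config$confounded)
      rep(1 + (match(s, STAGE_LEVELS) - 1) %% config$n_batches, length(i))
    else
      sample(rep_len(seq_len(config$n_batches), length(i)))
  }

  mu <- stats::rnorm(config$n_genes, config$base_mean, config$base_sd)
  names(mu) <- genes
  k <- match(stages, STAGE_LEVELS) - 1L  # 0 for NAU .. 5 for T4
  effect <- matrix(0, config$n_genes, n, dimnames = list(genes, sample_ids))
  if (length(up)) effect[up, ] <- matrix(rep(config$step * k, length(up)),
                                         nrow = length(up), byrow = TRUE)
  if (length(down)) effect[down, ] <- matrix(rep(-config$step * k, length(down)),
                                             nrow = length(down), byrow = TRUE)
  noise <- matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                  config$n_genes, n)
  gamma <- stats::rnorm(config$n_batches, 0, config$batch_shift_sd)
  delta <- exp(stats::rnorm(config$n_batches, 0, config$batch_scale_sd))
  X <- mu + effect + sweep(noise, 2, delta[batch], `*`)
  X <- sweep(X, 2, gamma[batch], `+`)
  dimnames(X) <- list(genes, sample_ids)

  score <- stats::rnorm(n)
  surv <- simulate_survival(score, config)
  fractions <- matrix(stats::rgamma(n * config$n_cell_types, shape = 2),
                      n, config$n_cell_types,
                      dimnames = list(sample_ids,
                                      paste0("celltype_", seq_len(config$n_cell_types))))
  fractions <- fractions / rowSums(fractions)

  samples <- sample_table(data.frame(
    sample_id = sample_ids, stage = stages, batch = batch,
    age = round(stats::rnorm(n, 68, 9)),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.78, 0.22)),
    time = surv$time, event = surv$event,
    stringsAsFactors = FALSE))

  list(matrix = expression_matrix(X),
       samples = samples,
       truth = list(monotone_up_genes = up, monotone_down_genes = down,
                    batch_assignments = batch, true_score = stats::setNames(score, sample_ids),
                    true_fractions = fractions,
                    batch_shifts = gamma, batch_scales = delta))
}

#' Simulate right-censored survival from a linear score
#'
#' Event times are exponential with hazard `h0 * exp(beta * score)`.
#' Each subject is independently censored with probability
#' `censor_rate` at a uniform time before its event, and all follow-up
#' is administratively censored at `horizon` months.
#'
#' @param score Numeric vector of per-sample prognostic scores.
#' @param config A [simulation_config()] (uses `survival_beta` and
#'   `censor_rate`).
#' @param h0 Baseline hazard per month (default gives a 36-month median
#'   at score 0).
#' @param horizon Administrative censoring time in months; `Inf`
#'   disables it.
#' @return List with numeric `time` (months) and integer `event` (0/1).
#' @export
simulate_survival <- function(score, config, h0 = log(2) / 36, horizon = 120) {
  stopifnot(all(is.finite(score)))
  n <- length(score)
  t_event <- stats::rexp(n, rate = h0 * exp(config$survival_beta * score))
  event <- rep(1L, n)
  cens <- stats::runif(n) < config$censor_rate
  t_obs <- t_event
  t_obs[cens] <- stats::runif(sum(cens), 0, t_event[cens])
  event[cens] <- 0L
  over <- t_obs > horizon
  t_obs[over] <- horizon
  event[over] <- 0L
  list(time = t_obs, event = event)
}

#' Simulate linear-scale cell-type mixtures
#'
#' Returns `reference %*% t(fractions)` plus Gaussian noise, on the
#' linear scale on which reference-based deconvolution operates.
#'
#' @param reference Gene x cell-type matrix of linear-scale profiles.
#' @param fractions Sample x cell-type matrix; rows must be nonnegative
#'   and sum to 1.
#' @param noise_sd SD of additive Gaussian noise (linear scale).
#' @return Gene x sample matrix of mixed expression (linear scale).
#' @export
simulate_mixtures <- function(reference, fractions, noise_sd = 0) {
  stopifnot(is.matrix(reference), is.matrix(fractions),
            ncol(reference) == ncol(fractions))
  if (any(fractions < 0)) stop("negative fraction")
  if (any(abs(rowSums(fractions) - 1) > 1e-8))
    stop("fractions must row-sum to 1")
  mix <- reference %*% t(fractions)
  if (noise_sd > 0)
    mix <- mix + matrix(stats::rnorm(length(mix), 0, noise_sd), nrow(mix))
  if (!is.null(rownames(fractions))) colnames(mix) <- rownames(fractions)
  mix
}

#' Generate linear-scale reference profiles for deconvolution fixtures
#'
#' Each cell type gets a block of marker genes with elevated expression
#' over a shared low background, giving well-separated (identifiable)
#' columns.
#'
#' @param n_genes Number of genes in the panel.
#' @param n_cell_types Number of cell types.
#' @param marker_high,background Linear-scale expression of marker and
#'   background genes.
#' @return Gene x cell-type matrix.
#' @export
make_reference_profiles <- function(n_genes = 200, n_cell_types = 5,
                                    marker_high = 100, background = 5) {
  genes <- sprintf("R%04d", seq_len(n_genes))
  ref <- matrix(background * stats::runif(n_genes * n_cell_types, 0.5, 1.5),
                n_genes, n_cell_types,
                dimnames = list(genes, paste0("celltype_", seq_len(n_cell_types))))
  blocks <- split(seq_len(n_genes),
                  cut(seq_len(n_genes), n_cell_types, labels = FALSE))
  for (ct in seq_len(n_cell_types))
    ref[blocks[[ct]], ct] <- marker_high * stats::runif(length(blocks[[ct]]), 0.5, 1.5)
  ref
}

#' Build gene-set fixtures from planted ground truth
#'
#' Emits one set of exactly the planted monotone-up genes, one of the
#' planted monotone-down genes, `n_gene_sets` decoy sets drawn without
#' replacement from non-planted genes, and a signed regulon fixture (a
#' synthetic "TF" whose targets are planted genes with known signs:
#' +1 for up, -1 for down).
#'
#' @param truth The `truth` element of [simulate_cohort()] output.
#' @param config The matching [simulation_config()].
#' @param genes All gene IDs in the simulated matrix.
#' @return A `gene_set_collection`.
#' @export
make_gene_sets <- function(truth, config, genes) {
  up <- truth$monotone_up_genes; down <- truth$monotone_down_genes
  nonplanted <- setdiff(genes, c(up, down))
  sets <- list(planted_up = up, planted_down = down)
  desc <- c(planted_up = "planted monotone-up genes",
            planted_down = "planted monotone-down genes")
  for (i in seq_len(config$n_gene_sets)) {
    nm <- sprintf("decoy_%02d", i)
    sets[[nm]] <- sample(nonplanted, min(config$set_size, length(nonplanted)))
    desc[nm] <- "random decoy set"
  }
  targets <- c(utils::head(up, config$set_size %/% 2),
               utils::head(down, config$set_size %/% 2))
  signs <- stats::setNames(vector("list", length(sets)), names(sets))
  if (length(targets) >= 2) {
    sets[["TF_planted"]] <- targets
    desc["TF_planted"] <- "synthetic regulon: planted targets with known signs"
    signs[["TF_planted"]] <- stats::setNames(
      c(rep(1, sum(targets %in% up)), rep(-1, sum(targets %in% down))), targets)
  }
  gene_set_collection(sets, desc, signs)
}
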