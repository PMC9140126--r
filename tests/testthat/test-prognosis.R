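toy_signature_fixture <- function() {
  # 8 genes x 2 samples with hand-set values; variances computed with
  # the n-1 denominator across the two samples
  genes <- c("A", "B", "C", "D", "E", "F", "G", "H")
  mat <- rbind(A = c(2, 4), B = c(1, 3), C = c(0, 2), D = c(5, 1),
               E = c(3, 1), F = c(2, 6), G = c(4, 2), H = c(1, 5))
  colnames(mat) <- c("s1", "s2")
  model <- signature_model(genes[1:4], genes[5:8])
  list(mat = mat, model = model)
}

test_that("the signature score matches the hand-computed eight-term sum", {
  fx <- toy_signature_fixture()
  v <- apply(fx$mat, 1, var)  # each gene has variance 2 or 8 here
  hand <- function(j) sum(fx$mat[1:4, j] / v[1:4]) - sum(fx$mat[5:8, j] / v[5:8])
  s <- signature_score(fx$mat, fx$model)
  expect_equal(unname(s), c(hand(1), hand(2)))
})

test_that("swapping up and down gene lists negates the score exactly", {
  fx <- toy_signature_fixture()
  s <- signature_score(fx$mat, fx$model)
  swapped <- signature_model(fx$model$down_genes, fx$model$up_genes)
  expect_equal(signature_score(fx$mat, swapped), -s)
})

test_that("scoring is linear: a constant added to one gene shifts all scores by c/Var", {
  fx <- toy_signature_fixture()
  s <- signature_score(fx$mat, fx$model)
  # freeze variances so the shift does not change them
  v <- apply(fx$mat, 1, var)
  model_v <- signature_model(fx$model$up_genes, fx$model$down_genes, variances = v)
  s0 <- signature_score(fx$mat, model_v)
  mat2 <- fx$mat
  mat2["A", ] <- mat2["A", ] + 3
  expect_equal(signature_score(mat2, model_v), s0 + 3 / v["A"],
               ignore_attr = TRUE)
})

test_that("zero-variance and missing genes raise the documented errors", {
  fx <- toy_signature_fixture()
  mat <- fx$mat
  mat["C", ] <- 7
  expect_error(signature_score(mat, fx$model), "C")
  expect_error(signature_score(fx$mat[1:6, ], fx$model), "missing")
  flat <- matrix(1, 8, 2, dimnames = dimnames(fx$mat))
  expect_error(signature_score(flat, fx$model), "zero variance")
})

test_that("Kaplan-Meier matches a hand-computed product-limit table", {
  # 6 subjects: event pattern 1,0,1,1,0,1 at times 1..6
  sm <- sample_table(data.frame(
    sample_id = paste0("p", 1:6), stage = "T2", batch = 1,
    time = 1:6, event = c(1, 0, 1, 1, 0, 1)))
  scores <- setNames(rep(0, 6), sm$sample_id)  # one group (all ties -> low)
  res <- suppressWarnings(survival_analysis(scores, sm))
  km <- res$km[res$km$group == "low", ]
  expect_equal(km$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3,
                          0), tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 0))
})

test_that("median dichotomization splits ties to the low group", {
  sm <- sample_table(data.frame(
    sample_id = paste0("p", 1:7), stage = "T2", batch = 1,
    time = c(10, 20, 30, 40, 50, 55, 58), event = c(1, 1, 0, 1, 0, 1, 1)))
  sc <- setNames(c(1, 2, 3, 4, 5, 6, 7), sm$sample_id)
  res <- suppressWarnings(survival_analysis(sc, sm))  # tiny-n Cox convergence noise
  expect_identical(as.vector(table(res$group)), c(4L, 3L))  # low gets the median
  sc2 <- setNames(c(1, 1, 1, 1, 2, 2, 2), sm$sample_id)
  res2 <- suppressWarnings(survival_analysis(sc2, sm))
  expect_identical(unname(res2$group[sc2 == 1]), factor(rep("low", 4), levels = c("low", "high")))
})

test_that("null and degenerate survival cases behave as specified", {
  # no events anywhere: both KM curves stay at 1 through the horizon
  sm <- sample_table(data.frame(
    sample_id = paste0("p", 1:10), stage = "T2", batch = 1,
    time = rep(100, 10), event = 0))
  sc <- setNames(1:10, sm$sample_id)
  res <- suppressWarnings(survival_analysis(sc, sm))
  expect_true(all(res$five_year == 1))
  # two statistically identical groups: HR near 1, log-rank p large
  set.seed(73)
  n <- 300
  sm2 <- sample_table(data.frame(
    sample_id = sprintf("q%03d", 1:n), stage = "T2", batch = 1,
    time = rexp(n, 0.02), event = 1))
  sc2 <- setNames(rnorm(n), sm2$sample_id)
  res2 <- survival_analysis(sc2, sm2)
  expect_equal(res2$cox_univariate$HR, 1, tolerance = 0.2)
  expect_gt(res2$logrank_p, 0.05)
})

test_that("univariate screening recovers a planted hazard and flips with sign", {
  set.seed(74)
  n <- 500
  cfg <- simulation_config(survival_beta = log(2), censor_rate = 0.2, seed = 1)
  x <- rnorm(n)
  sv <- simulate_survival(x, cfg)
  mat <- rbind(planted = x + rnorm(n, 0, 0.01), flat = rep(1, n),
               noise = rnorm(n))
  colnames(mat) <- sprintf("s%03d", 1:n)
  sm <- sample_table(data.frame(sample_id = colnames(mat), stage = "T2",
                                batch = 1, time = sv$time, event = sv$event))
  expect_warning(hits <- screen_prognostic_genes(mat, sm, alpha = 0.01), "flat")
  expect_true("planted" %in% hits$gene)
  expect_identical(hits$risk_direction[hits$gene == "planted"], "up")
  all_tab <- attr(hits, "all")
  # negating the gene flips the sign of its coefficient exactly
  mat_neg <- mat
  mat_neg["planted", ] <- -mat["planted", ]
  hits_neg <- suppressWarnings(screen_prognostic_genes(mat_neg, sm, alpha = 0.01))
  expect_equal(hits_neg$beta[hits_neg$gene == "planted"],
               -all_tab$beta[all_tab$gene == "planted"])
  # no events -> error
  sm0 <- sm; sm0$event <- 0
  expect_error(screen_prognostic_genes(mat, sm0), "no events")
})

test_that("null genes are retained at about the screening alpha", {
  set.seed(75)
  n <- 150; n_genes <- 2000
  cfg <- simulation_config(survival_beta = 0, censor_rate = 0.2, seed = 1)
  sv <- simulate_survival(rep(0, n), cfg)
  mat <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%04d", 1:n_genes), sprintf("s%03d", 1:n)))
  sm <- sample_table(data.frame(sample_id = colnames(mat), stage = "T2",
                                batch = 1, time = sv$time, event = sv$event))
  hits <- screen_prognostic_genes(mat, sm, alpha = 0.05)
  rate <- nrow(hits) / n_genes
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("signatures are built by concordant intersection with role assignment", {
  disc <- data.frame(gene = paste0("g", 1:10),
                     risk_direction = rep(c("up", "down"), 5))
  val <- data.frame(gene = paste0("g", 3:12),
                    risk_direction = rep(c("up", "down"), 5))
  model <- build_signature(disc, val)
  expect_setequal(c(model$up_genes, model$down_genes), paste0("g", 3:10))
  expect_true(all(model$up_genes %in% disc$gene[disc$risk_direction == "up"]))
  # conflicting direction is excluded with a warning
  val2 <- val
  val2$risk_direction[val2$gene == "g3"] <- "down"
  expect_warning(m2 <- build_signature(disc, val2), "g3")
  expect_false("g3" %in% c(m2$up_genes, m2$down_genes))
  # the canonical roster splits 4/4
  disc8 <- data.frame(gene = c("MED19", "ENO1", "ANLN", "GTPBP4",
                               "CBX7", "ZFP2", "AKAP7", "CDC14B"),
                      risk_direction = rep(c("up", "down"), each = 4))
  m8 <- build_signature(disc8, disc8)
  expect_setequal(m8$up_genes, c("MED19", "ENO1", "ANLN", "GTPBP4"))
  expect_setequal(m8$down_genes, c("CBX7", "ZFP2", "AKAP7", "CDC14B"))
  expect_error(build_signature(disc[1:2, ], val[1:2, ]), "fewer than 2")
})

test_that("the multivariate model separates a prognostic score from a null stage", {
  set.seed(76)
  n <- 300
  cfg <- simulation_config(survival_beta = log(2), censor_rate = 0.2, seed = 1)
  score <- rnorm(n)
  sv <- simulate_survival(score, cfg)
  sm <- sample_table(data.frame(
    sample_id = sprintf("s%03d", 1:n),
    stage = sample(STAGE_LEVELS, n, replace = TRUE),
    batch = 1, time = sv$time, event = sv$event))
  res <- survival_analysis(setNames(score, sm$sample_id), sm,
                           covariates = "stage")
  cf <- res$cox_multivariate$coefficients
  expect_lt(cf$p[cf$term == "sc"], 0.05)
  expect_gt(res$cox_multivariate$covariate_lrt[["stage"]], 0.05)
  # ordinal encoding also runs
  res_o <- survival_analysis(setNames(score, sm$sample_id), sm,
                             covariates = "stage", stage_coding = "ordinal")
  expect_true(is.finite(res_o$cox_multivariate$covariate_lrt[["stage"]]))
})
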