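test_that("Mann-Whitney matches enumeration exactly for small groups", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)  # 2 of the C(6,3)=20 labelings are as extreme
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)

  set.seed(4)
  for (i in 1:20) {
    m <- sample(2:6, 1); n <- sample(2:8, 1)
    x <- round(rnorm(m), 1); y <- round(rnorm(n, 0.5), 1)
    tie_lens <- rle(sort(c(x, y)))$lengths
    if (sum(tie_lens[tie_lens > 1]) / (m + n) > 0.25) next  # approx branch there
    expect_equal(mann_whitney(x, y)$p, oracle_mw_exact(x, y),
                 info = sprintf("case %d", i))
  }
})

test_that("the large-sample approximation agrees with a permutation oracle", {
  set.seed(8)
  x <- rnorm(40); y <- rnorm(45, 0.4)
  res <- mann_whitney(x, y)
  expect_lt(abs(res$p - oracle_mw_perm(x, y, n_perm = 10000, seed = 2)), 0.01)
  # and with ties present
  xt <- round(rnorm(30), 1); yt <- round(rnorm(30, 0.3), 1)
  expect_lt(abs(mann_whitney(xt, yt)$p -
                  oracle_mw_perm(xt, yt, n_perm = 10000, seed = 3)), 0.01)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("the differential table equals gene-by-gene Mann-Whitney application", {
  tc <- tiny_cohort(seed = 31, n_per_stage = 12, n_genes = 50)
  sim <- tc$sim
  tab <- stage_differential_table(sim$matrix, sim$samples)
  nau <- sim$samples$sample_id[sim$samples$stage == "NAU"]
  for (st in TUMOR_STAGES) {
    ids <- sim$samples$sample_id[sim$samples$stage == st]
    for (g in rownames(sim$matrix)) {
      mw <- mann_whitney(sim$matrix[g, ids], sim$matrix[g, nau])
      row <- tab[tab$gene == g & tab$stage == st, ]
      expect_equal(row$U, mw$U)
      expect_equal(row$p, mw$p)
      expect_equal(row$fc, mean(sim$matrix[g, ids]) - mean(sim$matrix[g, nau]))
    }
  }
})

test_that("a constant gene yields p = 1 and fc = 0 in every comparison", {
  tc <- tiny_cohort(seed = 32, n_genes = 20)
  mat <- tc$sim$matrix
  mat["G00001", ] <- 5
  tab <- stage_differential_table(mat, tc$sim$samples)
  flat <- tab[tab$gene == "G00001", ]
  expect_true(all(flat$p == 1))
  expect_true(all(flat$fc == 0))
})

test_that("planted staircase genes show the expected fold-change profile", {
  cfg <- simulation_config(n_per_stage = 30, n_genes = 200, n_monotone_up = 10,
                           n_monotone_down = 0, step = 0.5, noise_sd = 1,
                           n_batches = 1, batch_shift_sd = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  tab <- stage_differential_table(sim$matrix, sim$samples)
  g <- sim$truth$monotone_up_genes[1]
  fc <- tab$fc[tab$gene == g][match(TUMOR_STAGES, tab$stage[tab$gene == g])]
  se <- sqrt(1 / 30 + 1 / 30)  # SE of a difference of means at noise_sd 1
  expect_true(all(abs(fc - 0.5 * (1:5)) < 3 * se))
})

test_that("CDEG and monotone filters implement the literal definitions", {
  # hand-built table exercising each rule
  mk <- function(gene, p, fc) data.frame(gene = gene, stage = TUMOR_STAGES,
                                         U = 0, p = p, fc = fc)
  tab <- rbind(
    mk("sig4of5", c(0.01, 0.01, 0.2, 0.01, 0.01), rep(1, 5)),
    mk("flip", rep(0.01, 5), c(1, 1, -1, 1, 1)),
    mk("mono_up", rep(0.01, 5), c(0.5, 0.8, 1.1, 1.5, 2.0)),
    mk("bump", rep(0.01, 5), c(0.5, 0.9, 0.8, 1.5, 2.0)),
    mk("mono_down", rep(0.01, 5), c(-0.2, -0.4, -0.6, -0.9, -1.3)),
    mk("tied", rep(0.01, 5), c(0.5, 0.5, 1, 2, 3)))
  cd <- select_cdegs(tab)
  expect_setequal(cd$gene, c("mono_up", "bump", "mono_down", "tied"))
  mono <- select_monotone_genes(tab, cd)
  expect_identical(mono$gene[mono$direction == "up"], "mono_up")
  expect_identical(mono$gene[mono$direction == "down"], "mono_down")
  expect_identical(mono$fc_T4[mono$gene == "mono_up"], 2.0)
  # non-strict reading admits the tie
  mono2 <- select_monotone_genes(tab, cd, strict = FALSE)
  expect_true("tied" %in% mono2$gene)
})

test_that("filters nest, ignore ordering, and match the brute-force oracle", {
  tc <- tiny_cohort(seed = 33, n_per_stage = 10, n_genes = 80, n_up = 8,
                    n_down = 6, step = 1.2, noise_sd = 0.8)
  tab <- stage_differential_table(tc$sim$matrix, tc$sim$samples)
  cd <- select_cdegs(tab)
  mono <- select_monotone_genes(tab, cd)
  expect_true(all(mono$gene %in% cd$gene))
  expect_lte(nrow(cd), nrow(tc$sim$matrix))

  oracle <- oracle_monotone(tab)
  expect_setequal(mono$gene, names(oracle))
  expect_identical(unname(oracle[mono$gene]), mono$direction)

  # invariance to gene and sample order (rows are matched by sample_id)
  set.seed(6)
  perm_g <- sample(nrow(tc$sim$matrix))
  perm_s <- sample(ncol(tc$sim$matrix))
  tab2 <- stage_differential_table(tc$sim$matrix[perm_g, perm_s],
                                   tc$sim$samples[sample(nrow(tc$sim$samples)), ])
  mono2 <- select_monotone_genes(tab2, select_cdegs(tab2))
  expect_setequal(mono2$gene, mono$gene)
})

test_that("pooled NMI/MI fold changes correlate as constructed", {
  # proportional stage effects -> near-perfect concordance
  tc <- tiny_cohort(seed = 34, n_per_stage = 25, n_genes = 300, n_up = 150,
                    n_down = 100, step = 1.0, noise_sd = 0.5, n_batches = 1)
  lc <- logfc_concordance(tc$sim$matrix, tc$sim$samples)
  expect_gt(lc$r, 0.8)
  # null effects -> near-zero correlation. The baseline group is made
  # large so its sampling noise (shared by both fold-change vectors and
  # therefore a source of spurious positive correlation) is negligible
  # next to the group-specific noise.
  set.seed(99)
  n_nau <- 600; n_grp <- 25
  n <- n_nau + 2 * n_grp
  X <- matrix(rnorm(2000 * n), 2000, n,
              dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%03d", 1:n)))
  sm <- sample_table(data.frame(sample_id = colnames(X),
                                stage = rep(c("NAU", "Ta", "T2"),
                                            c(n_nau, n_grp, n_grp)),
                                batch = 1))
  lc0 <- logfc_concordance(X, sm)
  expect_lt(abs(lc0$r), 0.1)
})

test_that("missing baseline or undersized stages are handled as specified", {
  tc <- tiny_cohort(seed = 35)
  sm <- tc$sim$samples
  expect_error(stage_differential_table(tc$sim$matrix,
                                        sm[sm$stage != "NAU", ]), "NAU")
  sm3 <- sm[sm$stage != "T4" | sm$sample_id == sm$sample_id[sm$stage == "T4"][1], ]
  expect_warning(tab <- stage_differential_table(tc$sim$matrix, sm3), "T4")
  expect_false("T4" %in% tab$stage)
})
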