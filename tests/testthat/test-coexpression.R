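test_that("enumeration arithmetic for the network step is exact", {
  expect_identical(pair_weight_count(3108), 9659664)
  expect_identical(default_node_target(3108), 1554)
})

test_that("a dominant predictor gets the top importance, deterministically", {
  set.seed(51)
  n <- 60
  X <- matrix(rnorm(52 * n), 52, n,
              dimnames = list(c("x1", "y", sprintf("n%02d", 1:50)),
                              sprintf("s%02d", 1:n)))
  X["y", ] <- X["x1", ]  # y is an exact copy of x1
  w1 <- ensemble_importance(X, n_trees = 200, seed = 3)
  expect_identical(names(which.max(w1$W[, "y"])), "x1")
  w2 <- ensemble_importance(X, n_trees = 200, seed = 3)
  expect_identical(w1, w2)
  # per-target normalization and structural invariants
  expect_true(all(abs(colSums(w1$W) - 1) < 1e-9))
  expect_true(all(diag(w1$W) == 0))
  expect_true(all(w1$W >= 0))
  expect_equal(w1$rho, t(w1$rho))
  expect_error(ensemble_importance(X[, 1:5]), ">= 10 samples")
})

test_that("planted linear edges rank above null pairs", {
  aurocs <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 200; p <- 20
    X <- matrix(rnorm(p * n, 0, 1), p, n,
                dimnames = list(sprintf("g%02d", 1:p), sprintf("s%03d", 1:n)))
    # 5 true directed influences with effect 1.0, noise 0.5
    edges <- cbind(from = 1:5, to = 6:10)
    for (k in 1:5)
      X[edges[k, 2], ] <- X[edges[k, 1], ] + rnorm(n, 0, 0.5)
    w <- ensemble_importance(X, n_trees = 300, seed = seed)
    wp <- pmax(w$W, t(w$W))
    labels <- matrix(FALSE, p, p)
    labels[edges] <- TRUE
    labels <- labels | t(labels)
    ut <- upper.tri(wp)
    pos <- wp[ut][labels[ut]]; neg <- wp[ut][!labels[ut]]
    mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
  }, numeric(1))
  expect_gt(mean(aurocs), 0.8)
})

test_that("edge selection symmetrizes by max, drops negative correlation, nests in k", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- 0.9; W["b", "a"] <- 0.2   # strongest pair, but rho < 0
  W["a", "c"] <- 0.6; W["c", "d"] <- 0.5; W["b", "d"] <- 0.3
  rho <- matrix(0.5, 4, 4, dimnames = dimnames(W)); diag(rho) <- 1
  rho["a", "b"] <- rho["b", "a"] <- -0.9
  wm <- structure(list(W = W, rho = rho, genes = letters[1:4]),
                  class = "weight_matrix")
  top2 <- select_edges(wm, "top_k", 2)
  expect_setequal(paste(top2$gene_a, top2$gene_b), c("a c", "c d"))
  expect_false(any(paste(top2$gene_a, top2$gene_b) == "a b"))
  expect_true(all(top2$spearman_rho > 0))
  expect_equal(top2$weight, c(0.6, 0.5))  # max-symmetrized
  # monotone nesting: growing k never removes an edge
  for (k in 1:2) {
    ek <- select_edges(wm, "top_k", k)
    ek1 <- select_edges(wm, "top_k", k + 1)
    expect_true(all(paste(ek$gene_a, ek$gene_b) %in%
                      paste(ek1$gene_a, ek1$gene_b)))
  }
  expect_warning(all_e <- select_edges(wm, "top_k", 50), "keeping all")
  expect_identical(nrow(all_e), 3L)
})

test_that("target-node selection lands closest to the requested graph size", {
  set.seed(52)
  p <- 30
  W <- matrix(runif(p * p), p, p,
              dimnames = list(sprintf("g%02d", 1:p), sprintf("g%02d", 1:p)))
  diag(W) <- 0
  rho <- matrix(0.5, p, p, dimnames = dimnames(W))
  wm <- structure(list(W = W, rho = rho, genes = rownames(W)),
                  class = "weight_matrix")
  for (target in c(5, 12, 20)) {
    sel <- select_edges(wm, "target_nodes", target)
    nodes <- length(unique(c(sel$gene_a, sel$gene_b)))
    # no other k is strictly closer than the chosen one
    gaps <- vapply(seq_len(nrow(select_edges(wm, "top_k", p * (p - 1) / 2))),
                   function(k) {
                     e <- select_edges(wm, "top_k", k)
                     abs(length(unique(c(e$gene_a, e$gene_b))) - target)
                   }, numeric(1))
    expect_equal(abs(nodes - target), min(gaps))
  }
})

test_that("Louvain finds exact communities on closed-form and planted graphs", {
  two_tri <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  lv <- louvain_communities(two_tri, seed = 1)
  expect_equal(lv$Q, 0.5)
  memb <- lv$membership
  expect_identical(unname(memb[c("a", "b", "c")]), rep(memb[["a"]], 3))
  expect_identical(unname(memb[c("d", "e", "f")]), rep(memb[["d"]], 3))
  expect_false(memb[["a"]] == memb[["d"]])

  single <- igraph::make_graph(~ a - b)
  expect_equal(louvain_communities(single, seed = 1)$Q, 0)
  expect_error(louvain_communities(igraph::make_empty_graph(3, directed = FALSE)),
               "empty")

  skip_if_not_installed("mclust")
  aris <- vapply(1:10, function(seed) {
    set.seed(seed + 100)
    g <- igraph::sample_sbm(60, pref.matrix = matrix(c(0.3, 0.01, 0.01, 0.3), 2),
                            block.sizes = c(30, 30))
    igraph::V(g)$name <- sprintf("v%02d", 1:60)
    lv <- louvain_communities(g, seed = seed)
    mclust::adjustedRandIndex(lv$membership, rep(1:2, each = 30))
  }, numeric(1))
  expect_gt(mean(aris), 0.9)
})

test_that("betweenness matches closed forms and the brute-force oracle", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  # hub_sd = 1 here: on a 5-vertex star mean + 2 sd (6.57) exceeds the
  # center's score of 6, so the 2-sd default cannot flag anything
  bh <- betweenness_hubs(star, setNames(rep(1L, 5), igraph::V(star)$name),
                         hub_sd = 1)
  b <- setNames(bh$table$betweenness, bh$table$gene)
  expect_equal(unname(b["hub"]), 6)  # C(4,2) leaf pairs route through it
  expect_true(all(b[paste0("leaf", 1:4)] == 0))
  expect_true(bh$table$is_hub[bh$table$gene == "hub"])

  path3 <- igraph::make_graph(~ a - b, b - c)
  bh2 <- betweenness_hubs(path3, setNames(rep(1L, 3), c("a", "b", "c")))
  expect_equal(bh2$table$betweenness[bh2$table$gene == "b"], 1)

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:20, 1)
    g <- igraph::sample_gnp(n, 0.25)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    bh3 <- betweenness_hubs(g, setNames(rep(1L, n), igraph::V(g)$name))
    got <- setNames(bh3$table$betweenness, bh3$table$gene)
    expect_equal(unname(got[rownames(adj)]), oracle_betweenness(adj),
                 tolerance = 1e-10)
  }
})

test_that("hypergeometric enrichment and BH correction match closed forms", {
  universe <- sprintf("u%02d", 1:20)
  community <- universe[1:5]
  sets <- gene_set_collection(list(hit = universe[1:5],
                                   off = universe[11:15],
                                   partial = universe[4:8]))
  enr <- community_enrichment(community, sets, universe)
  expect_equal(enr$p[enr$set == "hit"], 1 / choose(20, 5))
  expect_equal(enr$p[enr$set == "off"], 1)  # tail includes overlap 0
  expect_identical(enr$overlap[enr$set == "partial"], 2L)
  # BH step-up closed form
  p <- c(0.01, 0.02, 0.03)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.03))
  expect_error(community_enrichment(community, sets, character(0)), "universe")
})

test_that("community matching finds shared modules and rejects disjoint ones", {
  mk_network <- function(blocks, cond) {
    edges <- do.call(rbind, lapply(blocks, function(genes) {
      t(combn(genes, 2))
    }))
    df <- data.frame(gene_a = edges[, 1], gene_b = edges[, 2],
                     weight = 1, spearman_rho = 0.9)
    build_stage_network(df, cond, seed = 1)
  }
  shared <- sprintf("s%02d", 1:8)
  nw1 <- mk_network(list(shared, sprintf("a%02d", 1:6)), "Ta")
  nw2 <- mk_network(list(shared, sprintf("b%02d", 1:6)), "T1")
  m <- match_communities(list(Ta = nw1, T1 = nw2))
  shared_row <- m[which.max(m$n_shared_genes), ]
  expect_identical(shared_row$n_shared_genes, 8L)
  expect_identical(shared_row$n_conditions_matched, 2L)

  # identical partitions match perfectly
  m2 <- match_communities(list(A = nw1, B = nw1))
  expect_true(all(m2$n_conditions_matched == 2))
  # disjoint partitions do not match
  nw3 <- mk_network(list(sprintf("c%02d", 1:6), sprintf("d%02d", 1:6)), "T2")
  m3 <- match_communities(list(A = nw1, B = nw3))
  expect_true(all(is.na(m3$n_shared_genes)))
})
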