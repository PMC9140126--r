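# Per-condition co-expression networks: ensemble importance weights,
# positive-correlation edge selection, Louvain communities, betweenness
# hubs, community enrichment and cross-condition matching.

#' Per-condition pairwise-weight enumeration size
#'
#' The ensemble step computes one directed importance weight for every
#' ordered gene pair (including the self pair, whose weight is fixed at
#' zero), i.e. `n^2` weights per condition.
#'
#' @param n_genes Number of genes entering the network step.
#' @return `n_genes^2`.
#' @export
pair_weight_count <- function(n_genes) as.numeric(n_genes)^2

#' Default node-count target for edge selection
#'
#' The size-targeted edge-selection recipe keeps the resulting graph's
#' gene count close to half the number of input (CDEG) genes.
#'
#' @param n_genes Number of input genes.
#' @return `round(n_genes / 2)`.
#' @export
default_node_target <- function(n_genes) round(n_genes / 2)

#' Ensemble co-expression importance weights
#'
#' For each target gene, a seeded random-forest regression of the
#' target on all other genes is fitted (`mtry = floor(sqrt(p))`,
#' impurity importance); `w(j -> i)` is predictor `j`'s total
#' importance for target `i`, normalized so each target's incoming
#' weights sum to 1. Spearman correlations are computed for all pairs
#' to carry the sign of co-expression.
#'
#' @param mat Gene x sample expression matrix for one condition.
#' @param genes Optional gene subset (default all rows).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed; forests run single-threaded so the same
#'   seed gives an identical weight matrix.
#' @return List of class `weight_matrix`: `W` (directed gene x gene,
#'   `W[j, i]` = weight of regulator j for target i, zero diagonal)
#'   and `rho` (symmetric Spearman matrix).
#' @export
ensemble_importance <- function(mat, genes = rownames(mat),
                                n_trees = 500, seed = 1L) {
  stopifnot(all(genes %in% rownames(mat)))
  X <- t(mat[genes, , drop = FALSE])  # samples x genes
  if (nrow(X) < 10) stop("need >= 10 samples for stable forests")
  p <- ncol(X)
  if (p < 2) stop("need >= 2 genes")
  W <- matrix(0, p, p, dimnames = list(genes, genes))
  mtry <- max(1, floor(sqrt(p - 1)))
  for (i in seq_len(p)) {
    df <- data.frame(y = X[, i], X[, -i, drop = FALSE], check.names = FALSE)
    fit <- ranger::ranger(y ~ ., data = df, num.trees = n_trees,
                          mtry = mtry, importance = "impurity",
                          num.threads = 1, seed = seed + i)
    imp <- fit$variable.importance
    imp[imp < 0] <- 0
    tot <- sum(imp)
    if (tot > 0) W[names(imp), i] <- imp / tot
  }
  rho <- stats::cor(X, method = "spearman")
  structure(list(W = W, rho = rho, genes = genes), class = "weight_matrix")
}

#' Select undirected edges from a weight matrix
#'
#' Directed importances are symmetrized by the maximum,
#' `w_pair(i,j) = max(w(i->j), w(j->i))`; pairs with Spearman
#' `rho <= 0` are discarded. `mode = "top_k"` keeps the `k_or_target`
#' largest pair weights. `mode = "target_nodes"` binary-searches `k`
#' until the node count of the resulting graph is closest to the
#' target (ties resolved toward the smaller `k`).
#'
#' @param weights A `weight_matrix` from [ensemble_importance()].
#' @param mode `"top_k"` or `"target_nodes"`.
#' @param k_or_target Edge count for `"top_k"`; desired node count for
#'   `"target_nodes"` (defaults to [default_node_target()] of the gene
#'   count when `NULL`).
#' @return Data frame with columns `gene_a`, `gene_b`, `weight`,
#'   `spearman_rho`, ordered by decreasing weight. Increasing `k` never
#'   removes an edge.
#' @export
select_edges <- function(weights, mode = c("top_k", "target_nodes"),
                         k_or_target = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(weights, "weight_matrix"))
  g <- weights$genes
  ut <- which(upper.tri(weights$W), arr.ind = TRUE)
  w_pair <- pmax(weights$W[ut], weights$W[ut[, c(2, 1)]])
  rho <- weights$rho[ut]
  keep <- rho > 0 & w_pair > 0
  df <- data.frame(gene_a = g[ut[keep, 1]], gene_b = g[ut[keep, 2]],
                   weight = w_pair[keep], spearman_rho = rho[keep],
                   stringsAsFactors = FALSE)
  ord <- order(-df$weight, df$gene_a, df$gene_b)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (mode == "top_k") {
    k <- k_or_target
    if (is.null(k)) stop("top_k mode needs k_or_target")
    if (k > nrow(df)) {
      warning("k = ", k, " exceeds the ", nrow(df),
              " positive-correlation pairs; keeping all")
      k <- nrow(df)
    }
    return(df[seq_len(k), , drop = FALSE])
  }
  target <- if (is.null(k_or_target)) default_node_target(length(g)) else k_or_target
  nodes_at <- function(k) length(unique(c(df$gene_a[seq_len(k)], df$gene_b[seq_len(k)])))
  lo <- 1L; hi <- nrow(df)
  if (nodes_at(hi) <= target) return(df)
  # smallest k whose node count reaches the target (node count is
  # nondecreasing in k)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (nodes_at(mid) >= target) hi <- mid else lo <- mid + 1L
  }
  cand <- unique(c(max(1L, lo - 1L), lo))
  gap <- vapply(cand, function(k) abs(nodes_at(k) - target), numeric(1))
  k_best <- cand[which.min(gap)]  # which.min takes the first (smaller k) on ties
  df[seq_len(k_best), , drop = FALSE]
}

#' Louvain community detection
#'
#' Greedy weighted-modularity optimization with seeded node-order
#' shuffling; community labels are canonicalized in order of first
#' appearance along the original vertex order (so label 1 contains the
#' first vertex).
#'
#' @param graph Undirected igraph graph with a `weight` edge attribute
#'   (unweighted graphs are treated as weight 1).
#' @param resolution Resolution parameter (default 1.0).
#' @param seed Integer seed for the node shuffle.
#' @return List with `membership` (named integer vector) and `Q`
#'   (final weighted modularity).
#' @export
louvain_communities <- function(graph, resolution = 1.0, seed = 1L) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::ecount(graph) == 0) stop("empty graph")
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  set.seed(seed)
  perm <- sample(igraph::vcount(graph))
  gp <- igraph::permute(graph, perm)
  cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                resolution = resolution)
  memb_p <- igraph::membership(cl)
  memb <- memb_p[perm]  # igraph::permute sends old vertex i to perm[i]
  # canonicalize: relabel in order of first appearance
  memb <- as.integer(factor(memb, levels = unique(memb)))
  names(memb) <- igraph::V(graph)$name
  Q <- igraph::modularity(graph, memb, weights = w, resolution = resolution)
  list(membership = memb, Q = Q)
}

#' Betweenness centrality and hub calls
#'
#' Exact betweenness on the unweighted selected graph (each pair of
#' distinct other vertices counted once). A vertex is flagged as a hub
#' when its betweenness exceeds `mean(b) + hub_sd * sd(b)` over the
#' whole graph; the per-community top-`top_n` vertices are reported
#' alongside so both readings of "default cutoffs" are available.
#'
#' @param graph Undirected igraph graph.
#' @param membership Named community membership (from
#'   [louvain_communities()]).
#' @param hub_sd SD multiplier for the global hub rule (default 2).
#' @param top_n Per-community top list size (default 5).
#' @return List with `table` (data frame gene/community/betweenness/
#'   is_hub) and `top_per_community` (list of character vectors).
#' @export
betweenness_hubs <- function(graph, membership, hub_sd = 2, top_n = 5) {
  b <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  genes <- igraph::V(graph)$name
  memb <- membership[genes]
  thr <- mean(b) + hub_sd * stats::sd(b)
  if (is.na(thr)) thr <- Inf
  tab <- data.frame(gene = genes, community = as.integer(memb),
                    betweenness = unname(b),
                    is_hub = unname(b > thr),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$betweenness), , drop = FALSE]
  rownames(tab) <- NULL
  top <- lapply(split(tab, tab$community), function(d)
    utils::head(d$gene[order(-d$betweenness)], top_n))
  list(table = tab, top_per_community = top, threshold = thr)
}

#' Assemble a per-condition stage network
#'
#' Builds the undirected weighted graph from a selected edge list and
#' attaches the Louvain partition and betweenness scores.
#'
#' @param edges Edge data frame from [select_edges()].
#' @param condition Condition label (e.g. `"T1"`).
#' @param resolution,seed Passed to [louvain_communities()].
#' @return Object of class `stage_network`: `condition`, `graph`,
#'   `membership`, `Q`, `betweenness`, `hubs`.
#' @export
build_stage_network <- function(edges, condition, resolution = 1.0, seed = 1L) {
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  igraph::E(g)$weight <- edges$weight
  igraph::E(g)$spearman_rho <- edges$spearman_rho
  lv <- louvain_communities(g, resolution = resolution, seed = seed)
  hubs <- betweenness_hubs(g, lv$membership)
  btw <- stats::setNames(hubs$table$betweenness, hubs$table$gene)
  structure(list(condition = condition, graph = g,
                 membership = lv$membership, Q = lv$Q,
                 betweenness = btw[igraph::V(g)$name], hubs = hubs),
            class = "stage_network")
}

#' @export
print.stage_network <- function(x, ...) {
  cat("stage_network [", x$condition, "]: ",
      igraph::vcount(x$graph), " genes, ", igraph::ecount(x$graph),
      " edges, ", length(unique(x$membership)), " communities (Q = ",
      signif(x$Q, 3), ")\n", sep = "")
  invisible(x)
}

#' Hypergeometric over-representation of gene sets in a community
#'
#' One-sided hypergeometric tail probability (observed overlap or
#' larger) per set, with Benjamini-Hochberg correction across sets.
#'
#' @param community Character vector of community genes (subset of the
#'   universe).
#' @param sets A `gene_set_collection`.
#' @param universe Character vector of background genes.
#' @return Data frame: `set`, `overlap`, `set_size` (in universe),
#'   `community_size`, `p`, `q`, sorted by `p`.
#' @export
community_enrichment <- function(community, sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(community %in% universe)) stop("community must be within the universe")
  community <- unique(community)
  N <- length(unique(universe))
  k <- length(community)
  rows <- lapply(names(sets$sets), function(nm) {
    s <- intersect(sets$sets[[nm]], universe)
    ov <- length(intersect(s, community))
    p <- stats::phyper(ov - 1, length(s), N - length(s), k, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(s),
               community_size = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match communities across per-condition networks
#'
#' Takes the top communities by gene count in each condition, computes
#' pairwise Jaccard similarities across conditions, and greedily
#' matches them above a similarity threshold, anchored on the first
#' network's top communities. For each matched group, the genes shared
#' across all conditions are counted.
#'
#' @param networks Named list of `stage_network` objects (>= 2).
#' @param top_n Number of largest communities per condition (default 5).
#' @param threshold Minimum Jaccard similarity for a match (default
#'   0.2).
#' @return Data frame: one row per anchor community with a column per
#'   condition (matched community ID or NA), `n_conditions_matched`,
#'   and `n_shared_genes` (genes present in the matched community of
#'   every condition).
#' @export
match_communities <- function(networks, top_n = 5, threshold = 0.2) {
  stopifnot(length(networks) >= 2)
  if (is.null(names(networks)))
    names(networks) <- vapply(networks, `[[`, character(1), "condition")
  top_comms <- lapply(networks, function(nw) {
    sizes <- sort(table(nw$membership), decreasing = TRUE)
    ids <- as.integer(names(sizes))[seq_len(min(top_n, length(sizes)))]
    lapply(stats::setNames(ids, paste0("C", ids)), function(id)
      names(nw$membership)[nw$membership == id])
  })
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  anchor <- top_comms[[1]]
  rows <- lapply(names(anchor), function(aid) {
    genes_a <- anchor[[aid]]
    matched <- stats::setNames(rep(NA_character_, length(networks)), names(networks))
    matched[1] <- aid
    shared <- genes_a
    for (cn in names(networks)[-1]) {
      sims <- vapply(top_comms[[cn]], jaccard, numeric(1), b = genes_a)
      if (length(sims) && max(sims) >= threshold) {
        best <- names(sims)[which.max(sims)]
        matched[cn] <- best
        shared <- intersect(shared, top_comms[[cn]][[best]])
      }
    }
    n_matched <- sum(!is.na(matched))
    data.frame(anchor = aid, t(matched),
               n_conditions_matched = n_matched,
               n_shared_genes = if (n_matched == length(networks))
                 length(shared) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
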