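# Independent oracles used by the unit and acceptance tests. These are
# deliberately written from the definitions (pair counting, BFS path
# counting, literal filter enumeration) and share no code with the
# package implementations they check.

# Two-sided Mann-Whitney p by full enumeration of group labelings,
# counting U directly from value pairs (x > y plus half-ties).
oracle_mw_exact <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  U_obs <- u_of(x, y)
  mid <- m * n / 2
  idx <- utils::combn(m + n, m)
  U_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(U_all - mid) >= abs(U_obs - mid) - 1e-12)
}

# Monte Carlo permutation p for the Mann-Whitney U.
oracle_mw_perm <- function(x, y, n_perm = 10000, seed = 1) {
  set.seed(seed)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  m <- length(x)
  pooled <- c(x, y)
  U_obs <- u_of(x, y)
  mid <- m * length(y) / 2
  U_all <- replicate(n_perm, {
    i <- sample(length(pooled), m)
    u_of(pooled[i], pooled[-i])
  })
  mean(abs(U_all - mid) >= abs(U_obs - mid) - 1e-12)
}

# Exact betweenness by all-pairs shortest-path counting over BFS
# distance/path-count tables computed from the adjacency matrix.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); cnt <- rep(0, n)
    d[s] <- 0; cnt[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) for (v in which(adj[u, ] > 0)) {
        if (is.infinite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
        if (d[v] == d[u] + 1) cnt[v] <- cnt[v] + cnt[u]
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d; nsp[s, ] <- cnt
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (dist[s, v] + dist[v, t] == dist[s, t])
        b[v] <- b[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
    }
  }
  b
}

# Literal enumeration of the CDEG + strict-monotonicity definition from
# a long differential table.
oracle_monotone <- function(tab, alpha = 0.05) {
  stages <- c("Ta", "T1", "T2", "T3", "T4")
  out <- character()
  for (g in unique(tab$gene)) {
    d <- tab[tab$gene == g, ]
    d <- d[match(stages, d$stage), ]
    if (any(is.na(d$p))) next
    if (!all(d$p < alpha)) next
    fc <- d$fc
    if (all(fc > 0) && all(diff(fc) > 0)) out[g] <- "up"
    else if (all(fc < 0) && all(diff(fc) < 0)) out[g] <- "down"
  }
  out
}

# Direct-summation ssGSEA walk for one sample and one set, written
# from the running-sum definition step by step.
oracle_ssgsea_one <- function(expr, members, alpha = 0.25) {
  r <- rank(expr)
  ord <- names(sort(expr, decreasing = TRUE))
  num <- 0; cdf_in <- 0; cdf_out <- 0
  denom <- sum(r[ord[ord %in% members]]^alpha)
  n_out <- sum(!ord %in% members)
  walk <- 0
  diffs <- numeric(length(ord))
  for (i in seq_along(ord)) {
    g <- ord[i]
    if (g %in% members) cdf_in <- cdf_in + r[g]^alpha / denom
    else cdf_out <- cdf_out + 1 / n_out
    diffs[i] <- cdf_in - cdf_out
    walk <- c(walk, walk[length(walk)] + diffs[i])
  }
  sum(diffs) / (max(walk) - min(walk))
}

# Small deterministic staged cohort for I/O-light tests.
tiny_cohort <- function(seed = 11, n_per_stage = 6, n_genes = 40,
                        n_up = 4, n_down = 3, step = 1.5, noise_sd = 0.6,
                        n_batches = 2) {
  cfg <- simulation_config(n_per_stage = n_per_stage, n_genes = n_genes,
                           n_monotone_up = n_up, n_monotone_down = n_down,
                           step = step, noise_sd = noise_sd,
                           n_batches = n_batches, batch_shift_sd = 0.3,
                           seed = seed)
  list(cfg = cfg, sim = simulate_cohort(cfg))
}
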