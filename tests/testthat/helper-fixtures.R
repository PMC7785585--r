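# Shared fixtures and independent brute-force oracles used across tests.

four_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# random count table, Poisson-ish, with guaranteed non-empty samples
random_table <- function(n_samples, n_otus, seed, lambda = 5,
                         ids = paste0("OTU_", seq_len(n_otus))) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(paste0("s", seq_len(n_samples)), ids))
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  as_otu_table(m)
}

# Bray-Curtis from the definition, one pair at a time
brute_bray <- function(x, y) {
  if (sum(x) + sum(y) == 0) return(0)
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# beta mean nearest taxon distance by explicit double loop over tip pairs
brute_bmntd <- function(table, tree, weighted = TRUE) {
  D <- ape::cophenetic.phylo(tree)[colnames(table), colnames(table)]
  n <- nrow(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (k in seq_len(n - 1)) {
    for (m in (k + 1):n) {
      pk <- which(table[k, ] > 0)
      pm <- which(table[m, ] > 0)
      fk <- if (weighted) table[k, pk] / sum(table[k, ]) else
        rep(1 / length(pk), length(pk))
      fm <- if (weighted) table[m, pm] / sum(table[m, ]) else
        rep(1 / length(pm), length(pm))
      s1 <- 0
      for (a in seq_along(pk)) {
        best <- Inf
        for (b in seq_along(pm)) best <- min(best, D[pk[a], pm[b]])
        s1 <- s1 + fk[a] * best
      }
      s2 <- 0
      for (b in seq_along(pm)) {
        best <- Inf
        for (a in seq_along(pk)) best <- min(best, D[pm[b], pk[a]])
        s2 <- s2 + fm[b] * best
      }
      out[k, m] <- out[m, k] <- 0.5 * (s1 + s2)
    }
  }
  out
}

# all-pairs shortest paths by Floyd-Warshall on an unweighted adjacency
brute_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# topology metrics from first principles on an adjacency matrix
brute_topology <- function(adj, signs) {
  n <- nrow(adj)
  e <- sum(adj[lower.tri(adj)])
  deg <- rowSums(adj)
  d <- brute_shortest_paths(adj)
  # largest connected component
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[is.finite(d[i, ])] <- cid
    }
  }
  giant <- which(comp == which.max(tabulate(comp)))
  dg <- d[giant, giant, drop = FALSE]
  finite_off <- dg[upper.tri(dg)]
  local_cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    links <- sum(adj[nb, nb][lower.tri(adj[nb, nb])])
    links / choose(length(nb), 2)
  }, numeric(1))
  list(nodes = n, edges = e,
       average_degree = 2 * e / n,
       density = 2 * e / (n * (n - 1)),
       diameter = if (length(finite_off)) max(finite_off) else 0,
       average_path_length = if (length(finite_off)) mean(finite_off) else 0,
       average_clustering = mean(local_cc),
       percent_positive = 100 * sum(signs > 0) / e)
}

# random connected-ish graph as a correlation + p matrix pair
random_graph_matrices <- function(n_nodes, seed, p_edge = 0.35) {
  set.seed(seed)
  ids <- paste0("OTU_", seq_len(n_nodes))
  r <- matrix(0, n_nodes, n_nodes, dimnames = list(ids, ids))
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) {
        r[i, j] <- r[j, i] <- runif(1, 0.45, 0.95) * sample(c(-1, 1), 1)
      }
    }
  }
  diag(r) <- 1
  p <- matrix(0.001, n_nodes, n_nodes, dimnames = dimnames(r))
  diag(p) <- NA_real_
  list(r = r, p = p)
}
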