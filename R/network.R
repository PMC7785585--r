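# Compositionality-robust co-occurrence networks: SparCC correlation
# estimation with Dirichlet fraction draws and iterative strong-pair
# exclusion, permutation pseudo p-values, Benjamini-Hochberg FDR, network
# construction at |r| and p thresholds, and topology/edge-sign summaries.

#' Filter OTUs by total count
#'
#' Keeps OTUs represented by strictly more than `min_total` reads across
#' the table's samples (so `min_total = 20` keeps totals of 21 and above).
#'
#' @param table OTU table (samples x OTUs).
#' @param min_total minimum total count (exclusive).
#' @return filtered OTU table; the sample set is unchanged.
#' @export
filter_min_count <- function(table, min_total = 20) {
  table <- as_otu_table(table)
  stopifnot(min_total >= 0)
  keep <- colSums(table) > min_total
  if (!any(keep))
    stop("no OTU exceeds ", min_total, " total reads; lower the threshold")
  table[, keep, drop = FALSE]
}

#' SparCC correlation estimation for compositional counts
#'
#' Counts are converted to fractions by Dirichlet draws (unit pseudocount);
#' for each draw, pairwise log-ratio variances
#' `t_ij = var(log(x_i / x_j))` are computed, basis variances `w_i^2` are
#' solved under the sparsity assumption (correlations sum to about zero),
#' and `r_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`, clipped to `[-1, 1]`.
#' The most strongly correlated pair above `exclusion_threshold` is
#' excluded and the system re-solved, for up to `n_iterations` rounds; the
#' final estimate is the average over `n_dirichlet` draws.
#'
#' The working exclusion threshold is floored at the estimator's own
#' sampling noise, `2 * sqrt(2 / (n_samples - 1))` (about two standard
#' errors of a log-ratio variance), so that at small sample counts noise
#' pairs are not excluded — excluding them truncates the noise
#' distribution and biases the remaining basis variances. Exclusion also
#' stops as soon as removing the top pair no longer shrinks the strongest
#' remaining correlation.
#'
#' @param table OTU count table (samples x OTUs), >= 4 OTUs.
#' @param n_iterations exclusion rounds per draw.
#' @param exclusion_threshold |r| above which the strongest pair is
#'   excluded from the basis-variance system.
#' @param n_dirichlet number of posterior fraction draws averaged over.
#' @param seed integer seed.
#' @return symmetric correlation matrix with unit diagonal (OTU x OTU).
#' @export
sparcc <- function(table, n_iterations = 20, exclusion_threshold = 0.1,
                   n_dirichlet = 20, seed = 1) {
  table <- as_otu_table(table)
  D <- ncol(table)
  if (D < 4) stop("SparCC needs at least 4 OTUs (basis system underdetermined)")
  if (nrow(table) < 2) stop("SparCC needs multiple samples")
  set.seed(seed)
  thr <- max(exclusion_threshold, 2 * sqrt(2 / (nrow(table) - 1)))
  acc <- matrix(0, D, D)
  for (k in seq_len(n_dirichlet)) {
    frac <- dirichlet_fractions(table)
    acc <- acc + sparcc_once(log(frac), n_iterations, thr)
  }
  r <- acc / n_dirichlet
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(colnames(table), colnames(table))
  r
}

# one Dirichlet(counts + 1) fraction draw per sample
dirichlet_fractions <- function(table) {
  g <- matrix(rgamma(length(table), shape = as.numeric(table) + 1),
              nrow(table), ncol(table))
  g / rowSums(g)
}

sparcc_once <- function(L, n_iterations, exclusion_threshold) {
  D <- ncol(L)
  V <- cov(L)
  Tm <- outer(diag(V), diag(V), "+") - 2 * V  # log-ratio variances
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  excluded <- matrix(FALSE, D, D)
  Texc <- Tm
  solve_r <- function() {
    tvec <- rowSums(Texc * !excluded) - diag(Texc)
    w2 <- tryCatch(solve(M, tvec), error = function(e) rep(NA_real_, D))
    w2 <- pmax(w2, 1e-10)  # clip non-positive basis variances
    w <- sqrt(w2)
    r <- (outer(w2, w2, "+") - Tm) / (2 * outer(w, w))
    pmin(pmax(r, -1), 1)
  }
  offmax <- function(r, excluded) {
    cand <- abs(r)
    diag(cand) <- 0
    cand[excluded] <- 0
    max(cand)
  }
  r <- solve_r()
  for (it in seq_len(n_iterations)) {
    mx <- offmax(r, excluded)
    if (mx <= exclusion_threshold) break
    ij <- which(abs(r) == mx & !excluded, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    # guard: keep every OTU in at least 3 pairs
    if (sum(!excluded[i, ]) - 2 < 3 || sum(!excluded[j, ]) - 2 < 3) break
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[j, i] <- 0
    r_new <- solve_r()
    # exclusion is only warranted while it shrinks the strongest remaining
    # correlation; once removing the top pair inflates the rest we are
    # truncating noise, not isolating signal, so roll back and stop
    if (offmax(r_new, excluded) >= mx) {
      excluded[i, j] <- excluded[j, i] <- FALSE
      M[i, i] <- M[i, i] + 1
      M[j, j] <- M[j, j] + 1
      M[i, j] <- M[j, i] <- 1
      break
    }
    r <- r_new
  }
  r
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' The null resamples the table `n_boot` times — by default shuffling each
#' OTU's counts across samples independently (destroying all correlation
#' while preserving marginals), optionally by resampling samples with
#' replacement — and recomputes the SparCC matrix each time. Two-sided
#' pseudo p-value per pair: `(#(|r_null| >= |r_obs|) + 1) / (n_boot + 1)`.
#'
#' @param table OTU count table used for `observed_r`.
#' @param observed_r SparCC correlation matrix from [sparcc()].
#' @param n_boot number of null datasets (>= 99).
#' @param seed integer seed.
#' @param method `"shuffle"` (default) or `"resample"`.
#' @param ... passed to [sparcc()] (iteration/draw settings).
#' @return symmetric matrix of p-values in `(0, 1]` with `NA` diagonal.
#' @export
bootstrap_pvalues <- function(table, observed_r, n_boot = 100, seed = 1,
                              method = c("shuffle", "resample"), ...) {
  method <- match.arg(method)
  table <- as_otu_table(table)
  if (n_boot < 99) stop("n_boot must be >= 99")
  stopifnot(identical(colnames(table), rownames(observed_r)))
  n <- nrow(table)
  exceed <- matrix(0, ncol(table), ncol(table))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    null_tab <- if (method == "shuffle") {
      apply(table, 2, function(col) col[sample.int(n)])
    } else {
      table[sample.int(n, n, replace = TRUE), , drop = FALSE]
    }
    rownames(null_tab) <- rownames(table)
    r_null <- sparcc(as_otu_table(null_tab), seed = sample.int(2^30, 1), ...)
    exceed <- exceed + (abs(r_null) >= abs(observed_r))
  }
  p <- (exceed + 1) / (n_boot + 1)
  p <- (p + t(p)) / 2
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed_r)
  p
}

#' Benjamini-Hochberg adjustment over unique OTU pairs
#'
#' The step-up adjustment is applied to the `m = N(N-1)/2` unique
#' off-diagonal p-values and written back symmetrically.
#'
#' @param p symmetric p-value matrix.
#' @return matrix of BH-adjusted p-values.
#' @export
fdr_bh <- function(p) {
  stopifnot(nrow(p) == ncol(p))
  lt <- lower.tri(p)
  adj <- p
  adj[lt] <- p.adjust(p[lt], method = "BH")
  adj[upper.tri(adj)] <- t(adj)[upper.tri(adj)]
  adj
}

#' Build a signed co-occurrence network from thresholded correlations
#'
#' An edge joins two OTUs iff `|r| > r_threshold` and
#' `p < p_threshold` (both strict). Isolated nodes are dropped, so the node
#' count equals the number of OTUs with at least one edge.
#'
#' @param r correlation matrix.
#' @param p_adj (adjusted) p-value matrix over the same OTUs.
#' @param r_threshold correlation magnitude threshold (exclusive).
#' @param p_threshold significance threshold (exclusive).
#' @return an [igraph::graph] with edge attributes `r`, `p`, `sign`.
#' @export
build_network <- function(r, p_adj, r_threshold = 0.4, p_threshold = 0.01) {
  stopifnot(identical(dim(r), dim(p_adj)),
            r_threshold > 0, r_threshold < 1,
            p_threshold > 0, p_threshold < 1)
  ids <- rownames(r)
  sel <- which(lower.tri(r) & abs(r) > r_threshold & p_adj < p_threshold,
               arr.ind = TRUE)
  if (nrow(sel) == 0) {
    warning("no edges pass the thresholds; returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  edges <- data.frame(from = ids[sel[, 2]], to = ids[sel[, 1]],
                      r = r[sel], p = p_adj[sel],
                      sign = ifelse(r[sel] > 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Topology summary of a co-occurrence network
#'
#' Average degree `2E/N`, density `2E/(N(N-1))`, diameter and average path
#' length on the largest connected component (unweighted shortest paths),
#' average local clustering coefficient (isolated/degree-1 nodes count 0),
#' modularity from seeded Louvain community detection on `|r|` weights, and
#' the percentage of positive edges.
#'
#' @param net igraph network from [build_network()].
#' @param modularity_seed seed for the community detection.
#' @return one-row data.frame of topology metrics.
#' @export
topology_metrics <- function(net, modularity_seed = 1) {
  N <- igraph::vcount(net)
  E <- igraph::ecount(net)
  if (N == 0 || E == 0) stop("network is empty")
  comps <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comps$membership == which.max(comps$csize)))
  set.seed(modularity_seed)
  cl <- igraph::cluster_louvain(net, weights = abs(igraph::E(net)$r))
  data.frame(
    nodes = N, edges = E,
    average_degree = 2 * E / N,
    density = 2 * E / (N * (N - 1)),
    diameter = igraph::diameter(giant, weights = NA),
    average_path_length = igraph::mean_distance(giant, weights = NA),
    average_clustering = igraph::transitivity(net, type = "localaverage",
                                              isolates = "zero"),
    modularity = igraph::modularity(cl),
    percent_positive = 100 * sum(igraph::E(net)$sign > 0) / E)
}

#' Percentage of positive edges between taxon groups
#'
#' For each requested group pair, the percentage of positive edges among
#' all edges joining the two groups; pairs with no inter-group edges are
#' flagged (`NA`), not reported as 0.
#'
#' @param net igraph network whose vertex names are OTU ids.
#' @param tax taxonomy data.frame covering the network's OTUs.
#' @param group_pairs list of 2-vectors of taxon-group names.
#' @param rank lineage rank at which groups are resolved.
#' @return data.frame: `group_a`, `group_b`, `n_edges`, `percent_positive`.
#' @export
edge_sign_summary <- function(net, tax, group_pairs, rank = 2) {
  ids <- igraph::V(net)$name
  grp <- taxon_at_rank(tax$lineage[match(ids, tax$otu_id)], rank)
  names(grp) <- ids
  available <- sort(unique(grp))
  el <- igraph::as_data_frame(net, what = "edges")
  out <- lapply(group_pairs, function(pr) {
    stopifnot(length(pr) == 2)
    unknown <- setdiff(pr, available)
    if (length(unknown) > 0)
      stop("unknown taxon group(s): ", paste(unknown, collapse = ", "),
           "; available: ", paste(available, collapse = ", "))
    ga <- grp[el$from]
    gb <- grp[el$to]
    inter <- (ga == pr[1] & gb == pr[2]) | (ga == pr[2] & gb == pr[1])
    n <- sum(inter)
    data.frame(group_a = pr[1], group_b = pr[2], n_edges = n,
               percent_positive = if (n == 0) NA_real_
                                  else 100 * sum(el$sign[inter] > 0) / n)
  })
  do.call(rbind, out)
}

#' Write a network's edge list as TSV
#'
#' @param net igraph network.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("source", "target")
  write_tsv_exact(el, path)
}
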