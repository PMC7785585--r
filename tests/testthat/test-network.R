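test_that("count filter keeps OTUs strictly above the threshold", {
  tab <- as_otu_table(matrix(c(10L, 10L, 11L, 0L,
                               10L, 10L, 10L, 0L), 2, 4, byrow = TRUE,
                             dimnames = list(c("a", "b"),
                                             c("O20", "O20b", "O21", "O0"))))
  f <- filter_min_count(tab, 20)
  expect_identical(colnames(f), "O21")
  expect_identical(rownames(f), rownames(tab))
  f0 <- filter_min_count(tab, 0)
  expect_setequal(colnames(f0), c("O20", "O20b", "O21"))
  expect_error(filter_min_count(tab, 1000), "threshold")
})

test_that("SparCC output is a unit-diagonal symmetric correlation matrix", {
  tab <- simulate_compositional(diag(8), 40, 2000, seed = 11)
  r <- sparcc(tab, seed = 2)
  expect_true(all(diag(r) == 1))
  expect_lt(max(abs(r - t(r))), 1e-12)
  expect_true(all(abs(r) <= 1))
  expect_identical(r, sparcc(tab, seed = 2))
  expect_error(sparcc(tab[, 1:3]), "at least 4")
})

test_that("SparCC is invariant to per-sample count scaling", {
  basis <- diag(10)
  basis[1, 2] <- basis[2, 1] <- 0.7
  tab <- simulate_compositional(basis, 60, 5000, seed = 12)
  scaled <- tab
  scaled[1:10, ] <- scaled[1:10, ] * 10L
  r1 <- sparcc(tab, seed = 3)
  r2 <- sparcc(as_otu_table(scaled), seed = 3)
  expect_lt(max(abs(r1 - r2)), 0.02)
})

test_that("bootstrap p-values respect the floor and detect planted signal", {
  basis <- diag(8)
  basis[1, 2] <- basis[2, 1] <- 0.8
  tab <- simulate_compositional(basis, 100, 5000, seed = 13)
  r <- sparcc(tab, seed = 4)
  p <- bootstrap_pvalues(tab, r, n_boot = 99, seed = 5)
  expect_true(all(p[lower.tri(p)] >= 1 / 100))
  expect_equal(p[1, 2], 1 / 100)
  expect_lt(max(abs(p - t(p)), na.rm = TRUE), 1e-12)
})

test_that("BH adjustment matches the hand-worked step-up example", {
  ids <- paste0("O", 1:4)
  # place (0.01, 0.02, 0.03, 0.04) plus padding in a 4x4 matrix: m = 6 pairs
  p <- matrix(1, 4, 4, dimnames = list(ids, ids))
  single <- matrix(c(NA, 0.03, 0.03, NA), 2, 2,
                   dimnames = list(ids[1:2], ids[1:2]))
  expect_equal(fdr_bh(single)[1, 2], 0.03)
  p4 <- p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH")
  expect_equal(p4, rep(0.04, 4))
  for (s in 1:5) {
    set.seed(s)
    raw <- matrix(runif(36), 6, 6)
    raw <- (raw + t(raw)) / 2
    adj <- fdr_bh(raw)
    expect_true(all(adj[lower.tri(adj)] >= raw[lower.tri(raw)] - 1e-12))
    expect_lt(max(abs(adj - t(adj))), 1e-12)
  }
})

test_that("network construction applies strict thresholds and drops isolates", {
  ids <- paste0("O", 1:4)
  r <- diag(4); dimnames(r) <- list(ids, ids)
  p <- matrix(1, 4, 4, dimnames = list(ids, ids))
  r[1, 2] <- r[2, 1] <- 0.41; p[1, 2] <- p[2, 1] <- 0.005
  r[1, 3] <- r[3, 1] <- 0.39; p[1, 3] <- p[3, 1] <- 0.005
  r[1, 4] <- r[4, 1] <- -0.41; p[1, 4] <- p[4, 1] <- 0.02
  net <- build_network(r, p)
  expect_equal(igraph::ecount(net), 1)
  expect_setequal(igraph::V(net)$name, c("O1", "O2"))
  expect_equal(igraph::E(net)$sign, 1L)
  p[] <- 1
  expect_warning(empty <- build_network(r, p), "no edges")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("topology metrics match closed forms and a brute-force oracle", {
  tri <- igraph::make_ring(3)
  igraph::E(tri)$r <- 0.5
  igraph::E(tri)$sign <- 1L
  igraph::V(tri)$name <- paste0("O", 1:3)
  m <- topology_metrics(tri, modularity_seed = 1)
  expect_equal(m$density, 1)
  expect_equal(m$average_clustering, 1)
  expect_equal(m$diameter, 1)
  expect_equal(m$average_path_length, 1)
  path4 <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
               r = c(0.5, -0.5, 0.5), sign = c(1L, -1L, 1L)),
    directed = FALSE)
  m4 <- topology_metrics(path4, modularity_seed = 1)
  expect_equal(m4$diameter, 3)
  expect_equal(m4$density, 0.5)
  expect_equal(m4$average_path_length, 10 / 6)
  for (s in 1:10) {
    gm <- random_graph_matrices(sample(5:10, 1), seed = 600 + s)
    net <- tryCatch(build_network(gm$r, gm$p), warning = function(w) NULL)
    if (is.null(net)) next
    got <- topology_metrics(net, modularity_seed = 2)
    ids <- igraph::V(net)$name
    adj <- (abs(gm$r[ids, ids]) > 0.4) * 1
    diag(adj) <- 0
    signs <- sign(gm$r[ids, ids][lower.tri(gm$r[ids, ids])][
      adj[lower.tri(adj)] > 0])
    want <- brute_topology(adj, signs)
    for (f in c("nodes", "edges", "average_degree", "density", "diameter",
                "average_path_length", "average_clustering",
                "percent_positive")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10, label = f)
    }
  }
})

test_that("edge-sign summaries count inter-group positives correctly", {
  ids <- paste0("O", 1:6)
  r <- diag(6); dimnames(r) <- list(ids, ids)
  p <- matrix(0.001, 6, 6, dimnames = list(ids, ids))
  # O1-O3 group X, O4-O6 group Y; 3 positive + 1 negative X-Y edges
  r[1, 4] <- r[4, 1] <- 0.8
  r[2, 5] <- r[5, 2] <- 0.7
  r[3, 6] <- r[6, 3] <- 0.6
  r[1, 5] <- r[5, 1] <- -0.6
  r[2, 3] <- r[3, 2] <- 0.9  # within-group, ignored
  net <- build_network(r, p)
  tax <- data.frame(otu_id = ids,
                    lineage = rep(c("SG;X", "SG;Y"), each = 3))
  es <- edge_sign_summary(net, tax, list(c("X", "Y")), rank = 2)
  expect_equal(es$percent_positive, 75)
  expect_equal(es$n_edges, 4)
  es2 <- edge_sign_summary(net, tax, list(c("X", "X")), rank = 2)
  expect_equal(es2$n_edges, 1)
  expect_error(edge_sign_summary(net, tax, list(c("X", "Zeta")), rank = 2),
               "available")
})
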