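test_that("rarefaction subsamples to exact depth and drops shallow samples", {
  tab <- random_table(5, 10, seed = 1, lambda = 20)
  depth <- min(rowSums(tab))
  r <- rarefy_table(tab, depth, seed = 1)
  expect_true(all(rowSums(r) == depth))
  expect_identical(colnames(r), colnames(tab))
  # sample at exactly depth is returned unchanged
  i <- which.min(rowSums(tab))
  expect_identical(r[i, ], tab[i, ])
  shallow <- tab; shallow[1, ] <- 0L; shallow[1, 1] <- 3L
  expect_warning(r2 <- rarefy_table(shallow, depth, seed = 1), "dropping")
  expect_equal(nrow(r2), 4)
  single <- as_otu_table(matrix(c(100L, 0L), 1, 2,
                                dimnames = list("s1", c("A", "B"))))
  expect_equal(unname(rarefy_table(single, 10, seed = 1)[1, "A"]), 10L)
  expect_error(rarefy_table(tab, 0), "positive")
})

test_that("rarefaction preserves expected per-OTU proportions", {
  tab <- as_otu_table(matrix(c(60L, 30L, 10L), 1, 3,
                             dimnames = list("s1", c("A", "B", "C"))))
  draws <- t(vapply(1:1000, function(s) rarefy_table(tab, 20, seed = s)[1, ],
                    integer(3)))
  expected <- 20 * c(60, 30, 10) / 100
  # s.e. of the mean of 1000 hypergeometric draws
  v <- apply(draws, 2, var) / 1000
  expect_true(all(abs(colMeans(draws) - expected) < 3 * sqrt(v) + 1e-9))
})

test_that("alpha diversity matches closed forms and the rooted-PD convention", {
  tree <- four_tip_tree()
  tab <- as_otu_table(matrix(c(5L, 5L, 5L, 5L,
                               1L, 1L, 2L, 0L,
                               2L, 3L, 0L, 0L), 3, 4, byrow = TRUE,
                             dimnames = list(c("u", "v", "w"),
                                             c("A", "B", "C", "D"))))
  a <- alpha_diversity(tab, tree)
  expect_equal(a$shannon[1], 2)                   # uniform over 4 OTUs
  expect_equal(a$shannon[2], 1.5)                 # counts (1,1,2)
  expect_equal(a$pd[1], sum(tree$edge.length))    # all tips present
  expect_equal(a$pd[3], 3)                        # {A,B}: two tips + stem
  expect_equal(a$richness, c(4L, 3L, 2L))
})

test_that("PD equals total branch length when all tips are present, on random trees", {
  for (s in 1:50) {
    tr <- simulate_tree(sample(5:40, 1), seed = s)
    tab <- as_otu_table(matrix(1L, 1, length(tr$tip.label),
                               dimnames = list("s1", tr$tip.label)))
    expect_equal(alpha_diversity(tab, tr)$pd, sum(tr$edge.length),
                 tolerance = 1e-10)
  }
})

test_that("PD is monotone under adding tips and Shannon is maximal at uniformity", {
  tree <- simulate_tree(20, seed = 8)
  set.seed(9)
  for (rep in 1:20) {
    pres <- sample(20, sample(2:18, 1))
    extra <- sample(setdiff(1:20, pres), 1)
    m <- matrix(0L, 2, 20, dimnames = list(c("a", "b"), tree$tip.label))
    m[1, pres] <- 1L
    m[2, c(pres, extra)] <- 1L
    a <- alpha_diversity(as_otu_table(m), tree)
    expect_gte(a$pd[2], a$pd[1])
  }
  for (rep in 1:20) {
    k <- sample(3:10, 1)
    counts <- as.integer(sample(1:50, k, replace = TRUE))
    m <- matrix(0L, 2, k, dimnames = list(c("a", "b"), paste0("O", 1:k)))
    m[1, ] <- counts
    m[2, ] <- 10L
    a <- alpha_diversity(as_otu_table(m), tree = NULL)
    expect_lte(a$shannon[1], a$shannon[2] + 1e-12)
  }
})

test_that("Bray-Curtis matches its definition and stays in [0,1]", {
  x <- as_otu_table(matrix(c(10L, 0L, 6L, 6L, 4L, 0L), 2, 3, byrow = TRUE,
                           dimnames = list(c("a", "b"), c("O1", "O2", "O3"))))
  expect_equal(bray_curtis(x)["a", "b"], 7 / 13, tolerance = 1e-12)
  same <- as_otu_table(matrix(c(3L, 1L, 3L, 1L), 2, 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("O1", "O2"))))
  expect_equal(bray_curtis(same)["a", "b"], 0)
  disj <- as_otu_table(matrix(c(3L, 0L, 0L, 2L), 2, 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("O1", "O2"))))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  for (s in 1:20) {
    tab <- random_table(5, 8, seed = 100 + s, lambda = 2)
    bc <- bray_curtis(tab)
    expect_true(all(bc >= 0 & bc <= 1))
    expect_equal(bc["s1", "s3"], brute_bray(tab["s1", ], tab["s3", ]),
                 tolerance = 1e-12)
  }
})

test_that("unweighted UniFrac matches hand-worked cases and picante", {
  tree <- four_tip_tree()
  tab <- as_otu_table(matrix(c(1L, 1L, 0L, 0L,
                               0L, 0L, 1L, 1L,
                               1L, 1L, 1L, 0L,
                               1L, 1L, 0L, 1L), 4, 4, byrow = TRUE,
                             dimnames = list(paste0("x", 1:4),
                                             c("A", "B", "C", "D"))))
  uf <- unweighted_unifrac(tab, tree)
  expect_equal(uf["x1", "x2"], 1)
  expect_equal(uf["x3", "x4"], 1 / 3, tolerance = 1e-12)
  expect_equal(uf["x1", "x1"], 0)
  tr <- simulate_tree(12, seed = 3)
  tab2 <- random_table(5, 12, seed = 4, lambda = 1, ids = tr$tip.label)
  uf2 <- unweighted_unifrac(tab2, tr)
  ref <- as.matrix(picante::unifrac(tab2, tr))
  expect_equal(uf2[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("PCoA reproduces Euclidean geometry and orders eigenvalues", {
  set.seed(5)
  pts <- matrix(rnorm(8), 4, 2)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("s", 1:4), paste0("s", 1:4))
  ord <- pcoa_ordination(dm)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(dm), tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  dm5 <- rbind(cbind(dm, s5 = dm[, 1]), s5 = c(dm[1, ], 0))
  ord5 <- pcoa_ordination(as_distance_matrix(dm5, tol = 1e-9))
  expect_equal(unname(ord5$coordinates["s5", ]),
               unname(ord5$coordinates["s1", ]), tolerance = 1e-9)
  expect_error(pcoa_ordination(dm[1:2, 1:2]), "three")
})
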