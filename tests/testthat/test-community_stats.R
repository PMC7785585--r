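toy_meta <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = paste0("s", 1:n), site = "Z1",
             latitude = runif(n, 23, 24), longitude = runif(n, 117, 118),
             water_depth = runif(n, 5, 30), sediment_depth = 1,
             bottom_temperature = runif(n, 26, 30),
             bottom_salinity = runif(n, 32, 34),
             As = 1, Cd = 1, Cr = 1, Cu = 1, Hg = 1, Pb = 1, Zn = 1,
             clay = 20, silt = 60, sand = 20)
}

test_that("Spearman screen is rank-invariant and matches the midrank formula", {
  meta <- toy_meta(10)
  meta$x <- 1:10
  r1 <- spearman_screen(data.frame(resp = exp(meta$x)), meta, "x")
  expect_equal(r1$spearman_r, 1)
  r2 <- spearman_screen(data.frame(resp = -meta$x), meta, "x")
  expect_equal(r2$spearman_r, -1)
  meta4 <- toy_meta(5)
  meta4$x <- c(1, 2, 3, 4, 5)
  scr <- spearman_screen(data.frame(resp = c(1, 3, 2, 4, 5)), meta4, "x")
  expect_equal(scr$spearman_r, 0.9, tolerance = 1e-12)
  meta$const <- 1
  flag <- spearman_screen(data.frame(resp = meta$x), meta, "const")
  expect_true(flag$flagged_constant)
  expect_true(is.na(flag$spearman_r))
})

test_that("environmental distance is standardized Euclidean and scale-invariant", {
  meta <- toy_meta(6, seed = 2)
  d1 <- env_distance(meta, c("water_depth", "bottom_temperature"))
  meta2 <- meta
  meta2$water_depth <- meta2$water_depth * 1000
  d2 <- env_distance(meta2, c("water_depth", "bottom_temperature"))
  expect_equal(d1, d2, tolerance = 1e-9)
  same <- meta
  same$water_depth <- 5
  same$bottom_temperature <- 20
  same$bottom_salinity <- meta$bottom_salinity
  expect_warning(
    d3 <- env_distance(same, c("water_depth", "bottom_salinity")),
    "zero-variance")
  expect_equal(unname(d3["s1", "s2"]),
               abs(scale(same$bottom_salinity)[1] - scale(same$bottom_salinity)[2]),
               tolerance = 1e-9)
})

test_that("geographic distance matches the haversine closed form", {
  meta <- toy_meta(2)
  meta$latitude <- c(0, 1)
  meta$longitude <- c(0, 0)
  d <- geo_distance(meta)
  expect_equal(unname(d["s1", "s2"]), 111.19, tolerance = 0.01)
  expect_equal(unname(d["s1", "s1"]), 0)
  expect_lt(max(abs(d - t(d))), 1e-12)
  meta$latitude <- c(0, 95)
  expect_error(geo_distance(meta), "range")
})

test_that("ANOSIM separates perfectly distinct groups and respects the p floor", {
  set.seed(3)
  pts <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 50), 5, 2))
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("s", 1:10), paste0("s", 1:10))
  groups <- rep(c("a", "b"), each = 5)
  res <- anosim_test(dm, groups, n_perm = 199, seed = 1)
  expect_equal(res$R, 1, tolerance = 1e-12)
  expect_gte(res$p, 1 / 200)
  expect_error(anosim_test(dm, c("a", rep("b", 9)), 99, 1), ">= 2 members")
})

test_that("ANOSIM R is centred at zero under random labels", {
  set.seed(4)
  pts <- matrix(rnorm(24), 12, 2)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("s", 1:12), paste0("s", 1:12))
  stats <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    anosim_test(dm, sample(rep(c("a", "b"), each = 6)), n_perm = 99,
                seed = s)$R
  }, numeric(1))
  expect_lt(abs(mean(stats)), 0.05)
  expect_true(all(stats >= -1 & stats <= 1))
})

test_that("SIMPER decomposes the mean between-group Bray-Curtis exactly", {
  # groups differing in exactly one OTU
  tab <- as_otu_table(matrix(c(5L, 3L, 0L, 5L, 3L, 0L, 5L, 3L, 7L, 5L, 3L, 7L),
                             4, 3, byrow = TRUE,
                             dimnames = list(paste0("s", 1:4),
                                             c("O1", "O2", "O3"))))
  res <- simper_contributions(tab, rep(c("g1", "g2"), each = 2))[[1]]
  expect_equal(res$contributions$percent[1], 100)
  expect_equal(res$contributions$otu_id[1], "O3")
  # hand-computed 2-sample groups, 3 OTUs
  tab2 <- as_otu_table(matrix(c(10L, 0L, 6L, 6L, 4L, 0L), 2, 3, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("O1", "O2", "O3"))))
  res2 <- simper_contributions(tab2, c("g1", "g2"))[[1]]
  hand <- c(O1 = 4 / 26, O2 = 4 / 26, O3 = 6 / 26)
  expect_equal(setNames(res2$contributions$average, res2$contributions$otu_id),
               sort(hand, decreasing = TRUE), tolerance = 1e-12)
  # decomposition identity on random instances
  for (s in 1:10) {
    tab3 <- random_table(6, 7, seed = 200 + s)
    groups <- rep(c("g1", "g2"), each = 3)
    r <- simper_contributions(tab3, groups)[[1]]
    bc <- bray_curtis(tab3)
    expect_equal(r$mean_dissimilarity, mean(bc[1:3, 4:6]), tolerance = 1e-10)
    expect_equal(sum(r$contributions$percent), 100, tolerance = 0.01)
    expect_true(all(diff(r$contributions$cumulative_percent) >= -1e-9))
  }
})

test_that("Mantel r equals Pearson on extracted triangles and is linear-invariant", {
  set.seed(6)
  pts <- matrix(rnorm(20), 10, 2)
  dmA <- as.matrix(dist(pts)); dimnames(dmA) <- list(paste0("s", 1:10), paste0("s", 1:10))
  dmB <- 3 * dmA
  res <- mantel_test(dmA, dmB, n_perm = 99, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 100)
  dmC <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  dimnames(dmC) <- dimnames(dmA)
  res2 <- mantel_test(dmA, dmC, n_perm = 99, seed = 1)
  expect_equal(res2$r,
               cor(dmA[lower.tri(dmA)], dmC[lower.tri(dmC)]),
               tolerance = 1e-12)
  set.seed(2)
  ref <- vegan::mantel(as.dist(dmA), as.dist(dmC), permutations = 199)
  expect_equal(res2$r, unname(ref$statistic), tolerance = 1e-12)
  const <- dmA * 0
  expect_error(mantel_test(const, dmA, 99, 1), "constant")
})

test_that("partial Mantel removes shared structure and is symmetric in A and B", {
  set.seed(7)
  pts <- matrix(rnorm(20), 10, 2)
  dmA <- as.matrix(dist(pts)); dimnames(dmA) <- list(paste0("s", 1:10), paste0("s", 1:10))
  dmB <- as.matrix(dist(matrix(rnorm(20), 10, 2))); dimnames(dmB) <- dimnames(dmA)
  # controlling for B itself leaves no signal: degenerate, defined as 0
  res_self <- partial_mantel_test(dmA, dmB, dmB, n_perm = 99, seed = 1)
  expect_equal(res_self$r, 0)
  expect_true(res_self$degenerate)
  # controlling for an unrelated constant-plus-noise matrix changes nothing
  dmC <- matrix(5, 10, 10); diag(dmC) <- 0; dimnames(dmC) <- dimnames(dmA)
  r_part <- partial_mantel_test(dmA, dmB, dmC, n_perm = 99, seed = 1)$r
  r_simple <- mantel_test(dmA, dmB, n_perm = 99, seed = 1)$r
  expect_equal(r_part, r_simple, tolerance = 1e-6)
  r_ab <- partial_mantel_test(dmA, dmB, dmA * 0.5 + dmB * 0.5, 99, 1)$r
  r_ba <- partial_mantel_test(dmB, dmA, dmA * 0.5 + dmB * 0.5, 99, 1)$r
  expect_equal(r_ab, r_ba, tolerance = 1e-10)
})

test_that("distance-decay regression recovers an exact linear relationship", {
  set.seed(8)
  meta <- toy_meta(8, seed = 8)
  meta$latitude <- seq(23, 23.7, length.out = 8)
  meta$longitude <- 117.5
  dgeo <- geo_distance(meta)
  dcomm <- 0.01 * dgeo  # similarity = 1 - 0.01 * distance
  dd <- distance_decay(as_distance_matrix(dcomm, tol = 1e-9), dgeo)
  expect_equal(dd$slope, -0.01, tolerance = 1e-10)
  expect_equal(dd$r, -1, tolerance = 1e-10)
  zero <- dgeo * 0
  expect_error(distance_decay(dcomm, zero), "variance")
})
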