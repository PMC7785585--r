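test_that("OTU table round-trips through write/read with ids and counts intact", {
  tab <- random_table(5, 8, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, f)
  expect_identical(read_otu_table(f), tab)
  # both orientations normalize to samples x OTUs
  f2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(otu_id = colnames(tab), t(tab), check.names = FALSE)
  write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_otu_table(f2, orientation = "otus_in_rows"), tab)
})

test_that("OTU table validation rejects bad cells with coordinates", {
  zero <- matrix(0L, 3, 2, dimnames = list(paste0("s", 1:3), c("A", "B")))
  expect_identical(rowSums(as_otu_table(zero)), setNames(rep(0, 3), paste0("s", 1:3)))
  bad <- zero; bad[2, 1] <- -1L
  expect_error(as_otu_table(bad), "s2.*A|A.*s2")
  dup <- matrix(0L, 2, 2, dimnames = list(c("s1", "s1"), c("A", "B")))
  expect_error(as_otu_table(dup), "duplicate sample")
})

test_that("newick reader handles lengths, rooting and malformed input", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", f)
  tr <- read_newick(f)
  expect_equal(length(tr$tip.label), 4)
  expect_equal(sum(tr$edge.length), 6)
  writeLines("(A:1,B:1,C:1);", f)  # basal trifurcation -> midpoint rooted
  expect_message(tr2 <- read_newick(f), "midpoint")
  expect_true(ape::is.rooted(tr2))
  writeLines("(A,B);", f)
  expect_warning(tr3 <- read_newick(f), "imputing 0|imputed")
  expect_true(all(tr3$edge.length == 0))
  writeLines("((A:1,B:1", f)
  expect_error(suppressWarnings(read_newick(f)))
})

make_meta_row <- function(clay = 20, silt = 60, sand = 20) {
  data.frame(sample_id = "Z1_L1", site = "Z1", latitude = 23.7,
             longitude = 117.5, water_depth = 10, sediment_depth = 1,
             bottom_temperature = 28, bottom_salinity = 33,
             As = 10, Cd = 0.1, Cr = 60, Cu = 20, Hg = 0.05, Pb = 35,
             Zn = 120, clay = clay, silt = silt, sand = sand)
}

test_that("metadata validation enforces the grain-size and schema contracts", {
  expect_silent(validate_metadata(make_meta_row(20, 60, 20)))
  expect_error(validate_metadata(make_meta_row(20, 60, 30)), "grain-size")
  m <- make_meta_row(); m$latitude <- NULL
  expect_error(validate_metadata(m), "latitude")
  m2 <- make_meta_row(); m2$latitude <- NA
  expect_error(validate_metadata(m2), "latitude")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(validate_metadata(make_meta_row()), f)
  expect_equal(read_metadata(f)$clay, 20)
})

test_that("align_datasets intersects, prunes, is idempotent, and errors on disjoint ids", {
  tab <- random_table(4, 4, seed = 2, ids = c("A", "B", "C", "D"))
  tree <- four_tip_tree()
  tax <- data.frame(otu_id = c("A", "B", "C", "D"),
                    lineage = rep("Alveolata;Ciliophora", 4))
  al <- align_datasets(tab, tree, tax = tax)
  expect_identical(al$table, tab)
  # extra tip pruned, OTU set unchanged
  tree5 <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,E:3);")
  al2 <- suppressMessages(align_datasets(tab, tree5, tax = tax))
  expect_setequal(al2$tree$tip.label, colnames(tab))
  expect_identical(colnames(al2$table), colnames(tab))
  al3 <- suppressMessages(align_datasets(al2$table, al2$tree, tax = al2$tax))
  expect_identical(al3$table, al2$table)
  meta_bad <- make_meta_row()  # sample_id Z1_L1 not in table
  expect_error(align_datasets(tab, meta = meta_bad), "no samples")
})

test_that("taxon aggregation yields relative abundances summing to one at every rank", {
  tab <- as_otu_table(matrix(c(3L, 1L, 0L, 2L), 1, 4,
                             dimnames = list("s1", c("A", "B", "C", "D"))))
  tax <- data.frame(otu_id = c("A", "B", "C", "D"),
                    lineage = c("X;x1", "X;x2", "Y;y1", "Y"))
  g1 <- aggregate_by_taxon(tab, tax, rank = 1)
  expect_equal(as.numeric(g1[1, c("X", "Y")]), c(4 / 6, 2 / 6))
  g2 <- aggregate_by_taxon(tab, tax, rank = 2)
  expect_true("unclassified" %in% colnames(g2))
  for (rank in 1:2) {
    g <- aggregate_by_taxon(random_table(6, 4, seed = 3,
                                         ids = c("A", "B", "C", "D")),
                            tax, rank = rank)
    expect_equal(unname(rowSums(g)), rep(1, 6), tolerance = 1e-12)
  }
  # single group -> single column of ones
  tax1 <- data.frame(otu_id = c("A", "B", "C", "D"),
                     lineage = rep("X;only", 4))
  gg <- aggregate_by_taxon(tab, tax1, rank = 1)
  expect_equal(unname(gg[, "X"]), 1)
})

test_that("distance matrices round-trip and reject asymmetry", {
  m <- as.matrix(dist(matrix(rnorm(12), 4, 3)))
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(m, f)
  expect_equal(read_distance_matrix(f), m, tolerance = 1e-12)
  bad <- m; bad[1, 2] <- bad[1, 2] + 1
  expect_error(as_distance_matrix(bad), "symmetric")
})
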