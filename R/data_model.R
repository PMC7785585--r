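#' @useDynLib sedcomm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor cor.test cov lm median p.adjust quantile resid
#'   rgamma rlnorm rmultinom rnorm runif sd var setNames cmdscale dist
#'   complete.cases
#' @importFrom utils read.delim write.table head modifyList
NULL

# ---------------------------------------------------------------------------
# OTU table -----------------------------------------------------------------

#' Validate an OTU count table
#'
#' The canonical in-memory representation of an OTU table is a plain integer
#' matrix with samples in rows and OTUs in columns, sample identifiers as row
#' names and OTU identifiers as column names. `as_otu_table()` checks the
#' invariants (non-negative integer counts, unique identifiers) and returns
#' the matrix in that layout.
#'
#' @param x numeric matrix of counts, samples x OTUs.
#' @return validated integer matrix, samples x OTUs.
#' @export
as_otu_table <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("OTU table must have sample row names and OTU column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "OTU counts must be non-negative integers; offending cell sample '%s', OTU '%s' (value %s)",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]], x[bad[1, 1], bad[1, 2]]))
  storage.mode(x) <- "integer"
  x
}

#' Read an OTU count table from a tab-separated file
#'
#' The file must have a header row and an identifier column (first column).
#' Both orientations are accepted; the returned matrix is always samples x
#' OTUs.
#'
#' @param path file path.
#' @param orientation `"samples_in_rows"` (default) or `"otus_in_rows"`.
#' @return integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path, orientation = c("samples_in_rows", "otus_in_rows")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in OTU table: ", path)
  rownames(m) <- ids
  if (orientation == "otus_in_rows") m <- t(m)
  as_otu_table(m)
}

#' Write an OTU table as tab-separated text (samples in rows)
#'
#' @param table OTU table (samples x OTUs).
#' @param path output path.
#' @param id_column name of the identifier column in the header.
#' @export
write_otu_table <- function(table, path, id_column = "sample_id") {
  table <- as_otu_table(table)
  df <- data.frame(id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write_tsv_exact(df, path)
}

# Full-precision TSV writer shared by all writers: UTF-8, LF endings,
# doubles serialized with repr-exact precision (format via %.17g then trim).
write_tsv_exact <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- num_repr(df[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n", useBytes = TRUE)
  if (nrow(df) > 0) {
    lines <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

# shortest decimal representation that round-trips a double
num_repr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 1:17) {
      s <- trimws(formatC(v, digits = d, format = "g"))
      if (as.numeric(s) == v) return(s)
    }
    trimws(formatC(v, digits = 17, format = "g"))
  }, character(1))
}

# ---------------------------------------------------------------------------
# Taxonomy ------------------------------------------------------------------

#' Read taxonomy assignments
#'
#' Expects a tab-separated file with columns `otu_id` and `lineage`, the
#' lineage a `;`-separated rank string from supergroup down to the lowest
#' assigned rank (PR2-style), e.g. `Alveolata;Ciliophora;Spirotrichea`.
#'
#' @param path file path.
#' @return data.frame with columns `otu_id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(df)))
    stop("taxonomy file must have columns 'otu_id' and 'lineage'")
  df$otu_id <- as.character(df$otu_id)
  df$lineage <- as.character(df$lineage)
  if (anyDuplicated(df$otu_id))
    stop("duplicate otu_id in taxonomy: ",
         paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  if (any(!nzchar(df$lineage)))
    stop("empty lineage for: ",
         paste(df$otu_id[!nzchar(df$lineage)], collapse = ", "))
  df[, c("otu_id", "lineage")]
}

#' @rdname read_taxonomy
#' @param tax taxonomy data.frame.
#' @export
write_taxonomy <- function(tax, path) {
  write_tsv_exact(tax[, c("otu_id", "lineage")], path)
}

#' Extract the taxon label at a lineage rank
#'
#' @param lineage character vector of `;`-separated lineages.
#' @param rank 1-based rank index (1 = supergroup).
#' @return character vector; `"unclassified"` where the lineage is shallower
#'   than `rank`.
#' @export
taxon_at_rank <- function(lineage, rank) {
  stopifnot(rank >= 1)
  parts <- strsplit(lineage, ";", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) >= rank && nzchar(p[rank])) p[rank] else "unclassified"
  }, character(1))
}

# ---------------------------------------------------------------------------
# Phylogeny -----------------------------------------------------------------

#' Read a rooted OTU phylogeny from Newick
#'
#' Unrooted trees (basal multifurcation) are midpoint-rooted, with a message,
#' because downstream UniFrac and Faith's PD require a root. Missing branch
#' lengths are imputed as zero with a warning.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree, rooted, with branch lengths.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse Newick file ",
                                            path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse Newick file ", path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in ", path)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; imputing 0 for every branch")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths imputed as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) {
    message("input tree is unrooted; midpoint-rooting it")
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sample metadata -----------------------------------------------------------

metadata_schema <- c(
  "sample_id", "site", "latitude", "longitude", "water_depth",
  "sediment_depth", "bottom_temperature", "bottom_salinity",
  "As", "Cd", "Cr", "Cu", "Hg", "Pb", "Zn",
  "clay", "silt", "sand"
)

#' Read per-sample environmental metadata
#'
#' The schema is fixed: `sample_id`, `site`, `latitude`, `longitude`
#' (decimal degrees), `water_depth` (m), `sediment_depth` (cm, layers 1-5),
#' `bottom_temperature` (deg C), `bottom_salinity`, the seven metal
#' concentrations `As`, `Cd`, `Cr`, `Cu`, `Hg`, `Pb`, `Zn` (mg/kg), and
#' grain-size fractions `clay` (<4 um), `silt` (4-63 um), `sand`
#' (63-2000 um) in percent, which must sum to 100 +- 0.5. Extra columns
#' pass through untouched.
#'
#' @param path tab-separated file, one row per sample.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
validate_metadata <- function(meta) {
  missing_cols <- setdiff(metadata_schema, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  num_cols <- setdiff(metadata_schema, c("sample_id", "site"))
  for (col in num_cols) {
    meta[[col]] <- as.numeric(meta[[col]])
    if (anyNA(meta[[col]]))
      stop("missing or non-numeric values in metadata field '", col, "'")
  }
  if (any(abs(meta$latitude) > 90) || any(abs(meta$longitude) > 180))
    stop("latitude/longitude out of range")
  if (!all(meta$sediment_depth %in% 1:5))
    stop("sediment_depth must be an integer layer in 1..5")
  conc <- c("As", "Cd", "Cr", "Cu", "Hg", "Pb", "Zn")
  if (any(as.matrix(meta[conc]) < 0)) stop("negative metal concentration")
  gsum <- meta$clay + meta$silt + meta$sand
  off <- which(abs(gsum - 100) > 0.5)
  if (length(off) > 0)
    stop("grain-size fractions must sum to 100 +- 0.5; sample(s) ",
         paste(meta$sample_id[off], collapse = ", "),
         " sum to ", paste(round(gsum[off], 3), collapse = ", "))
  rownames(meta) <- meta$sample_id
  meta
}

#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  write_tsv_exact(meta, path)
}

# ---------------------------------------------------------------------------
# Distance matrices ---------------------------------------------------------

#' Validate a distance matrix
#'
#' @param m square numeric matrix with dimnames.
#' @param tol symmetry tolerance.
#' @return the matrix, with the diagonal forced to exactly zero.
#' @export
as_distance_matrix <- function(m, tol = 1e-12) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix must carry identifiers")
  if (max(abs(m - t(m))) > tol) stop("distance matrix is not symmetric")
  if (any(m < 0)) stop("negative distances")
  diag(m) <- 0
  colnames(m) <- rownames(m)
  m
}

#' @rdname as_distance_matrix
#' @param path file path.
#' @export
write_distance_matrix <- function(m, path) {
  m <- as_distance_matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write_tsv_exact(df, path)
}

#' @rdname as_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_distance_matrix(m)
}

# lower-triangle vector in a fixed (column-major) order
lower_triangle <- function(m) m[lower.tri(m)]

# ---------------------------------------------------------------------------
# Alignment and aggregation -------------------------------------------------

#' Align OTU table, tree, metadata and taxonomy to common identifiers
#'
#' Samples are restricted to those present in both the table and the
#' metadata; OTUs to those present in the table, the tree's tips and the
#' taxonomy. Dropped identifiers are reported via `message()`.
#'
#' @param table OTU table (samples x OTUs).
#' @param tree phylo tree whose tips are OTU ids (optional, `NULL` to skip).
#' @param meta metadata data.frame (optional).
#' @param tax taxonomy data.frame (optional).
#' @return list with elements `table`, `tree`, `meta`, `tax`, aligned.
#' @export
align_datasets <- function(table, tree = NULL, meta = NULL, tax = NULL) {
  table <- as_otu_table(table)
  samples <- rownames(table)
  if (!is.null(meta)) samples <- intersect(samples, meta$sample_id)
  otus <- colnames(table)
  if (!is.null(tree)) otus <- intersect(otus, tree$tip.label)
  if (!is.null(tax)) otus <- intersect(otus, tax$otu_id)
  if (length(samples) == 0) stop("no samples shared between table and metadata")
  if (length(otus) == 0) stop("no OTUs shared across table/tree/taxonomy")
  d_s <- setdiff(rownames(table), samples)
  d_o <- setdiff(colnames(table), otus)
  if (length(d_s) > 0) message("align_datasets: dropped ", length(d_s), " sample(s)")
  if (length(d_o) > 0) message("align_datasets: dropped ", length(d_o), " OTU(s) from table")
  table <- table[samples, otus, drop = FALSE]
  if (!is.null(tree)) {
    extra <- setdiff(tree$tip.label, otus)
    if (length(extra) > 0) {
      message("align_datasets: pruned ", length(extra), " tip(s) from tree")
      tree <- ape::drop.tip(tree, extra)
    }
  }
  if (!is.null(meta)) {
    meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
    rownames(meta) <- meta$sample_id
  }
  if (!is.null(tax)) tax <- tax[match(otus, tax$otu_id), , drop = FALSE]
  list(table = table, tree = tree, meta = meta, tax = tax)
}

#' Aggregate an OTU table to taxon-group relative abundances
#'
#' @param table OTU table (samples x OTUs).
#' @param tax taxonomy data.frame covering the table's OTUs.
#' @param rank 1-based lineage rank to aggregate at.
#' @return matrix samples x taxon groups of relative abundances (rows sum to
#'   1 for non-empty samples; empty samples give all-zero rows with a
#'   warning).
#' @export
aggregate_by_taxon <- function(table, tax, rank = 1) {
  table <- as_otu_table(table)
  idx <- match(colnames(table), tax$otu_id)
  if (anyNA(idx)) stop("taxonomy missing for ",
                       paste(colnames(table)[is.na(idx)], collapse = ", "))
  groups <- taxon_at_rank(tax$lineage[idx], rank)
  agg <- t(rowsum(t(table), groups))
  totals <- rowSums(agg)
  empty <- totals == 0
  if (any(empty)) warning("empty sample(s): ",
                          paste(rownames(table)[empty], collapse = ", "))
  agg / ifelse(totals == 0, 1, totals)
}
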