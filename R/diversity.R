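# Alpha and beta diversity: rarefaction, richness/Shannon/Faith's PD,
# Bray-Curtis, unweighted UniFrac, and principal coordinates analysis.

#' Rarefy an OTU table to even depth
#'
#' One seeded subsampling draw without replacement per sample (not an
#' average over draws). Samples whose total is below `depth` are dropped
#' with a warning; all-zero OTU columns are retained so identifiers are
#' preserved.
#'
#' @param table OTU table (samples x OTUs).
#' @param depth target depth (reads per sample, >= 1).
#' @param seed integer seed.
#' @return rarefied OTU table; every row sums to exactly `depth`.
#' @export
rarefy_table <- function(table, depth, seed = 1) {
  table <- as_otu_table(table)
  if (depth <= 0) stop("rarefaction depth must be positive")
  totals <- rowSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  if (any(!keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[!keep], collapse = ", "))
  set.seed(seed)
  # vegan warns heuristically when the smallest nonzero count exceeds 1;
  # irrelevant for validated count tables
  out <- withCallingHandlers(
    vegan::rrarefy(table[keep, , drop = FALSE], depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  as_otu_table(out)
}

#' Alpha diversity: richness, Shannon entropy, Faith's PD
#'
#' Richness counts OTUs with positive counts; Shannon is
#' `-sum(p_i * log(p_i))` in the given log base (default 2, bits); Faith's
#' PD is the branch length of the minimal subtree connecting a sample's
#' tips to the root (rooted convention, root path included). Empty samples
#' yield zeros and are flagged.
#'
#' @param table OTU table (samples x OTUs).
#' @param tree rooted `phylo` tree covering the table's OTUs (set `NULL` to
#'   skip PD).
#' @param base logarithm base for Shannon.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`, `pd`,
#'   `flagged_empty`.
#' @export
alpha_diversity <- function(table, tree = NULL, base = 2) {
  table <- as_otu_table(table)
  richness <- as.integer(rowSums(table > 0))
  shannon <- as.numeric(vegan::diversity(table, index = "shannon",
                                         base = base))
  empty <- rowSums(table) == 0
  shannon[empty] <- 0
  pd <- rep(NA_real_, nrow(table))
  if (!is.null(tree)) {
    missing_tips <- setdiff(colnames(table), tree$tip.label)
    if (length(missing_tips) > 0)
      stop("OTUs absent from the tree: ",
           paste(head(missing_tips, 5), collapse = ", "))
    pd <- rep(0, nrow(table))
    nonempty <- which(!empty)
    if (length(nonempty) > 0) {
      res <- picante::pd(table[nonempty, , drop = FALSE], tree,
                         include.root = TRUE)
      pd[nonempty] <- res$PD
    }
  }
  if (any(empty)) warning("empty sample(s) flagged: ",
                          paste(rownames(table)[empty], collapse = ", "))
  data.frame(sample_id = rownames(table), richness = richness,
             shannon = shannon, pd = pd, flagged_empty = empty,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`. Pairs where
#' both samples are empty are defined as 0 with a warning.
#'
#' @param table OTU table (samples x OTUs), >= 2 samples.
#' @return symmetric distance matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  table <- as_otu_table(table)
  if (nrow(table) < 2) stop("need at least two samples")
  m <- as.matrix(vegan::vegdist(table, method = "bray"))
  if (anyNA(m)) {
    warning("pair(s) of all-zero samples; their distance is defined as 0")
    m[is.na(m)] <- 0
  }
  as_distance_matrix(m)
}

#' Unweighted UniFrac distance between all sample pairs
#'
#' Presence/absence only: for each pair, the tree branch length leading
#' exclusively to one sample's tips divided by the branch length leading to
#' either sample's tips (all branches of the rooted tree are eligible, so
#' the shared path to the root counts as shared).
#'
#' @param table OTU table (samples x OTUs); OTUs must be tips of `tree`.
#' @param tree rooted `phylo` tree with branch lengths.
#' @return symmetric distance matrix in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  table <- as_otu_table(table)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  missing_tips <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_tips) > 0)
    stop("OTUs absent from the tree: ",
         paste(head(missing_tips, 5), collapse = ", "))
  n <- nrow(table)
  S <- length(tree$tip.label)
  # per-sample presence at each tip, in tip-index order
  pres_tip <- matrix(0L, S, n)
  idx <- match(colnames(table), tree$tip.label)
  pres_tip[idx, ] <- t(table > 0) * 1L
  # accumulate presence counts up the tree (postorder)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- tree$Nnode
  npres <- matrix(0L, S + nnode, n)
  npres[seq_len(S), ] <- pres_tip
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    npres[par, ] <- npres[par, ] + npres[ch, ]
  }
  # B[e, k]: does any tip below edge e occur in sample k
  B <- (npres[po$edge[, 2], , drop = FALSE] > 0) * 1
  el <- po$edge.length
  Lk <- as.numeric(t(B) %*% el)          # branch length per sample
  shared <- t(B * el) %*% B              # shared branch length per pair
  union <- outer(Lk, Lk, "+") - shared
  uf <- matrix(0, n, n)
  pos <- union > 0
  uf[pos] <- pmin(pmax((union[pos] - shared[pos]) / union[pos], 0), 1)
  if (any(!pos & upper.tri(union)))
    warning("pair(s) with no occupied branches; distance defined as 0")
  dimnames(uf) <- list(rownames(table), rownames(table))
  as_distance_matrix(uf, tol = 1e-9)
}

#' Principal coordinates analysis
#'
#' Gower double-centring and eigendecomposition via [stats::cmdscale()].
#' Negative eigenvalues are reported but excluded from the coordinates and
#' from the proportion of variance explained.
#'
#' @param dm distance matrix (symmetric, zero diagonal), >= 3 samples.
#' @return list with `ids`, `coordinates` (samples x axes, positive-
#'   eigenvalue axes only), `eigenvalues` (all, descending), and
#'   `proportion_explained` per retained axis.
#' @export
pcoa_ordination <- function(dm) {
  dm <- as_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("PCoA needs at least three samples")
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  coords <- fit$points[, seq_len(min(npos, ncol(fit$points))), drop = FALSE]
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  prop <- eig[seq_len(ncol(coords))] / sum(eig[eig > 0])
  list(ids = rownames(dm), coordinates = coords, eigenvalues = eig,
       proportion_explained = prop)
}

#' Write a PCoA ordination to TSV (coordinates + eigenvalue sidecar)
#'
#' @param ord ordination from [pcoa_ordination()].
#' @param path coordinates path; eigenvalues go to `<path>.eig.tsv`.
#' @export
write_ordination <- function(ord, path) {
  df <- data.frame(sample_id = ord$ids, ord$coordinates, check.names = FALSE)
  write_tsv_exact(df, path)
  eig <- data.frame(axis = seq_along(ord$eigenvalues),
                    eigenvalue = ord$eigenvalues)
  write_tsv_exact(eig, paste0(path, ".eig.tsv"))
  invisible(path)
}
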