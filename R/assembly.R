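# Null-model quantification of community assembly: weighted beta mean
# nearest taxon distance (bMNTD), its standardized effect size against a
# taxa-shuffle null (bNTI), the abundance-based Raup-Crick metric on
# Bray-Curtis (RCbray), and the five-way process partition.

#' Beta mean nearest taxon distance between all sample pairs
#'
#' For samples k and m,
#' `bMNTD(k,m) = 0.5 * (sum_i f_ik min_j d(i, j in m) +
#'               sum_j f_jm min_i d(j, i in k))`,
#' with `f` the within-sample relative abundances (weighted mode, default)
#' or uniform weights over present OTUs (unweighted), and `d` the patristic
#' distance on the tree. An OTU present in both samples has nearest-taxon
#' distance zero.
#'
#' @param table OTU table (samples x OTUs); OTUs must be tips of `tree`.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param weighted use relative-abundance weights (default) or uniform.
#' @return symmetric matrix of bMNTD values (phylogenetic distance units).
#' @export
bmntd <- function(table, tree, weighted = TRUE) {
  table <- as_otu_table(table)
  prep <- bmntd_prepare(table, tree, weighted)
  out <- bmntd_kernel(prep$D, prep$F, prep$identity_perm)
  dimnames(out) <- list(rownames(table), rownames(table))
  out
}

bmntd_prepare <- function(table, tree, weighted) {
  missing_tips <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_tips) > 0)
    stop("OTUs absent from the tree: ",
         paste(head(missing_tips, 5), collapse = ", "))
  if (any(rowSums(table) == 0)) stop("sample with zero total abundance")
  D <- ape::cophenetic.phylo(tree)[colnames(table), colnames(table)]
  Fm <- if (weighted) {
    table / rowSums(table)
  } else {
    pres <- (table > 0) * 1
    pres / rowSums(pres)
  }
  list(D = D, F = unname(as.matrix(Fm)),
       identity_perm = seq_len(ncol(table)) - 1L)
}

#' Beta nearest taxon index (standardized bMNTD)
#'
#' The null model shuffles OTU identities across the tree tips (preserving
#' both the table and the tree shape); each of `n_null` randomizations
#' yields one null bMNTD matrix, and
#' `bNTI = (bMNTD_obs - mean(null)) / sd(null)` per pair. Pairs with a
#' degenerate null (sd = 0) are `NA` and counted in `n_undefined`.
#'
#' @inheritParams bmntd
#' @param n_null number of randomizations (>= 99; 999 is the conventional
#'   choice).
#' @param seed integer seed.
#' @return list with matrices `bnti`, `bmntd_obs`, `null_mean`, `null_sd`,
#'   plus `n_null` and `n_undefined`.
#' @export
bnti <- function(table, tree, n_null = 999, seed = 1, weighted = TRUE) {
  table <- as_otu_table(table)
  if (n_null < 99) stop("n_null must be >= 99")
  prep <- bmntd_prepare(table, tree, weighted)
  obs <- bmntd_kernel(prep$D, prep$F, prep$identity_perm)
  S <- ncol(table)
  n <- nrow(table)
  sum1 <- matrix(0, n, n)
  sum2 <- matrix(0, n, n)
  set.seed(seed)
  for (k in seq_len(n_null)) {
    perm <- sample.int(S) - 1L
    nb <- bmntd_kernel(prep$D, prep$F, perm)
    sum1 <- sum1 + nb
    sum2 <- sum2 + nb * nb
  }
  mu <- sum1 / n_null
  sdv <- sqrt(pmax(sum2 / n_null - mu^2, 0) * n_null / (n_null - 1))
  z <- (obs - mu) / sdv
  z[!is.finite(z)] <- NA_real_
  diag(z) <- 0
  ids <- rownames(table)
  dimnames(z) <- dimnames(obs) <- dimnames(mu) <- dimnames(sdv) <-
    list(ids, ids)
  n_undef <- sum(is.na(z[lower.tri(z)]))
  if (n_undef > 0)
    warning(n_undef, " pair(s) with degenerate null (sd = 0) flagged NA")
  list(bnti = z, bmntd_obs = obs, null_mean = mu, null_sd = sdv,
       n_null = n_null, n_undefined = n_undef)
}

#' Abundance-based Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' For each sample pair, `n_null` pairs of null communities are drawn
#' preserving each sample's observed richness and total abundance: taxa are
#' selected with probability proportional to their occurrence frequency
#' across samples, then individuals are distributed with probability
#' proportional to regional relative abundance. With `alpha` the fraction
#' of null Bray-Curtis values below the observed one (ties at half weight),
#' `RCbray = (alpha - 0.5) * 2`, in `[-1, 1]`.
#'
#' @param table OTU table (samples x OTUs), >= 2 samples.
#' @param n_null number of null draws per pair (>= 99).
#' @param seed integer seed.
#' @return symmetric matrix of RCbray values in `[-1, 1]`.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = 1) {
  table <- as_otu_table(table)
  if (nrow(table) < 2) stop("need at least two samples")
  set.seed(seed)
  out <- rcbray_kernel(table, as.integer(n_null))
  dimnames(out) <- list(rownames(table), rownames(table))
  out
}

process_levels <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

#' Partition community turnover into five assembly processes
#'
#' Per sample pair: `bNTI > 2` -> variable selection; `bNTI < -2` ->
#' homogeneous selection; otherwise (`|bNTI| <= 2`, ties at exactly 2 are
#' assigned to the stochastic side) `RCbray > 0.95` -> dispersal
#' limitation, `RCbray < -0.95` -> homogenizing dispersal, and
#' `|RCbray| <= 0.95` -> undominated ("drift" in common usage). Pairs with
#' undefined bNTI are excluded from the denominators and counted.
#'
#' @param bnti matrix of bNTI values (or the list from [bnti()]).
#' @param rc matrix of RCbray values over the same ids.
#' @return list with `results` (one row per pair: ids, bnti, rc_bray,
#'   process), `partition` (named fractions over the five processes,
#'   summing to 1), `n_pairs`, `n_excluded`.
#' @export
partition_processes <- function(bnti, rc) {
  if (is.list(bnti) && !is.null(bnti$bnti)) bnti <- bnti$bnti
  if (!identical(rownames(bnti), rownames(rc)))
    stop("bnti and rc must cover identical samples in identical order")
  n <- nrow(bnti)
  ii <- which(lower.tri(bnti), arr.ind = TRUE)
  b <- bnti[lower.tri(bnti)]
  r <- rc[lower.tri(rc)]
  lab <- ifelse(is.na(b), NA_character_,
         ifelse(b > 2, "variable_selection",
         ifelse(b < -2, "homogeneous_selection",
         ifelse(r > 0.95, "dispersal_limitation",
         ifelse(r < -0.95, "homogenizing_dispersal", "undominated")))))
  results <- data.frame(
    sample_1 = rownames(bnti)[ii[, 2]], sample_2 = rownames(bnti)[ii[, 1]],
    bnti = b, rc_bray = r, process = lab, stringsAsFactors = FALSE)
  ok <- !is.na(lab)
  counts <- table(factor(lab[ok], levels = process_levels))
  frac <- as.numeric(counts) / max(sum(ok), 1)
  names(frac) <- process_levels
  list(results = results, partition = frac, n_pairs = sum(ok),
       n_excluded = sum(!ok))
}

#' Write per-pair assembly results and the process partition
#'
#' @param part partition list from [partition_processes()].
#' @param pair_path per-pair TSV path.
#' @param summary_path partition-summary TSV path.
#' @export
write_assembly_results <- function(part, pair_path, summary_path) {
  write_tsv_exact(part$results, pair_path)
  summ <- data.frame(process = names(part$partition),
                     fraction = as.numeric(part$partition),
                     n_pairs = part$n_pairs, n_excluded = part$n_excluded)
  write_tsv_exact(summ, summary_path)
  invisible(summary_path)
}
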