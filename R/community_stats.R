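# Environmental correlation screens, group statistics (ANOSIM, SIMPER),
# simple and partial Mantel tests, geographic/environmental distances and
# the distance-decay regression.

#' Spearman correlation screen between responses and environmental variables
#'
#' Midrank handling of ties, two-sided p from the t-approximation. Constant
#' variables or responses yield an undefined correlation, reported as `NA`
#' and flagged.
#'
#' @param responses data.frame/matrix of per-sample response values (alpha
#'   diversity indices or taxon-group relative abundances), rows aligned
#'   with `meta`.
#' @param meta metadata data.frame.
#' @param variables metadata column names to screen against.
#' @return tidy data.frame: `response`, `variable`, `spearman_r`, `p_value`,
#'   `n`, `flagged_constant`.
#' @export
spearman_screen <- function(responses, meta, variables) {
  responses <- as.data.frame(responses)
  stopifnot(nrow(responses) == nrow(meta))
  bad <- setdiff(variables, names(meta))
  if (length(bad) > 0)
    stop("unknown metadata variable(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (resp in names(responses)) {
    y <- as.numeric(responses[[resp]])
    for (v in variables) {
      x <- as.numeric(meta[[v]])
      ok <- complete.cases(x, y)
      n <- sum(ok)
      if (n < 5) stop("need >= 5 paired observations for ", resp, " ~ ", v)
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        out[[length(out) + 1]] <- data.frame(
          response = resp, variable = v, spearman_r = NA_real_,
          p_value = NA_real_, n = n, flagged_constant = TRUE)
        next
      }
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                      exact = FALSE))
      out[[length(out) + 1]] <- data.frame(
        response = resp, variable = v,
        spearman_r = unname(ct$estimate), p_value = ct$p.value, n = n,
        flagged_constant = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Standardized Euclidean environmental distance
#'
#' Each variable is z-scored across samples, then Euclidean distance is
#' taken. Zero-variance variables are dropped with a warning.
#'
#' @param meta metadata data.frame with `sample_id`.
#' @param variables metadata columns to use (>= 2 before dropping).
#' @return distance matrix over samples.
#' @export
env_distance <- function(meta, variables) {
  if (length(variables) < 2) stop("need at least two variables")
  bad <- setdiff(variables, names(meta))
  if (length(bad) > 0)
    stop("unknown metadata variable(s): ", paste(bad, collapse = ", "))
  X <- as.matrix(meta[, variables, drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(variables[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no variables left after dropping constants")
  Z <- scale(X)
  m <- as.matrix(dist(Z))
  dimnames(m) <- list(meta$sample_id, meta$sample_id)
  as_distance_matrix(m, tol = 1e-9)
}

#' Great-circle geographic distance between samples (km)
#'
#' Haversine formula with Earth radius 6371 km.
#'
#' @param meta metadata data.frame with `sample_id`, `latitude`, `longitude`.
#' @return distance matrix in kilometres.
#' @export
geo_distance <- function(meta) {
  if (any(abs(meta$latitude) > 90) || any(abs(meta$longitude) > 180))
    stop("latitude/longitude out of range")
  pts <- cbind(meta$longitude, meta$latitude)
  m <- geosphere::distm(pts, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(m) <- list(meta$sample_id, meta$sample_id)
  as_distance_matrix(m, tol = 1e-9)
}

#' ANOSIM permutation test
#'
#' Rank-based analysis of similarities:
#' `R = (mean rank between - mean rank within) / (n(n-1)/4)`, with the
#' p-value from `n_perm` label permutations under the +1 correction.
#'
#' @param dm distance matrix.
#' @param groups group labels, aligned with the matrix ids; >= 2 groups,
#'   each of size >= 2.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999, seed = 1) {
  dm <- as_distance_matrix(dm)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(dm))
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group must have >= 2 members")
  set.seed(seed)
  fit <- vegan::anosim(as.dist(dm), grouping = groups, permutations = n_perm)
  p <- (sum(fit$perm >= fit$statistic) + 1) / (n_perm + 1)
  list(R = unname(fit$statistic), p = p, n_perm = n_perm)
}

#' SIMPER: per-OTU contributions to between-group Bray-Curtis dissimilarity
#'
#' For each group pair, every OTU's contribution is the mean over
#' between-group sample pairs of its Bray-Curtis term
#' `|x_i - y_i| / (sum(x) + sum(y))`; contributions sum to the mean
#' between-group Bray-Curtis and are expressed as percentages of it.
#'
#' @param table OTU count table (samples x OTUs).
#' @param groups group labels aligned with samples.
#' @param tax optional taxonomy data.frame; adds per-taxon aggregated
#'   percentages.
#' @param rank lineage rank for the taxon aggregation.
#' @return named list, one element per group pair, each with `contributions`
#'   (data.frame: `otu_id`, `average`, `percent`, `cumulative_percent`),
#'   `mean_dissimilarity`, and (if `tax` given) `taxon_percent`.
#' @export
simper_contributions <- function(table, groups, tax = NULL, rank = 1) {
  table <- as_otu_table(table)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(table))
  lev <- levels(droplevels(groups))
  if (length(lev) < 2) stop("need at least two groups")
  if (any(table(groups) == 0)) stop("empty group")
  totals <- rowSums(table)
  out <- list()
  for (a in seq_len(length(lev) - 1)) {
    for (b in seq((a + 1), length(lev))) {
      ia <- which(groups == lev[a])
      ib <- which(groups == lev[b])
      contrib <- numeric(ncol(table))
      npair <- 0L
      for (i in ia) {
        for (j in ib) {
          denom <- totals[i] + totals[j]
          if (denom == 0) next
          contrib <- contrib + abs(table[i, ] - table[j, ]) / denom
          npair <- npair + 1L
        }
      }
      if (npair == 0) stop("no usable sample pairs between groups ",
                           lev[a], " and ", lev[b])
      contrib <- contrib / npair
      total <- sum(contrib)
      ord <- order(contrib, decreasing = TRUE)
      df <- data.frame(otu_id = colnames(table)[ord],
                       average = unname(contrib[ord]),
                       percent = unname(100 * contrib[ord] / total))
      df$cumulative_percent <- cumsum(df$percent)
      res <- list(contributions = df, mean_dissimilarity = total,
                  groups = c(lev[a], lev[b]))
      if (!is.null(tax)) {
        tx <- taxon_at_rank(tax$lineage[match(df$otu_id, tax$otu_id)], rank)
        agg <- tapply(df$percent, tx, sum)
        res$taxon_percent <- sort(agg, decreasing = TRUE)
      }
      out[[paste(lev[a], lev[b], sep = "_vs_")]] <- res
    }
  }
  out
}

#' Simple Mantel test
#'
#' Pearson correlation between the lower triangles of two distance
#' matrices; significance by jointly permuting rows/columns of the first
#' matrix. One-tailed (`r >= observed`) by default, matching the ecological
#' convention for positive association; the tail is recorded in the result.
#'
#' @param dmA,dmB distance matrices over the same ids.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param tail `"greater"` (default) or `"two_sided"`.
#' @return list: `r`, `p`, `n_perm`, `tail`, `controlled` (`NA` here).
#' @export
mantel_test <- function(dmA, dmB, n_perm = 9999, seed = 1,
                        tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  dmA <- as_distance_matrix(dmA, tol = 1e-9)
  dmB <- as_distance_matrix(dmB, tol = 1e-9)
  check_matching_ids(dmA, dmB)
  if (n_perm < 99) stop("n_perm must be >= 99")
  va <- lower_triangle(dmA)
  vb <- lower_triangle(dmB)
  if (sd(va) == 0 || sd(vb) == 0) stop("constant lower triangle")
  r_obs <- cor(va, vb)
  n <- nrow(dmA)
  set.seed(seed)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    pidx <- sample.int(n)
    rp <- cor(lower_triangle(dmA[pidx, pidx]), vb)
    hit <- if (tail == "greater") rp >= r_obs else abs(rp) >= abs(r_obs)
    if (hit) exceed <- exceed + 1L
  }
  list(r = r_obs, p = (exceed + 1) / (n_perm + 1), n_perm = n_perm,
       tail = tail, controlled = NA_character_)
}

#' Partial Mantel test
#'
#' Correlation between the residuals of `A ~ C` and `B ~ C` over lower
#' triangles; significance by permuting the rows/columns of `A`,
#' re-residualizing against `C` each time (residual permutation).
#'
#' @param dmA,dmB,dmC distance matrices over the same ids (`dmC` is the
#'   control).
#' @inheritParams mantel_test
#' @return list as [mantel_test()], `controlled = "dmC"`.
#' @export
partial_mantel_test <- function(dmA, dmB, dmC, n_perm = 9999, seed = 1,
                                tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  dmA <- as_distance_matrix(dmA, tol = 1e-9)
  dmB <- as_distance_matrix(dmB, tol = 1e-9)
  dmC <- as_distance_matrix(dmC, tol = 1e-9)
  check_matching_ids(dmA, dmB)
  check_matching_ids(dmA, dmC)
  if (n_perm < 99) stop("n_perm must be >= 99")
  va <- lower_triangle(dmA)
  vb <- lower_triangle(dmB)
  vc <- lower_triangle(dmC)
  if (sd(va) == 0 || sd(vb) == 0) stop("constant lower triangle")
  res_b <- resid(lm(vb ~ vc))
  res_a <- resid(lm(va ~ vc))
  # if the control explains a matrix completely the partial correlation is
  # degenerate: nothing remains to correlate, so it is defined as 0
  tol_a <- 1e-10 * sd(va)
  tol_b <- 1e-10 * sd(vb)
  if (sd(res_a) <= tol_a || sd(res_b) <= tol_b) {
    return(list(r = 0, p = 1, n_perm = n_perm, tail = tail,
                controlled = "dmC", degenerate = TRUE))
  }
  r_obs <- cor(res_a, res_b)
  n <- nrow(dmA)
  set.seed(seed)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    pidx <- sample.int(n)
    ra <- resid(lm(lower_triangle(dmA[pidx, pidx]) ~ vc))
    rp <- cor(ra, res_b)
    hit <- if (tail == "greater") rp >= r_obs else abs(rp) >= abs(r_obs)
    if (hit) exceed <- exceed + 1L
  }
  list(r = r_obs, p = (exceed + 1) / (n_perm + 1), n_perm = n_perm,
       tail = tail, controlled = "dmC")
}

check_matching_ids <- function(a, b) {
  if (!identical(rownames(a), rownames(b)))
    stop("distance matrices must share identical ids in identical order")
  invisible(TRUE)
}

#' Distance-decay regression of community similarity on geographic distance
#'
#' Ordinary least squares of `1 - dissimilarity` on geographic distance over
#' the lower triangles.
#'
#' @param dm_comm community dissimilarity matrix.
#' @param dm_geo geographic distance matrix (same ids).
#' @return list: `slope`, `intercept`, `r` (Pearson), `n_pairs`.
#' @export
distance_decay <- function(dm_comm, dm_geo) {
  dm_comm <- as_distance_matrix(dm_comm, tol = 1e-9)
  dm_geo <- as_distance_matrix(dm_geo, tol = 1e-9)
  check_matching_ids(dm_comm, dm_geo)
  sim <- 1 - lower_triangle(dm_comm)
  g <- lower_triangle(dm_geo)
  if (length(g) < 3) stop("need at least three sample pairs")
  if (var(g) == 0) stop("zero geographic variance")
  fit <- lm(sim ~ g)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(sim, g), n_pairs = length(g))
}

#' Write a list of test results as one tidy TSV row per test
#'
#' @param results named list of result lists (each with scalar fields).
#' @param path output path.
#' @export
write_stat_results <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(test = nm,
               statistic = if (!is.null(x$R)) x$R else x$r,
               p = x$p,
               n_perm = if (!is.null(x$n_perm)) x$n_perm else NA_integer_,
               stringsAsFactors = FALSE)
  })
  write_tsv_exact(do.call(rbind, rows), path)
}
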