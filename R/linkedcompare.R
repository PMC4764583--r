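#' Gene-linked isoform sets between cluster groups
#'
#' Collects, for every gene with isoforms on both sides of a high/low
#' cluster partition, all cross pairs of (high-cluster isoform,
#' low-cluster isoform). Features of each member contribute to its side's
#' pooled distribution: e.g. gene A with isoform 001 in a high cluster and
#' isoforms 002, 003 in a low cluster yields pairs 001-002 and 001-003.
#'
#' @param assignments named integer vector: isoform id -> cluster label.
#' @param high_clusters,low_clusters disjoint sets of cluster labels.
#' @param gene_map data.frame with columns `isoform_id`, `gene_id`.
#' @return list with `high_ids`, `low_ids` (isoform ids contributing to
#'   each side) and `pairs` (data.frame gene_id, isoform_high, isoform_low).
#' @export
build_linked_sets <- function(assignments, high_clusters, low_clusters,
                              gene_map) {
  if (length(intersect(high_clusters, low_clusters)))
    stop("high and low cluster sets must be disjoint")
  ids <- names(assignments)
  if (is.null(ids)) stop("'assignments' must be named by isoform id")
  gene <- setNames(as.character(gene_map$gene_id),
                   as.character(gene_map$isoform_id))[ids]
  side <- ifelse(assignments %in% high_clusters, "high",
                 ifelse(assignments %in% low_clusters, "low", NA))
  keep <- !is.na(side) & !is.na(gene)
  df <- data.frame(isoform_id = ids[keep], gene_id = gene[keep],
                   side = side[keep], stringsAsFactors = FALSE)
  pairs <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    hi <- g$isoform_id[g$side == "high"]
    lo <- g$isoform_id[g$side == "low"]
    if (length(hi) == 0 || length(lo) == 0) return(NULL)
    expand.grid(isoform_high = hi, isoform_low = lo,
                stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    pairs <- data.frame(gene_id = character(), isoform_high = character(),
                        isoform_low = character(), stringsAsFactors = FALSE)
  } else {
    pairs$gene_id <- gene[pairs$isoform_high]
    pairs <- pairs[, c("gene_id", "isoform_high", "isoform_low")]
    rownames(pairs) <- NULL
  }
  linked_genes <- unique(pairs$gene_id)
  list(high_ids = sort(unique(df$isoform_id[df$side == "high" &
                                              df$gene_id %in% linked_genes])),
       low_ids = sort(unique(df$isoform_id[df$side == "low" &
                                             df$gene_id %in% linked_genes])),
       pairs = pairs)
}

# Mann-Whitney U (count-of-greater-pairs form, +1/2 per tie), via midranks.
mw_u_stat <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  sum(r[seq_len(m)]) - m * (m + 1) / 2
}

#' Cliff's delta effect size
#'
#' d = (#(x_i > y_j) - #(x_i < y_j)) / (m n), the dimensionless distance
#' between two distributions in \[-1, 1\]; ties contribute zero. Computed
#' via midranks (equivalent to the exhaustive pairwise count through the
#' identity d = 2U/(mn) - 1).
#'
#' @param x,y non-empty numeric vectors.
#' @return Cliff's d.
#' @export
cliffs_d <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both sets must be non-empty")
  2 * mw_u_stat(x, y) / (length(x) * length(y)) - 1
}

#' Mann-Whitney U test (two-tailed)
#'
#' U is the count of (x, y) pairs with x > y plus one half per tie,
#' computed from midranks. The two-tailed p-value uses the exact null
#' distribution when both sets have at most 20 observations and no ties
#' are present, and the normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `U`, `p`, `m`, `n`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both sets must be non-empty")
  m <- length(x); n <- length(y)
  u <- mw_u_stat(x, y)
  ties <- any(duplicated(c(x, y)))
  if (m <= 20 && n <= 20 && !ties) {
    p <- min(1, 2 * min(stats::pwilcox(u, m, n),
                        1 - stats::pwilcox(u - 1, m, n)))
  } else {
    N <- m + n
    tie_tab <- table(c(x, y))
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    mu <- m * n / 2
    if (sigma2 == 0) {
      p <- 1       # all values identical
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
  }
  list(U = u, p = p, m = m, n = n)
}

#' Percentile bootstrap confidence interval for a two-sample statistic
#'
#' Resamples `x` and `y` independently with replacement and returns the
#' percentile interval of the resampled statistic.
#'
#' @param x,y numeric vectors.
#' @param statistic function(x, y) -> scalar (default [cliffs_d()]).
#' @param n_boot bootstrap replicates (default 2000; fewer than 100 warns).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(x, y, statistic = cliffs_d, n_boot = 2000,
                         level = 0.95, seed = 1) {
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  stat <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      statistic(sample(x, replace = TRUE), sample(y, replace = TRUE)),
      numeric(1))
  })
  a <- (1 - level) / 2
  unname(stats::quantile(stat, c(a, 1 - a)))
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step function F(t) = (#values <= t) / n.
#'
#' @param values numeric vector.
#' @return a function of class `ecdf` (see [stats::ecdf()]).
#' @export
ecdf_fun <- function(values) stats::ecdf(values)

#' Compare features between high- and low-polysome isoform sets
#'
#' For each numeric feature column, pools the values of the high-side and
#' low-side isoforms and reports Cliff's d (high vs low), a percentile
#' bootstrap confidence interval, and the two-tailed Mann-Whitney U test.
#' Missing feature values are dropped per side.
#'
#' @param feature_table data.frame with an `isoform_id` column and numeric
#'   feature columns.
#' @param high_ids,low_ids isoform id sets from [build_linked_sets()].
#' @param n_boot,level,seed bootstrap parameters (see [bootstrap_ci()]).
#' @param alpha significance convention for the `significant` flag
#'   (default 0.001).
#' @return data.frame: feature, d, ci_low, ci_high, U, p, m, n, significant.
#' @export
compare_features <- function(feature_table, high_ids, low_ids,
                             n_boot = 2000, level = 0.95, seed = 1,
                             alpha = 0.001) {
  if (!"isoform_id" %in% names(feature_table))
    stop("feature table must have an 'isoform_id' column")
  hi <- feature_table[feature_table$isoform_id %in% high_ids, , drop = FALSE]
  lo <- feature_table[feature_table$isoform_id %in% low_ids, , drop = FALSE]
  if (nrow(hi) == 0 || nrow(lo) == 0)
    stop("no isoforms from the feature table on one side of the comparison")
  feats <- names(feature_table)[vapply(feature_table, is.numeric, logical(1))]
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[i]
    # sorted so results are invariant to the row order of the table
    x <- sort(hi[[f]][!is.na(hi[[f]])])
    y <- sort(lo[[f]][!is.na(lo[[f]])])
    if (length(x) == 0 || length(y) == 0)
      return(data.frame(feature = f, d = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, U = NA_real_, p = NA_real_,
                        m = length(x), n = length(y), significant = NA))
    d <- cliffs_d(x, y)
    ci <- bootstrap_ci(x, y, cliffs_d, n_boot = n_boot, level = level,
                       seed = seed + i)
    mw <- mann_whitney(x, y)
    data.frame(feature = f, d = d, ci_low = ci[1], ci_high = ci[2],
               U = mw$U, p = mw$p, m = mw$m, n = mw$n,
               significant = mw$p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
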