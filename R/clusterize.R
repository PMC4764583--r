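#' Spearman rank-correlation distance matrix
#'
#' d(i, j) = 1 - rho_s(row_i, row_j), in \[0, 2\]. Rows with zero variance
#' have an undefined rank correlation; their off-diagonal distances are set
#' to 1 with a warning.
#'
#' @param rows numeric matrix, profiles in rows (>= 2 columns).
#' @return symmetric distance matrix with zero diagonal.
#' @export
spearman_distance_matrix <- function(rows) {
  rows <- as.matrix(rows)
  if (ncol(rows) < 2) stop("need at least 2 columns per profile")
  const <- apply(rows, 1, function(r) max(r) == min(r))
  if (any(const))
    warning(sum(const), " constant row(s): Spearman correlation undefined, ",
            "distance to other rows set to 1")
  rho <- suppressWarnings(stats::cor(t(rows), method = "spearman"))
  d <- 1 - rho
  d[is.na(d)] <- 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(rows), rownames(rows))
  d
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Thin wrapper over [stats::hclust()] on a precomputed dissimilarity.
#' Ties in merge height are broken by `hclust`'s deterministic
#' lowest-index rule, so the tree is reproducible for identical input.
#'
#' @param distance_matrix square symmetric matrix or `dist` object.
#' @param linkage agglomeration method, e.g. `"ward.D2"` (profiles) or
#'   `"complete"` (samples).
#' @return an `hclust` tree.
#' @export
hcluster <- function(distance_matrix, linkage = "ward.D2") {
  if (!inherits(distance_matrix, "dist")) {
    distance_matrix <- as.matrix(distance_matrix)
    if (nrow(distance_matrix) != ncol(distance_matrix))
      stop("distance matrix must be square")
    distance_matrix <- stats::as.dist(distance_matrix)
  }
  stats::hclust(distance_matrix, method = linkage)
}

new_cluster_result <- function(assignments, tree, linkage, distance) {
  structure(list(assignments = assignments, k = length(unique(assignments)),
                 tree = tree, linkage = linkage, distance = distance),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Cluster result:", length(x$assignments), "items in", x$k,
      "clusters (", x$linkage, "linkage,", x$distance, "distance )\n")
  print(table(x$assignments))
  invisible(x)
}

#' Cut a dendrogram into clusters
#'
#' Fixed-k or fixed-height cutting, plus an iterative-refinement mode that
#' increases k stepwise and keeps the deepest cut whose cluster
#' meta-profiles remain pairwise distinguishable (all pairwise Spearman
#' correlations of meta-profile means below `distinct_rho`).
#'
#' @param tree an `hclust` object (see [hcluster()]).
#' @param k number of clusters; ignored when `height` or `refine` given.
#' @param height cut height alternative to `k`.
#' @param refine if `TRUE`, choose k automatically by meta-profile
#'   distinguishability; requires `matrix`.
#' @param matrix profile matrix (rows in tree order) used to compute
#'   meta-profiles in refinement mode.
#' @param distinct_rho distinguishability threshold (default 0.95).
#' @param k_max largest k explored in refinement mode (default 12).
#' @param distance label stored in the result (bookkeeping only).
#' @return a `cluster_result` with contiguous labels `1..k`.
#' @export
cut_to_clusters <- function(tree, k = NULL, height = NULL, refine = FALSE,
                            matrix = NULL, distinct_rho = 0.95, k_max = 12,
                            distance = "spearman") {
  n <- length(tree$order)
  if (refine) {
    if (is.null(matrix)) stop("refinement mode needs the profile matrix")
    best <- 2L
    for (kk in 2:min(k_max, n)) {
      asg <- stats::cutree(tree, k = kk)
      mp <- meta_profiles(matrix, asg)
      means <- t(sapply(mp, `[[`, "mean"))
      rho <- suppressWarnings(stats::cor(t(means), method = "spearman"))
      if (all(rho[upper.tri(rho)] < distinct_rho, na.rm = TRUE)) best <- kk
      else break
    }
    asg <- stats::cutree(tree, k = best)
  } else if (!is.null(height)) {
    asg <- stats::cutree(tree, h = height)
  } else {
    if (is.null(k)) stop("supply k, height, or refine = TRUE")
    if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
    asg <- stats::cutree(tree, k = k)
  }
  new_cluster_result(asg, tree, tree$method, distance)
}

#' Per-cluster meta-profiles
#'
#' Mean and standard deviation of member profiles per column, the
#' "average relative abundance" summary of each cluster.
#'
#' @param matrix profile matrix (items x fractions).
#' @param assignments integer cluster labels, one per row (names optional;
#'   if named, matched to rownames).
#' @return named list of `meta_profile` objects, each a list with
#'   `cluster`, `n`, `mean`, `sd` (sd is 0 for singleton clusters).
#' @export
meta_profiles <- function(matrix, assignments) {
  matrix <- as.matrix(matrix)
  if (!is.null(names(assignments)) && !is.null(rownames(matrix)))
    assignments <- assignments[rownames(matrix)]
  if (length(assignments) != nrow(matrix))
    stop("one assignment per profile row required")
  labs <- sort(unique(assignments))
  out <- lapply(labs, function(l) {
    sub <- matrix[assignments == l, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty cluster: ", l)
    sds <- apply(sub, 2, stats::sd)
    sds[is.na(sds)] <- 0
    structure(list(cluster = l, n = nrow(sub), mean = colMeans(sub),
                   sd = sds), class = "meta_profile")
  })
  names(out) <- labs
  out
}

# Per-reference-cluster best Jaccard match against a new clustering,
# computed over the point indices in `use`.
jaccard_match <- function(ref, new, use) {
  ref_labs <- sort(unique(ref))
  vapply(ref_labs, function(l) {
    A <- intersect(which(ref == l), use)
    if (length(A) == 0) return(NA_real_)
    best <- 0
    for (m in unique(new[use])) {
      B <- intersect(which(new == m), use)
      j <- length(intersect(A, B)) / length(union(A, B))
      if (j > best) best <- j
    }
    best
  }, numeric(1))
}

#' Cluster stability by resampling (Jaccard coefficients)
#'
#' Assesses how reproducible each cluster is when the data are perturbed.
#' For each resample the data are re-clustered and every reference cluster
#' is matched to the most similar new cluster by the Jaccard coefficient
#' |A intersect B| / |A union B|; per-cluster means over `n` resamples are
#' reported. Schemes: `bootstrap` resamples points with replacement
#' (coefficients computed over the unique sampled points); `jitter` adds
#' Gaussian noise of `jitter_scale` times each column's s.d.; `noise`
#' replaces a fraction `noise_rate` of points with uniform draws within
#' each column's observed range (replaced points are excluded from the
#' Jaccard comparison). Clusters with mean coefficient >= 0.75 are
#' conventionally called stable.
#'
#' @param matrix data matrix, points (the objects being clustered) in rows.
#' @param clusterer function(matrix) -> integer cluster labels; must
#'   reproduce the reference clustering on the unperturbed matrix.
#' @param schemes subset of `c("bootstrap", "jitter", "noise")`.
#' @param n resamples per scheme (default 100).
#' @param seed integer seed.
#' @param jitter_scale s.d. multiplier for the jitter scheme (default 0.1).
#' @param noise_rate expected fraction of points replaced under the noise
#'   scheme (default 0.05; at least one point per resample).
#' @return a `stability_report`: list with `mean_jaccard` (scheme x cluster
#'   matrix), `stable` (logical matrix at the 0.75 rule), `n_resamples`.
#' @export
jaccard_stability <- function(matrix, clusterer,
                              schemes = c("bootstrap", "jitter", "noise"),
                              n = 100, seed = 1, jitter_scale = 0.1,
                              noise_rate = 0.05) {
  if (n < 1) stop("need at least one resample")
  schemes <- match.arg(schemes, several.ok = TRUE)
  dat <- as.matrix(matrix)
  np <- nrow(dat)
  ref <- clusterer(dat)
  labs <- sort(unique(ref))
  col_sd <- apply(dat, 2, stats::sd)
  col_min <- apply(dat, 2, min)
  col_rng <- apply(dat, 2, max) - col_min
  mean_j <- base::matrix(NA_real_, nrow = length(schemes),
                         ncol = length(labs),
                         dimnames = list(schemes, paste0("cluster", labs)))
  withr::with_seed(seed, {
    for (sc in schemes) {
      acc <- base::matrix(NA_real_, nrow = n, ncol = length(labs))
      for (b in seq_len(n)) {
        if (sc == "bootstrap") {
          idx <- sample.int(np, np, replace = TRUE)
          new_full <- rep(NA_integer_, np)
          uniq <- unique(idx)
          cl <- clusterer(dat[idx, , drop = FALSE])
          new_full[idx] <- cl
          acc[b, ] <- jaccard_match(ref, new_full, uniq)
        } else if (sc == "jitter") {
          pert <- dat + sweep(
            base::matrix(stats::rnorm(length(dat)), nrow = np), 2,
            jitter_scale * col_sd, `*`)
          acc[b, ] <- jaccard_match(ref, clusterer(pert), seq_len(np))
        } else {
          k_noise <- max(1L, stats::rbinom(1, np, noise_rate))
          repl <- sample.int(np, k_noise)
          pert <- dat
          pert[repl, ] <- sweep(sweep(
            base::matrix(stats::runif(k_noise * ncol(dat)), nrow = k_noise),
            2, col_rng, `*`), 2, col_min, `+`)
          acc[b, ] <- jaccard_match(ref, clusterer(pert),
                                    setdiff(seq_len(np), repl))
        }
      }
      mean_j[sc, ] <- colMeans(acc, na.rm = TRUE)
    }
  })
  structure(list(mean_jaccard = mean_j, stable = mean_j >= 0.75,
                 n_resamples = n, reference = ref),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Cluster stability over", x$n_resamples, "resamples (mean Jaccard):\n")
  print(round(x$mean_jaccard, 3))
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Clusters the columns of a variance-stabilized matrix with Euclidean
#' distance and complete linkage, the standard check that gradient
#' fractions recapitulate their physical order.
#'
#' @param vst_matrix matrix with samples in columns.
#' @param k optional number of groups to cut into (e.g. 4 for
#'   monosome / low-polysome / high-polysome / cytoplasmic).
#' @return an `hclust` tree if `k` is `NULL`, else a `cluster_result`
#'   over columns.
#' @export
cluster_samples <- function(vst_matrix, k = NULL) {
  tree <- stats::hclust(stats::dist(t(as.matrix(vst_matrix))),
                        method = "complete")
  if (is.null(k)) return(tree)
  asg <- stats::cutree(tree, k = k)
  new_cluster_result(asg, tree, "complete", "euclidean")
}

#' Rank clusters by polysome association of their meta-profiles
#'
#' Orders clusters by the weighted mean ribosome load of their mean
#' relative-abundance profile, used to pick high- and low-polysome
#' cluster sets for gene-linked comparisons.
#'
#' @param profiles list of meta-profiles from [meta_profiles()]; the mean
#'   vectors must carry ribosome-fraction names (`mono`..`p8plus`).
#' @param scheme a [weight_scheme()] supplying per-fraction ribosome loads.
#' @return numeric vector of polysome-skew scores, named by cluster, sorted
#'   decreasing (most polysome-associated first).
#' @export
rank_clusters_by_polysome <- function(profiles, scheme = weight_scheme()) {
  w <- scheme$weights
  score <- vapply(profiles, function(p) {
    m <- p$mean[names(w)]
    m <- m - min(m)            # centered profiles: shift to non-negative
    if (sum(m) == 0) return(NA_real_)
    sum(w * m) / sum(m)
  }, numeric(1))
  sort(score, decreasing = TRUE)
}
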