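# Projection of an external expression matrix (e.g. staged single-cell
# data) onto reference polysome clusters, and detection of isoform
# switches with translational consequences.

#' Cluster an external expression matrix
#'
#' Averages cells within stages, removes constant rows (undefined rank
#' correlation) with a warning, and applies the same machinery as the
#' reference profile clustering: Spearman distance, Ward linkage, fixed-k
#' cut on row-centered log-scale profiles.
#'
#' @param tpm isoform x cell TPM matrix.
#' @param samples data.frame with `cell`, `stage` columns matching the
#'   matrix columns.
#' @param k number of clusters (default 7).
#' @return a `cluster_result` over the retained isoforms.
#' @export
cluster_external <- function(tpm, samples, k = 7) {
  tpm <- as.matrix(tpm)
  if (!all(colnames(tpm) %in% samples$cell))
    stop("every matrix column needs a stage in 'samples'")
  stage <- samples$stage[match(colnames(tpm), samples$cell)]
  stages <- unique(stage)
  avg <- sapply(stages, function(s)
    rowMeans(tpm[, stage == s, drop = FALSE]))
  lg <- log2(avg + 1)
  const <- apply(lg, 1, function(r) max(r) == min(r))
  if (any(const))
    warning("removed ", sum(const), " constant row(s) before clustering")
  lg <- lg[!const, , drop = FALSE]
  lg <- lg - rowMeans(lg)
  d <- spearman_distance_matrix(lg)
  tree <- hcluster(d, linkage = "ward.D2")
  res <- cut_to_clusters(tree, k = k)
  names(res$assignments) <- rownames(lg)
  res
}

#' Map expressed transcripts onto reference clusters per stage
#'
#' For each cell, transcripts expressed above `expression_threshold` and
#' present in the reference clustering are assigned their reference
#' cluster; the per-cluster percentages (summing to 100 per cell) are
#' then averaged within stages, with the s.d. across cells reported.
#' Transcripts absent from the reference clustering are excluded.
#'
#' @param tpm isoform x cell TPM matrix.
#' @param samples data.frame with `cell`, `stage`.
#' @param reference_assignments named vector isoform -> reference cluster.
#' @param expression_threshold TPM threshold for "expressed" (default 1,
#'   strict greater-than).
#' @return a `stage_map` data.frame: stage, cluster, mean_pct, sd_pct,
#'   n_cells.
#' @export
map_to_reference <- function(tpm, samples, reference_assignments,
                             expression_threshold = 1) {
  tpm <- as.matrix(tpm)
  shared <- intersect(rownames(tpm), names(reference_assignments))
  if (length(shared) == 0)
    stop("no shared transcript identifiers with the reference clustering")
  tpm <- tpm[shared, , drop = FALSE]
  ref <- reference_assignments[shared]
  labs <- sort(unique(reference_assignments))
  per_cell <- sapply(colnames(tpm), function(cell) {
    expressed <- tpm[, cell] > expression_threshold
    if (!any(expressed)) return(rep(NA_real_, length(labs)))
    tab <- table(factor(ref[expressed], levels = labs))
    100 * as.vector(tab) / sum(tab)
  })
  per_cell <- base::matrix(per_cell, nrow = length(labs),
                           dimnames = list(as.character(labs),
                                           colnames(tpm)))
  stage <- samples$stage[match(colnames(tpm), samples$cell)]
  out <- do.call(rbind, lapply(unique(stage), function(s) {
    sub <- per_cell[, stage == s, drop = FALSE]
    data.frame(stage = s, cluster = labs,
               mean_pct = apply(sub, 1, mean, na.rm = TRUE),
               sd_pct = apply(sub, 1, function(r)
                 if (sum(!is.na(r)) > 1) stats::sd(r, na.rm = TRUE) else 0),
               n_cells = ncol(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("stage_map", "data.frame")
  out
}

#' Detect translationally consequential isoform switches
#'
#' Finds same-gene isoform pairs that fall in different external
#' (stage-pattern) clusters and whose reference polysome clusters lie on
#' opposite sides of the high/low partition. When external stage
#' meta-profiles are supplied, the isoform whose external cluster peaks
#' earlier is reported first and the direction is annotated as
#' `low_to_high` or `high_to_low` (reference side of the early isoform
#' first); otherwise direction is `NA`.
#'
#' @param external_assignments named vector isoform -> external cluster.
#' @param reference_assignments named vector isoform -> reference cluster.
#' @param high_clusters,low_clusters reference cluster labels on each side.
#' @param gene_map data.frame `isoform_id`, `gene_id`.
#' @param external_profiles optional list of meta-profiles (from
#'   [meta_profiles()] on the stage-averaged matrix) used to orient
#'   switches in time.
#' @return data.frame: gene_id, isoform_a, isoform_b, external clusters,
#'   reference clusters, direction; attributes `n_pairs`, `n_genes`.
#' @export
find_switches <- function(external_assignments, reference_assignments,
                          high_clusters, low_clusters, gene_map,
                          external_profiles = NULL) {
  ids <- intersect(names(external_assignments),
                   names(reference_assignments))
  gene <- setNames(as.character(gene_map$gene_id),
                   as.character(gene_map$isoform_id))[ids]
  side <- ifelse(reference_assignments[ids] %in% high_clusters, "high",
                 ifelse(reference_assignments[ids] %in% low_clusters,
                        "low", NA))
  peak_stage <- NULL
  if (!is.null(external_profiles)) {
    peak_stage <- vapply(external_profiles,
                         function(p) which.max(p$mean), numeric(1))
    names(peak_stage) <- vapply(external_profiles, function(p)
      as.character(p$cluster), character(1))
  }
  rows <- list()
  for (g in unique(gene[!is.na(gene)])) {
    members <- ids[gene == g & !is.na(side)]
    if (length(members) < 2) next
    cmb <- utils::combn(members, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      if (external_assignments[a] == external_assignments[b]) next
      if (side[match(a, ids)] == side[match(b, ids)]) next
      dir <- NA_character_
      if (!is.null(peak_stage)) {
        pa <- peak_stage[as.character(external_assignments[a])]
        pb <- peak_stage[as.character(external_assignments[b])]
        if (!is.na(pa) && !is.na(pb) && pa != pb) {
          early <- if (pa < pb) a else b
          late <- if (pa < pb) b else a
          a <- early; b <- late
          dir <- if (side[match(a, ids)] == "low") "low_to_high"
                 else "high_to_low"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, isoform_a = a, isoform_b = b,
        external_a = unname(external_assignments[a]),
        external_b = unname(external_assignments[b]),
        reference_a = unname(reference_assignments[a]),
        reference_b = unname(reference_assignments[b]),
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(gene_id = character(), isoform_a = character(),
                    isoform_b = character(), external_a = integer(),
                    external_b = integer(), reference_a = integer(),
                    reference_b = integer(), direction = character(),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_pairs") <- nrow(out)
  attr(out, "n_genes") <- length(unique(out$gene_id))
  out
}
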