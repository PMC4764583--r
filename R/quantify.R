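#' Per-fraction ribosome weight scheme
#'
#' Weights used to convert per-fraction read counts into an estimated number
#' of ribosome-bound reads. Each ribosome-containing fraction is weighted by
#' its nominal ribosome load (1 for the monosome, 2..7 for the discrete
#' polysome peaks). The final, unresolved eight-plus fraction is weighted by
#' the midpoint between its nominal load (8) and an assumed ceiling on
#' ribosomes per transcript: with the default ceiling of 40 this gives
#' (40 + 8) / 2 = 24.
#'
#' @param ceiling assumed maximum number of ribosomes per transcript
#'   (default 40).
#' @param include_monosome should the 80S monosome fraction contribute to
#'   weighted sums? Default `TRUE` (eight-term sum); `FALSE` restricts the
#'   sum to fractions carrying two or more ribosomes.
#' @return an object of class `weight_scheme`: a list with `weights` (named
#'   numeric over the eight ribosome-containing fractions), `ceiling`, and
#'   `include_monosome`.
#' @examples
#' weight_scheme()$weights[["p8plus"]]  # 24
#' @export
weight_scheme <- function(ceiling = 40, include_monosome = TRUE) {
  if (!is.numeric(ceiling) || length(ceiling) != 1L || ceiling < 8)
    stop("'ceiling' must be a single number >= 8")
  w <- RIBO_POSITIONS
  w[["p8plus"]] <- (ceiling + 8) / 2
  if (!include_monosome) w[["mono"]] <- 0
  structure(list(weights = w, ceiling = ceiling,
                 include_monosome = include_monosome),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Ribosome weight scheme (ceiling", x$ceiling, "ribosomes/transcript)\n")
  print(x$weights)
  invisible(x)
}

#' Convert RPKM to TPM
#'
#' TPM_i = RPKM_i * 1e6 / sum_g RPKM_g, so TPM sums to one million within a
#' sample.
#'
#' @param rpkm numeric vector of non-negative RPKM values, at least one
#'   positive.
#' @return numeric vector of TPM values summing to 1e6.
#' @export
rpkm_to_tpm <- function(rpkm) {
  if (any(rpkm < 0)) stop("RPKM values must be non-negative")
  tot <- sum(rpkm)
  if (tot == 0) stop("all-zero RPKM vector: TPM undefined")
  rpkm * 1e6 / tot
}

#' Convert raw counts to RPKM
#'
#' RPKM_i = counts_i * 1e9 / (length_i * library_size). Effective length is
#' the annotated transcript length; no fragment-length correction is applied.
#'
#' @param counts non-negative read counts.
#' @param effective_lengths transcript lengths in nt, all positive.
#' @param library_size total mapped reads in the sample, positive.
#' @return numeric vector of RPKM values.
#' @export
counts_to_rpkm <- function(counts, effective_lengths, library_size) {
  if (any(effective_lengths <= 0)) stop("effective lengths must be positive")
  if (length(library_size) != 1L || library_size <= 0)
    stop("library size must be a single positive number")
  counts * 1e9 / (effective_lengths * library_size)
}

#' Ribosome-weighted polysome count
#'
#' Weighted sum of per-fraction read counts, sum_i w_i * n_i over the
#' ribosome-containing fractions, with the eight-plus fraction weighted 24
#' under the default scheme. Accepts a single replicate-averaged profile
#' (named vector) or a matrix with fraction-named columns.
#'
#' @param profile named numeric vector, or matrix with columns named by
#'   fraction type, of replicate-averaged read counts.
#' @param scheme a [weight_scheme()].
#' @return a single weighted count, or a vector (one per matrix row).
#' @export
polysome_count <- function(profile, scheme = weight_scheme()) {
  w <- scheme$weights
  if (is.matrix(profile) || is.data.frame(profile)) {
    profile <- as.matrix(profile)
    missing <- setdiff(names(w), colnames(profile))
    if (length(missing))
      stop("profile lacks fraction column(s): ", paste(missing, collapse = ", "))
    return(drop(profile[, names(w), drop = FALSE] %*% w))
  }
  missing <- setdiff(names(w), names(profile))
  if (length(missing))
    stop("profile lacks fraction(s): ", paste(missing, collapse = ", "))
  sum(w * profile[names(w)])
}

#' Ribosome density
#'
#' Weighted polysome count divided by the cytoplasmic read count, an
#' estimate of the average ribosome load per transcript copy.
#'
#' @param profile per-fraction counts as in [polysome_count()].
#' @param cytoplasmic_count positive cytoplasmic read count(s).
#' @param scheme a [weight_scheme()].
#' @return numeric density value(s).
#' @export
ribosome_density <- function(profile, cytoplasmic_count,
                             scheme = weight_scheme()) {
  if (any(cytoplasmic_count <= 0))
    stop("cytoplasmic count must be positive: density undefined")
  polysome_count(profile, scheme) / cytoplasmic_count
}

#' Translation efficiency
#'
#' Ratio of a ribosome-associated signal (e.g. ribosome-profiling counts)
#' to the cytoplasmic RNA level of the same transcript.
#'
#' @param signal non-negative ribosome-associated signal.
#' @param cytoplasmic_level positive cytoplasmic RNA level.
#' @return `signal / cytoplasmic_level`.
#' @export
translation_efficiency <- function(signal, cytoplasmic_level) {
  if (any(cytoplasmic_level <= 0))
    stop("cytoplasmic level must be positive: efficiency undefined")
  signal / cytoplasmic_level
}

#' Variance-stabilizing transformation for counts
#'
#' Analytic variance-stabilizing map for negative-binomially distributed
#' counts with variance mu + alpha * mu^2:
#' `vst(x) = 2 * asinh(sqrt(alpha * x)) / log(2)`.
#' The map is finite at zero, strictly increasing, and approaches
#' log2(x) + constant for large counts, compressing low counts where
#' Poisson noise dominates.
#'
#' @param counts non-negative numeric matrix or vector.
#' @param alpha NB dispersion; if `NULL`, estimated by method of moments
#'   across columns (median of (var - mean) / mean^2 over rows), clamped to
#'   a minimum of 1e-4.
#' @return transformed matrix/vector with attribute `"alpha"`.
#' @export
vst <- function(counts, alpha = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(alpha)) {
    m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    ok <- is.finite(v) & mu > 0
    est <- (v[ok] - mu[ok]) / mu[ok]^2
    est <- est[is.finite(est) & est > 0]
    alpha <- if (length(est)) stats::median(est) else 1e-4
    alpha <- max(alpha, 1e-4)
  }
  if (alpha <= 0) stop("'alpha' must be positive")
  out <- 2 * asinh(sqrt(alpha * counts)) / log(2)
  attr(out, "alpha") <- alpha
  out
}

#' Average replicates, filter by abundance, and center rows
#'
#' Averages variance-stabilized replicate columns within each fraction type,
#' drops isoforms whose mean across the nine fraction types is at or below
#' `mean_threshold` (strict "greater than" retention), and subtracts each
#' surviving row's mean, yielding relative expression profiles.
#'
#' @param vst_matrix matrix of variance-stabilized values, columns named
#'   `<fraction>_<replicate>` or mapped via `replicate_map`.
#' @param replicate_map character vector mapping each column to its fraction
#'   type; default parses the part of each column name before the last `_`.
#' @param mean_threshold retention threshold on the nine-fraction mean
#'   (default 1).
#' @return matrix with one column per fraction type (gradient order),
#'   row means zero; attribute `"dropped"` holds the removed isoform ids.
#' @export
filter_and_center <- function(vst_matrix, replicate_map = NULL,
                              mean_threshold = 1) {
  vst_matrix <- as.matrix(vst_matrix)
  if (is.null(replicate_map))
    replicate_map <- sub("_[^_]*$", "", colnames(vst_matrix))
  if (length(replicate_map) != ncol(vst_matrix))
    stop("'replicate_map' must name a fraction for every column")
  bad <- setdiff(unique(replicate_map), FRACTIONS)
  if (length(bad))
    stop("unknown fraction type(s) in replicate map: ",
         paste(bad, collapse = ", "))
  fr <- intersect(FRACTIONS, unique(replicate_map))
  avg <- sapply(fr, function(f)
    rowMeans(vst_matrix[, replicate_map == f, drop = FALSE]))
  avg <- matrix(avg, nrow = nrow(vst_matrix),
                dimnames = list(rownames(vst_matrix), fr))
  keep <- rowMeans(avg) > mean_threshold
  out <- avg[keep, , drop = FALSE]
  out <- out - rowMeans(out)
  attr(out, "dropped") <- rownames(avg)[!keep]
  out
}

#' Retain isoforms exceeding a read threshold in given fractions
#'
#' An isoform is retained when its count is strictly greater than
#' `min_reads` in every named fraction. An empty fraction list retains all
#' isoforms.
#'
#' @param counts_matrix counts with fraction-named columns.
#' @param fractions character vector of column names to test.
#' @param min_reads strict threshold (default 100).
#' @return character vector of retained isoform ids (rownames).
#' @export
threshold_by_reads <- function(counts_matrix, fractions, min_reads = 100) {
  counts_matrix <- as.matrix(counts_matrix)
  if (length(fractions) == 0) return(rownames(counts_matrix))
  missing <- setdiff(fractions, colnames(counts_matrix))
  if (length(missing))
    stop("fraction(s) not present: ", paste(missing, collapse = ", "))
  sub <- counts_matrix[, fractions, drop = FALSE]
  keep <- rowSums(sub > min_reads) == length(fractions)
  rownames(counts_matrix)[keep]
}
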