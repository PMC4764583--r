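# Shared synthetic fixtures, generated once per test run. Everything is
# seeded, so every file sees identical data.

synth_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(synth_cache$sim))
    synth_cache$sim <- simulate_counts(make_archetypes(8), seed = 42)
  synth_cache$sim
}

shared_ann <- function() {
  if (is.null(synth_cache$ann))
    synth_cache$ann <- simulate_annotation(shared_sim()$truth, seed = 43)
  synth_cache$ann
}

shared_vst <- function() {
  if (is.null(synth_cache$vst))
    synth_cache$vst <- vst(shared_sim()$counts)
  synth_cache$vst
}

shared_rel <- function() {
  if (is.null(synth_cache$rel))
    synth_cache$rel <- filter_and_center(shared_vst())
  synth_cache$rel
}

# Reference isoform clustering of the shared data (Spearman + ward.D2, k=8).
shared_isoform_clusters <- function() {
  if (is.null(synth_cache$iso)) {
    rel <- shared_rel()
    d <- spearman_distance_matrix(rel[, fraction_types(ribosomal = TRUE)])
    synth_cache$iso <- cut_to_clusters(hcluster(d), k = 8)
  }
  synth_cache$iso
}

# Exhaustive pairwise-count oracles for Cliff's d and the U statistic.
oracle_cliffs_d <- function(x, y) {
  (sum(outer(x, y, ">")) - sum(outer(x, y, "<"))) / (length(x) * length(y))
}
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exhaustive non-crossing base-pair maximization oracle (Watson-Crick +
# GU wobble, minimum hairpin loop `minloop`), feasible for sequences of
# up to ~16 nt. Recursion over contiguous index segments enforces
# nestedness, matching the dynamic program's model.
oracle_max_pairs <- function(seq, minloop = 3) {
  ch <- strsplit(chartr("Uu", "TT", toupper(seq)), "")[[1]]
  wc <- function(a, b)
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i < minloop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + minloop + 1L):j) {
      if (wc(ch[i], ch[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  n <- length(ch)
  if (n < 2) 0L else rec(1L, n)
}

# The four expected sample groups of the default gradient design.
expected_sample_groups <- function(n_replicates = 2) {
  reps <- seq_len(n_replicates)
  list(as.vector(outer("cyto", reps, paste, sep = "_")),
       as.vector(outer("mono", reps, paste, sep = "_")),
       sort(as.vector(outer(c("p2", "p3", "p4"), reps, paste, sep = "_"))),
       sort(as.vector(outer(c("p5", "p6", "p7", "p8plus"), reps,
                            paste, sep = "_"))))
}

# Does a cluster_result over samples reproduce the expected 4 groups?
same_partition <- function(assignments, want) {
  parts <- lapply(unname(split(names(assignments), assignments)), sort)
  setequal(parts, lapply(want, sort))
}
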