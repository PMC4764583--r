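# Generator: archetypes, count simulation, annotation, external matrix.

test_that("make_archetypes validates k and spans the required shapes", {
  expect_error(make_archetypes(1), "between 2 and 12")
  expect_error(make_archetypes(13), "between 2 and 12")
  expect_error(make_archetypes("a"), "between 2 and 12")

  a2 <- make_archetypes(2)
  ribo <- fraction_types(ribosomal = TRUE)
  w1 <- a2[[1]]$fraction_weights[ribo]
  w2 <- a2[[2]]$fraction_weights[ribo]
  # one shape peaked in the heavy fractions (5..8+), one at the monosome
  expect_true(names(which.max(w1)) %in% c("p5", "p6", "p7", "p8plus"))
  expect_identical(names(which.max(w2)), "mono")
  expect_identical(a2[[1]]$class, "high")
  expect_identical(a2[[2]]$class, "low")
})

test_that("archetype weights are normalized, non-negative, rank-distinct", {
  ribo <- fraction_types(ribosomal = TRUE)
  for (k in 2:12) {
    arch <- make_archetypes(k)
    expect_length(arch, k)
    W <- vapply(arch, function(a) a$fraction_weights[ribo], numeric(8))
    expect_true(all(W >= 0))
    expect_equal(colSums(W), rep(1, k), tolerance = 1e-12,
                 ignore_attr = TRUE)
    rho <- cor(W, method = "spearman")
    expect_lt(max(rho[upper.tri(rho)]), 0.95)
  }
})

test_that("simulate_counts is deterministic and shape-consistent", {
  arch <- make_archetypes(8)
  s1 <- simulate_counts(arch, n_genes = 30, seed = 9)
  s2 <- simulate_counts(arch, n_genes = 30, seed = 9)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(arch, n_genes = 30, seed = 10)
  expect_false(identical(s1$counts, s3$counts))

  sim <- shared_sim()
  expect_identical(nrow(sim$counts), nrow(sim$truth))
  expect_identical(rownames(sim$counts), sim$truth$isoform_id)
  expect_false(anyDuplicated(sim$truth$isoform_id) > 0)
  expect_identical(ncol(sim$counts), 18L)   # 9 fraction types x 2 replicates
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == floor(sim$counts)))
  # every multi-isoform gene carries a planted high/low pair
  multi <- names(which(table(sim$truth$gene_id) >= 2))
  for (g in multi[1:10]) {
    cls <- sim$truth$class[sim$truth$gene_id == g]
    expect_true(all(c("high", "low") %in% cls))
  }
})

test_that("simulate_counts rejects bad parameters and archetype sets", {
  arch <- make_archetypes(8)
  expect_error(simulate_counts(arch, depth = 0), "depth")
  expect_error(simulate_counts(arch, depth = -5), "depth")
  expect_error(simulate_counts(arch, dispersion = 0), "dispersion")
  mid_only <- lapply(arch[1:2], function(a) { a$class <- "mid"; a })
  expect_error(simulate_counts(mid_only), "high- and low-polysome")
})

test_that("zero archetype weight propagates to zero observed counts", {
  ribo <- fraction_types(ribosomal = TRUE)
  mk <- function(name, w, cls) {
    fw <- c(cyto = 0.3, setNames(w, ribo))
    structure(list(name = name, fraction_weights = fw,
                   skew = sum(seq_len(8) * w), class = cls),
              class = "archetype")
  }
  a_hi <- mk("H", c(0, 0, 0, 0, 0.2, 0.2, 0.3, 0.3), "high")
  a_lo <- mk("L", c(0.6, 0.4, 0, 0, 0, 0, 0, 0), "low")
  sim <- simulate_counts(list(a_hi, a_lo), n_genes = 40, seed = 3)
  for (a in list(a_hi, a_lo)) {
    zero_fr <- ribo[a$fraction_weights[ribo] == 0]
    rows <- sim$truth$archetype == a$name
    cols <- as.vector(outer(zero_fr, 1:2, paste, sep = "_"))
    expect_true(all(sim$counts[rows, cols] == 0))
  }
})

test_that("counts approach their expectations in the Poisson limit", {
  sim <- simulate_counts(make_archetypes(2), n_genes = 80,
                         dispersion = 1e8, seed = 7)
  c1 <- sim$counts[, paste(fraction_types(), 1, sep = "_")]
  c2 <- sim$counts[, paste(fraction_types(), 2, sep = "_")]
  mu <- (c1 + c2) / 2
  big <- mu >= 1000
  expect_gt(sum(big), 100)
  rel <- abs(c1[big] - c2[big]) / mu[big]
  # Poisson at mu >= 1000: sd of the relative replicate gap ~ sqrt(2/mu)
  expect_lt(stats::median(rel), 0.05)
  expect_lt(stats::quantile(rel, 0.99), 0.15)
})

test_that("annotation realizes planted UTR classes with ordered pairs", {
  ann <- shared_ann()
  tr <- ann$truth
  expect_identical(nrow(tr), nrow(shared_sim()$truth))
  # per-gene ordering: every planted long UTR exceeds every short one
  for (g in unique(tr$gene_id)) {
    s <- tr[tr$gene_id == g, ]
    L <- s$utr3_length[s$utr3_class == "long"]
    S <- s$utr3_length[s$utr3_class == "short"]
    if (length(L) && length(S)) expect_true(min(L) > max(S))
  }
  expect_gt(sum(tr$utr3_class == "long") + sum(tr$utr3_class == "short"),
            500)
  expect_equal(mean(tr$utr3_length[tr$utr3_class == "long"]), 1551,
               tolerance = 0.1)
  expect_equal(mean(tr$utr3_length[tr$utr3_class == "short"]), 982,
               tolerance = 0.1)
})

test_that("annotation sequences satisfy the CDS construction invariants", {
  ann <- shared_ann()
  reg <- ann$regions
  expect_true(all(nchar(reg$cds) %% 3 == 0))
  expect_true(all(substr(reg$cds, 1, 3) == "ATG"))
  last <- substr(reg$cds, nchar(reg$cds) - 2, nchar(reg$cds))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  # spliced transcript = leader + CDS + 3' UTR
  expect_identical(unname(ann$transcripts[reg$isoform_id]),
                   paste0(reg$leader, reg$cds, reg$utr3))
  # GTF / genome / transcript sequences are mutually consistent
  models <- decompose_all(ann$gtf, ann$genome)
  ids <- reg$isoform_id[1:25]
  for (id in ids) {
    expect_identical(models[[id]]$spliced, unname(ann$transcripts[id]))
    expect_identical(models[[id]]$leader,
                     reg$leader[reg$isoform_id == id])
    expect_identical(models[[id]]$utr3, reg$utr3[reg$isoform_id == id])
    expect_true(models[[id]]$complete)
  }
})

test_that("annotation is deterministic and rejects inconsistent truth", {
  tr <- shared_sim()$truth[1:12, ]
  a1 <- simulate_annotation(tr, seed = 5)
  a2 <- simulate_annotation(tr, seed = 5)
  expect_identical(a1$genome, a2$genome)
  expect_identical(a1$gtf, a2$gtf)
  expect_identical(a1$transcripts, a2$transcripts)
  bad <- tr
  bad$gene_id[3] <- NA
  expect_error(simulate_annotation(bad), "isoform without gene")
  expect_error(simulate_annotation(tr[, c("isoform_id", "gene_id")]),
               "class")
})

test_that("simulate_external plants switches at the requested rate", {
  truth <- shared_sim()$truth
  ext0 <- simulate_external(truth, switch_rate = 0, seed = 2)
  expect_identical(nrow(ext0$switches), 0L)
  # no gene changes dominant isoform across stages
  dom_const <- vapply(unique(truth$gene_id), function(g) {
    sm <- ext0$stage_means[truth$gene_id == g, , drop = FALSE]
    length(unique(apply(sm, 2, which.max))) == 1
  }, logical(1))
  expect_true(all(dom_const))

  ext <- simulate_external(truth, switch_rate = 0.2, seed = 2)
  n_elig <- sum(vapply(split(truth$class, truth$gene_id), function(cl)
    any(cl == "high") && any(cl == "low"), logical(1)))
  bounds <- stats::qbinom(c(0.0025, 0.9975), n_elig, 0.2)
  expect_gte(nrow(ext$switches), bounds[1])
  expect_lte(nrow(ext$switches), bounds[2])
  # switching pairs span the high/low partition
  cls <- setNames(truth$class, truth$isoform_id)
  pair_cls <- cbind(cls[ext$switches$isoform_early],
                    cls[ext$switches$isoform_late])
  expect_true(all(apply(pair_cls, 1, function(p)
    setequal(p, c("high", "low")))))
})

test_that("simulate_external shapes, TPM scaling, and validation", {
  truth <- shared_sim()$truth
  ext <- simulate_external(truth, n_stages = 2, cells_per_stage = 1,
                           seed = 4)
  expect_identical(dim(ext$tpm), c(nrow(truth), 2L))
  full <- simulate_external(truth, seed = 4)
  expect_equal(unname(colSums(full$tpm)), rep(1e6, ncol(full$tpm)),
               tolerance = 1e-9)
  expect_identical(full$tpm,
                   simulate_external(truth, seed = 4)$tpm)
  expect_error(simulate_external(truth, n_stages = 1), "at least 2")
  expect_error(simulate_external(truth, switch_rate = 1.5), "switch_rate")
  expect_error(simulate_external(truth, switch_rate = -0.1), "switch_rate")
})
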