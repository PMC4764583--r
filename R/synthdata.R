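# Synthetic TrIP-seq-like data with planted ground truth. The generator
# emulates the statistical structure the downstream analysis assumes:
# isoform profiles drawn from a small set of fraction-distribution
# archetypes with negative-binomial replicate noise, a toy annotation in
# which gene-linked isoform pairs carry planted 3' UTR / AU-run / uORF
# differences, and an external stage-by-cell matrix with planted isoform
# switches.

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                    c("T", "C", "A", "G"), paste0),
                              c("T", "C", "A", "G"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, c("TAA", "TAG", "TGA"))

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Construct fraction-distribution archetypes
#'
#' Builds `k` archetypal profiles over the eight ribosome-containing
#' fractions from a fixed library of qualitatively distinct shapes. The
#' library is organized around the three ribosome-load regimes visible in
#' a sucrose gradient -- monosome-bound, light polysomes (two to four
#' ribosomes), heavy polysomes (five to eight-plus) -- with the
#' transitions between regimes wider than the steps within a regime (a
#' transcript bound by one ribosome differs qualitatively from one bound
#' by several, while neighboring heavy fractions overlap physically).
#' Each archetype has a core block in one or more regimes with a
#' distinctive within-block tilt, plus deterministic tails that decay
#' geometrically with distance in that warped gradient coordinate and a
#' small uniform baseline, so every pair of archetypes differs in its
#' fraction rank order (all pairwise Spearman correlations < 0.95 for any
#' `k`). The first two shapes are the canonical heavy-polysome and
#' monosome-skewed profiles. Weights are non-negative and sum to one over
#' the eight ribosome-containing fractions; the free cytoplasmic weight
#' is larger for low-polysome archetypes (poorly translated messages
#' still present in cytoplasm).
#'
#' @param k number of archetypes, between 2 and 12.
#' @return list of `archetype` objects: `name`, `fraction_weights`
#'   (named 9-vector: `cyto` plus the eight ribosome fractions), `skew`
#'   (weighted mean ribosome load), `class` ("high"/"mid"/"low").
#' @export
make_archetypes <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k > 12)
    stop("'k' must be between 2 and 12")
  pos <- seq_along(RIBO_FRACTIONS)           # 1 = mono .. 8 = p8plus
  # Warped gradient coordinate: mono|p2 and p4|p5 transitions are wide.
  u <- c(1, 3.3, 3.87, 4.44, 6.28, 6.85, 7.43, 8)
  mono <- c(1, rep(0, 7))
  light <- function(t) c(0, t / sum(t), rep(0, 4))      # over p2..p4
  heavy <- function(t) c(rep(0, 4), t / sum(t))         # over p5..p8plus
  mix <- function(a, wa, b) wa * a + (1 - wa) * b
  cores <- list(
    heavy(c(1, 2, 3.5, 6)),                          # 1 heavy, rising
    mono,                                            # 2 monosome
    light(c(5, 3, 1.8)),                             # 3 light, falling
    heavy(c(6, 3.5, 2, 1)),                          # 4 heavy, falling
    mix(light(c(2, 1.3, 1)), 0.5,
        heavy(c(1, 1.3, 1.8, 2.6))),                 # 5 bimodal, out-tilted
    mix(mono, 0.45, heavy(c(1, 1.3, 1.6, 2))),       # 6 mono + heavy rising
    light(c(1, 1.6, 2.6)),                           # 7 light, rising
    mix(mono, 0.5, light(c(1, 1.3, 1.7))),           # 8 mono + light rising
    mix(mono, 0.3, mix(light(c(1, 1.4, 1.9)), 0.5,
        heavy(c(1.8, 1.3, 1, 0.9)))),                # 9 all three blocks
    light(c(1, 3.5, 1.2)),                           # 10 light peak at 3
    mix(light(c(2, 1.2, 1)), 0.45,
        heavy(c(2, 1.4, 1, 0.8))),                   # 11 bimodal, in-tilted
    mix(mono, 0.4, heavy(c(5, 3, 2, 1))))            # 12 mono + heavy falling
  shape_from_core <- function(core) {
    w <- vapply(seq_along(u), function(i)
      max(core * 2^(-2.2 * abs(u[i] - u))), numeric(1))
    w <- w / sum(w) + 0.008
    w / sum(w)
  }
  lapply(seq_len(k), function(j) {
    w <- shape_from_core(cores[[j]])
    skew <- sum(pos * w)
    cyto <- 0.2 + 0.6 * (8 - skew) / 7
    fw <- c(cyto = cyto, setNames(w, RIBO_FRACTIONS))
    cls <- if (skew >= 5.5) "high" else if (skew <= 3.5) "low" else "mid"
    structure(list(name = paste0("A", j), fraction_weights = fw,
                   skew = skew, class = cls), class = "archetype")
  })
}

#' Simulate an isoform-by-fraction count matrix with ground truth
#'
#' Genes receive 2-4 isoforms; the first two isoforms of each
#' multi-isoform gene are planted in a high- and a low-polysome archetype
#' respectively, guaranteeing gene-linked pairs spanning the partition.
#' Expected counts are `depth * abundance_i * weight_f`; the cytoplasmic
#' expectation is a `cyto_mix` combination of the ribosome-fraction
#' expectations plus the archetype's free cytoplasmic term. Counts are
#' negative binomial with NB size `dispersion` (large values approach the
#' Poisson limit); replicates share expectations.
#'
#' The truth table also plants per-isoform feature classes realized later
#' by [simulate_annotation()]: low-polysome isoforms get long 3' UTRs,
#' high AU-run content, and cognate uORFs at an elevated rate.
#'
#' @param archetypes list from [make_archetypes()].
#' @param n_genes number of genes (default 200).
#' @param isoforms_per_gene integer vector sampled uniformly per gene
#'   (default 2:4).
#' @param depth expected total reads across the ribosome fractions
#'   (default 2e6).
#' @param dispersion NB size parameter (> 0, default 20).
#' @param n_replicates biological replicates per fraction (default 2).
#' @param seed integer seed; identical seeds give identical output.
#' @param cyto_mix weight of the ribosome-fraction mixture in the
#'   cytoplasmic expectation (default 0.5).
#' @param uorf_rates planting rates: cognate uORF in low / high class,
#'   and non-cognate anywhere.
#' @return list of class `polysome_sim`: `counts` (integer matrix,
#'   columns `<fraction>_<rep>`), `truth` (isoform_id, gene_id, archetype,
#'   class, abundance, utr3_class, au_class, uorf_class), `archetypes`,
#'   and the simulation parameters.
#' @export
simulate_counts <- function(archetypes, n_genes = 200,
                            isoforms_per_gene = 2:4, depth = 2e6,
                            dispersion = 20, n_replicates = 2, seed = 1,
                            cyto_mix = 0.5,
                            uorf_rates = c(low_cognate = 0.4,
                                           high_cognate = 0.1,
                                           noncognate = 0.15)) {
  if (depth <= 0) stop("'depth' must be positive")
  if (dispersion <= 0) stop("'dispersion' must be positive")
  cls <- vapply(archetypes, `[[`, character(1), "class")
  names(archetypes) <- vapply(archetypes, `[[`, character(1), "name")
  hi <- names(archetypes)[cls == "high"]
  lo <- names(archetypes)[cls == "low"]
  if (!length(hi) || !length(lo))
    stop("archetype set must contain both high- and low-polysome shapes")
  withr::with_seed(seed, {
    n_iso_per_gene <- sample(isoforms_per_gene, n_genes, replace = TRUE)
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    truth <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
      n <- n_iso_per_gene[g]
      arch <- character(n)
      if (n >= 2) {
        arch[1] <- sample(hi, 1)
        arch[2] <- sample(lo, 1)
        if (n > 2) arch[3:n] <- sample(names(archetypes), n - 2,
                                       replace = TRUE)
      } else {
        arch[1] <- sample(names(archetypes), 1)
      }
      data.frame(isoform_id = sprintf("%s.%d", gene_ids[g], seq_len(n)),
                 gene_id = gene_ids[g], archetype = arch,
                 stringsAsFactors = FALSE)
    }))
    truth$class <- cls[match(truth$archetype, names(archetypes))]
    n_iso <- nrow(truth)
    ab <- stats::rlnorm(n_iso, 0, 1)
    truth$abundance <- ab / sum(ab)
    truth$utr3_class <- ifelse(truth$class == "low", "long",
                               ifelse(truth$class == "high", "short",
                                      sample(c("long", "short"), n_iso,
                                             replace = TRUE)))
    truth$au_class <- ifelse(truth$class == "low", "high", "low")
    p_cog <- ifelse(truth$class == "low", uorf_rates[["low_cognate"]],
                    uorf_rates[["high_cognate"]])
    cog <- stats::rbinom(n_iso, 1, p_cog) == 1
    noncog <- !cog & stats::rbinom(n_iso, 1, uorf_rates[["noncognate"]]) == 1
    truth$uorf_class <- ifelse(cog, "cognate",
                               ifelse(noncog, "noncognate", "none"))

    W <- t(vapply(archetypes[truth$archetype], `[[`, numeric(9),
                  "fraction_weights"))
    mu_ribo <- depth * truth$abundance * W[, RIBO_FRACTIONS]
    mu_cyto <- cyto_mix * rowSums(mu_ribo) +
      depth * truth$abundance * W[, "cyto"]
    mu <- cbind(cyto = mu_cyto, mu_ribo)
    counts <- base::matrix(0L, nrow = n_iso,
                           ncol = length(FRACTIONS) * n_replicates)
    colnames(counts) <- as.vector(t(outer(FRACTIONS,
                                          seq_len(n_replicates),
                                          paste, sep = "_")))
    rownames(counts) <- truth$isoform_id
    for (f in FRACTIONS) {
      for (r in seq_len(n_replicates)) {
        counts[, paste(f, r, sep = "_")] <-
          stats::rnbinom(n_iso, mu = mu[, f], size = dispersion)
      }
    }
    structure(list(counts = counts, truth = truth,
                   archetypes = archetypes,
                   params = list(n_genes = n_genes, depth = depth,
                                 dispersion = dispersion,
                                 n_replicates = n_replicates, seed = seed,
                                 cyto_mix = cyto_mix)),
              class = "polysome_sim")
  })
}

#' @export
print.polysome_sim <- function(x, ...) {
  cat("Synthetic polysome-profile counts:", nrow(x$counts), "isoforms x",
      ncol(x$counts), "samples;", length(x$archetypes),
      "archetypes; seed", x$params$seed, "\n")
  invisible(x)
}

# Map a transcript-coordinate interval to genomic intervals given the
# exon layout. All coordinates 1-based inclusive.
tx_interval_to_genomic <- function(iv, tx_start, tx_end, g_start, g_end,
                                   strand) {
  out <- NULL
  for (i in seq_along(tx_start)) {
    s <- max(iv[1], tx_start[i]); t <- min(iv[2], tx_end[i])
    if (s > t) next
    if (strand == "+") {
      gs <- g_start[i] + (s - tx_start[i])
      ge <- g_start[i] + (t - tx_start[i])
    } else {
      ge <- g_end[i] - (s - tx_start[i])
      gs <- g_end[i] - (t - tx_start[i])
    }
    out <- rbind(out, c(gs, ge))
  }
  out
}

#' Realize a toy annotation and sequence set from a truth table
#'
#' Generates, for every isoform in the truth table, a spliced transcript
#' (5' leader + CDS + 3' UTR) realizing the planted feature classes:
#' low-polysome isoforms get 3' UTRs drawn around `utr3_mean_long`
#' (default 1551 nt) versus `utr3_mean_short` (982 nt) for high-polysome
#' isoforms, more inserted A/U runs, and uORF cassettes (ATG or
#' near-cognate start ... stop) in the leader per the planted uORF class.
#' Every CDS starts with ATG, ends with a stop, and has length divisible
#' by three. Transcripts are laid out with introns on one contig per gene
#' (strand alternating by gene) and emitted as mutually consistent GTF,
#' genome FASTA, and per-transcript sequences, plus auxiliary tables
#' (codon usage, miRNA target sites, half-lives, planted uORFs).
#'
#' @param truth truth table from [simulate_counts()].
#' @param seed integer seed.
#' @param utr3_mean_long,utr3_mean_short mean planted 3' UTR lengths (nt).
#' @param utr3_cv coefficient of variation of UTR lengths (default 0.25).
#' @param leader_range,cds_codon_range uniform sampling ranges for leader
#'   length (nt) and CDS length (codons).
#' @param intron_length intron size in nt (default 60).
#' @return list: `gtf` (data.frame), `genome` (named character by contig),
#'   `transcripts`, `regions` (leader/cds/utr3 sequences per isoform),
#'   `codon_usage`, `mirna_sites`, `half_life`, `uorfs`,
#'   `expressed_mirnas`, augmented `truth`.
#' @export
simulate_annotation <- function(truth, seed = 1, utr3_mean_long = 1551,
                                utr3_mean_short = 982, utr3_cv = 0.25,
                                leader_range = c(100, 260),
                                cds_codon_range = c(120, 400),
                                intron_length = 60) {
  if (!all(c("isoform_id", "gene_id", "class") %in% names(truth)))
    stop("truth table must carry isoform_id, gene_id, and class")
  if (anyNA(truth$gene_id)) stop("isoform without gene in truth table")
  withr::with_seed(seed, {
    genes <- unique(truth$gene_id)
    strand_of <- setNames(rep(c("+", "-"), length.out = length(genes)),
                          genes)
    gtf_rows <- list(); region_rows <- list(); uorf_rows <- list()
    mirna_rows <- list(); tx_seqs <- character(0)
    genome <- setNames(vector("list", length(genes)), genes)
    mirna_ids <- sprintf("miR-%03d", 1:50)
    expressed <- sample(mirna_ids, 25)

    utr3_len_all <- integer(nrow(truth))
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      sub <- which(truth$gene_id == g)
      strand <- strand_of[[g]]
      cursor <- 1L
      chunks <- character(0)
      # Draw all 3' UTR lengths of the gene first, then hand the largest
      # draws to the long-class isoforms so every planted (short, long)
      # pair is ordered, while the within-gene multiset of lengths (and
      # hence the class means across genes) is essentially unchanged.
      mus <- ifelse(truth$utr3_class[sub] == "long", utr3_mean_long,
                    utr3_mean_short)
      lens <- pmax(40L, round(stats::rnorm(length(sub), mus,
                                           utr3_cv * mus)))
      ord_cls <- order(mus, decreasing = TRUE)   # long-class first
      lens[ord_cls] <- sort(lens, decreasing = TRUE)
      is_long <- truth$utr3_class[sub] == "long"
      if (any(is_long) && any(!is_long) &&
          min(lens[is_long]) <= max(lens[!is_long]))
        lens[is_long] <- lens[is_long] +
          (max(lens[!is_long]) - min(lens[is_long]) + 1L)
      for (ii in sub) {
        cls <- truth$class[ii]
        id <- truth$isoform_id[ii]
        # --- spliced sequence with planted features -------------------
        utr3_len <- lens[[match(ii, sub)]]
        utr3 <- rand_seq(utr3_len)
        n_runs <- if (truth$au_class[ii] == "high")
          max(1L, round(utr3_len / 150)) else round(utr3_len / 500)
        if (n_runs > 0) {
          for (r in seq_len(n_runs)) {
            rl <- sample(6:10, 1)
            p <- sample.int(utr3_len - rl, 1)
            substr(utr3, p, p + rl - 1) <-
              paste(sample(c("A", "T"), rl, replace = TRUE, prob = c(.6, .4)),
                    collapse = "")
          }
        }
        leader_len <- sample(leader_range[1]:leader_range[2], 1)
        leader <- rand_seq(leader_len)
        if (truth$uorf_class[ii] != "none") {
          start_codon <- if (truth$uorf_class[ii] == "cognate") "ATG"
                         else sample(NEAR_COGNATE_STARTS, 1)
          cassette <- paste0(start_codon,
                             paste(sample(SENSE_CODONS, 4, replace = TRUE),
                                   collapse = ""), "TAA")
          p <- sample.int(leader_len - nchar(cassette), 1)
          substr(leader, p, p + nchar(cassette) - 1) <- cassette
          uorf_rows[[length(uorf_rows) + 1L]] <-
            data.frame(transcript_id = id, start = p,
                       end = p + nchar(cassette) - 1,
                       start_codon = start_codon, stringsAsFactors = FALSE)
        }
        n_codons <- sample(cds_codon_range[1]:cds_codon_range[2], 1)
        cds <- paste0("ATG",
                      paste(sample(SENSE_CODONS, n_codons - 2,
                                   replace = TRUE), collapse = ""),
                      sample(STOP_CODONS, 1))
        spliced <- paste0(leader, cds, utr3)
        L <- nchar(spliced)
        utr3_len_all[ii] <- utr3_len

        # --- exon layout ----------------------------------------------
        n_ex <- switch(cls, high = sample(3:6, 1), low = sample(1:3, 1),
                       sample(2:4, 1))
        n_ex <- min(n_ex, L - 1L)
        cuts <- sort(sample(2:(L - 1), n_ex - 1))
        tx_start <- c(1L, cuts)
        tx_end <- c(cuts - 1L, L)
        ex_len <- tx_end - tx_start + 1L
        if (strand == "+") {
          g_start <- cursor + c(0L, cumsum(ex_len[-n_ex] + intron_length))
          g_end <- g_start + ex_len - 1L
          piece <- character(0)
          for (e in seq_len(n_ex)) {
            piece <- c(piece, substr(spliced, tx_start[e], tx_end[e]))
            if (e < n_ex) piece <- c(piece, rand_seq(intron_length))
          }
        } else {
          # genomic ascending exon j corresponds to transcript exon
          # n_ex + 1 - j, reverse-complemented
          glen <- rev(ex_len)
          g_start_asc <- cursor + c(0L, cumsum(glen[-n_ex] + intron_length))
          g_end_asc <- g_start_asc + glen - 1L
          g_start <- rev(g_start_asc)   # indexed by transcript exon
          g_end <- rev(g_end_asc)
          piece <- character(0)
          for (j in seq_len(n_ex)) {
            e <- n_ex + 1L - j
            piece <- c(piece, revcomp(substr(spliced, tx_start[e],
                                             tx_end[e])))
            if (j < n_ex) piece <- c(piece, rand_seq(intron_length))
          }
        }
        chunk <- paste(piece, collapse = "")
        chunks <- c(chunks, chunk, rand_seq(100L))
        span <- c(cursor, cursor + nchar(chunk) - 1L)
        cursor <- cursor + nchar(chunk) + 100L

        ex_g <- cbind(pmin(g_start, g_end), pmax(g_start, g_end))
        cds_iv <- c(leader_len + 1L, leader_len + nchar(cds))
        cds_g <- tx_interval_to_genomic(cds_iv, tx_start, tx_end,
                                        g_start, g_end, strand)
        gtf_rows[[length(gtf_rows) + 1L]] <- rbind(
          data.frame(seqname = g, source = "polyprof",
                     feature = "transcript", start = span[1], end = span[2],
                     strand = strand, gene_id = g, transcript_id = id,
                     stringsAsFactors = FALSE),
          data.frame(seqname = g, source = "polyprof", feature = "exon",
                     start = ex_g[, 1], end = ex_g[, 2], strand = strand,
                     gene_id = g, transcript_id = id,
                     stringsAsFactors = FALSE),
          data.frame(seqname = g, source = "polyprof", feature = "CDS",
                     start = cds_g[, 1], end = cds_g[, 2], strand = strand,
                     gene_id = g, transcript_id = id,
                     stringsAsFactors = FALSE))
        region_rows[[length(region_rows) + 1L]] <-
          data.frame(isoform_id = id, leader = leader, cds = cds,
                     utr3 = utr3, stringsAsFactors = FALSE)
        tx_seqs[id] <- spliced

        # --- miRNA sites: density follows UTR length ------------------
        n_sites <- stats::rpois(1, utr3_len / 400)
        if (n_sites > 0) {
          ss <- sample.int(utr3_len - 7L, n_sites, replace = TRUE) +
            leader_len + nchar(cds)
          mirna_rows[[length(mirna_rows) + 1L]] <-
            data.frame(transcript_id = id, site_start = ss,
                       site_end = ss + 7L,
                       mirna_id = sample(mirna_ids, n_sites, replace = TRUE),
                       context_score = -round(stats::runif(n_sites, .05, .5),
                                              3),
                       stringsAsFactors = FALSE)
        }
      }
      genome[[g]] <- paste(chunks, collapse = "")
    }
    usage <- stats::rgamma(64, shape = 2)
    usage <- setNames(round(usage / sum(usage) * 1000, 2), ALL_CODONS)
    hl_mu <- ifelse(truth$class == "low", log(4), log(9))
    half_life <- data.frame(transcript_id = truth$isoform_id,
                            hours = round(stats::rlnorm(nrow(truth), hl_mu,
                                                        0.4), 2),
                            stringsAsFactors = FALSE)
    truth$utr3_length <- utr3_len_all
    list(gtf = do.call(rbind, gtf_rows),
         genome = unlist(genome),
         transcripts = tx_seqs,
         regions = do.call(rbind, region_rows),
         codon_usage = usage,
         mirna_sites = if (length(mirna_rows)) do.call(rbind, mirna_rows)
                       else NULL,
         half_life = half_life,
         uorfs = if (length(uorf_rows)) do.call(rbind, uorf_rows) else NULL,
         expressed_mirnas = expressed,
         truth = truth)
  })
}

#' Simulate an external stage-by-cell expression matrix with switches
#'
#' Generates per-stage isoform expression for the genes in the truth
#' table. A planted fraction of eligible genes (those with a gene-linked
#' high/low archetype pair) change dominant isoform between the first and
#' last stage, with a linear share transition in between; the switching
#' pair spans the high/low partition, so the switch is translationally
#' consequential against the reference clustering. Per-cell values are
#' log-normal noise around stage means, scaled to TPM (columns sum to
#' one million).
#'
#' @param truth truth table from [simulate_counts()].
#' @param n_stages number of developmental stages (>= 2, default 7).
#' @param cells_per_stage cells per stage (default 8).
#' @param switch_rate probability that an eligible gene switches
#'   (default 0.1).
#' @param seed integer seed.
#' @param cell_noise_sd log-normal noise s.d. per cell (default 0.3).
#' @return list: `tpm` (isoform x cell matrix), `samples` (cell, stage),
#'   `switches` (gene_id, isoform_early, isoform_late), `stage_means`.
#' @export
simulate_external <- function(truth, n_stages = 7, cells_per_stage = 8,
                              switch_rate = 0.1, seed = 1,
                              cell_noise_sd = 0.3) {
  if (n_stages < 2) stop("need at least 2 stages")
  if (switch_rate < 0 || switch_rate > 1)
    stop("'switch_rate' must be in [0, 1]")
  withr::with_seed(seed, {
    genes <- unique(truth$gene_id)
    shapes <- list(rise = function(t) 0.2 + 0.8 * t,
                   fall = function(t) 1 - 0.8 * t,
                   transient = function(t) 0.2 + exp(-((t - .5) / .25)^2),
                   flat = function(t) rep(1, length(t)))
    tt <- seq(0, 1, length.out = n_stages)
    n_iso <- nrow(truth)
    stage_means <- base::matrix(0, n_iso, n_stages,
                                dimnames = list(truth$isoform_id,
                                                paste0("stage", 1:n_stages)))
    switches <- list()
    for (g in genes) {
      sub <- which(truth$gene_id == g)
      base_expr <- stats::rlnorm(1, log(50), 1)
      shape <- shapes[[sample(names(shapes), 1)]](tt)
      gene_expr <- base_expr * shape
      n <- length(sub)
      hi_iso <- sub[truth$class[sub] == "high"]
      lo_iso <- sub[truth$class[sub] == "low"]
      eligible <- length(hi_iso) >= 1 && length(lo_iso) >= 1
      share <- base::matrix(0.25 / max(1, n - 1), n, n_stages)
      if (eligible && stats::rbinom(1, 1, switch_rate) == 1) {
        pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1)
        pair <- c(pick1(hi_iso), pick1(lo_iso))
        if (stats::rbinom(1, 1, 0.5) == 1) pair <- rev(pair)
        iearly <- match(pair[1], sub); ilate <- match(pair[2], sub)
        w <- tt  # 0 at first stage, 1 at last
        share[iearly, ] <- 0.75 * (1 - w) + 0.05 * w
        share[ilate, ] <- 0.05 * (1 - w) + 0.75 * w
        switches[[length(switches) + 1L]] <-
          data.frame(gene_id = g,
                     isoform_early = truth$isoform_id[pair[1]],
                     isoform_late = truth$isoform_id[pair[2]],
                     stringsAsFactors = FALSE)
      } else {
        dom <- sample.int(n, 1)
        share[dom, ] <- 0.75
      }
      share <- sweep(share, 2, colSums(share), `/`)
      stage_means[sub, ] <- sweep(share, 2, gene_expr, `*`)
    }
    cells <- as.vector(t(outer(seq_len(n_stages), seq_len(cells_per_stage),
                               function(s, c) sprintf("S%02dC%02d", s, c))))
    samples <- data.frame(cell = cells,
                          stage = rep(paste0("stage", seq_len(n_stages)),
                                      each = cells_per_stage),
                          stringsAsFactors = FALSE)
    tpm <- base::matrix(0, n_iso, length(cells),
                        dimnames = list(truth$isoform_id, cells))
    for (j in seq_along(cells)) {
      s <- match(samples$stage[j], colnames(stage_means))
      v <- stage_means[, s] * stats::rlnorm(n_iso, 0, cell_noise_sd)
      tpm[, j] <- v / sum(v) * 1e6
    }
    switches <- if (length(switches)) do.call(rbind, switches)
      else data.frame(gene_id = character(), isoform_early = character(),
                      isoform_late = character(), stringsAsFactors = FALSE)
    list(tpm = tpm, samples = samples, switches = switches,
         stage_means = stage_means)
  })
}
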