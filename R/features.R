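# Transcript-region decomposition and per-isoform feature tabulation.
# Coordinates follow GTF conventions (1-based, inclusive) at the interface;
# splicing arithmetic is done on explicit per-base coordinate vectors, which
# is exact and fast enough at toy-annotation scale.

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

gc_fraction <- function(seq) {
  if (is.na(seq) || nchar(seq) == 0) return(NA_real_)
  ch <- strsplit(toupper(seq), "")[[1]]
  mean(ch %in% c("G", "C"))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
NEAR_COGNATE_STARTS <- c("CTG", "GTG", "TTG", "ACG", "ATA", "ATT", "ATC")

#' Decompose a transcript annotation into regions
#'
#' Extracts the spliced transcript sequence from genomic sequence and
#' splits it into 5' leader, CDS, and 3' UTR, strand-aware (minus-strand
#' transcripts are reverse-complemented). Exons must be non-overlapping;
#' the CDS span must fall within the exons. Transcripts without CDS
#' records are returned as noncoding with undefined leader/UTR.
#'
#' @param records data.frame of GTF rows for one transcript: columns
#'   `seqname`, `feature` ("exon"/"CDS"), `start`, `end` (1-based
#'   inclusive), `strand`, `gene_id`, `transcript_id`.
#' @param genome named list or `DNAStringSet` of chromosome sequences.
#' @return a `transcript_model`: list with ids, strand, exon table,
#'   `spliced`, `leader`, `cds`, `utr3` sequences, region lengths,
#'   `exon_count`, `coding`, and `complete` (ATG start, in-frame stop).
#' @export
decompose <- function(records, genome) {
  tid <- unique(records$transcript_id)
  if (length(tid) != 1) stop("records must describe a single transcript")
  exons <- records[records$feature == "exon", , drop = FALSE]
  if (nrow(exons) == 0) stop("transcript has no exon records: ", tid)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", tid)
  strand <- unique(records$strand)
  chr <- unique(records$seqname)
  if (length(strand) != 1 || length(chr) != 1)
    stop("inconsistent strand/seqname in transcript ", tid)
  chrseq <- genome[[chr]]
  if (is.null(chrseq)) stop("missing sequence for ", chr)
  chrseq <- as.character(chrseq)

  gcoords <- unlist(mapply(seq.int, exons$start, exons$end,
                           SIMPLIFY = FALSE), use.names = FALSE)
  plus_seq <- paste(substring(chrseq, exons$start, exons$end), collapse = "")
  spliced <- if (strand == "-") revcomp(plus_seq) else plus_seq
  tx_of_genomic <- if (strand == "-") rev(gcoords) else gcoords

  cds_rows <- records[records$feature == "CDS", , drop = FALSE]
  coding <- nrow(cds_rows) > 0
  leader <- cds <- utr3 <- NA_character_
  complete <- FALSE
  cds_tx <- c(NA_integer_, NA_integer_)
  if (coding) {
    cs <- min(cds_rows$start); ce <- max(cds_rows$end)
    inside <- tx_of_genomic >= cs & tx_of_genomic <= ce
    n_in_exons <- sum(gcoords >= cs & gcoords <= ce)
    if (n_in_exons != sum(cds_rows$end - cds_rows$start + 1))
      stop("CDS extends outside exons in transcript ", tid)
    pos <- which(inside)
    cds_tx <- c(min(pos), max(pos))
    leader <- substr(spliced, 1, cds_tx[1] - 1)
    cds <- substr(spliced, cds_tx[1], cds_tx[2])
    utr3 <- substr(spliced, cds_tx[2] + 1, nchar(spliced))
    complete <- nchar(cds) %% 3 == 0 &&
      substr(cds, 1, 3) == "ATG" &&
      substr(cds, nchar(cds) - 2, nchar(cds)) %in% STOP_CODONS
  }
  structure(list(
    transcript_id = tid, gene_id = unique(records$gene_id), strand = strand,
    seqname = chr, exons = exons[, c("start", "end")],
    exon_count = nrow(exons), spliced = spliced,
    leader = leader, cds = cds, utr3 = utr3, cds_tx = cds_tx,
    lengths = c(leader = ifelse(is.na(leader), NA, nchar(leader)),
                cds = ifelse(is.na(cds), NA, nchar(cds)),
                utr3 = ifelse(is.na(utr3), NA, nchar(utr3)),
                transcript = nchar(spliced)),
    coding = coding, complete = complete), class = "transcript_model")
}

#' Decompose every transcript in a GTF table
#'
#' @param gtf GTF data.frame (see [read_gtf()]).
#' @param genome chromosome sequences (named list or `DNAStringSet`).
#' @return named list of `transcript_model` objects.
#' @export
decompose_all <- function(gtf, genome) {
  gtf <- gtf[gtf$feature %in% c("exon", "CDS"), , drop = FALSE]
  chr <- if (is.list(genome)) genome else {
    s <- as.character(genome)
    if (is.null(names(s))) names(s) <- names(genome)
    as.list(s)
  }
  genome <- chr
  models <- lapply(split(gtf, gtf$transcript_id), decompose, genome = genome)
  models[unique(gtf$transcript_id)]
}

#' Fraction of a 3' UTR covered by AU runs
#'
#' Total nucleotides inside maximal runs consisting only of A or U/T and
#' longer than 5 nt (i.e. length >= 6), divided by the UTR length.
#'
#' @param utr_sequence character over ACGT/ACGU; empty input is an error.
#' @return fraction in \[0, 1\].
#' @export
au_element_fraction <- function(utr_sequence) {
  if (is.na(utr_sequence) || nchar(utr_sequence) == 0)
    stop("empty sequence: AU-element fraction undefined")
  ch <- strsplit(toupper(utr_sequence), "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "T", "U")))
    stop("non-nucleotide character in sequence")
  r <- rle(ch %in% c("A", "T", "U"))
  sum(r$lengths[r$values & r$lengths > 5]) / length(ch)
}

#' Codon-usage statistics over a CDS
#'
#' Mean codon usage, the minimum over all sliding windows of `window`
#' codons of the window-mean usage (a CDS shorter than the window uses a
#' single whole-CDS window), and the number of rare-codon stretches:
#' maximal runs of at least `min_stretch` consecutive codons whose usage
#' falls below `rare_threshold` (default the bottom decile of the usage
#' table).
#'
#' @param cds_sequence in-frame CDS (length divisible by 3).
#' @param usage_table named numeric vector codon -> frequency per thousand.
#' @param window window size in codons (default 5).
#' @param rare_threshold rarity cutoff; default `quantile(usage_table, 0.1)`.
#' @param min_stretch minimum run length for a rare stretch (default 3).
#' @return list: `mean_frequency`, `min_window_frequency`,
#'   `rare_stretch_count`.
#' @export
codon_window_stats <- function(cds_sequence, usage_table, window = 5,
                               rare_threshold = NULL, min_stretch = 3) {
  L <- nchar(cds_sequence)
  if (L %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- substring(cds_sequence, seq(1, L, 3), seq(3, L, 3))
  if (any(!codons %in% names(usage_table)))
    stop("codon(s) absent from usage table: ",
         paste(unique(setdiff(codons, names(usage_table))), collapse = ", "))
  f <- unname(usage_table[codons])
  nc <- length(f)
  if (nc >= window) {
    win <- vapply(seq_len(nc - window + 1),
                  function(i) mean(f[i:(i + window - 1)]), numeric(1))
  } else {
    win <- mean(f)
  }
  if (is.null(rare_threshold))
    rare_threshold <- stats::quantile(usage_table, 0.1, names = FALSE)
  r <- rle(f < rare_threshold)
  list(mean_frequency = mean(f),
       min_window_frequency = min(win),
       rare_stretch_count = sum(r$values & r$lengths >= min_stretch))
}

#' Scan a 5' leader for upstream open reading frames
#'
#' Scan mode finds every ORF starting at an ATG (cognate) or a
#' near-cognate codon (non-cognate: CTG, GTG, TTG, ACG, ATA, ATT, ATC)
#' whose in-frame stop codon ends at or before `boundary` (default: the
#' leader end). Table mode counts provided uORF records overlapping the
#' leader instead of scanning.
#'
#' @param leader_sequence 5' leader (upstream of the start codon).
#' @param table optional data.frame of known uORFs with columns `start`,
#'   `end`, `start_codon` in leader (transcript) coordinates.
#' @param boundary last allowed position of the uORF stop codon.
#' @param near_cognate near-cognate start-codon set for scan mode.
#' @return data.frame: `start`, `stop` (end of stop codon), `start_codon`,
#'   `cognate`.
#' @export
scan_uorfs <- function(leader_sequence, table = NULL, boundary = NULL,
                       near_cognate = NEAR_COGNATE_STARTS) {
  empty <- data.frame(start = integer(), stop = integer(),
                      start_codon = character(), cognate = logical(),
                      stringsAsFactors = FALSE)
  L <- if (is.na(leader_sequence)) 0 else nchar(leader_sequence)
  if (!is.null(table)) {
    if (nrow(table) == 0) return(empty)
    hit <- table[table$start <= L, , drop = FALSE]
    if (nrow(hit) == 0) return(empty)
    return(data.frame(start = hit$start, stop = hit$end,
                      start_codon = hit$start_codon,
                      cognate = hit$start_codon == "ATG",
                      stringsAsFactors = FALSE))
  }
  if (L < 6) return(empty)
  if (is.null(boundary)) boundary <- L
  seq <- chartr("u", "T", chartr("U", "T", toupper(leader_sequence)))
  starts <- substring(seq, 1:(L - 2), 3:L)
  cand <- which(starts %in% c("ATG", near_cognate))
  rows <- lapply(cand, function(p) {
    if (p + 5 > boundary) return(NULL)
    stops <- seq(p + 3, boundary - 2, by = 3)
    stops <- stops[stops + 2 <= boundary]
    if (!length(stops)) return(NULL)
    cods <- substring(seq, stops, stops + 2)
    hit <- which(cods %in% STOP_CODONS)
    if (!length(hit)) return(NULL)
    s <- stops[hit[1]]
    data.frame(start = p, stop = s + 2, start_codon = starts[p],
               cognate = starts[p] == "ATG", stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' uORF density per 100 isoforms
#'
#' @param cluster_isoforms character vector of isoform ids in a cluster.
#' @param uorf_calls data.frame with columns `transcript_id` and `cognate`.
#' @return list `cognate`, `noncognate`: uORFs per 100 isoforms.
#' @export
uorf_density <- function(cluster_isoforms, uorf_calls) {
  n <- length(cluster_isoforms)
  if (n == 0) stop("empty cluster")
  hits <- uorf_calls[uorf_calls$transcript_id %in% cluster_isoforms, ,
                     drop = FALSE]
  list(cognate = 100 * sum(hits$cognate) / n,
       noncognate = 100 * sum(!hits$cognate) / n)
}

#' 5' leader structure scores
#'
#' Folding-proxy structure scores: the default backend is base-pair
#' maximization by dynamic programming (Watson-Crick plus GU wobble,
#' minimum hairpin loop of 3 nt), negated so that lower scores indicate
#' more structure. The cap score is the score of the first `window` nt;
#' the minimum-window score is the minimum over all sliding windows
#' (step 1). Leaders shorter than the window are folded whole. A custom
#' thermodynamic backend can be supplied as `function(subsequence)` that
#' returns a score (lower = more structured).
#'
#' @param leader_sequence leader sequence (>= 1 nt).
#' @param window window size in nt (default 75).
#' @param backend optional per-window scoring function.
#' @return list `cap_score`, `min_window_score`.
#' @export
structure_scores <- function(leader_sequence, window = 75, backend = NULL) {
  if (is.na(leader_sequence) || nchar(leader_sequence) < 1)
    stop("leader sequence must have length >= 1")
  if (is.null(backend)) {
    sc <- -.nussinov_windows(leader_sequence, as.integer(window))
  } else {
    L <- nchar(leader_sequence)
    starts <- if (L <= window) 1L else seq_len(L - window + 1L)
    sc <- vapply(starts, function(i)
      backend(substr(leader_sequence, i, min(L, i + window - 1L))),
      numeric(1))
  }
  list(cap_score = sc[1], min_window_score = min(sc))
}

#' miRNA target-site statistics over a 3' UTR
#'
#' Counts and summed context scores of target sites overlapping the 3'
#' UTR interval, with optional restriction to an expressed-miRNA set.
#'
#' @param utr_interval `c(start, end)` of the 3' UTR in transcript
#'   coordinates (1-based inclusive).
#' @param site_table data.frame: `transcript_id`, `site_start`, `site_end`,
#'   `mirna_id`, `context_score`.
#' @param expressed_set optional character vector of expressed miRNA ids.
#' @return list: `count_all`, `score_all`, `count_expressed`,
#'   `score_expressed` (expressed values `NA` when no set is supplied).
#' @export
mirna_site_stats <- function(utr_interval, site_table, expressed_set = NULL) {
  need <- c("site_start", "site_end", "mirna_id", "context_score")
  if (!all(need %in% names(site_table)))
    stop("malformed site table; need columns: ", paste(need, collapse = ", "))
  ov <- site_table[site_table$site_end >= utr_interval[1] &
                     site_table$site_start <= utr_interval[2], , drop = FALSE]
  res <- list(count_all = nrow(ov), score_all = sum(ov$context_score),
              count_expressed = NA_real_, score_expressed = NA_real_)
  if (!is.null(expressed_set)) {
    ex <- ov[ov$mirna_id %in% expressed_set, , drop = FALSE]
    res$count_expressed <- nrow(ex)
    res$score_expressed <- sum(ex$context_score)
  }
  res
}

#' Tabulate the full isoform feature registry
#'
#' Assembles one row per transcript model with region lengths and GC
#' content, exon count, leader structure scores, codon-usage statistics,
#' AU-element fraction, uORF counts (from a uORF table when given,
#' otherwise by scanning), miRNA site counts/scores (all and
#' expressed-filtered), half-life lookup, cytoplasmic expression, and the
#' median expression from the 80S through the eight-plus fraction.
#' Isoforms absent from an auxiliary table get `NA`, not zero.
#'
#' @param models list of `transcript_model` objects.
#' @param expression replicate-averaged expression matrix with fraction
#'   columns (`cyto`, `mono`, .., `p8plus`), rows named by isoform.
#' @param codon_usage named numeric codon -> frequency per thousand.
#' @param mirna_sites site table as in [mirna_site_stats()], or `NULL`.
#' @param half_life data.frame `transcript_id`, `hours`, or `NULL`.
#' @param uorf_table data.frame `transcript_id`, `start`, `end`,
#'   `start_codon`, or `NULL` to scan leaders instead.
#' @param expressed_mirnas optional expressed-miRNA id set.
#' @param structure_window window for [structure_scores()] (default 75).
#' @return data.frame, one row per isoform, `isoform_id` first.
#' @export
tabulate_features <- function(models, expression = NULL, codon_usage = NULL,
                              mirna_sites = NULL, half_life = NULL,
                              uorf_table = NULL, expressed_mirnas = NULL,
                              structure_window = 75) {
  hl <- if (!is.null(half_life))
    setNames(half_life$hours, half_life$transcript_id) else NULL
  rows <- lapply(models, function(m) {
    id <- m$transcript_id
    has_leader <- m$coding && !is.na(m$leader) && nchar(m$leader) > 0
    has_utr3 <- m$coding && !is.na(m$utr3) && nchar(m$utr3) > 0
    st <- if (has_leader)
      structure_scores(m$leader, window = structure_window)
    else list(cap_score = NA_real_, min_window_score = NA_real_)
    cw <- if (m$coding && !is.null(codon_usage) && m$complete)
      codon_window_stats(m$cds, codon_usage)
    else list(mean_frequency = NA_real_, min_window_frequency = NA_real_,
              rare_stretch_count = NA_real_)
    uo <- if (has_leader) {
      tab <- if (!is.null(uorf_table))
        uorf_table[uorf_table$transcript_id == id, , drop = FALSE]
      else NULL
      scan_uorfs(m$leader, table = tab)
    } else data.frame(cognate = logical())
    mi <- if (has_utr3 && !is.null(mirna_sites))
      mirna_site_stats(c(m$cds_tx[2] + 1, nchar(m$spliced)),
                       mirna_sites[mirna_sites$transcript_id == id, ,
                                   drop = FALSE],
                       expressed_mirnas)
    else list(count_all = NA_real_, score_all = NA_real_,
              count_expressed = NA_real_, score_expressed = NA_real_)
    cyto <- med_poly <- NA_real_
    if (!is.null(expression) && id %in% rownames(expression)) {
      cyto <- expression[id, "cyto"]
      med_poly <- stats::median(expression[id, RIBO_FRACTIONS])
    }
    data.frame(
      isoform_id = id,
      leader_length = unname(m$lengths["leader"]),
      cds_length = unname(m$lengths["cds"]),
      utr3_length = unname(m$lengths["utr3"]),
      transcript_length = unname(m$lengths["transcript"]),
      leader_gc = if (has_leader) gc_fraction(m$leader) else NA_real_,
      cds_gc = if (m$coding) gc_fraction(m$cds) else NA_real_,
      utr3_gc = if (has_utr3) gc_fraction(m$utr3) else NA_real_,
      transcript_gc = gc_fraction(m$spliced),
      exon_count = m$exon_count,
      cap_structure = st$cap_score,
      min_window_structure = st$min_window_score,
      mean_codon_freq = cw$mean_frequency,
      min_window_codon_freq = cw$min_window_frequency,
      rare_codon_stretches = cw$rare_stretch_count,
      au_element_fraction = if (has_utr3) au_element_fraction(m$utr3)
                            else NA_real_,
      cognate_uorfs = if (has_leader) sum(uo$cognate) else NA_real_,
      noncognate_uorfs = if (has_leader) sum(!uo$cognate) else NA_real_,
      mirna_sites_all = mi$count_all,
      mirna_score_all = mi$score_all,
      mirna_sites_expressed = mi$count_expressed,
      mirna_score_expressed = mi$score_expressed,
      half_life = if (!is.null(hl) && id %in% names(hl)) unname(hl[id])
                  else NA_real_,
      cytoplasmic_expression = cyto,
      median_polysome_expression = med_poly,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
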