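# Transcript decomposition and the feature registry.

# A toy single-exon plus-strand transcript: exon 1-90, CDS 31-60.
toy_gtf <- function(strand = "+", chr = "chrT", id = "tx1") {
  data.frame(seqname = chr, source = "toy",
             feature = c("exon", "CDS"),
             start = c(1L, 31L), end = c(90L, 60L),
             strand = strand, gene_id = "g1", transcript_id = id,
             stringsAsFactors = FALSE)
}

test_that("decompose splits a single-exon transcript by hand arithmetic", {
  withr::with_seed(61, {
    chr <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                 collapse = "")
  })
  # plant a clean CDS at 31..60 (ATG + 8 sense codons + TAA)
  substr(chr, 31, 33) <- "ATG"
  substr(chr, 58, 60) <- "TAA"
  substr(chr, 34, 57) <- paste(rep("GCT", 8), collapse = "")
  m <- decompose(toy_gtf(), list(chrT = chr))
  expect_equal(unname(m$lengths["leader"]), 30)
  expect_equal(unname(m$lengths["cds"]), 30)
  expect_equal(unname(m$lengths["utr3"]), 30)
  expect_equal(unname(m$lengths["transcript"]), 90)
  expect_identical(m$leader, substr(chr, 1, 30))
  expect_identical(m$cds, substr(chr, 31, 60))
  expect_identical(m$utr3, substr(chr, 61, 90))
  expect_identical(m$spliced, chr)
  expect_true(m$coding)
  expect_true(m$complete)
  # region additivity
  expect_equal(sum(m$lengths[c("leader", "cds", "utr3")]),
               unname(m$lengths["transcript"]))
})

test_that("decompose is strand-aware: minus strand reverse-complements", {
  # Build the minus-strand genomic sequence as the reverse complement of a
  # designed transcript, then check the regions come back identical.
  leader <- paste(rep("CA", 15), collapse = "")      # 30 nt
  cds <- paste0("ATG", paste(rep("GGA", 8), collapse = ""), "TAG")
  utr3 <- paste(rep("TC", 15), collapse = "")        # 30 nt
  tx <- paste0(leader, cds, utr3)                    # 90 nt
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tx)))
  # On the minus strand, transcript position 1 maps to genomic 90: the
  # leader occupies genomic 61..90, the CDS genomic 31..60.
  m <- decompose(toy_gtf(strand = "-"), list(chrT = rc))
  expect_identical(m$spliced, tx)
  expect_identical(m$leader, leader)
  expect_identical(m$cds, cds)
  expect_identical(m$utr3, utr3)
  expect_true(m$complete)
})

test_that("decompose handles splicing, noncoding, and error cases", {
  # two exons with an intron; CDS spans the junction
  leader <- strrep("C", 10)
  cds <- paste0("ATG", strrep("GCA", 4), "TAA")     # 18 nt
  utr3 <- strrep("G", 12)
  tx <- paste0(leader, cds, utr3)                    # 40 nt
  # exon1 = tx[1..25] at genomic 1..25, intron 26..45, exon2 at 46..60
  chr <- paste0(substr(tx, 1, 25), strrep("T", 20), substr(tx, 26, 40))
  gtf <- data.frame(seqname = "c", source = "toy",
                    feature = c("exon", "exon", "CDS", "CDS"),
                    start = c(1L, 46L, 11L, 46L),
                    end = c(25L, 60L, 25L, 48L),
                    strand = "+", gene_id = "g", transcript_id = "t",
                    stringsAsFactors = FALSE)
  m <- decompose(gtf, list(c = chr))
  expect_identical(m$spliced, tx)
  expect_identical(m$cds, cds)
  expect_identical(m$exon_count, 2L)

  nc <- toy_gtf()
  nc <- nc[nc$feature == "exon", ]
  withr::with_seed(62, {
    chr90 <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                   collapse = "")
  })
  mn <- decompose(nc, list(chrT = chr90))
  expect_false(mn$coding)
  expect_true(is.na(mn$leader) && is.na(mn$utr3))
  expect_identical(unname(mn$lengths["transcript"]), 90L)

  bad_cds <- toy_gtf()
  bad_cds$end[bad_cds$feature == "CDS"] <- 95L   # outside the exon
  expect_error(decompose(bad_cds, list(chrT = chr90)), "outside exons")
  overlap <- rbind(nc, within(nc, { start <- 50L; end <- 95L }))
  expect_error(decompose(overlap, list(chrT = chr90)), "overlapping exons")
  expect_error(decompose(toy_gtf(chr = "nope"), list(chrT = chr90)),
               "missing sequence")
})

test_that("au_element_fraction counts nucleotides in runs longer than 5", {
  expect_equal(au_element_fraction("GCGCGCGCGC"), 0)
  expect_equal(au_element_fraction("AAAAAA"), 1)
  expect_equal(au_element_fraction("GGAAAAAAGG"), 0.6)
  expect_equal(au_element_fraction("AAAAA"), 0)       # run of 5, not > 5
  expect_equal(au_element_fraction("ATUTAT"), 1)      # mixed A/U/T run
  expect_equal(au_element_fraction("GGGGGG"), 0)
  expect_error(au_element_fraction(""), "empty")
  expect_error(au_element_fraction(NA_character_), "empty")
  expect_error(au_element_fraction("ACGTN"), "non-nucleotide")
  # monotone non-decreasing when extending a qualifying run
  base <- "GGAAAAAAGG"
  expect_gte(au_element_fraction(paste0(base, "A")),
             au_element_fraction(base) * 10 / 11)
  f1 <- au_element_fraction("CCAAAAAA")
  f2 <- au_element_fraction("CCAAAAAAA")
  expect_gte(f2, f1)
})

test_that("codon_window_stats matches the hand-computed window case", {
  usage <- setNames(rep(10, 3), c("ATG", "GCT", "TAA"))
  usage["CGG"] <- 1
  # 5 codons with usages (10, 10, 1, 10, 10): single window, mean 8.2
  cds <- paste0("ATG", "GCT", "CGG", "GCT", "TAA")
  st <- codon_window_stats(cds, usage)
  expect_equal(st$min_window_frequency, 8.2)
  expect_equal(st$mean_frequency, 8.2)
  # uniform usage: min window equals the table value
  uni <- setNames(rep(7, 2), c("ATG", "AAA"))
  st2 <- codon_window_stats(paste0("ATG", strrep("AAA", 9)), uni)
  expect_equal(st2$min_window_frequency, 7)
  # CDS shorter than the window: single whole-CDS window
  st3 <- codon_window_stats("ATGGCT", usage)
  expect_equal(st3$min_window_frequency, 10)
  expect_error(codon_window_stats("ATGG", usage), "divisible by 3")
  expect_error(codon_window_stats("ATGNNN", usage), "absent")
})

test_that("codon_window_stats counts rare-codon stretches", {
  usage <- setNames(c(20, 20, 1, 1.2), c("AAA", "GGG", "CGG", "CGA"))
  # rare = below threshold 2: runs of >= 3 rare codons count once each
  cds <- paste0("AAA", "CGG", "CGA", "CGG",        # rare run of 3
                "GGG", "GGG",
                "CGG", "CGG",                      # rare run of 2: no
                "GGG",
                "CGA", "CGA", "CGG", "CGA")        # rare run of 4
  st <- codon_window_stats(cds, usage, rare_threshold = 2)
  expect_identical(st$rare_stretch_count, 2L)
  st_strict <- codon_window_stats(cds, usage, rare_threshold = 2,
                                  min_stretch = 4)
  expect_identical(st_strict$rare_stretch_count, 1L)
})

test_that("scan_uorfs finds cognate and near-cognate uORFs", {
  # leader with one clean ATG...TAA cassette
  lead <- paste0("CCCCC", "ATG", "GCAGCA", "TAA", "CCCCC")
  u <- scan_uorfs(lead)
  expect_identical(nrow(u), 1L)
  expect_identical(u$start, 6L)
  expect_equal(u$stop, 17)
  expect_identical(u$start_codon, "ATG")
  expect_true(u$cognate)
  expect_identical(nrow(scan_uorfs("GGGGGG")), 0L)
  # near-cognate CTG ... TGA
  nc <- scan_uorfs(paste0("CCC", "CTG", "GGC", "TGA", "CCC"))
  expect_identical(nrow(nc), 1L)
  expect_identical(nc$start_codon, "CTG")
  expect_false(nc$cognate)
  # stop must land within the boundary
  expect_identical(nrow(scan_uorfs(paste0("CCC", "ATG", "GGC", "TGA"),
                                   boundary = 11)), 0L)
  expect_identical(nrow(scan_uorfs(paste0("CCC", "ATG", "GGC", "TGA"),
                                   boundary = 12)), 1L)
  # no in-frame stop: no call
  expect_identical(nrow(scan_uorfs("CCCATGGGCGGCCC")), 0L)
  # table mode counts provided records, ignoring scan hits
  tab <- data.frame(start = c(2L, 50L), end = c(13L, 61L),
                    start_codon = c("ATG", "GTG"), stringsAsFactors = FALSE)
  tm <- scan_uorfs(strrep("C", 30), table = tab)
  expect_identical(nrow(tm), 1L)       # second record beyond the leader
  expect_true(tm$cognate)
})

test_that("uorf_density reports calls per 100 isoforms", {
  calls <- data.frame(transcript_id = paste0("i", 1:10),
                      cognate = rep(c(TRUE, FALSE), 5),
                      stringsAsFactors = FALSE)
  d <- uorf_density(paste0("i", 1:50), calls)
  expect_equal(d$cognate, 10)          # 5 cognate per 50 isoforms
  expect_equal(d$noncognate, 10)
  empty <- uorf_density(paste0("x", 1:10), calls)
  expect_equal(empty$cognate, 0)
  expect_error(uorf_density(character(0), calls), "empty cluster")
})

test_that("default structure backend equals the exhaustive pairing oracle", {
  expect_equal(structure_scores(strrep("A", 75))$cap_score, 0)
  # perfect 10-bp hairpin with a 4-nt loop: 10 pairs on 24 nt
  hairpin <- paste0(strrep("G", 10), "AAAA", strrep("C", 10))
  expect_identical(oracle_max_pairs(hairpin), 10L)
  expect_equal(structure_scores(hairpin, window = 24)$cap_score, -10)
  withr::with_seed(71, {
    for (i in 1:12) {
      n <- sample(6:14, 1)
      s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
      expect_identical(structure_scores(s, window = n)$cap_score * -1L,
                       oracle_max_pairs(s),
                       label = paste("sequence", s))
    }
  })
  # window longer than leader: single-window score
  short <- structure_scores("GGGAAAACCC", window = 75)
  expect_identical(short$cap_score, short$min_window_score)
  # sliding windows: min over all windows <= first window
  lead <- paste0(strrep("A", 30), hairpin, strrep("A", 30))
  sc <- structure_scores(lead, window = 24)
  expect_lte(sc$min_window_score, sc$cap_score)
  expect_equal(sc$min_window_score, -10)
  expect_error(structure_scores("ACGTN"), "non-nucleotide")
  expect_error(structure_scores(NA_character_), "length >= 1")
  # pluggable backend
  custom <- structure_scores("ACGTACGT", window = 4,
                             backend = function(s) nchar(s) * 1.0)
  expect_equal(custom$cap_score, 4)
})

test_that("mirna_site_stats counts overlapping sites with filtering", {
  sites <- data.frame(transcript_id = "t",
                      site_start = c(105, 140, 180, 10),
                      site_end = c(112, 147, 187, 17),
                      mirna_id = c("miR-1", "miR-2", "miR-1", "miR-9"),
                      context_score = c(-0.2, -0.3, -0.1, -0.4),
                      stringsAsFactors = FALSE)
  st <- mirna_site_stats(c(100, 200), sites, expressed_set = "miR-2")
  expect_identical(st$count_all, 3L)             # the site at 10 is outside
  expect_equal(st$score_all, -0.6)
  expect_identical(st$count_expressed, 1L)
  expect_equal(st$score_expressed, -0.3)
  none <- mirna_site_stats(c(100, 200), sites[0, ])
  expect_identical(none$count_all, 0L)
  expect_equal(none$score_all, 0)
  expect_true(is.na(none$count_expressed))
  expect_error(mirna_site_stats(c(1, 10), data.frame(x = 1)), "malformed")
})

test_that("tabulate_features assembles the registry on synthetic data", {
  ann <- shared_ann()
  ids <- ann$regions$isoform_id[1:40]
  gtf <- ann$gtf[ann$gtf$transcript_id %in% ids, ]
  models <- decompose_all(gtf, ann$genome)
  counts <- shared_sim()$counts[ids, ]
  avg <- sapply(fraction_types(), function(f)
    rowMeans(counts[, paste(f, 1:2, sep = "_")]))
  ft <- tabulate_features(models, expression = avg,
                          codon_usage = ann$codon_usage,
                          mirna_sites = ann$mirna_sites,
                          half_life = ann$half_life,
                          uorf_table = ann$uorfs,
                          expressed_mirnas = ann$expressed_mirnas)
  expect_identical(nrow(ft), 40L)
  expect_identical(ft$isoform_id, ids)
  expect_identical(ncol(ft), 25L)      # isoform_id + 24 features
  expect_false(any(vapply(ft[-1], function(col) all(is.na(col)),
                          logical(1))))
  # median polysome expression is the median over the 8 ribosome fractions
  expect_equal(ft$median_polysome_expression[1],
               stats::median(avg[ids[1], fraction_types(ribosomal = TRUE)]))
  expect_equal(ft$cytoplasmic_expression, unname(avg[ids, "cyto"]))
  # isoform absent from the half-life table: NA, not 0
  hl <- ann$half_life[!ann$half_life$transcript_id %in% ids[1], ]
  ft2 <- tabulate_features(models[1], expression = avg,
                           codon_usage = ann$codon_usage,
                           half_life = hl)
  expect_true(is.na(ft2$half_life))
  # fractions within [0, 1], counts non-negative
  expect_true(all(ft$au_element_fraction >= 0 & ft$au_element_fraction <= 1,
                  na.rm = TRUE))
  expect_true(all(ft$cognate_uorfs >= 0 & ft$noncognate_uorfs >= 0,
                  na.rm = TRUE))
  expect_true(all(ft$leader_gc >= 0 & ft$leader_gc <= 1, na.rm = TRUE))
})
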