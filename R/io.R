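# Readers and writers for the pipeline's interchange formats: TSV count
# matrices (columns <fraction>_<replicate>), GTF (1-based inclusive),
# FASTA, plain TSV tables, Newick dendrograms, and JSON manifests.
# Missing values are written as empty fields, never 0.

#' Read a count/expression matrix from TSV
#'
#' First column holds isoform ids (header `isoform_id`); remaining columns
#' are samples. Duplicate ids are rejected. CRLF line endings are handled
#' transparently.
#'
#' @param path TSV file.
#' @return numeric matrix with isoform rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate isoform id(s) in ", path, ": ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a count/expression matrix to TSV
#'
#' @param matrix numeric matrix with isoform rownames.
#' @param path output file.
#' @export
write_counts <- function(matrix, path) {
  df <- data.frame(isoform_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a data.frame to TSV (header, no quoting, NA as empty field)
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#'
#' @param path TSV file.
#' @return data.frame (empty fields become NA).
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Read a GTF annotation
#'
#' Parses with `rtracklayer` (1-based inclusive coordinates) and validates:
#' `gene_id`/`transcript_id` attributes must be present, and duplicate
#' transcript-level records are rejected with the offending record index.
#'
#' @param path GTF file.
#' @return data.frame: seqname, source, feature, start, end, strand,
#'   gene_id, transcript_id.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(seqname = as.character(GenomicRanges::seqnames(gr)),
                   source = as.character(gr$source),
                   feature = as.character(gr$type),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  if (anyNA(df$transcript_id) || anyNA(df$gene_id))
    stop("GTF record(s) without gene_id/transcript_id attribute in ", path)
  tx <- which(df$feature == "transcript")
  dup <- tx[duplicated(df$transcript_id[tx])]
  if (length(dup))
    stop("duplicate transcript record in ", path, " at line ", dup[1],
         ": ", df$transcript_id[dup[1]])
  df
}

#' Write a GTF annotation
#'
#' Emits the 9-column GTF text format (1-based inclusive) with
#' `gene_id`/`transcript_id` attributes.
#'
#' @param gtf data.frame as returned by [read_gtf()].
#' @param path output file.
#' @export
write_gtf <- function(gtf, path) {
  lines <- sprintf(
    "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    gtf$seqname, gtf$source, gtf$feature, gtf$start, gtf$end, gtf$strand,
    gtf$gene_id, gtf$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (or `DNAStringSet`).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Export a dendrogram in Newick format
#'
#' @param tree an `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Write a provenance manifest
#'
#' Records parameters, seed, package version, and md5 checksums of the
#' input files alongside pipeline outputs.
#'
#' @param path output JSON file.
#' @param params named list of parameters.
#' @param inputs character vector of input file paths to checksum.
#' @export
write_manifest <- function(path, params, inputs = character(0)) {
  inputs <- as.character(unlist(inputs))
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "polyprof",
    version = as.character(utils::packageVersion("polyprof")),
    parameters = params,
    input_checksums = if (length(inputs))
      as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs)))
    else NULL)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
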