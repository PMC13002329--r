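# Readers and writers for the tabular interchange formats the pipeline
# consumes: domain-scan and similarity-search hit tables, species rosters,
# GFF3-derived gene order, and 0/1 PAV matrices.

#' Read a domain-scan hit table
#'
#' Parses space-delimited tabular output of a profile domain scan (hmmscan
#' `--tblout` layout: target name, target accession, query name, query
#' accession, full-sequence E-value, full-sequence bit score, ...).
#' Comment lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return data.frame of hit records: `query_id`, `source`
#'   (`"domain_scan"`), `evalue`, `bitscore`, `subject_id`.
#' @export
read_domain_hits <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(raw) < 6) stop("expected at least 6 columns in domain-scan table")
  data.frame(query_id = raw[[3]], source = "domain_scan",
             evalue = as.numeric(raw[[5]]), bitscore = as.numeric(raw[[6]]),
             subject_id = raw[[1]], stringsAsFactors = FALSE)
}

#' Read a 12-column similarity-search hit table
#'
#' Parses the standard 12-column tab-separated hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, E-value, bit score).
#'
#' @param path file path.
#' @return data.frame of hit records: `query_id`, `source`
#'   (`"similarity"`), `evalue`, `bitscore`, `subject_id`, `pident`.
#' @export
read_similarity_hits <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(raw) != 12) stop("expected exactly 12 columns, got ", ncol(raw))
  data.frame(query_id = raw[[1]], source = "similarity",
             evalue = as.numeric(raw[[11]]), bitscore = as.numeric(raw[[12]]),
             subject_id = raw[[2]], pident = as.numeric(raw[[3]]),
             stringsAsFactors = FALSE)
}

#' Derive per-chromosome gene order from a GFF3 annotation
#'
#' Reads gene features from a GFF3 file and ranks them 0-based by start
#' coordinate within each chromosome — the rank space used by the synteny
#' chaining and duplication classification.
#'
#' @param path GFF3 file path.
#' @param feature_type feature to extract (default `"gene"`).
#' @return data.frame with `gene_id`, `chrom`, `rank`, `start`, `end`,
#'   `strand`.
#' @export
gene_order_from_gff <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("gene_order_from_gff requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  if (length(gr) == 0) stop("no '", feature_type, "' features in ", path)
  df <- data.frame(
    gene_id = if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start), ]
  df$rank <- stats::ave(df$start, df$chrom,
                        FUN = function(s) seq_along(s) - 1L)
  rownames(df) <- NULL
  df[, c("gene_id", "chrom", "rank", "start", "end", "strand")]
}

#' Write a presence/absence matrix as a 0/1 TSV
#'
#' @param pav logical matrix (OGG x variety).
#' @param path output file; the header row carries the variety names and
#'   the first column the OGG ids.
#' @export
write_pav_tsv <- function(pav, path) {
  out <- data.frame(ogg = rownames(pav), 1L * pav, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 0/1 PAV TSV written by [write_pav_tsv()]
#'
#' @param path file path.
#' @return logical matrix with OGG rownames and variety colnames.
#' @export
read_pav_tsv <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE]) > 0
  rownames(m) <- raw[[1]]
  m
}
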