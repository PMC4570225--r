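#' Read a FASTQ file into a data frame
#'
#' @param path Path to a FASTQ file (Sanger Phred+33 qualities).
#' @return A data frame with columns `sequence` and `quality`.
#' @export
read_fastq <- function(path) {
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    out <- data.frame(sequence = as.character(x),
                      quality = as.character(S4Vectors::mcols(x)$qualities),
                      row.names = NULL, stringsAsFactors = FALSE)
    if (any(nchar(out$sequence) != nchar(out$quality)))
      stop("sequence/quality length mismatch")
    out
  },
  error = function(e) {
    idx <- locate_bad_fastq_record(path)
    stop("malformed FASTQ record at index ", idx, " in '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

# Best-effort scan for the first structurally broken 4-line FASTQ record.
locate_bad_fastq_record <- function(path) {
  ln <- readLines(path, warn = FALSE)
  nrec <- ceiling(length(ln) / 4)
  for (i in seq_len(nrec)) {
    b <- ln[(4 * (i - 1) + 1):min(4 * i, length(ln))]
    if (length(b) < 4 || !startsWith(b[1], "@") || !startsWith(b[3], "+") ||
        nchar(b[2]) != nchar(b[4])) return(i)
  }
  nrec
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with columns `sequence` and `quality`.
#' @param path Output path.
#' @param ids Optional read identifiers (defaults to `read1..readN`).
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- if (is.null(ids)) sprintf("read%06d", seq_along(x)) else ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Write named sequences to a FASTA file
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path Path to a FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write collapsed tags in the count-in-header FASTA dialect
#'
#' Headers follow the `>tagNNN_xCOUNT` convention so that collapsed libraries
#' can be exchanged with other small RNA tools.
#'
#' @param tags Data frame with columns `sequence` and `count`.
#' @param path Output path.
#' @export
write_collapsed_fasta <- function(tags, path) {
  ids <- sprintf("tag%06d_x%d", seq_len(nrow(tags)), tags$count)
  write_fasta(stats::setNames(tags$sequence, ids), path)
}

#' Read a collapsed FASTA file (count-in-header dialect)
#' @param path Path to a collapsed FASTA file with `_xCOUNT` headers.
#' @return Data frame with columns `sequence` and `count`.
#' @export
read_collapsed_fasta <- function(path) {
  x <- read_fasta(path)
  cnt <- as.integer(sub(".*_x(\\d+)$", "\\1", names(x)))
  if (anyNA(cnt)) stop("headers do not follow the '_xCOUNT' dialect", call. = FALSE)
  data.frame(sequence = unname(x), count = cnt, stringsAsFactors = FALSE)
}

#' Export feature annotations to GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 output is 1-based
#' inclusive. Requires the rtracklayer package.
#'
#' @param annotations Data frame with columns `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `category`, `id`.
#' @param path Output path.
#' @export
write_gff3 <- function(annotations, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 export requires the 'rtracklayer' package", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$contig,
    ranges = IRanges::IRanges(start = annotations$start + 1L, end = annotations$end),
    strand = annotations$strand)
  gr$type <- annotations$category
  gr$ID <- annotations$id
  if (!is.null(annotations$source_db)) gr$source_db <- annotations$source_db
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Import feature annotations from GFF3
#'
#' @param path Path to a GFF3 file whose feature-type column carries the
#'   annotation category.
#' @return Data frame in the package's internal 0-based half-open convention.
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 import requires the 'rtracklayer' package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             category = as.character(gr$type),
             id = if (!is.null(gr$ID)) gr$ID else NA_character_,
             stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
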