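#' Map tags to a genome by exact full-length matching
#'
#' Finds all exact, full-length, both-strand occurrences of each tag in the
#' genome. A minus-strand hit means the reverse complement of the tag occurs
#' in the plus-strand sequence. Coordinates are 0-based half-open.
#'
#' @param tags Character vector of tag sequences, or a data frame with a
#'   `sequence` column.
#' @param genome Named character vector or `DNAStringSet` of contigs.
#' @return Data frame with columns `sequence`, `contig`, `start`, `end`,
#'   `strand`. Tags without hits are absent from the result.
#' @export
map_exact <- function(tags, genome) {
  seqs <- unique(if (is.data.frame(tags)) tags$sequence else tags)
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  out <- list()
  for (w in unique(nchar(seqs))) {
    sw <- seqs[nchar(seqs) == w]
    fwd <- Biostrings::PDict(Biostrings::DNAStringSet(sw))
    rev <- Biostrings::PDict(Biostrings::reverseComplement(Biostrings::DNAStringSet(sw)))
    for (ci in seq_along(genome)) {
      for (str in c("+", "-")) {
        m <- Biostrings::matchPDict(if (str == "+") fwd else rev, genome[[ci]])
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0) next
        ir <- unlist(m)
        out[[length(out) + 1]] <- data.frame(
          sequence = rep(sw, nh),
          contig = names(genome)[ci],
          start = BiocGenerics::start(ir) - 1L,
          end = BiocGenerics::end(ir),
          strand = str, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(sequence = character(0), contig = character(0),
                      start = integer(0), end = integer(0), strand = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$sequence, res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Locate each mature on its precursor (first exact occurrence). Errors if a
# mature cannot be found -- a reference-consistency failure.
locate_matures <- function(matures, precursors, mature_meta) {
  off <- integer(nrow(mature_meta))
  for (i in seq_len(nrow(mature_meta))) {
    mid <- mature_meta$mature_id[i]
    pid <- mature_meta$precursor_id[i]
    if (!pid %in% names(precursors))
      stop("precursor '", pid, "' for mature '", mid, "' missing from reference",
           call. = FALSE)
    p <- regexpr(matures[[mid]], precursors[[pid]], fixed = TRUE)
    if (p < 0)
      stop("reference inconsistency: mature '", mid,
           "' does not occur on its precursor '", pid, "'", call. = FALSE)
    off[i] <- p - 1L
  }
  mature_meta$offset <- off
  mature_meta$mature_len <- nchar(matures[mature_meta$mature_id])
  mature_meta
}

#' Match tags against known miRNA references
#'
#' A tag is assigned to a known mature miRNA when (i) it is an exact
#' substring of a miRNA precursor and (ii) its interval on that precursor
#' overlaps the annotated mature interval by at least 16 nt, overhangs past
#' either mature end being permitted. Ties across matures are resolved to the
#' maximal overlap, then to the lexicographically smallest mature id.
#'
#' @param tags Character vector of tag sequences or data frame with
#'   `sequence`.
#' @param precursors Named character vector of precursor sequences.
#' @param matures Named character vector of mature sequences.
#' @param mature_meta Data frame with `mature_id` and `precursor_id` columns
#'   associating each mature with its precursor.
#' @param min_overlap Minimum tag/mature overlap in nt (default 16).
#' @return Data frame with one row per matched tag: `sequence`, `mature_id`,
#'   `precursor_id`, `overlap`, `offset5`, `offset3` (end shifts of the tag
#'   relative to the annotated mature; 0/0 is the exact mature).
#' @export
assign_known_mirna <- function(tags, precursors, matures, mature_meta,
                               min_overlap = 16) {
  seqs <- unique(if (is.data.frame(tags)) tags$sequence else tags)
  meta <- locate_matures(matures, precursors, mature_meta)
  hits <- list()
  for (pid in unique(meta$precursor_id)) {
    pseq <- precursors[[pid]]
    mrows <- meta[meta$precursor_id == pid, , drop = FALSE]
    for (s in seqs) {
      p <- regexpr(s, pseq, fixed = TRUE)
      if (p < 0) next
      tag_s <- as.integer(p) - 1L
      tag_e <- tag_s + nchar(s)
      for (k in seq_len(nrow(mrows))) {
        mat_s <- mrows$offset[k]
        mat_e <- mat_s + mrows$mature_len[k]
        ov <- min(tag_e, mat_e) - max(tag_s, mat_s)
        if (ov >= min_overlap)
          hits[[length(hits) + 1]] <- data.frame(
            sequence = s, mature_id = mrows$mature_id[k], precursor_id = pid,
            overlap = ov, offset5 = tag_s - mat_s, offset3 = tag_e - mat_e,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(sequence = character(0), mature_id = character(0),
                      precursor_id = character(0), overlap = integer(0),
                      offset5 = integer(0), offset3 = integer(0)))
  h <- do.call(rbind, hits)
  h <- h[order(h$sequence, -h$overlap, h$mature_id), , drop = FALSE]
  h <- h[!duplicated(h$sequence), , drop = FALSE]
  rownames(h) <- NULL
  h
}

ANNOT_CATEGORIES <- c("rRNA", "snRNA", "snoRNA", "tRNA", "known_miRNA",
                      "repeat", "exon_sense", "exon_antisense",
                      "intron_sense", "intron_antisense", "unannotated")

#' Assign each tag exactly one annotation category by priority
#'
#' Implements the single-annotation priority rule: rRNA > snRNA > snoRNA >
#' tRNA (within each, a GenBank-like source outranks an Rfam-like one) >
#' known miRNA > repeat-associated > exon > intron; unmatched tags are
#' `unannotated`. Sense/antisense for exon and intron is decided by the tag's
#' genome-hit strand against the feature strand, sense outranking antisense.
#'
#' @param tags Data frame with `sequence` (and optionally `count`,
#'   `library_id`, carried through).
#' @param reference A reference bundle: a list with `genome` (named character
#'   or `DNAStringSet`), `annotations` (data frame: `contig`, `start`, `end`
#'   0-based half-open, `strand`, `category` in
#'   repeat/exon/intron, `id`), `ncrna` (named character vector),
#'   `ncrna_meta` (data frame: `id`, `category` in rRNA/snRNA/snoRNA/tRNA,
#'   `source` in genbank_like/rfam_like), `precursor`, `mature` (named
#'   character vectors) and `mature_meta` (see [assign_known_mirna()]).
#' @param genome_hits Optional precomputed result of [map_exact()].
#' @return The input data frame with `category`, `source` and `mature_id`
#'   columns added; the genome-hit table is attached as attribute
#'   `genome_hits`.
#' @export
annotate_tags <- function(tags, reference, genome_hits = NULL) {
  stopifnot(is.data.frame(tags))
  seqs <- unique(tags$sequence)
  if (is.null(genome_hits)) genome_hits <- map_exact(seqs, reference$genome)

  category <- stats::setNames(rep("unannotated", length(seqs)), seqs)
  source <- stats::setNames(rep("none", length(seqs)), seqs)
  mature_id <- stats::setNames(rep(NA_character_, length(seqs)), seqs)

  # ncRNA classes by substring match against reference sequences.
  if (length(reference$ncrna)) {
    nc_meta <- reference$ncrna_meta
    src_rank <- c(genbank_like = 1L, rfam_like = 2L)
    cat_rank <- c(rRNA = 1L, snRNA = 2L, snoRNA = 3L, tRNA = 4L)
    best_rank <- stats::setNames(rep(Inf, length(seqs)), seqs)
    for (i in seq_len(nrow(nc_meta))) {
      rid <- nc_meta$id[i]
      found <- seqs[vapply(seqs, function(s)
        grepl(s, reference$ncrna[[rid]], fixed = TRUE), logical(1))]
      if (!length(found)) next
      rank <- cat_rank[[nc_meta$category[i]]] * 10 + src_rank[[nc_meta$source[i]]]
      upd <- found[rank < best_rank[found]]
      best_rank[upd] <- rank
      category[upd] <- nc_meta$category[i]
      source[upd] <- nc_meta$source[i]
    }
  }

  # Known miRNA (only for tags not already claimed by an ncRNA class).
  open <- seqs[category == "unannotated"]
  if (length(open) && length(reference$precursor)) {
    km <- assign_known_mirna(open, reference$precursor, reference$mature,
                             reference$mature_meta)
    if (nrow(km)) {
      category[km$sequence] <- "known_miRNA"
      source[km$sequence] <- "mirbase_like"
      mature_id[km$sequence] <- km$mature_id
    }
  }

  # Interval-based classes from genome hits.
  open <- seqs[category == "unannotated"]
  ann <- reference$annotations
  if (length(open) && !is.null(ann) && nrow(ann)) {
    hits <- genome_hits[genome_hits$sequence %in% open, , drop = FALSE]
    if (nrow(hits)) {
      hg <- GenomicRanges::GRanges(hits$contig,
              IRanges::IRanges(hits$start + 1L, hits$end), strand = hits$strand)
      for (feat in c("repeat", "exon", "intron")) {
        fa <- ann[ann$category == feat, , drop = FALSE]
        if (!nrow(fa)) next
        fg <- GenomicRanges::GRanges(fa$contig,
                IRanges::IRanges(fa$start + 1L, fa$end), strand = fa$strand)
        ov <- GenomicRanges::findOverlaps(hg, fg, ignore.strand = TRUE)
        if (!length(ov)) next
        qh <- S4Vectors::queryHits(ov)
        sense <- hits$strand[qh] == fa$strand[S4Vectors::subjectHits(ov)]
        for (s in unique(hits$sequence[qh])) {
          if (category[[s]] != "unannotated") next
          rows <- hits$sequence[qh] == s
          if (feat == "repeat") {
            category[s] <- "repeat"; source[s] <- "repeat_lib"
          } else {
            category[s] <- paste0(feat, if (any(sense[rows])) "_sense" else "_antisense")
            source[s] <- "gene_model"
          }
        }
      }
    }
  }

  tags$category <- unname(category[tags$sequence])
  tags$source <- unname(source[tags$sequence])
  tags$mature_id <- unname(mature_id[tags$sequence])
  attr(tags, "genome_hits") <- genome_hits
  tags
}

#' Per-library annotation distribution report
#'
#' Tabulates total and unique clean reads per annotation category per
#' library, with percentages of the clean-read total.
#'
#' @param assignments Output of [annotate_tags()] carrying `count`,
#'   `library_id` and `category` columns.
#' @return Data frame with columns `library_id`, `category`, `reads`,
#'   `unique`, `pct_reads`, `pct_unique`.
#' @export
distribution_report <- function(assignments) {
  if (nrow(assignments) == 0)
    return(data.frame(library_id = character(0), category = character(0),
                      reads = integer(0), unique = integer(0),
                      pct_reads = numeric(0), pct_unique = numeric(0)))
  out <- list()
  for (lib in unique(assignments$library_id)) {
    a <- assignments[assignments$library_id == lib, , drop = FALSE]
    tot <- sum(a$count); uni <- nrow(a)
    for (cat in ANNOT_CATEGORIES) {
      sel <- a$category == cat
      if (!any(sel)) next
      out[[length(out) + 1]] <- data.frame(
        library_id = lib, category = cat,
        reads = sum(a$count[sel]), unique = sum(sel),
        pct_reads = 100 * sum(a$count[sel]) / tot,
        pct_unique = 100 * sum(sel) / uni, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Quantify known mature miRNAs with isomiR breakdown
#'
#' Sums the counts of all tags assigned to each known mature miRNA per
#' library (the >= 16 nt overlap rule having already grouped end-variant
#' isomiRs with their annotated mature), computes TPM against the library
#' clean-read total, and reports the dominant variant (highest count, ties to
#' the lexicographically smallest sequence).
#'
#' @param assignments Output of [annotate_tags()] for one or more libraries,
#'   with `count` and `library_id` columns.
#' @param library_meta Data frame with `library_id`, `variety`, `tissue`,
#'   `condition` and `clean_total` columns.
#' @param reference The reference bundle used for annotation (for variant
#'   end-offsets).
#' @param zero_fill If `TRUE`, emit zero-count records for matures absent
#'   from a library (default `FALSE`: absent means no record).
#' @return A list with `expression` (one row per miRNA x library:
#'   `mirna_id`, `library_id`, `variety`, `tissue`, `condition`, `raw_count`,
#'   `tpm`, `dominant_variant`) and `variants` (per-tag breakdown with end
#'   offsets relative to the annotated mature).
#' @export
quantify_known <- function(assignments, library_meta, reference,
                           zero_fill = FALSE) {
  known <- assignments[assignments$category == "known_miRNA", , drop = FALSE]
  km <- assign_known_mirna(unique(known$sequence), reference$precursor,
                           reference$mature, reference$mature_meta)
  known <- merge(known[, c("sequence", "count", "library_id")],
                 km[, c("sequence", "offset5", "offset3", "mature_id")],
                 by = "sequence")
  expr <- list(); vars <- list()
  for (lib in library_meta$library_id) {
    meta <- library_meta[library_meta$library_id == lib, , drop = FALSE]
    a <- known[known$library_id == lib, , drop = FALSE]
    ids <- if (zero_fill) names(reference$mature) else unique(a$mature_id)
    for (mid in sort(ids)) {
      v <- a[a$mature_id == mid, , drop = FALSE]
      raw <- sum(v$count)
      dom <- if (nrow(v)) v$sequence[order(-v$count, v$sequence)][1] else NA_character_
      expr[[length(expr) + 1]] <- data.frame(
        mirna_id = mid, library_id = lib, variety = meta$variety,
        tissue = meta$tissue, condition = meta$condition,
        raw_count = raw, tpm = 1e6 * raw / meta$clean_total,
        dominant_variant = dom, stringsAsFactors = FALSE)
      if (nrow(v))
        vars[[length(vars) + 1]] <- data.frame(
          mirna_id = mid, library_id = lib, sequence = v$sequence,
          count = v$count, offset5 = v$offset5, offset3 = v$offset3,
          stringsAsFactors = FALSE)
    }
  }
  list(expression = if (length(expr)) do.call(rbind, expr) else
         data.frame(mirna_id = character(0), library_id = character(0),
                    variety = character(0), tissue = character(0),
                    condition = character(0), raw_count = integer(0),
                    tpm = numeric(0), dominant_variant = character(0)),
       variants = if (length(vars)) do.call(rbind, vars) else NULL)
}

#' Classify an expression level from its TPM
#'
#' Bands: high (TPM > 10000), moderate (100 <= TPM <= 10000, endpoints
#' inclusive), low (TPM < 100).
#'
#' @param tpm Numeric vector of non-negative TPM values.
#' @return Character vector in `{"high", "moderate", "low"}`.
#' @examples
#' classify_expression(c(150000, 100, 99.9))
#' @export
classify_expression <- function(tpm) {
  if (any(tpm < 0)) stop("TPM must be non-negative", call. = FALSE)
  ifelse(tpm > 10000, "high", ifelse(tpm >= 100, "moderate", "low"))
}
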