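#' Complementarity-scoring weights
#'
#' psRNATarget-style penalties: mismatch +1, G:U wobble +0.5, gap +2, each
#' doubled within the seed region (miRNA positions 2-13, 1-based from the 5'
#' end). The total penalty of the best alignment is the expectation score
#' (0 = perfect complementarity; lower is better).
#'
#' @param mismatch,wobble,gap Penalty weights.
#' @param seed_start,seed_end Seed region bounds on the miRNA (1-based).
#' @return Named list of weights.
#' @export
target_weights <- function(mismatch = 1, wobble = 0.5, gap = 2,
                           seed_start = 2, seed_end = 13) {
  list(mismatch = mismatch, wobble = wobble, gap = gap,
       seed_start = as.integer(seed_start), seed_end = as.integer(seed_end))
}

#' Score a miRNA against one target window
#'
#' Aligns the miRNA (5' to 3') against the reverse orientation of the
#' transcript window with a gapped dynamic program minimising the penalty
#' total under [target_weights()].
#'
#' @param mirna miRNA sequence (18-26 nt, A/C/G/T or U).
#' @param window Transcript window (5' to 3', plus strand), at least as long
#'   as the miRNA.
#' @param weights [target_weights()].
#' @return List with `expectation` and an alignment block (`mirna_aln`,
#'   `marks` -- `|` pair, `o` wobble, space otherwise -- and `target_aln`,
#'   the window in 3' to 5' orientation opposite the miRNA).
#' @examples
#' score_site("TGGAGCTCCCTTCATTCCAAT", "ATTGGAATGAAGGGAGCTCCA")
#' @export
score_site <- function(mirna, window, weights = target_weights()) {
  mirna <- as_dna(mirna); window <- as_dna(window)
  check_dna(mirna, "miRNA"); check_dna(window, "target window")
  stopifnot(nchar(window) >= nchar(mirna))
  res <- .align_site(mirna, revcomp(window), weights$mismatch, weights$wobble,
                     weights$gap, weights$seed_start, weights$seed_end)
  # display the target strand 3'->5' under the miRNA 5'->3'
  target_aln <- chartr("ACGT-", "TGCA-", res$window_aln)
  list(expectation = res$expectation, mirna_aln = res$mirna_aln,
       marks = res$marks, target_aln = target_aln)
}

#' Predict miRNA target sites in a transcript set
#'
#' Scans every window of each transcript (window lengths equal to the miRNA
#' and one extra nucleotide, so single target-side bulges are representable),
#' scores it with the gapped penalty alignment, and keeps sites whose
#' expectation is at or below the cutoff. The best site per (miRNA,
#' transcript) is reported together with all ties.
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param cutoff Maximum expectation (the served default range is 3.0-3.5;
#'   values outside it are accepted with a warning).
#' @param weights [target_weights()].
#' @return A data frame of target sites: `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end` (0-based half-open on the transcript),
#'   `expectation`, `cleavage_pos` (transcript coordinate opposite miRNA
#'   position 10, 0-based), plus alignment display columns.
#' @export
predict_targets <- function(mirnas, transcripts, cutoff = 3.5,
                            weights = target_weights()) {
  if (cutoff < 3.0 || cutoff > 3.5)
    warning("expectation cutoff ", cutoff, " is outside the usual 3.0-3.5 range")
  if (length(transcripts) == 0)
    return(empty_targets())
  rows <- list()
  for (mi in names(mirnas)) {
    m <- as_dna(mirnas[[mi]])
    check_dna(m, "miRNA")
    stopifnot(nchar(m) >= 18, nchar(m) <= 26)
    for (ti in names(transcripts)) {
      tr <- as_dna(transcripts[[ti]])
      if (nchar(tr) < nchar(m)) next
      sc <- .scan_transcript(m, revcomp(tr), weights$mismatch, weights$wobble,
                             weights$gap, weights$seed_start, weights$seed_end)
      best <- min(c(sc$len_m, sc$len_m1, Inf))
      if (!is.finite(best) || best > cutoff) next
      hits0 <- which(sc$len_m == best) - 1L
      hits1 <- which(sc$len_m1 == best) - 1L
      # drop length-(m+1) ties duplicating a length-m site at the same start
      hits1 <- setdiff(hits1, hits0)
      for (h in hits0) rows[[length(rows) + 1]] <-
        site_row(mi, ti, m, tr, h, nchar(m), best, weights)
      for (h in hits1) rows[[length(rows) + 1]] <-
        site_row(mi, ti, m, tr, h, nchar(m) + 1L, best, weights)
    }
  }
  if (!length(rows)) return(empty_targets())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

site_row <- function(mirna_id, transcript_id, m, tr, start0, len, score,
                     weights) {
  window <- substr(tr, start0 + 1, start0 + len)
  aln <- score_site(m, window, weights)
  data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
             site_start = start0, site_end = start0 + len,
             expectation = score,
             cleavage_pos = start0 + len - 10L,
             mirna_aln = aln$mirna_aln, marks = aln$marks,
             target_aln = aln$target_aln, stringsAsFactors = FALSE)
}

empty_targets <- function() {
  data.frame(mirna_id = character(0), transcript_id = character(0),
             site_start = integer(0), site_end = integer(0),
             expectation = numeric(0), cleavage_pos = integer(0),
             mirna_aln = character(0), marks = character(0),
             target_aln = character(0))
}

#' Confirm predicted target sites against degradome tags
#'
#' Degradome tags are mapped to the transcripts by exact match; a site is
#' confirmed when at least one tag's 5' end coincides with the predicted
#' cleavage coordinate (between transcript positions opposite miRNA
#' positions 10 and 11).
#'
#' @param sites Target sites from [predict_targets()].
#' @param degradome Data frame with `sequence` and `count` columns (or a
#'   character vector of tag sequences), or `NULL` if no degradome data are
#'   available.
#' @param transcripts Named character vector of transcript sequences.
#' @return `sites` with `degradome_confirmed` (logical, `NA` when not
#'   assessed) and `degradome_tag_count` columns added.
#' @export
confirm_degradome <- function(sites, degradome, transcripts) {
  if (is.null(degradome)) {
    sites$degradome_confirmed <- NA
    sites$degradome_tag_count <- 0L
    attr(sites, "degradome_status") <- "not_assessed"
    return(sites)
  }
  if (is.character(degradome))
    degradome <- data.frame(sequence = degradome, count = 1L,
                            stringsAsFactors = FALSE)
  sites$degradome_confirmed <- FALSE
  sites$degradome_tag_count <- 0L
  if (!nrow(sites)) return(sites)
  # 5' end positions (0-based) of every tag on every transcript
  for (i in seq_len(nrow(sites))) {
    tr <- as_dna(transcripts[[sites$transcript_id[i]]])
    cp <- sites$cleavage_pos[i]
    cnt <- 0L
    for (j in seq_len(nrow(degradome))) {
      hit <- gregexpr(degradome$sequence[j], tr, fixed = TRUE)[[1]]
      if (hit[1] == -1) next
      if (any(hit - 1L == cp)) cnt <- cnt + degradome$count[j]
    }
    sites$degradome_tag_count[i] <- cnt
    sites$degradome_confirmed[i] <- cnt >= 1L
  }
  sites
}

#' Tally functional annotations of target genes
#'
#' Counts target transcripts per annotation category from a user-supplied
#' table (for example GO molecular-function or biological-process labels),
#' with percentages over the annotated targets; unannotated targets are
#' reported as a separate row per facet.
#'
#' @param sites Target sites (only `transcript_id` is used; duplicates from
#'   multiple sites on a transcript are counted once).
#' @param annotation Data frame with `transcript_id`, `aspect` (facet) and
#'   `term` columns.
#' @return Data frame with `aspect`, `term`, `count`, `percentage`
#'   (percentages within an aspect sum to 100 over annotated targets).
#' @export
tally_annotations <- function(sites, annotation) {
  targets <- unique(sites$transcript_id)
  if (is.null(annotation) || nrow(annotation) == 0)
    return(data.frame(aspect = "unannotated", term = "unannotated",
                      count = length(targets), percentage = NA_real_,
                      stringsAsFactors = FALSE))
  rows <- list()
  for (a in unique(annotation$aspect)) {
    ann <- annotation[annotation$aspect == a &
                        annotation$transcript_id %in% targets, , drop = FALSE]
    annotated <- unique(ann$transcript_id)
    tab <- table(unique(ann[, c("transcript_id", "term")])$term)
    tot <- sum(tab)
    for (term in names(tab))
      rows[[length(rows) + 1]] <- data.frame(
        aspect = a, term = term, count = as.integer(tab[[term]]),
        percentage = 100 * tab[[term]] / tot, stringsAsFactors = FALSE)
    un <- setdiff(targets, annotated)
    rows[[length(rows) + 1]] <- data.frame(
      aspect = a, term = "unannotated", count = length(un),
      percentage = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
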