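#' Preprocessing parameters
#'
#' Tunable thresholds for the five-class filter cascade. The quality and
#' poly(A) rules are declared defaults (conventional for Phred+33 small RNA
#' data) rather than values fixed by the protocol the cascade mirrors.
#'
#' @param quality_mean_min Minimum mean Phred score of a read (default 20).
#' @param quality_low_phred Per-base Phred score counted as "low" (default 10).
#' @param quality_low_frac Maximum tolerated fraction of low-Phred bases
#'   (default 0.10).
#' @param adapter_seed_len Length of the exact adapter prefix searched for in
#'   the read (default 8).
#' @param min_len,max_len Post-trim insert length bounds (defaults 18 and 30,
#'   the size range enriched during library construction).
#' @param polyA_frac Insert fraction of A calling a poly(A) read (default 0.8).
#' @param polyA_run Terminal run of A calling a poly(A) read (default 8).
#' @return A named list of parameters.
#' @export
preprocess_params <- function(quality_mean_min = 20, quality_low_phred = 10,
                              quality_low_frac = 0.10, adapter_seed_len = 8,
                              min_len = 18, max_len = 30,
                              polyA_frac = 0.8, polyA_run = 8) {
  list(quality_mean_min = quality_mean_min, quality_low_phred = quality_low_phred,
       quality_low_frac = quality_low_frac, adapter_seed_len = adapter_seed_len,
       min_len = min_len, max_len = max_len,
       polyA_frac = polyA_frac, polyA_run = polyA_run)
}

FILTER_CLASSES <- c("low_quality", "no_3prime_adapter", "no_insert",
                    "has_5prime_adapter", "too_short_after_trim", "poly_A")

# Vectorised single-pass classifier. Classes are applied in the fixed listing
# order, so a read matching several junk rules is counted once, in the
# earliest class. Returns the class of every read and the trimmed insert for
# clean reads. Inserts longer than max_len are counted under
# too_short_after_trim, which doubles as the general post-trim length-bounds
# class.
classify_reads <- function(seqs, quals, adapter3, adapter5, params) {
  n <- length(seqs)
  cls <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  if (n == 0) return(list(class = cls, insert = insert))

  phred <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  meanq <- vapply(phred, mean, numeric(1))
  lowfrac <- vapply(phred, function(p) mean(p < params$quality_low_phred), numeric(1))
  low <- meanq < params$quality_mean_min | lowfrac > params$quality_low_frac

  seed3 <- substr(adapter3, 1, params$adapter_seed_len)
  seed5 <- substr(adapter5, 1, params$adapter_seed_len)
  pos3 <- regexpr(seed3, seqs, fixed = TRUE)
  ins <- ifelse(pos3 > 0, substr(seqs, 1, pos3 - 1), "")
  len <- nchar(ins)
  has5 <- grepl(seed5, ins, fixed = TRUE)
  fracA <- ifelse(len > 0,
                  (len - nchar(gsub("A", "", ins, fixed = TRUE))) / pmax(len, 1), 0)
  runA <- grepl(strrep("A", params$polyA_run), ins, fixed = TRUE)

  cls[low] <- "low_quality"
  sel <- is.na(cls) & pos3 < 0;                       cls[sel] <- "no_3prime_adapter"
  sel <- is.na(cls) & pos3 == 1;                      cls[sel] <- "no_insert"
  sel <- is.na(cls) & has5;                           cls[sel] <- "has_5prime_adapter"
  sel <- is.na(cls) & (len < params$min_len | len > params$max_len)
  cls[sel] <- "too_short_after_trim"
  sel <- is.na(cls) & (fracA >= params$polyA_frac | runA)
  cls[sel] <- "poly_A"
  sel <- is.na(cls)
  cls[sel] <- "clean"
  insert[sel] <- ins[sel]
  list(class = cls, insert = insert)
}

#' Filter raw reads and collapse clean tags
#'
#' Applies the five-class filter cascade in a fixed order -- low sequencing
#' quality, no 3' adapter, no insert, 5' adapter contamination, post-trim
#' length out of bounds, poly(A) -- assigning every read to exactly one
#' removal class (the first matching rule). Survivors are trimmed at the
#' first exact match of the 3' adapter seed, length-bounded, and collapsed to
#' unique tags with summed counts.
#'
#' @param reads Either a path to a FASTQ file or a data frame with columns
#'   `sequence` and `quality` (Phred+33).
#' @param adapter3,adapter5 3' and 5' adapter sequences (non-empty).
#' @param params Parameter list from [preprocess_params()].
#' @param library_id Label attached to the collapsed tags.
#' @return A list with `tags` (data frame: `sequence`, `count`, `library_id`)
#'   and `report` (a `filter_report`: `raw_reads`, named `removed` counts,
#'   `clean_reads`, `clean_unique`).
#' @examples
#' reads <- data.frame(sequence = paste0(strrep("AG", 11), "TGGAATTCTCGGGTGCCAAGG",
#'                                       strrep("C", 7)),
#'                     quality = strrep("I", 50))
#' filter_and_trim(reads, "TGGAATTCTCGGGTGCCAAGG", "GTTCAGAGTTCTACAGTCCGACGATC")
#' @export
filter_and_trim <- function(reads, adapter3, adapter5,
                            params = preprocess_params(), library_id = "lib1") {
  stopifnot(nzchar(adapter3), nzchar(adapter5))
  if (is.character(reads)) reads <- read_fastq(reads)
  n <- nrow(reads)
  if (n == 0) {
    report <- new_filter_report(0L, stats::setNames(integer(length(FILTER_CLASSES)),
                                                    FILTER_CLASSES), 0L, 0L)
    return(list(tags = data.frame(sequence = character(0), count = integer(0),
                                  library_id = character(0)),
                report = report))
  }
  cl <- classify_reads(reads$sequence, reads$quality, adapter3, adapter5, params)
  removed <- vapply(FILTER_CLASSES, function(k) sum(cl$class == k), integer(1))
  inserts <- cl$insert[cl$class == "clean"]
  tab <- table(inserts)
  tags <- data.frame(sequence = as.character(names(tab)),
                     count = as.integer(tab),
                     library_id = rep(library_id, length(tab)),
                     stringsAsFactors = FALSE)
  tags <- tags[order(-tags$count, tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL
  report <- new_filter_report(n, removed, length(inserts), nrow(tags))
  list(tags = tags, report = report)
}

new_filter_report <- function(raw, removed, clean, unique) {
  structure(list(raw_reads = as.integer(raw), removed = removed,
                 clean_reads = as.integer(clean), clean_unique = as.integer(unique)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report:", x$raw_reads, "raw reads ->", x$clean_reads,
      "clean reads (", x$clean_unique, "unique tags )\n")
  for (k in names(x$removed))
    cat(sprintf("  removed %-22s %d\n", k, x$removed[[k]]))
  invisible(x)
}

#' Length distribution of collapsed tags
#'
#' @param tags Data frame with `sequence` and `count` columns.
#' @param plot If `TRUE`, draw a bar chart of total counts per length.
#' @return Data frame with columns `length`, `total`, `unique`.
#' @export
length_distribution <- function(tags, plot = FALSE) {
  if (nrow(tags) == 0)
    return(data.frame(length = integer(0), total = integer(0), unique = integer(0)))
  len <- nchar(tags$sequence)
  total <- vapply(split(tags$count, len), sum, numeric(1))
  uniq <- vapply(split(tags$count, len), length, integer(1))
  out <- data.frame(length = as.integer(names(total)),
                    total = as.integer(total), unique = uniq, row.names = NULL)
  out <- out[order(out$length), , drop = FALSE]
  if (plot)
    graphics::barplot(out$total, names.arg = out$length,
                      xlab = "tag length (nt)", ylab = "reads")
  out
}
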