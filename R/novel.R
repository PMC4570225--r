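#' Parameters for novel miRNA discovery
#'
#' @param flank_up,flank_down Maximum genomic flank excised around an
#'   anchoring tag when searching for a hairpin precursor (default 150 nt
#'   each, capped at 300).
#' @param extents Candidate precursor extents tried on the star side of the
#'   tag; the best-scoring extent is kept. Values above `flank_up`/
#'   `flank_down` are ignored.
#' @param anchor_margin Extra nucleotides retained on the mature side of the
#'   tag (default 10).
#' @param max_bulge Largest internal loop or bulge (nt) tolerated within the
#'   mature:star duplex (default 4).
#' @param min_paired_frac Minimum fraction of mature bases paired in the
#'   duplex (default 0.6).
#' @param energy_max Duplex hybridisation energy threshold in kcal/mol
#'   (default -18; candidates must be at or below it).
#' @param min_support Minimum summed mature read support across libraries
#'   (default 5).
#' @param min_libraries Minimum number of libraries in which the candidate
#'   must be detected (default 2).
#' @param max_shift Terminal tolerance (nt) when counting reads against the
#'   mature or star interval (default 3), with no internal mismatch allowed.
#' @param cluster_gap Maximum genomic gap when clustering tag hits into loci
#'   (default 30 nt).
#' @return Named list of parameters.
#' @export
novel_params <- function(flank_up = 150, flank_down = 150,
                         extents = c(40, 70, 110, 150), anchor_margin = 10,
                         max_bulge = 4, min_paired_frac = 0.6,
                         energy_max = -18, min_support = 5, min_libraries = 2,
                         max_shift = 3, cluster_gap = 30) {
  stopifnot(flank_up <= 300, flank_down <= 300)
  list(flank_up = flank_up, flank_down = flank_down,
       extents = extents, anchor_margin = anchor_margin,
       max_bulge = max_bulge, min_paired_frac = min_paired_frac,
       energy_max = energy_max, min_support = min_support,
       min_libraries = min_libraries, max_shift = max_shift,
       cluster_gap = cluster_gap)
}

pair_energy_r <- function(a, b) {
  ifelse((a == "G" & b == "C") | (a == "C" & b == "G"), -3,
  ifelse((a == "A" & b == "T") | (a == "T" & b == "A"), -2,
  ifelse((a == "G" & b == "T") | (a == "T" & b == "G"), -1, 0)))
}

#' Excise candidate precursor windows around a genomic tag hit and fold them
#'
#' For each excision register (tag on the 5' arm with the putative star
#' downstream, and tag on the 3' arm with the star upstream) and each
#' precursor extent, the genomic window is excised in transcript orientation
#' (reverse-complemented for minus-strand hits), truncated at contig edges,
#' and folded.
#'
#' @param hit A single-row data frame (or list) with `contig`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @param genome Named character vector or `DNAStringSet`.
#' @param params [novel_params()].
#' @return A list of drafts; each draft holds `window` (sequence, transcript
#'   orientation), `structure`, `mfe`, `mature_start`/`mature_end` (1-based
#'   inclusive window coordinates of the tag), `register`, genomic window
#'   coordinates and strand.
#' @export
excise_and_fold <- function(hit, genome, params = novel_params()) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  cseq <- as.character(genome[[hit$contig]])
  clen <- nchar(cseq)
  exts <- unique(pmin(params$extents, max(params$flank_up, params$flank_down)))
  drafts <- list()
  for (register in c("5p", "3p")) {
    for (ext in exts) {
      u <- if (register == "5p") params$anchor_margin else ext
      d <- if (register == "5p") ext else params$anchor_margin
      if (hit$strand == "+") {
        ws <- max(0L, hit$start - u); we <- min(clen, hit$end + d)
      } else {
        ws <- max(0L, hit$start - d); we <- min(clen, hit$end + u)
      }
      win <- substr(cseq, ws + 1L, we)
      if (hit$strand == "-") win <- revcomp(win)
      ms <- if (hit$strand == "+") hit$start - ws + 1L else we - hit$end + 1L
      me <- ms + (hit$end - hit$start) - 1L
      f <- fold_rna(win)
      drafts[[length(drafts) + 1]] <- list(
        window = win, structure = f$structure, mfe = f$mfe,
        mature_start = ms, mature_end = me, register = register,
        contig = hit$contig, window_start = ws, window_end = we,
        strand = hit$strand)
    }
  }
  drafts
}

#' Evaluate the five hairpin-precursor conditions on a folded draft
#'
#' Flags: `arm_placement` (the mature lies wholly on one arm and does not
#' run into the terminal loop of its own hairpin), `star_duplex_geometry`
#' (the pairing partner of the mature, offset to give 2 nt 3' overhangs on
#' both strands, fits inside the window and does not overlap the mature),
#' `loop_bulge_ok` (no internal loop or bulge larger than `max_bulge` within
#' the mature:star duplex, and at least `min_paired_frac` of mature bases
#' paired), `energy_ok` (duplex hybridisation energy at or below
#' `energy_max`), and `support_ok` (summed mature read support at or above
#' `min_support`).
#'
#' @param draft A draft from [excise_and_fold()].
#' @param support Summed mature read support across libraries.
#' @param params [novel_params()].
#' @return The draft augmented with `condition_flags`, `star_start`,
#'   `star_end`, `star_seq`, `duplex_energy` and `pass_structure`.
#' @export
evaluate_conditions <- function(draft, support = 0, params = novel_params()) {
  partner <- pair_table(draft$structure)
  n <- nchar(draft$window)
  ms <- draft$mature_start; me <- draft$mature_end
  mat_pos <- ms:me
  paired <- mat_pos[!is.na(partner[mat_pos])]
  flags <- c(arm_placement = FALSE, star_duplex_geometry = FALSE,
             loop_bulge_ok = FALSE, energy_ok = FALSE,
             support_ok = support >= params$min_support)
  draft$star_start <- NA_integer_; draft$star_end <- NA_integer_
  draft$star_seq <- NA_character_; draft$duplex_energy <- NA_real_

  if (length(paired) > 0) {
    part <- partner[paired]
    one_sided <- all(part > me) || all(part < ms)
    in_loop <- if (all(part > me)) {
      # 5p arm: terminal loop lies 3' of the last paired mature base
      any(mat_pos > max(paired))
    } else if (all(part < ms)) {
      # 3p arm: terminal loop lies 5' of the first paired mature base
      any(mat_pos < min(paired))
    } else TRUE
    flags["arm_placement"] <- one_sided && !in_loop

    # Dicer duplex: star = partner of the mature with 2 nt 3' overhangs.
    if (one_sided && !is.na(partner[ms]) && me - 2 >= ms && !is.na(partner[me - 2])) {
      lo <- partner[me - 2]; hi <- partner[ms] + 2L
      if (lo <= hi && lo >= 1 && hi <= n && (hi < ms || lo > me)) {
        flags["star_duplex_geometry"] <- TRUE
        draft$star_start <- lo; draft$star_end <- hi
        draft$star_seq <- substr(draft$window, lo, hi)
      }
    }

    # Internal loops/bulges within the duplex, on both strands.
    frac <- length(paired) / length(mat_pos)
    internal <- diff(sort(paired)) - 1L
    star_gap <- abs(diff(partner[sort(paired)])) - 1L
    flags["loop_bulge_ok"] <- frac >= params$min_paired_frac &&
      (length(internal) == 0 ||
         (max(internal) <= params$max_bulge && max(star_gap) <= params$max_bulge))

    w <- strsplit(draft$window, "")[[1]]
    draft$duplex_energy <- sum(pair_energy_r(w[paired], w[partner[paired]]))
    flags["energy_ok"] <- draft$duplex_energy <= params$energy_max
  }
  draft$condition_flags <- flags
  draft$pass_structure <- all(flags[c("arm_placement", "star_duplex_geometry",
                                      "loop_bulge_ok", "energy_ok")])
  draft
}

# Cheap prefilter for anchored counting: a tag can only qualify if its
# middle portion (which must match exactly) occurs in the window.
tags_near <- function(seqs, window) {
  core <- substr(seqs, 4, nchar(seqs) - 3)
  seqs[vapply(core, function(s) regexpr(s, window, fixed = TRUE) > 0, logical(1))]
}

# Does `tag` align to `window` anchored at [anchor_s, anchor_e] (1-based
# inclusive) under the counting tolerance: both ends within `max_shift` nt of
# the anchor ends, mismatches only within the terminal 3 nt of the tag, at
# most `max_shift` of them, none in the middle?
aligns_anchored <- function(tag, window, anchor_s, anchor_e, max_shift = 3) {
  len <- nchar(tag)
  tg <- strsplit(tag, "")[[1]]
  n <- nchar(window)
  for (p in (anchor_s - max_shift):(anchor_s + max_shift)) {
    q <- p + len - 1L
    if (p < 1 || q > n) next
    if (abs(q - anchor_e) > max_shift) next
    wv <- strsplit(substr(window, p, q), "")[[1]]
    mm <- which(tg != wv)
    if (length(mm) > max_shift) next
    if (all(mm <= 3 | mm > len - 3)) return(TRUE)
  }
  FALSE
}

#' Detect a sequenced miRNA* for a candidate
#'
#' @param candidate An evaluated candidate with `star_start`/`star_end`.
#' @param tags Data frame of collapsed tags (`sequence`, `count`,
#'   `library_id`) pooled over libraries.
#' @param params [novel_params()].
#' @return `TRUE` if any tag aligns to the star interval under the counting
#'   tolerance (terminal overhangs of at most 3 nt, no internal mismatch).
#' @export
detect_star <- function(candidate, tags, params = novel_params()) {
  if (is.na(candidate$star_start)) return(FALSE)
  for (s in tags_near(unique(tags$sequence), candidate$window)) {
    if (aligns_anchored(s, candidate$window, candidate$star_start,
                        candidate$star_end, params$max_shift)) return(TRUE)
  }
  FALSE
}

#' Quantify a candidate's expression per library
#'
#' Per-library expression is the summed count of tags aligning to the mature
#' anchor with no more than 3 nt terminal overhang and no internal mismatch.
#'
#' @param candidate An evaluated candidate.
#' @param tags Data frame (`sequence`, `count`, `library_id`).
#' @param params [novel_params()].
#' @return Named numeric vector of counts per library (only libraries with
#'   support appear).
#' @export
quantify_candidate <- function(candidate, tags, params = novel_params()) {
  near <- tags_near(unique(tags$sequence), candidate$window)
  qual <- vapply(near, function(s)
    aligns_anchored(s, candidate$window, candidate$mature_start,
                    candidate$mature_end, params$max_shift), logical(1))
  t2 <- tags[tags$sequence %in% names(qual)[qual], , drop = FALSE]
  if (nrow(t2) == 0) return(stats::setNames(numeric(0), character(0)))
  vapply(split(t2$count, t2$library_id), sum, numeric(1))
}

# Genomic interval (0-based half-open, plus-strand coordinates) of window
# positions [a, b] (1-based inclusive, transcript orientation).
window_to_genomic <- function(draft, a, b) {
  if (draft$strand == "+")
    c(draft$window_start + a - 1L, draft$window_start + b)
  else
    c(draft$window_end - b, draft$window_end - a + 1L)
}

#' Discover novel miRNA candidates from unannotated and intronic tags
#'
#' Tags annotated as unannotated (with a genome hit), intronic (either
#' sense) or exon-antisense are clustered into genomic loci; the
#' highest-count tag anchors each cluster. Both excision registers are
#' folded over several precursor extents, the best-scoring draft is
#' evaluated against the five hairpin conditions, expression is counted
#' under the terminal tolerance, and the star arm is searched in the
#' sequenced tags. Bistranded loci (a passing hairpin supported by reads on
#' both genomic strands at the same locus) are merged and flagged.
#'
#' @param assignments Annotated tags from [annotate_tags()] for all
#'   libraries (columns `sequence`, `count`, `library_id`, `category`).
#' @param genome Named character vector or `DNAStringSet`.
#' @param params [novel_params()].
#' @param genome_hits Optional precomputed [map_exact()] table.
#' @return A list with `candidates` (one row per evaluated locus, with
#'   condition flags, star status, per-locus support), `putative` (ids
#'   passing all conditions in at least `min_libraries` libraries), `novel`
#'   (putative with a detected star) and `expression` (per candidate per
#'   library counts).
#' @export
discover_novel <- function(assignments, genome, params = novel_params(),
                           genome_hits = NULL) {
  cand_cat <- c("unannotated", "intron_sense", "intron_antisense", "exon_antisense")
  cand <- assignments[assignments$category %in% cand_cat, , drop = FALSE]
  totals <- vapply(split(cand$count, cand$sequence), sum, numeric(1))
  keep <- names(totals)[totals >= params$min_support]
  if (length(keep) == 0)
    return(list(candidates = empty_candidates(), putative = character(0),
                novel = character(0), expression = NULL))
  if (is.null(genome_hits)) genome_hits <- attr(assignments, "genome_hits")
  if (is.null(genome_hits)) genome_hits <- map_exact(keep, genome)
  hits <- genome_hits[genome_hits$sequence %in% keep, , drop = FALSE]
  if (nrow(hits) == 0)
    return(list(candidates = empty_candidates(), putative = character(0),
                novel = character(0), expression = NULL))

  # Cluster hits into loci per (contig, strand); anchor = highest-count tag.
  hits <- hits[order(hits$contig, hits$strand, hits$start), , drop = FALSE]
  grp <- paste(hits$contig, hits$strand)
  cluster <- integer(nrow(hits)); cid <- 0L; last_end <- -Inf; last_grp <- ""
  for (i in seq_len(nrow(hits))) {
    if (grp[i] != last_grp || hits$start[i] > last_end + params$cluster_gap) {
      cid <- cid + 1L; last_end <- hits$end[i]
    } else last_end <- max(last_end, hits$end[i])
    cluster[i] <- cid; last_grp <- grp[i]
  }

  rows <- list(); expr <- list()
  for (cl in unique(cluster)) {
    h <- hits[cluster == cl, , drop = FALSE]
    tot <- totals[h$sequence]
    anchor <- h[order(-tot, h$sequence), , drop = FALSE][1, ]
    drafts <- excise_and_fold(anchor, genome, params)
    support0 <- totals[[anchor$sequence]]
    evs <- lapply(drafts, evaluate_conditions, support = support0, params = params)
    score <- vapply(evs, function(e)
      sum(e$condition_flags[c("arm_placement", "star_duplex_geometry",
                              "loop_bulge_ok", "energy_ok")]), numeric(1))
    denergy <- vapply(evs, function(e)
      ifelse(is.na(e$duplex_energy), 0, e$duplex_energy), numeric(1))
    best <- evs[[order(-score, denergy)[1]]]

    counts <- quantify_candidate(best, cand, params)
    support <- sum(counts)
    best <- evaluate_conditions(best, support = support, params = params)
    star <- detect_star(best, cand, params)
    arm <- if (length(best$condition_flags) && best$condition_flags["arm_placement"]) {
      partner <- pair_table(best$structure)
      mat_pos <- best$mature_start:best$mature_end
      paired <- mat_pos[!is.na(partner[mat_pos])]
      if (all(partner[paired] > best$mature_end)) "5p" else "3p"
    } else best$register
    mg <- window_to_genomic(best, best$mature_start, best$mature_end)
    wg <- c(best$window_start, best$window_end)
    rows[[length(rows) + 1]] <- data.frame(
      contig = best$contig, strand = best$strand,
      window_start = wg[1], window_end = wg[2],
      mature_gstart = mg[1], mature_gend = mg[2],
      mature_seq = anchor$sequence, arm = arm,
      mature_wstart = best$mature_start, mature_wend = best$mature_end,
      star_seq = best$star_seq, star_detected = star,
      star_wstart = if (is.na(best$star_start)) NA_integer_ else best$star_start,
      star_wend = if (is.na(best$star_end)) NA_integer_ else best$star_end,
      precursor_seq = best$window, structure = best$structure,
      mfe = best$mfe, duplex_energy = best$duplex_energy,
      arm_placement = unname(best$condition_flags["arm_placement"]),
      star_duplex_geometry = unname(best$condition_flags["star_duplex_geometry"]),
      loop_bulge_ok = unname(best$condition_flags["loop_bulge_ok"]),
      energy_ok = unname(best$condition_flags["energy_ok"]),
      support_ok = unname(best$condition_flags["support_ok"]),
      pass_all = best$pass_structure && best$condition_flags["support_ok"],
      read_support = support, n_libraries = length(counts),
      stringsAsFactors = FALSE)
    if (length(counts))
      expr[[length(expr) + 1]] <- data.frame(
        mature_seq = anchor$sequence, library_id = names(counts),
        count = as.numeric(counts), stringsAsFactors = FALSE)
  }
  cands <- do.call(rbind, rows)

  # Merge candidates describing the same hairpin locus. A perfectly
  # complementary stem makes the mature tag map to both strands (its reverse
  # complement is the star arm), so one hairpin can surface as up to four
  # mirror candidates; merging is by overlap of the hairpin core (the
  # mature:star span). The kept representative prefers condition-passing
  # candidates, then higher read support, then the lexicographically
  # smaller mature (this also collapses 1-nt-shifted mature pairs from one
  # precursor). A locus is bistranded when a distinct tag sequence supports
  # a passing hairpin on the opposite strand.
  core <- t(vapply(seq_len(nrow(cands)), function(i) {
    lo <- cands$mature_gstart[i]; hi <- cands$mature_gend[i]
    if (!is.na(cands$star_seq[i])) {
      # star interval in genomic coordinates via the stored window
      d <- list(strand = cands$strand[i], window_start = cands$window_start[i],
                window_end = cands$window_end[i])
      sg <- window_to_genomic(d, cands$star_wstart[i], cands$star_wend[i])
      lo <- min(lo, sg[1]); hi <- max(hi, sg[2])
    }
    c(lo, hi)
  }, numeric(2)))
  ord <- order(-cands$pass_all, -cands$read_support, cands$mature_seq)
  drop <- rep(FALSE, nrow(cands))
  for (i in ord) {
    if (drop[i]) next
    for (j in ord) {
      if (j == i || drop[j] || cands$contig[i] != cands$contig[j]) next
      if (!(core[j, 1] < core[i, 2] && core[i, 1] < core[j, 2])) next
      # i outranks j by the ordering above
      drop[j] <- TRUE
      cands$star_detected[i] <- cands$star_detected[i] || cands$star_detected[j]
    }
  }
  cands <- cands[!drop, , drop = FALSE]

  # Bistranded loci: the exact antisense mature was sequenced. In a 2-nt
  # overhang duplex the star arm itself aligns to the antisense mature
  # anchor within the +/-3 counting tolerance, so only an exact antisense
  # tag is accepted as evidence of transcription from both strands.
  pool <- unique(cand$sequence)
  cands$bistranded <- cands$pass_all & revcomp(cands$mature_seq) %in% pool
  ord <- order(cands$contig, cands$mature_gstart)
  cands <- cands[ord, , drop = FALSE]
  cands$id <- sprintf("cand_mir_%03d-%s", seq_len(nrow(cands)), cands$arm)
  rownames(cands) <- NULL

  putative <- cands$id[cands$pass_all & cands$n_libraries >= params$min_libraries]
  novel <- cands$id[cands$id %in% putative & cands$star_detected]
  expression <- if (length(expr)) do.call(rbind, expr) else NULL
  if (!is.null(expression)) {
    key <- match(expression$mature_seq, cands$mature_seq)
    expression$id <- cands$id[key]
    expression <- expression[!is.na(expression$id), , drop = FALSE]
  }
  list(candidates = cands, putative = putative, novel = novel,
       expression = expression)
}

empty_candidates <- function() {
  data.frame(contig = character(0), strand = character(0),
             window_start = integer(0), window_end = integer(0),
             mature_gstart = integer(0), mature_gend = integer(0),
             mature_seq = character(0), arm = character(0),
             mature_wstart = integer(0), mature_wend = integer(0),
             star_seq = character(0), star_detected = logical(0),
             star_wstart = integer(0), star_wend = integer(0),
             precursor_seq = character(0), structure = character(0),
             mfe = numeric(0), duplex_energy = numeric(0),
             arm_placement = logical(0), star_duplex_geometry = logical(0),
             loop_bulge_ok = logical(0), energy_ok = logical(0),
             support_ok = logical(0), pass_all = logical(0),
             read_support = numeric(0), n_libraries = integer(0),
             bistranded = logical(0), id = character(0))
}
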