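# Target-site planting for the synthetic transcriptome.
#
# A planted site starts from the perfect reverse complement of the mature
# miRNA and introduces mismatches/G:U wobbles at chosen miRNA positions to
# reach a designed expectation score by construction arithmetic (mismatch
# +1, wobble +0.5, doubled at seed positions 2-13); the scorer is never
# consulted, so the designed value is an independent oracle.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Transcript-side base creating a mismatch (neither Watson-Crick nor wobble)
# against miRNA base `x`.
mismatch_base <- function(x) {
  avoid <- c(COMP[[x]], if (x == "G") "T" else if (x == "T") "G")
  setdiff(DNA_BASES, c(avoid, x))[1]
}

# Transcript-side base creating a G:U wobble against miRNA base `x` (which
# must be G or T).
wobble_base <- function(x) {
  if (x == "G") "T" else if (x == "T") "G" else
    stop("wobble requires a G or U miRNA base", call. = FALSE)
}

# Build a target site for `mature` with designed expectation `score`.
# Returns the transcript-side site sequence (5'->3').
design_site <- function(mature, score) {
  m <- strsplit(mature, "")[[1]]
  L <- length(m)
  outside <- setdiff(seq_len(L), 2:13)
  out_wob <- outside[m[outside] %in% c("G", "T")]
  # atoms: list of (positions pool, penalty, type)
  plans <- list(
    "0" = list(),
    "2.5" = list(list(outside, "mm"), list(outside, "mm"), list(out_wob, "wob")),
    "3" = list(list(outside, "mm"), list(outside, "mm"), list(outside, "mm")),
    "3.5" = list(list(2:13, "mm"), list(outside, "mm"), list(out_wob, "wob")),
    "4" = list(list(2:13, "mm"), list(2:13, "mm")))
  key <- as.character(score)
  if (!key %in% names(plans))
    stop("no designed-site plan for expectation ", score, call. = FALSE)
  plan <- plans[[key]]
  # half-unit scores need a wobble-capable (G/U) miRNA position outside the
  # seed (penalty +0.5); scores at such granularity are unreachable otherwise
  if (length(plan) && any(vapply(plan, function(a) length(a[[1]]) == 0, logical(1))))
    stop("mature sequence admits no suitable positions for expectation ", score,
         call. = FALSE)
  used <- integer(0)
  site <- rev(vapply(m, function(x) COMP[[x]], character(1)))  # perfect rc
  for (a in plan) {
    pool <- setdiff(a[[1]], used)
    if (!length(pool)) stop("no free position for designed site", call. = FALSE)
    p <- pool[1]
    used <- c(used, p)
    b <- if (a[[2]] == "mm") mismatch_base(m[p]) else wobble_base(m[p])
    site[L - p + 1] <- b           # miRNA position p pairs site position L-p+1
  }
  paste(site, collapse = "")
}

# Plant target sites into a synthetic transcriptome and fabricate a GO-style
# annotation table for the transcripts.
plant_targets <- function(planted, n_transcripts, adapter3, adapter5) {
  novel <- planted[!planted$known & is.na(planted$ablation), , drop = FALSE]
  donors <- if (nrow(novel)) novel else planted
  if (nrow(donors) == 0) {
    transcripts <- stats::setNames(
      vapply(seq_len(max(n_transcripts, 1)), function(i) random_dna(600),
             character(1)),
      sprintf("tr_%02d", seq_len(max(n_transcripts, 1))))
    return(list(transcripts = transcripts,
                targets = data.frame(locus_id = character(0),
                                     mature_seq = character(0),
                                     transcript_id = character(0),
                                     site_start = integer(0),
                                     site_end = integer(0),
                                     expectation = numeric(0),
                                     confirmed = logical(0),
                                     cleavage_pos = integer(0)),
                go = NULL))
  }
  design <- data.frame(
    expectation = c(0, 2.5, 3, 3.5, 4, 0),
    confirmed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  n_tr <- max(n_transcripts, nrow(design))
  transcripts <- stats::setNames(
    vapply(seq_len(n_tr), function(i) random_dna(600), character(1)),
    sprintf("tr_%02d", seq_len(n_tr)))
  targets <- list()
  for (i in seq_len(nrow(design))) {
    don <- donors[((i - 1) %% nrow(donors)) + 1, ]
    site <- design_site(don$mature_seq, design$expectation[i])
    tid <- names(transcripts)[i]
    off <- 150 + 17 * i                       # 0-based site start
    tr <- transcripts[[tid]]
    transcripts[[tid]] <- paste0(substr(tr, 1, off), site,
                                 substr(tr, off + nchar(site) + 1, nchar(tr)))
    site_end <- off + nchar(site)
    targets[[i]] <- data.frame(
      locus_id = don$locus_id, mature_seq = don$mature_seq,
      transcript_id = tid, site_start = off, site_end = site_end,
      expectation = design$expectation[i], confirmed = design$confirmed[i],
      cleavage_pos = site_end - 10L,  # 5' end of the downstream fragment
      stringsAsFactors = FALSE)
  }
  terms_mf <- c("catalytic activity", "binding", "transporter activity",
                "structural molecule activity")
  terms_bp <- c("metabolic process", "cellular process", "response to stimulus")
  go <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
    if (i %% 5 == 0) return(NULL)  # some transcripts stay unannotated
    rbind(data.frame(transcript_id = names(transcripts)[i],
                     aspect = "molecular_function",
                     term = terms_mf[(i %% length(terms_mf)) + 1],
                     stringsAsFactors = FALSE),
          data.frame(transcript_id = names(transcripts)[i],
                     aspect = "biological_process",
                     term = terms_bp[(i %% length(terms_bp)) + 1],
                     stringsAsFactors = FALSE))
  }))
  list(transcripts = transcripts, targets = do.call(rbind, targets), go = go)
}
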