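#' Default adapters used by the synthetic study
#'
#' TruSeq-style small RNA adapters; the 3' adapter is ligated to every
#' sequenced insert and the 5' adapter appears only in the 5'-adapter
#' contamination junk class.
#' @name sim_adapters
#' @keywords internal
NULL

SIM_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
SIM_ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
# Sequencing continuation past the 3' adapter, used to pad reads to 50 nt.
SIM_ADAPTER3_TAIL <- "AACTCCAGTCACATCACGATCTCGTATGCCGTCTTCTGCTTG"

# A sequence is "clean" if the preprocessing cascade would keep it: no 3' or
# 5' adapter seed inside the insert, no poly(A) signal.
seq_is_clean <- function(s, adapter3 = SIM_ADAPTER3, adapter5 = SIM_ADAPTER5,
                         params = preprocess_params()) {
  seed3 <- substr(adapter3, 1, params$adapter_seed_len)
  seed5 <- substr(adapter5, 1, params$adapter_seed_len)
  !grepl(seed3, s, fixed = TRUE) & !grepl(seed5, s, fixed = TRUE) &
    !grepl(strrep("A", params$polyA_run), s, fixed = TRUE) &
    (nchar(gsub("[^A]", "", s)) / nchar(s)) < params$polyA_frac
}

# Draw until `maker()` returns a clean sequence.
draw_clean <- function(maker, what, tries = 200) {
  for (i in seq_len(tries)) {
    s <- maker()
    if (all(seq_is_clean(s))) return(s)
  }
  stop("could not draw a clean sequence for ", what, call. = FALSE)
}

# ---------------------------------------------------------------------------
# Hairpin constructors. A planted hairpin is mature + loop + reverse
# complement of the mature + a short 3' tail; the tail provides the star's
# 2 nt 3' overhang. Construction is verified by folding through the
# discovery module itself, never trusted.

make_hairpin <- function(mature_len = 21, pad5 = 0, tail = 2) {
  M <- random_dna(mature_len, gc_min = 0.5)
  loop <- random_dna(sample(9:14, 1))
  list(precursor = paste0(if (pad5 > 0) random_dna(pad5) else "",
                          M, loop, revcomp(M),
                          if (tail > 0) random_dna(tail) else ""),
       mature = M, mature_off = pad5, mature_len = mature_len)
}

# Hairpin whose emitted "mature" tag runs 2 nt into the terminal loop:
# the tag covers the last 19 stem bases plus the first 2 loop bases.
make_hairpin_mature_in_loop <- function(mature_len = 21) {
  h <- make_hairpin(mature_len, pad5 = 0, tail = 2)
  h$mature_off <- 2L
  h$mature <- substr(h$precursor, 3, 2 + mature_len)
  h$mature_len <- mature_len
  h
}

# Hairpin whose star arm cannot form a 2 nt 3' overhang duplex: the arm only
# pairs mature positions 3..L, so the mature 5' end is unpaired.
make_hairpin_star_overhang <- function(mature_len = 21) {
  M <- random_dna(mature_len, gc_min = 0.5)
  loop <- random_dna(sample(9:14, 1))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m12 <- strsplit(substr(M, 1, 2), "")[[1]]
  # tail chosen not to re-establish pairing with mature positions 2 then 1
  tail <- paste0(sample(setdiff(DNA_BASES, c(comp[[m12[2]]],
                   if (m12[2]  %in% c("G", "T")) chartr("GT", "TG", m12[2]))), 1),
                 sample(setdiff(DNA_BASES, c(comp[[m12[1]]],
                   if (m12[1] %in% c("G", "T")) chartr("GT", "TG", m12[1]))), 1))
  list(precursor = paste0(M, loop, revcomp(substr(M, 3, mature_len)), tail),
       mature = M, mature_off = 0L, mature_len = mature_len)
}

# Hairpin with a 6 nt bulge on the star side of the duplex.
make_hairpin_bulge <- function(mature_len = 21, bulge = 6) {
  M <- random_dna(mature_len, gc_min = 0.5)
  loop <- random_dna(sample(9:14, 1))
  cut <- 11
  list(precursor = paste0(M, loop,
                          revcomp(substr(M, cut + 1, mature_len)),
                          random_dna(bulge),
                          revcomp(substr(M, 1, cut)),
                          random_dna(2)),
       mature = M, mature_off = 0L, mature_len = mature_len)
}

# Unstable hairpin whose excised window folds to exactly -17 kcal/mol under
# the maximal-pairing model, by a composition cap: the window (hairpin plus
# poly(A) flanking islands) contains exactly one C, one G and seven U, so
# the best attainable structure anywhere in it is one G:C (-3) plus seven
# A:U (-14) pairs. The mature:star duplex energy therefore cannot reach
# -18 and the stability condition fails for every excision register. Note
# that under this energy model a locus violating *only* the stability
# condition cannot exist: any duplex between -18 and 0 with >= 60% of an
# 18+ nt mature paired forces G:U wobbles, which put both G and U in the
# window, leaving no base that the maximal-pairing optimiser will not pair
# off and push the energy past -18. This fixture therefore also undershoots
# the pairing-fraction floor; its removal from the candidate set is driven
# by the energy flag.
make_hairpin_energy <- function() {
  M <- paste0("C", strrep("AC", 7), "CCC")     # 18 nt, seven A, no G/U
  list(precursor = paste0(M, strrep("C", 4), strrep("T", 7), "G"),
       mature = M, mature_off = 0L, mature_len = 18L,
       island = 170L)
}

# ---------------------------------------------------------------------------

# Non-overlapping feature placement. `occ` is a two-column matrix of occupied
# (start, end) half-open intervals.
place_feature <- function(occ, len, genome_len, margin = 40, edge = 200,
                          category = "feature", tries = 500) {
  for (i in seq_len(tries)) {
    s <- sample.int(genome_len - len - 2 * edge, 1) + edge
    if (!any(s < occ[, 2] + margin & occ[, 1] - margin < s + len))
      return(s)
  }
  stop("feature placement failed for category '", category,
       "': genome too crowded", call. = FALSE)
}

plant_seq <- function(genome_str, pos0, s) {
  paste0(substr(genome_str, 1, pos0), s,
         substr(genome_str, pos0 + nchar(s) + 1, nchar(genome_str)))
}

# Run the discovery module's excision + evaluation on a planted locus and
# return the best draft (same selection rule as discover_novel).
verify_planted <- function(genome_str, mstart, mend, strand, support = 5,
                           params = novel_params()) {
  hit <- list(contig = "chr1", start = mstart, end = mend, strand = strand)
  drafts <- excise_and_fold(hit, c(chr1 = genome_str), params)
  evs <- lapply(drafts, evaluate_conditions, support = support, params = params)
  score <- vapply(evs, function(e)
    sum(e$condition_flags[c("arm_placement", "star_duplex_geometry",
                            "loop_bulge_ok", "energy_ok")]), numeric(1))
  denergy <- vapply(evs, function(e)
    ifelse(is.na(e$duplex_energy), 0, e$duplex_energy), numeric(1))
  evs[[order(-score, denergy)[1]]]
}

struct_flags <- function(ev) ev$condition_flags[c("arm_placement",
  "star_duplex_geometry", "loop_bulge_ok", "energy_ok")]

#' Generate a synthetic small RNA study genome with a ground-truth ledger
#'
#' Builds a random genome into which the generator plants: novel miRNA
#' hairpin loci (verified by folding through the discovery module itself --
#' every planted locus must pass all five candidate conditions, otherwise it
#' is redrawn), known miRNA loci with mature/precursor reference entries,
#' ncRNA loci (rRNA, snRNA, snoRNA, tRNA from GenBank-like and Rfam-like
#' sources), repeat intervals and multi-exon gene models. A synthetic
#' transcriptome (not embedded in the genome) carries planted miRNA target
#' sites with designed expectation scores, and a fabricated GO-style
#' annotation table covers the transcripts. Every decision is recorded in
#' the returned ledger.
#'
#' @param length_bp Genome length (must accommodate all features).
#' @param n_mirna_loci Number of novel miRNA hairpin loci to plant.
#' @param n_ncrna_loci Number of ncRNA loci (cycled over rRNA, tRNA, snRNA,
#'   snoRNA and GenBank-like/Rfam-like sources).
#' @param n_genes Number of three-exon gene models.
#' @param n_repeats Number of repeat intervals.
#' @param seed Integer RNG seed; the same seed reproduces the study
#'   bit-identically.
#' @param n_known_mirna Number of known miRNA loci (present in the
#'   mature/precursor references).
#' @param n_transcripts Number of synthetic transcripts.
#' @param n_bistranded How many novel loci additionally receive reads from
#'   the opposite genomic strand (default 2).
#' @param plant_conflict If `TRUE`, add an rRNA reference record containing
#'   the first known mature sequence, creating a deliberate annotation
#'   priority conflict.
#' @param ablation One of `NULL`, `"mature_in_loop"`, `"star_overhang"`,
#'   `"duplex_bulge"`, `"energy"`, `"support"`: additionally plant one locus
#'   engineered to violate exactly that candidate condition.
#' @param adapter3,adapter5 Adapters the simulated libraries will use (the
#'   generator keeps planted sequences free of adapter seeds and poly(A)
#'   signals so that the filter census stays exact).
#' @return A `smirna_ledger` object.
#' @export
generate_genome <- function(length_bp = 100000, n_mirna_loci = 10,
                            n_ncrna_loci = 12, n_genes = 6, n_repeats = 6,
                            seed = 1, n_known_mirna = 16, n_transcripts = 20,
                            n_bistranded = 2, plant_conflict = FALSE,
                            ablation = NULL,
                            adapter3 = SIM_ADAPTER3, adapter5 = SIM_ADAPTER5) {
  if (!is.null(ablation))
    ablation <- match.arg(ablation, c("mature_in_loop", "star_overhang",
                                      "duplex_bulge", "energy", "support"))
  with_seed(seed, generate_genome_impl(
    length_bp, n_mirna_loci, n_ncrna_loci, n_genes, n_repeats, seed,
    n_known_mirna, n_transcripts, n_bistranded, plant_conflict, ablation,
    adapter3, adapter5))
}

generate_genome_impl <- function(length_bp, n_mirna_loci, n_ncrna_loci,
                                 n_genes, n_repeats, seed, n_known_mirna,
                                 n_transcripts, n_bistranded, plant_conflict,
                                 ablation, adapter3, adapter5) {
  genome <- random_dna(length_bp)
  occ <- matrix(numeric(0), ncol = 2)
  ann <- list()
  planted <- list()
  nparams <- novel_params()

  clean_ok <- function(s) all(seq_is_clean(s, adapter3, adapter5))

  # --- known miRNA loci (mature/precursor references) ----------------------
  mature_ref <- character(0); precursor_ref <- character(0)
  mature_meta <- list()
  for (k in seq_len(n_known_mirna)) {
    h <- NULL
    for (try in 1:100) {
      cand <- make_hairpin(21, pad5 = 4, tail = 4)
      vars <- precursor_variants(cand)
      if (clean_ok(cand$mature) && all(seq_is_clean(vars, adapter3, adapter5))) {
        h <- cand; break
      }
    }
    if (is.null(h)) stop("could not construct clean known hairpin", call. = FALSE)
    pos <- place_feature(occ, nchar(h$precursor), length_bp, category = "known_miRNA")
    genome <- plant_seq(genome, pos, h$precursor)
    occ <- rbind(occ, c(pos, pos + nchar(h$precursor)))
    mid <- sprintf("kmir_%02d", k); pid <- paste0(mid, "_pre")
    mature_ref[mid] <- h$mature; precursor_ref[pid] <- h$precursor
    mature_meta[[k]] <- data.frame(mature_id = mid, precursor_id = pid,
                                   stringsAsFactors = FALSE)
    ann[[length(ann) + 1]] <- data.frame(
      contig = "chr1", start = pos, end = pos + nchar(h$precursor),
      strand = "+", category = "miRNA", id = mid, stringsAsFactors = FALSE)
    planted[[length(planted) + 1]] <- data.frame(
      locus_id = mid, known = TRUE, contig = "chr1",
      start = pos, end = pos + nchar(h$precursor), strand = "+",
      mature_seq = h$mature, star_seq = NA_character_, arm = "5p",
      mature_gstart = pos + h$mature_off,
      mature_gend = pos + h$mature_off + h$mature_len,
      mature_off = h$mature_off, precursor_seq = h$precursor,
      ablation = NA_character_, bistranded = FALSE, stringsAsFactors = FALSE)
  }

  # --- novel miRNA loci, verified through the discovery module -------------
  for (k in seq_len(n_mirna_loci)) {
    ok <- FALSE
    for (try in 1:60) {
      h <- make_hairpin(21, pad5 = 0, tail = 2)
      star_expect <- paste0(revcomp(substr(h$mature, 1, 19)),
                            substr(h$precursor, nchar(h$precursor) - 1,
                                   nchar(h$precursor)))
      if (!clean_ok(h$mature) || !clean_ok(star_expect)) next
      strand <- if (k %% 3 == 0) "-" else "+"
      pos <- place_feature(occ, nchar(h$precursor), length_bp, margin = 170,
                           category = "novel_miRNA")
      gseq <- plant_seq(genome, pos,
                        if (strand == "+") h$precursor else revcomp(h$precursor))
      plen <- nchar(h$precursor)
      mg <- if (strand == "+") c(pos + h$mature_off, pos + h$mature_off + 21)
            else c(pos + plen - h$mature_off - 21, pos + plen - h$mature_off)
      ev <- verify_planted(gseq, mg[1], mg[2], strand, params = nparams)
      if (!all(struct_flags(ev))) next
      if (!clean_ok(ev$star_seq)) next
      bistr <- k <= n_bistranded
      if (bistr) {
        ev2 <- verify_planted(gseq, mg[1], mg[2],
                              if (strand == "+") "-" else "+", params = nparams)
        if (!all(struct_flags(ev2))) next
      }
      genome <- gseq
      occ <- rbind(occ, c(pos, pos + plen))
      lid <- sprintf("nmir_%02d", k)
      planted[[length(planted) + 1]] <- data.frame(
        locus_id = lid, known = FALSE, contig = "chr1",
        start = pos, end = pos + plen, strand = strand,
        mature_seq = h$mature, star_seq = ev$star_seq, arm = "5p",
        mature_gstart = mg[1], mature_gend = mg[2],
        mature_off = h$mature_off, precursor_seq = h$precursor,
        ablation = NA_character_, bistranded = bistr, stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not verify a planted novel hairpin locus", call. = FALSE)
  }

  # --- ablation locus ------------------------------------------------------
  if (!is.null(ablation)) {
    target_flag <- c(mature_in_loop = "arm_placement",
                     star_overhang = "star_duplex_geometry",
                     duplex_bulge = "loop_bulge_ok",
                     energy = "energy_ok",
                     support = NA)[[ablation]]
    ok <- FALSE
    for (try in 1:2000) {
      h <- switch(ablation,
        mature_in_loop = make_hairpin_mature_in_loop(),
        star_overhang = make_hairpin_star_overhang(),
        duplex_bulge = make_hairpin_bulge(),
        energy = make_hairpin_energy(),
        support = make_hairpin(21, pad5 = 0, tail = 2))
      if (!clean_ok(h$mature)) next
      island <- if (is.null(h$island)) 0L else h$island
      plant <- paste0(strrep("A", island), h$precursor, strrep("A", island))
      pos <- place_feature(occ, nchar(plant), length_bp, margin = 170,
                           category = paste0("ablation_", ablation))
      gseq <- plant_seq(genome, pos, plant)
      mg <- c(pos + island + h$mature_off,
              pos + island + h$mature_off + h$mature_len)
      ev <- verify_planted(gseq, mg[1], mg[2], "+", params = nparams)
      fl <- struct_flags(ev)
      want <- switch(ablation,
        support = all(fl),
        # the -17 window cap cannot leave the other flags intact (see
        # make_hairpin_energy); require the energy flag down and the exact
        # designed window energy
        energy = !fl[["energy_ok"]] && ev$mfe == -17,
        !fl[[target_flag]] && all(fl[setdiff(names(fl), target_flag)]))
      if (!want) next
      if (!is.na(ev$star_seq) && !clean_ok(ev$star_seq)) next
      # the tag must map uniquely, or a mirror-strand candidate at the
      # palindromic stem could resurrect the locus (full-stem tags always
      # map both strands, so the support fixture is exempt -- its support
      # floor blocks both orientations)
      if (ablation != "support" &&
          nrow(map_exact(h$mature, c(chr1 = gseq))) != 1) next
      genome <- gseq
      occ <- rbind(occ, c(pos, pos + nchar(plant)))
      planted[[length(planted) + 1]] <- data.frame(
        locus_id = paste0("ablat_", ablation), known = FALSE, contig = "chr1",
        start = pos + island, end = pos + island + nchar(h$precursor),
        strand = "+",
        mature_seq = h$mature, star_seq = ev$star_seq, arm = "5p",
        mature_gstart = mg[1], mature_gend = mg[2],
        mature_off = h$mature_off, precursor_seq = h$precursor,
        ablation = ablation, bistranded = FALSE, stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not construct the '", ablation, "' ablation locus",
                  call. = FALSE)
  }

  # --- ncRNA loci ----------------------------------------------------------
  nc_cats <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA"), length.out = n_ncrna_loci)
  nc_len <- c(rRNA = 300, tRNA = 80, snRNA = 150, snoRNA = 120)
  nc_src <- rep(c("genbank_like", "rfam_like"), length.out = n_ncrna_loci)
  ncrna <- character(0); nc_meta <- list()
  for (k in seq_len(n_ncrna_loci)) {
    cat <- nc_cats[k]
    s <- draw_clean(function() random_dna(nc_len[[cat]]), cat)
    pos <- place_feature(occ, nchar(s), length_bp, category = cat)
    genome <- plant_seq(genome, pos, s)
    occ <- rbind(occ, c(pos, pos + nchar(s)))
    rid <- sprintf("%s_%s_%02d", tolower(cat), substr(nc_src[k], 1, 2), k)
    ncrna[rid] <- s
    nc_meta[[k]] <- data.frame(id = rid, category = cat, source = nc_src[k],
                               stringsAsFactors = FALSE)
    ann[[length(ann) + 1]] <- data.frame(
      contig = "chr1", start = pos, end = pos + nchar(s), strand = "+",
      category = cat, id = rid, stringsAsFactors = FALSE)
  }

  # --- repeats -------------------------------------------------------------
  for (k in seq_len(n_repeats)) {
    s <- draw_clean(function() random_dna(sample(200:350, 1)), "repeat")
    pos <- place_feature(occ, nchar(s), length_bp, category = "repeat")
    genome <- plant_seq(genome, pos, s)
    occ <- rbind(occ, c(pos, pos + nchar(s)))
    ann[[length(ann) + 1]] <- data.frame(
      contig = "chr1", start = pos, end = pos + nchar(s), strand = "+",
      category = "repeat", id = sprintf("rep_%02d", k), stringsAsFactors = FALSE)
  }

  # --- gene models (three exons, two introns) ------------------------------
  for (k in seq_len(n_genes)) {
    ex <- c(200, 180, 160); intr <- c(150, 140)
    glen <- sum(ex) + sum(intr)
    s <- draw_clean(function() random_dna(glen), "gene")
    pos <- place_feature(occ, glen, length_bp, category = "gene")
    genome <- plant_seq(genome, pos, s)
    occ <- rbind(occ, c(pos, pos + glen))
    strand <- if (k %% 2 == 0) "-" else "+"
    gid <- sprintf("gene_%02d", k)
    off <- 0
    parts <- c("exon", "intron", "exon", "intron", "exon")
    lens <- c(ex[1], intr[1], ex[2], intr[2], ex[3])
    for (p in seq_along(parts)) {
      ann[[length(ann) + 1]] <- data.frame(
        contig = "chr1", start = pos + off, end = pos + off + lens[p],
        strand = strand, category = parts[p],
        id = sprintf("%s_%s%d", gid, parts[p], p), stringsAsFactors = FALSE)
      off <- off + lens[p]
    }
  }

  # --- deliberate priority conflict ----------------------------------------
  if (plant_conflict && n_known_mirna > 0) {
    pre1 <- precursor_ref[["kmir_01_pre"]]
    ncrna["rrna_conflict"] <- pre1
    nc_meta[[length(nc_meta) + 1]] <- data.frame(
      id = "rrna_conflict", category = "rRNA", source = "genbank_like",
      stringsAsFactors = FALSE)
  }

  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(locus_id = character(0), known = logical(0),
               contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), mature_seq = character(0),
               star_seq = character(0), arm = character(0),
               mature_gstart = integer(0), mature_gend = integer(0),
               mature_off = integer(0), precursor_seq = character(0),
               ablation = character(0), bistranded = logical(0))
  fold_changes <- default_fold_changes(planted)
  expression <- default_expression_means(planted)

  # --- transcripts with planted target sites -------------------------------
  tg <- plant_targets(planted, n_transcripts, adapter3, adapter5)

  ann_df <- if (length(ann)) do.call(rbind, ann) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), category = character(0),
               id = character(0))
  ledger <- structure(list(
    genome = c(chr1 = genome),
    annotations = ann_df,
    occupied = occ,
    reference = list(genome = c(chr1 = genome),
                     annotations = ann_df[
                       ann_df$category %in%
                         c("repeat", "exon", "intron"), , drop = FALSE],
                     ncrna = ncrna,
                     ncrna_meta = do.call(rbind, nc_meta),
                     mature = mature_ref, precursor = precursor_ref,
                     mature_meta = do.call(rbind, mature_meta)),
    planted_mirnas = planted,
    planted_fold_changes = fold_changes,
    expression_means = expression,
    planted_targets = tg$targets,
    transcripts = tg$transcripts,
    go_annotation = tg$go,
    adapter3 = adapter3, adapter5 = adapter5,
    rng_seed = seed), class = "smirna_ledger")
  ledger
}

# All isomiR variant sequences a known locus can emit (end shifts drawn from
# the precursor context).
precursor_variants <- function(h, shifts = isomir_shifts()) {
  vapply(shifts, function(sh) {
    s <- h$mature_off + 1 + sh[1]
    e <- h$mature_off + h$mature_len + sh[2]
    substr(h$precursor, s, e)
  }, character(1))
}

# IsomiR end-shift classes (d5, d3) and their emission probabilities; the
# annotated mature dominates, single-end +/-1-2 nt shifts make up the rest.
isomir_shifts <- function() {
  list(c(0L, 0L), c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
       c(0L, 2L), c(-2L, 0L))
}
isomir_probs <- function() c(0.70, 0.08, 0.07, 0.05, 0.05, 0.03, 0.02)

# Study-design fold multipliers: four known loci carry the
# tolerant-down/susceptible-up contrast motif in leaf (8-fold each way, so
# the motif survives the compositional shift of TPM normalisation with
# margin); three are drought-induced 8x everywhere; one is repressed 8x
# everywhere.
default_fold_changes <- function(planted) {
  known <- planted$locus_id[planted$known]
  rows <- list()
  addrow <- function(l, v, t, f) data.frame(locus_id = l, variety = v,
                                            tissue = t, fold = f,
                                            stringsAsFactors = FALSE)
  if (!length(known))
    return(data.frame(locus_id = character(0), variety = character(0),
                      tissue = character(0), fold = numeric(0)))
  for (l in known[seq_len(min(4, length(known)))]) {
    rows[[length(rows) + 1]] <- addrow(l, "tolerant_A", "leaf", 0.125)
    rows[[length(rows) + 1]] <- addrow(l, "tolerant_B", "leaf", 0.125)
    rows[[length(rows) + 1]] <- addrow(l, "susceptible", "leaf", 8.0)
  }
  for (l in known[seq_len(min(7, length(known)))][-seq_len(4)])
    for (v in c("tolerant_A", "tolerant_B", "susceptible"))
      for (t in c("leaf", "stem"))
        rows[[length(rows) + 1]] <- addrow(l, v, t, 8.0)
  if (length(known) >= 8)
    for (v in c("tolerant_A", "tolerant_B", "susceptible"))
      for (t in c("leaf", "stem"))
        rows[[length(rows) + 1]] <- addrow(known[8], v, t, 0.125)
  do.call(rbind, rows)
}

# Baseline expected counts per locus at a 50k-read library, spanning the
# high / moderate / low TPM bands; stored as fractions of depth so the
# study composition is depth-invariant.
default_expression_means <- function(planted) {
  ids <- planted$locus_id
  mean <- numeric(length(ids))
  names(mean) <- ids
  known <- planted$known
  kn <- ids[known]
  base <- c(150, 150, 150, 150, 100, 100, 100, 400, 8000, 1500,
            200, 120, 60, 50, 2, 1)
  mean[kn] <- rep(base, length.out = length(kn))
  nov <- ids[!known & is.na(planted$ablation)]
  mean[nov] <- 40
  abl <- ids[!is.na(planted$ablation)]
  mean[abl] <- ifelse(planted$ablation[!is.na(planted$ablation)] == "support", 4, 30)
  mean / 50000
}

#' @export
print.smirna_ledger <- function(x, ...) {
  p <- x$planted_mirnas
  cat("Synthetic small RNA study ledger (seed ", x$rng_seed, ")\n", sep = "")
  cat("  genome:", nchar(x$genome[[1]]), "bp;",
      sum(p$known), "known and", sum(!p$known & is.na(p$ablation)),
      "novel miRNA loci planted\n")
  if (any(!is.na(p$ablation)))
    cat("  ablation locus:", p$ablation[!is.na(p$ablation)], "\n")
  cat("  ", NROW(x$reference$ncrna_meta), "ncRNA references;",
      length(x$transcripts), "transcripts;",
      NROW(x$planted_targets), "planted target sites\n")
  invisible(x)
}
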