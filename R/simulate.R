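#' Library specifications for the synthetic study
#'
#' The study design: 3 varieties (two drought-tolerant, one susceptible) x
#' 2 tissues x 2 conditions = 12 small RNA libraries.
#'
#' @param depth Target raw read depth per library (default 50000).
#' @param adapter3,adapter5 Adapter sequences.
#' @param junk_fractions Named fractions of raw reads per junk class.
#' @return Data frame of library specifications, one row per library.
#' @export
library_specs <- function(depth = 50000,
                          adapter3 = SIM_ADAPTER3, adapter5 = SIM_ADAPTER5,
                          junk_fractions = c(low_quality = 0.02,
                                             no_3prime_adapter = 0.03,
                                             no_insert = 0.02,
                                             has_5prime_adapter = 0.01,
                                             too_short_after_trim = 0.02,
                                             poly_A = 0.02)) {
  stopifnot(depth > 0, all(junk_fractions >= 0), all(junk_fractions <= 1),
            sum(junk_fractions) < 1)
  g <- expand.grid(condition = c("control", "drought"),
                   tissue = c("leaf", "stem"),
                   variety = c("tolerant_A", "tolerant_B", "susceptible"),
                   stringsAsFactors = FALSE)
  specs <- data.frame(
    library_id = paste(g$variety, g$tissue, g$condition, sep = "_"),
    variety = g$variety, tissue = g$tissue, condition = g$condition,
    depth = depth, adapter3 = adapter3, adapter5 = adapter5,
    stringsAsFactors = FALSE)
  attr(specs, "junk_fractions") <- junk_fractions
  specs
}

# Fractions of raw depth emitted for the non-miRNA clean classes.
CLEAN_FRACTIONS <- c(rRNA = 0.06, tRNA = 0.10, snRNA = 0.01, snoRNA = 0.01,
                     "repeat" = 0.06, exon_sense = 0.015, exon_antisense = 0.007,
                     intron_sense = 0.01, intron_antisense = 0.007,
                     background = 0.08)

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate the study's small RNA libraries
#'
#' Emits, for every library of the design: known-miRNA reads (the annotated
#' mature plus +/-1-2 nt end-shift isomiRs drawn from the precursor context),
#' novel-locus mature and star reads, ncRNA degradation fragments,
#' repeat/exon/intron fragments, unannotated background tags, and all six
#' junk classes, each read carrying the 3' adapter and padded to 50 nt.
#' Counts for miRNA loci are negative-binomial around the planted expression
#' means scaled by the planted fold multipliers (Poisson when
#' `dispersion = 0`); junk and fragment class totals are binomial draws of
#' their configured fractions. The returned census records the exact emitted
#' composition and is the oracle for the preprocessing filter counts.
#'
#' @param ledger A [generate_genome()] ledger.
#' @param specs Library specifications from [library_specs()].
#' @param seed RNG seed.
#' @param dispersion Negative-binomial dispersion of miRNA counts
#'   (default 0.01; 0 gives Poisson).
#' @param star_mean Mean star-read count per novel locus per 50k-read
#'   library (scaled with depth).
#' @return A `smirna_study`: list with `libraries` (named list of read data
#'   frames), `census` (per-library filter-class counts), `category_census`
#'   (per-library clean composition by annotation category), `mirna_counts`
#'   (true per-locus per-library emitted totals) and `specs`.
#' @export
simulate_libraries <- function(ledger, specs = library_specs(), seed = 1,
                               dispersion = 0.01, star_mean = 4) {
  stopifnot(is(ledger, "smirna_ledger"))
  fc <- ledger$planted_fold_changes
  need <- unique(fc[, c("variety", "tissue")])
  for (i in seq_len(nrow(need))) {
    sel <- specs$variety == need$variety[i] & specs$tissue == need$tissue[i]
    if (!all(c("control", "drought") %in% specs$condition[sel]))
      stop("planted fold change for (", need$variety[i], ", ", need$tissue[i],
           ") lacks a control/drought library pair", call. = FALSE)
  }
  with_seed(seed, simulate_libraries_impl(ledger, specs, dispersion, star_mean))
}

simulate_libraries_impl <- function(ledger, specs, dispersion, star_mean) {
  junk_fracs <- attr(specs, "junk_fractions")
  p <- preprocess_params()
  planted <- ledger$planted_mirnas
  means <- ledger$expression_means
  fc <- ledger$planted_fold_changes
  genome <- ledger$genome[[1]]
  ann <- ledger$annotations

  # partition background positions across libraries so no background tag
  # recurs between libraries
  bg_pool <- background_positions(ledger, n = 2000 * nrow(specs),
                                  nlib = nrow(specs))

  libraries <- list(); census <- list(); catcensus <- list(); truth <- list()
  for (li in seq_len(nrow(specs))) {
    sp <- specs[li, ]
    full3 <- paste0(sp$adapter3, SIM_ADAPTER3_TAIL)
    inserts <- character(0); counts <- integer(0); cats <- character(0)

    emit <- function(seqs, n, category) {
      if (length(seqs) == 0 || sum(n) == 0) return()
      keep <- n > 0
      inserts <<- c(inserts, seqs[keep])
      counts <<- c(counts, as.integer(n[keep]))
      cats <<- c(cats, rep(category, sum(keep)))
    }

    # --- miRNA loci ---
    for (k in seq_len(nrow(planted))) {
      loc <- planted[k, ]
      mu <- means[[loc$locus_id]]
      f <- 1
      if (sp$condition == "drought") {
        row <- fc[fc$locus_id == loc$locus_id & fc$variety == sp$variety &
                    fc$tissue == sp$tissue, ]
        if (nrow(row)) f <- row$fold[1]
      }
      if (!is.na(loc$ablation) && loc$ablation == "support") {
        # deterministic: 2 reads in each of the first two libraries
        total <- if (li <= 2) 2L else 0L
        emit(loc$mature_seq, total, "unannotated")
        truth[[length(truth) + 1]] <- data.frame(
          locus_id = loc$locus_id, library_id = sp$library_id, count = total)
        next
      }
      total <- nb_draw(1, mu * f * sp$depth, dispersion)
      truth[[length(truth) + 1]] <- data.frame(
        locus_id = loc$locus_id, library_id = sp$library_id, count = total)
      if (loc$known) {
        h <- list(precursor = loc$precursor_seq, mature_off = loc$mature_off,
                  mature_len = nchar(loc$mature_seq))
        vars <- precursor_variants(h)
        split <- as.integer(rmultinom(1, total, isomir_probs()))
        emit(vars, split, "known_miRNA")
      } else {
        emit(loc$mature_seq, total, "unannotated")
        if (is.na(loc$ablation)) {
          emit(loc$star_seq, nb_draw(1, star_mean * sp$depth / 50000, dispersion),
               "unannotated")
          if (loc$bistranded)
            emit(revcomp(loc$mature_seq),
                 nb_draw(1, 8 * sp$depth / 50000, dispersion), "unannotated")
        }
      }
    }

    # --- ncRNA / repeat / exon / intron fragments ---
    for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
      tot <- rbinom(1, sp$depth, CLEAN_FRACTIONS[[cls]])
      frs <- class_fragments(ledger$reference$ncrna,
                             ledger$reference$ncrna_meta, cls, tot,
                             ledger$adapter3, ledger$adapter5)
      emit(frs$seq, frs$n, cls)
    }
    for (cls in c("repeat", "exon_sense", "exon_antisense",
                  "intron_sense", "intron_antisense")) {
      feat <- sub("_(sense|antisense)$", "", cls)
      anti <- grepl("antisense", cls)
      tot <- rbinom(1, sp$depth, CLEAN_FRACTIONS[[cls]])
      frs <- interval_fragments(genome, ann[ann$category == feat, , drop = FALSE],
                                tot, anti, ledger$adapter3, ledger$adapter5)
      emit(frs$seq, frs$n, cls)
    }

    # --- unannotated background ---
    tot <- rbinom(1, sp$depth, CLEAN_FRACTIONS[["background"]])
    bg <- bg_pool[[li]]
    nuniq <- min(length(bg$pos), max(1, ceiling(tot / 2)))
    if (tot > 0 && nuniq > 0) {
      seqs <- substr(rep(genome, nuniq), bg$pos[seq_len(nuniq)] + 1,
                     bg$pos[seq_len(nuniq)] + bg$len[seq_len(nuniq)])
      n <- as.integer(rmultinom(1, tot, rep(1, nuniq)))
      emit(seqs, pmin(n, 3L), "unannotated")
    }

    # --- junk classes ---
    junk <- junk_reads(sp, junk_fracs, full3, p)

    # assemble
    clean_reads <- data.frame(
      sequence = substr(paste0(rep(inserts, counts), full3), 1, 50),
      quality = strrep("I", 50), stringsAsFactors = FALSE)
    reads <- rbind(clean_reads, junk$reads)
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    rownames(reads) <- NULL
    libraries[[sp$library_id]] <- reads

    census[[length(census) + 1]] <- data.frame(
      library_id = sp$library_id,
      class = c(FILTER_CLASSES, "clean", "raw"),
      count = c(junk$counts[FILTER_CLASSES], sum(counts),
                sum(junk$counts) + sum(counts)),
      row.names = NULL, stringsAsFactors = FALSE)
    cc <- vapply(split(counts, cats), sum, numeric(1))
    cu <- vapply(split(inserts, cats), function(s) length(unique(s)), integer(1))
    catcensus[[length(catcensus) + 1]] <- data.frame(
      library_id = sp$library_id, category = names(cc),
      reads = as.integer(cc), unique = as.integer(cu[names(cc)]),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(libraries = libraries,
                 census = do.call(rbind, census),
                 category_census = do.call(rbind, catcensus),
                 mirna_counts = do.call(rbind, truth),
                 specs = specs), class = "smirna_study")
}

# Junk read constructors; every read is verified against the classifier
# predicates so the census stays an exact oracle.
junk_reads <- function(sp, junk_fracs, full3, p) {
  seed3 <- substr(sp$adapter3, 1, p$adapter_seed_len)
  counts <- stats::setNames(integer(length(FILTER_CLASSES)), FILTER_CLASSES)
  out <- list()
  addreads <- function(seqs, qual) {
    if (length(seqs))
      out[[length(out) + 1]] <<- data.frame(sequence = seqs, quality = qual,
                                            stringsAsFactors = FALSE)
  }
  nn <- vapply(FILTER_CLASSES, function(cl) rbinom(1, sp$depth, junk_fracs[[cl]]),
               integer(1))
  counts[] <- nn

  mk_insert <- function(len) {
    repeat {
      s <- random_dna(len)
      if (all(seq_is_clean(s, sp$adapter3, sp$adapter5, p))) return(s)
    }
  }
  # low quality: ordinary reads with a failing quality string
  addreads(vapply(seq_len(nn[["low_quality"]]), function(i)
    substr(paste0(mk_insert(21), full3), 1, 50), character(1)), strrep("#", 50))
  # no 3' adapter: random 50-mers free of the adapter seed
  addreads(vapply(seq_len(nn[["no_3prime_adapter"]]), function(i) {
    repeat {
      s <- random_dna(50)
      if (!grepl(seed3, s, fixed = TRUE)) return(s)
    }
  }, character(1)), strrep("I", 50))
  # no insert: adapter dimer
  addreads(rep(substr(full3, 1, 50), nn[["no_insert"]]), strrep("I", 50))
  # 5' adapter contamination
  addreads(vapply(seq_len(nn[["has_5prime_adapter"]]), function(i)
    substr(paste0(random_dna(4), sp$adapter5, full3), 1, 50), character(1)),
    strrep("I", 50))
  # insert shorter than 18 nt after trimming
  addreads(vapply(seq_len(nn[["too_short_after_trim"]]), function(i)
    substr(paste0(mk_insert(sample(10:17, 1)), full3), 1, 50), character(1)),
    strrep("I", 50))
  # poly(A) inserts
  addreads(vapply(seq_len(nn[["poly_A"]]), function(i)
    substr(paste0(strrep("A", sample(20:26, 1)), full3), 1, 50), character(1)),
    strrep("I", 50))
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(sequence = character(0), quality = character(0))
  list(reads = reads, counts = counts)
}

# ncRNA degradation fragments: random 18-30 nt substrings of the reference
# sequences of one class.
class_fragments <- function(ncrna, nc_meta, cls, total, adapter3, adapter5) {
  ids <- nc_meta$id[nc_meta$category == cls & nc_meta$id %in% names(ncrna)]
  ids <- setdiff(ids, "rrna_conflict")
  if (!length(ids) || total == 0) return(list(seq = character(0), n = integer(0)))
  nuniq <- max(1, min(total, ceiling(total / 8)))
  seqs <- character(nuniq)
  for (i in seq_len(nuniq)) {
    ref <- ncrna[[ids[((i - 1) %% length(ids)) + 1]]]
    seqs[i] <- draw_clean(function() {
      len <- sample(18:30, 1)
      s <- sample.int(nchar(ref) - len, 1)
      substr(ref, s, s + len - 1)
    }, cls)
  }
  n <- as.integer(rmultinom(1, total, rep(1, nuniq)))
  list(seq = seqs, n = n)
}

# Fragments from annotated genomic intervals (repeat/exon/intron), sense or
# antisense relative to the feature strand.
interval_fragments <- function(genome, feats, total, antisense,
                               adapter3, adapter5) {
  if (nrow(feats) == 0 || total == 0)
    return(list(seq = character(0), n = integer(0)))
  nuniq <- max(1, min(total, ceiling(total / 8)))
  seqs <- character(nuniq)
  for (i in seq_len(nuniq)) {
    f <- feats[((i - 1) %% nrow(feats)) + 1, ]
    seqs[i] <- draw_clean(function() {
      len <- sample(18:30, 1)
      s <- f$start + sample.int(f$end - f$start - len, 1)
      frag <- substr(genome, s + 1, s + len)
      sense_frag <- if (f$strand == "+") frag else revcomp(frag)
      if (antisense) revcomp(sense_frag) else sense_frag
    }, "interval fragment")
  }
  n <- as.integer(rmultinom(1, total, rep(1, nuniq)))
  list(seq = seqs, n = n)
}

# Background tag positions outside every planted feature, partitioned across
# libraries so no background tag recurs between libraries.
background_positions <- function(ledger, n, nlib = 12) {
  glen <- nchar(ledger$genome[[1]])
  occ <- ledger$occupied
  pos <- integer(0); len <- integer(0)
  while (length(pos) < n) {
    cand <- sample.int(glen - 60, n) + 10
    l <- sample(18:30, n, replace = TRUE)
    bad <- vapply(seq_along(cand), function(i)
      any(cand[i] < occ[, 2] + 2 & occ[, 1] - 2 < cand[i] + l[i]), logical(1))
    seqs <- substr(rep(ledger$genome[[1]], n), cand + 1, cand + l)
    bad <- bad | !seq_is_clean(seqs, ledger$adapter3, ledger$adapter5)
    pos <- c(pos, cand[!bad]); len <- c(len, l[!bad])
    keep <- !duplicated(pos)
    pos <- pos[keep]; len <- len[keep]
  }
  idx <- seq_len(n)
  split_idx <- split(idx, rep(seq_len(nlib), length.out = n))
  lapply(split_idx, function(ii) list(pos = pos[ii], len = len[ii]))
}

#' @export
print.smirna_study <- function(x, ...) {
  cat("Synthetic small RNA study:", length(x$libraries), "libraries\n")
  raw <- x$census[x$census$class == "raw", ]
  cat("  raw reads per library:", paste(range(raw$count), collapse = "-"), "\n")
  invisible(x)
}

#' Write the study's libraries and census to disk
#'
#' @param study A `smirna_study`.
#' @param dir Output directory (created if missing); one FASTQ per library
#'   plus `census.tsv`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lib in names(study$libraries))
    write_fastq(study$libraries[[lib]], file.path(dir, paste0(lib, ".fastq")))
  write_tsv(study$census, file.path(dir, "census.tsv"))
  invisible(dir)
}

#' Simulate degradome tags for the planted targets
#'
#' Degradome-confirmed targets receive tags whose 5' end sits at the
#' cleavage coordinate (opposite miRNA position 10); unconfirmed targets
#' receive tags offset +/-2 nt from it (which must never confirm), plus a
#' uniform background of random transcript fragments.
#'
#' @param ledger A [generate_genome()] ledger.
#' @param depth Background tag count (default 500).
#' @param tags_per_target Tag copies at each confirmed cleavage site.
#' @param seed RNG seed.
#' @return Data frame with `sequence` and `count` columns.
#' @export
simulate_degradome <- function(ledger, depth = 500, tags_per_target = 5,
                               seed = 1) {
  with_seed(seed, {
    tg <- ledger$planted_targets
    seqs <- character(0); cnt <- integer(0)
    for (i in seq_len(nrow(tg))) {
      tr <- ledger$transcripts[[tg$transcript_id[i]]]
      if (tg$confirmed[i]) {
        s <- substr(tr, tg$cleavage_pos[i] + 1, tg$cleavage_pos[i] + 20)
        seqs <- c(seqs, s); cnt <- c(cnt, tags_per_target)
      } else {
        for (off in c(-2L, 2L)) {
          pos <- tg$cleavage_pos[i] + off
          seqs <- c(seqs, substr(tr, pos + 1, pos + 20)); cnt <- c(cnt, 2L)
        }
      }
    }
    if (depth > 0) {
      for (i in seq_len(depth)) {
        tid <- sample(names(ledger$transcripts), 1)
        tr <- ledger$transcripts[[tid]]
        pos <- sample.int(nchar(tr) - 20, 1)
        # keep background off every planted cleavage coordinate
        if (any(tg$transcript_id == tid & tg$cleavage_pos == pos - 1)) next
        seqs <- c(seqs, substr(tr, pos, pos + 19)); cnt <- c(cnt, 1L)
      }
    }
    agg <- vapply(split(cnt, seqs), sum, numeric(1))
    data.frame(sequence = names(agg), count = as.integer(agg),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Simulate a qPCR Ct table
#'
#' Ct values follow `offset - log2(expression) + N(0, noise_sd)`; the
#' reference gene has constant expression across conditions, so with
#' `noise_sd = 0` the Livak method recovers the planted fold exactly.
#'
#' @param folds Named numeric vector of planted drought/control fold changes
#'   per gene, or a `smirna_ledger` (folds are then taken from the planted
#'   fold-change table for `variety`/`tissue`).
#' @param noise_sd Gaussian Ct noise (cycles), default 0.
#' @param n_rep Replicates per gene x condition (default 3).
#' @param seed RNG seed.
#' @param base_expr Control-condition expression of each target gene.
#' @param offset Ct at unit expression (default 30).
#' @param reference_id Reference gene id (default `"U6"`).
#' @param variety,tissue Design cell used when `folds` is a ledger.
#' @return Data frame with `gene_id`, `condition`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(folds, noise_sd = 0, n_rep = 3, seed = 1,
                              base_expr = 500, offset = 30,
                              reference_id = "U6",
                              variety = "tolerant_A", tissue = "leaf") {
  stopifnot(noise_sd >= 0)
  if (is(folds, "smirna_ledger")) {
    fc <- folds$planted_fold_changes
    fc <- fc[fc$variety == variety & fc$tissue == tissue, , drop = FALSE]
    folds <- stats::setNames(fc$fold, fc$locus_id)
  }
  with_seed(seed, {
    rows <- list()
    for (g in names(folds)) {
      for (cond in c("control", "drought")) {
        expr <- base_expr * if (cond == "drought") folds[[g]] else 1
        for (r in seq_len(n_rep))
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = g, condition = cond, replicate = r,
            ct = offset - log2(expr) + rnorm(1, 0, noise_sd),
            stringsAsFactors = FALSE)
      }
    }
    ref_expr <- 1000
    for (cond in c("control", "drought"))
      for (r in seq_len(n_rep))
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = reference_id, condition = cond, replicate = r,
          ct = offset - log2(ref_expr) + rnorm(1, 0, noise_sd),
          stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })
}
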