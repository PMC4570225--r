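test_that("the same seed reproduces the study bit-identically", {
  a <- generate_genome(length_bp = 30000, n_mirna_loci = 2, n_known_mirna = 2,
                       n_ncrna_loci = 4, n_genes = 1, n_repeats = 1, seed = 9)
  b <- generate_genome(length_bp = 30000, n_mirna_loci = 2, n_known_mirna = 2,
                       n_ncrna_loci = 4, n_genes = 1, n_repeats = 1, seed = 9)
  expect_identical(a$genome, b$genome)
  expect_identical(a$planted_mirnas, b$planted_mirnas)
  expect_identical(a$transcripts, b$transcripts)
  specs <- library_specs(depth = 2000)
  s1 <- simulate_libraries(a, specs, seed = 4)
  s2 <- simulate_libraries(b, specs, seed = 4)
  expect_identical(s1$libraries, s2$libraries)
  expect_identical(s1$census, s2$census)
  # a different seed changes the reads
  s3 <- simulate_libraries(a, specs, seed = 5)
  expect_false(identical(s1$libraries[[1]], s3$libraries[[1]]))
})

test_that("every planted novel hairpin re-folds to a passing candidate", {
  led <- small_ledger()
  pn <- led$planted_mirnas[!led$planted_mirnas$known &
                             is.na(led$planted_mirnas$ablation), ]
  for (i in seq_len(nrow(pn))) {
    ev <- smirna:::verify_planted(led$genome[[1]], pn$mature_gstart[i],
                                  pn$mature_gend[i], pn$strand[i])
    expect_true(all(smirna:::struct_flags(ev)), info = pn$locus_id[i])
    expect_equal(ev$star_seq, pn$star_seq[i], info = pn$locus_id[i])
  }
})

test_that("an empty miRNA request yields a valid genome with no planted loci", {
  led <- generate_genome(length_bp = 20000, n_mirna_loci = 0, n_known_mirna = 0,
                         n_ncrna_loci = 2, n_genes = 1, n_repeats = 1,
                         seed = 13)
  expect_equal(nrow(led$planted_mirnas), 0L)
  expect_equal(nrow(led$planted_fold_changes), 0L)
  expect_equal(nchar(led$genome[[1]]), 20000L)
  expect_gt(length(led$reference$ncrna), 0L)
})

test_that("an overcrowded genome fails with the offending category named", {
  expect_error(generate_genome(length_bp = 1200, n_mirna_loci = 0,
                               n_known_mirna = 0, n_ncrna_loci = 8,
                               n_genes = 0, n_repeats = 0, seed = 1),
               "placement failed")
})

test_that("census totals account for every emitted read", {
  study <- small_study()
  for (lib in unique(study$census$library_id)) {
    cen <- study$census[study$census$library_id == lib, ]
    raw <- cen$count[cen$class == "raw"]
    expect_equal(raw, sum(cen$count[!cen$class %in% c("raw")]) , info = lib)
    expect_equal(nrow(study$libraries[[lib]]), raw, info = lib)
  }
})

test_that("junk class counts follow the spec'd fractions binomially", {
  study <- small_study()
  fr <- attr(study$specs, "junk_fractions")
  for (cls in names(fr)) {
    cnt <- study$census$count[study$census$class == cls]
    expected <- fr[[cls]] * study$specs$depth[1]
    # 12 libraries: the mean should sit within 5 binomial SDs
    tol <- 5 * sqrt(expected * (1 - fr[[cls]])) / sqrt(12)
    expect_lt(abs(mean(cnt) - expected), tol + 1, label = cls)
  }
})

test_that("planted fold multipliers are recovered in the emitted counts", {
  led <- small_ledger()
  # accumulate drought/control count ratios for the 8x-induced loci over
  # several simulated studies
  fc <- led$planted_fold_changes
  induced <- unique(fc$locus_id[fc$fold == 8 & fc$tissue == "stem"])
  specs <- library_specs(depth = 8000)
  rat <- c()
  for (seed in 1:6) {
    st <- simulate_libraries(led, specs, seed = 100 + seed)
    tr <- st$mirna_counts
    tr <- merge(tr, st$specs[, c("library_id", "variety", "tissue", "condition")])
    for (l in induced) {
      d <- tr[tr$locus_id == l & tr$condition == "drought", ]
      c0 <- tr[tr$locus_id == l & tr$condition == "control", ]
      rat <- c(rat, sum(d$count) / sum(c0$count))
    }
  }
  expect_lt(abs(mean(rat) - 8), 0.8)
})

test_that("Poisson degeneration holds when dispersion is zero", {
  led <- small_ledger()
  specs <- library_specs(depth = 5000)
  st <- simulate_libraries(led, specs, seed = 7, dispersion = 0)
  tr <- merge(st$mirna_counts,
              st$specs[, c("library_id", "condition")])
  # fold-1 loci: control and drought counts share one Poisson mean, so the
  # standardised difference of the summed halves is small
  p <- led$planted_mirnas
  null_loci <- setdiff(p$locus_id[is.na(p$ablation)],
                       led$planted_fold_changes$locus_id)
  checked <- 0
  for (l in null_loci) {
    d <- sum(tr$count[tr$locus_id == l & tr$condition == "drought"])
    c0 <- sum(tr$count[tr$locus_id == l & tr$condition == "control"])
    if (d + c0 < 20) next
    z <- (d - c0) / sqrt(d + c0)
    expect_lt(abs(z), 5, label = paste("z for", l))
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("degradome tags sit at (or only off) the planted cleavage sites", {
  led <- small_ledger()
  deg <- simulate_degradome(led, depth = 100, seed = 3)
  tg <- led$planted_targets
  for (i in seq_len(nrow(tg))) {
    tr <- led$transcripts[[tg$transcript_id[i]]]
    at_cleavage <- substr(tr, tg$cleavage_pos[i] + 1, tg$cleavage_pos[i] + 20)
    if (tg$confirmed[i])
      expect_true(at_cleavage %in% deg$sequence, info = i)
    else
      expect_false(at_cleavage %in% deg$sequence, info = i)
  }
})

test_that("collapsed FASTA and GFF3 round trips preserve the data", {
  tags <- data.frame(sequence = c("ACGTGCCATGCAGTCCAGTCA", "TTGCATCGGATCAGGCACCAT"),
                     count = c(11L, 2L))
  path <- tempfile(fileext = ".fa")
  write_collapsed_fasta(tags, path)
  back <- read_collapsed_fasta(path)
  expect_equal(back$sequence, tags$sequence)
  expect_equal(back$count, tags$count)

  led <- small_ledger()
  ann <- led$annotations[led$annotations$category %in% c("exon", "intron"), ]
  gff <- tempfile(fileext = ".gff3")
  write_gff3(ann, gff)
  back <- read_gff3(gff)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$category, ann$category)
  expect_equal(back$strand, ann$strand)
})
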