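test_that("map_exact finds planted loci, minus-strand hits, and nothing else", {
  led <- small_ledger()
  p <- led$planted_mirnas[led$planted_mirnas$strand == "+" &
                            !led$planted_mirnas$known, ][1, ]
  hits <- map_exact(p$mature_seq, led$genome)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$start == p$mature_gstart & plus$end == p$mature_gend))

  # reverse complement of a genome substring maps to the minus strand
  sub <- substr(led$genome[[1]], 1001, 1025)
  rc <- smirna:::revcomp(sub)
  hits <- map_exact(rc, led$genome)
  expect_true(any(hits$strand == "-" & hits$start == 1000 & hits$end == 1025))

  # a 30-mer verified absent from the genome has zero hits
  set.seed(2)
  repeat {
    probe <- random_seq(30)
    absent <- !grepl(probe, led$genome[[1]], fixed = TRUE) &&
      !grepl(smirna:::revcomp(probe), led$genome[[1]], fixed = TRUE)
    if (absent) break
  }
  expect_equal(nrow(map_exact(probe, led$genome)), 0L)
})

test_that("known-miRNA matching enforces the 16 nt overlap boundary", {
  mature <- "ACGTGCCATGCAGTCCAGTCA"                     # 21 nt
  pre <- paste0("GGAC", mature, "TTCAGGCAAGCTTCGATGCAGGCAACT")
  meta <- data.frame(mature_id = "m1", precursor_id = "p1")
  mats <- c(m1 = mature); pres <- c(p1 = pre)

  # tag = mature: overlap 21 >= 16
  hit <- assign_known_mirna(mature, pres, mats, meta)
  expect_equal(hit$mature_id, "m1")
  expect_equal(hit$overlap, 21L)
  expect_equal(c(hit$offset5, hit$offset3), c(0L, 0L))

  # mature interval on precursor is [4, 25); engineer 16 vs 15 nt overlaps
  tag_ov16 <- substr(pre, 4 + 5 + 1, 4 + 5 + 21)   # starts 5 into mature
  expect_equal(nrow(assign_known_mirna(tag_ov16, pres, mats, meta)), 1L)
  tag_ov15 <- substr(pre, 4 + 6 + 1, 4 + 6 + 21)   # 15 nt overlap
  expect_equal(nrow(assign_known_mirna(tag_ov15, pres, mats, meta)), 0L)

  # +2 nt shifted isomiR with 19 nt overlap is counted toward the mature
  tag_shift <- substr(pre, 4 + 2 + 1, 4 + 2 + 21)
  hit <- assign_known_mirna(tag_shift, pres, mats, meta)
  expect_equal(hit$mature_id, "m1")
  expect_equal(hit$offset5, 2L)

  # a mature that is not on its precursor is a reference-consistency error
  expect_error(
    assign_known_mirna(mature, c(p1 = "ACGTACGTACGTACGTACGTACGTACGT"),
                       mats, meta),
    "reference inconsistency")
})

test_that("priority assigns one category per tag in the declared order", {
  led <- generate_genome(length_bp = 40000, n_mirna_loci = 2, n_known_mirna = 3,
                         n_ncrna_loci = 4, n_genes = 2, n_repeats = 2,
                         seed = 21, plant_conflict = TRUE)
  ref <- led$reference
  conflict_tag <- unname(ref$mature[["kmir_01"]])

  tags <- data.frame(sequence = conflict_tag, count = 1L, library_id = "L1")
  ann <- annotate_tags(tags, ref)
  expect_equal(ann$category, "rRNA")
  expect_equal(ann$source, "genbank_like")

  # removing the conflicting rRNA record reclassifies the tag as known miRNA
  ref2 <- ref
  keep <- ref2$ncrna_meta$id != "rrna_conflict"
  ref2$ncrna_meta <- ref2$ncrna_meta[keep, ]
  ref2$ncrna <- ref2$ncrna[setdiff(names(ref2$ncrna), "rrna_conflict")]
  ann2 <- annotate_tags(tags, ref2)
  expect_equal(ann2$category, "known_miRNA")
  expect_equal(ann2$mature_id, "kmir_01")

  # a tag matching only the opposite strand of an exon is exon_antisense
  ex <- ref$annotations[ref$annotations$category == "exon", ][1, ]
  frag <- substr(led$genome[[1]], ex$start + 10, ex$start + 33)
  if (ex$strand == "+") frag <- smirna:::revcomp(frag)
  ann3 <- annotate_tags(data.frame(sequence = frag, count = 1L,
                                   library_id = "L1"), ref)
  expect_equal(ann3$category, "exon_antisense")

  # a genome-mapped tag hitting no reference is unannotated
  occ <- led$occupied
  set.seed(4)
  repeat {
    pos <- sample(500:39000, 1)
    if (!any(pos < occ[, 2] & occ[, 1] < pos + 24)) break
  }
  free_tag <- substr(led$genome[[1]], pos + 1, pos + 24)
  ann4 <- annotate_tags(data.frame(sequence = free_tag, count = 1L,
                                   library_id = "L1"), ref)
  expect_equal(ann4$category, "unannotated")
})

test_that("annotation distribution equals the generator's composition census", {
  led <- small_ledger()
  study <- small_study()
  res <- small_results()
  for (lib in names(study$libraries)[c(2, 9)]) {
    got <- res$distribution[res$distribution$library_id == lib, ]
    want <- study$category_census[study$category_census$library_id == lib, ]
    m <- merge(got, want, by = "category", suffixes = c("_got", "_want"))
    expect_equal(nrow(m), nrow(want))
    expect_equal(m$reads_got, m$reads_want, info = lib)
    expect_equal(m$unique_got, m$unique_want, info = lib)
    # percentages sum to 100 and each read is counted exactly once
    expect_equal(sum(got$pct_reads), 100, tolerance = 1e-9)
    expect_equal(sum(got$reads), unname(res$library_totals[lib]))
  }
  # empty input gives zero rows, no division by zero
  expect_equal(nrow(distribution_report(res$assignments[0, ])), 0L)
})

test_that("deleting a higher-priority reference never shrinks lower categories", {
  res <- small_results()
  led <- small_ledger()
  lib <- names(res$filter_reports)[1]
  tags <- res$tags[res$tags$library_id == lib, ]
  full <- annotate_tags(tags, led$reference)
  ref2 <- led$reference
  drop <- ref2$ncrna_meta$category == "rRNA"
  ref2$ncrna <- ref2$ncrna[!names(ref2$ncrna) %in% ref2$ncrna_meta$id[drop]]
  ref2$ncrna_meta <- ref2$ncrna_meta[!drop, ]
  reduced <- annotate_tags(tags, ref2)
  for (cat in setdiff(unique(full$category), "rRNA")) {
    expect_gte(sum(reduced$count[reduced$category == cat]),
               sum(full$count[full$category == cat]))
  }
})

test_that("known-miRNA quantification sums variants and reports the dominant one", {
  mature <- "ACGTGCCATGCAGTCCAGTCA"
  pre <- paste0("GGAC", mature, "TTCAGGCAAGCTTCGATGCAGGCAACT")
  ref <- list(genome = c(chr1 = pre), annotations = NULL,
              ncrna = character(0), ncrna_meta = NULL,
              mature = c(m1 = mature), precursor = c(p1 = pre),
              mature_meta = data.frame(mature_id = "m1", precursor_id = "p1"))
  v1 <- mature
  v2 <- substr(pre, 5, 26)   # +1 at the 3' end
  v3 <- substr(pre, 6, 25)   # -1 at the 5' end
  tags <- data.frame(sequence = c(v1, v2, v3), count = c(50L, 30L, 20L),
                     library_id = "L1")
  ann <- annotate_tags(tags, ref)
  meta <- data.frame(library_id = "L1", variety = "v", tissue = "t",
                     condition = "control", clean_total = 1000)
  q <- quantify_known(ann, meta, ref)
  expect_equal(q$expression$raw_count, 100L)
  expect_equal(q$expression$dominant_variant, v1)
  expect_equal(q$expression$tpm, 1e5)
  expect_equal(sort(q$variants$count), c(20L, 30L, 50L))

  # absent mature: no record unless zero-fill requested
  tags2 <- data.frame(sequence = "TTTTGCATCGGATCAGGCACC", count = 5L,
                      library_id = "L1")
  ann2 <- annotate_tags(tags2, ref)
  expect_equal(nrow(quantify_known(ann2, meta, ref)$expression), 0L)
  zf <- quantify_known(ann2, meta, ref, zero_fill = TRUE)$expression
  expect_equal(zf$raw_count, 0L)

  # recovered counts track the planted means within sampling error
  study <- small_study()
  res <- small_results()
  truth <- study$mirna_counts
  led <- small_ledger()
  kn <- led$planted_mirnas$locus_id[led$planted_mirnas$known]
  for (lid in kn[1:3]) {
    mat_id <- lid   # known locus ids double as mature reference ids
    got <- res$expression[res$expression$mirna_id == mat_id, ]
    want <- truth[truth$locus_id == lid, ]
    m <- merge(got[, c("library_id", "raw_count")], want, by = "library_id")
    expect_equal(m$raw_count, m$count, info = lid)
  }
})

test_that("TPM conservation holds per library", {
  res <- small_results()
  for (lib in names(res$filter_reports)[c(3, 8)]) {
    e <- res$expression[res$expression$library_id == lib, ]
    expect_equal(sum(e$tpm),
                 1e6 * sum(e$raw_count) / res$library_totals[[lib]],
                 tolerance = 1e-9)
  }
})

test_that("expression classes follow the TPM bands with inclusive endpoints", {
  expect_equal(classify_expression(150000), "high")
  expect_equal(classify_expression(10001), "high")
  expect_equal(classify_expression(10000), "moderate")
  expect_equal(classify_expression(100), "moderate")
  expect_equal(classify_expression(99.9), "low")
  expect_equal(classify_expression(0), "low")
  expect_error(classify_expression(-1), "non-negative")
  # the planted high / moderate / low loci land in their bands
  res <- small_results()
  e <- res$expression
  expect_true(all(e$level[e$mirna_id == "kmir_09"] == "high"))
  expect_true(all(e$level[e$mirna_id == "kmir_16" &
                            e$condition == "control"] == "low"))
})
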