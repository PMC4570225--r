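# A clean synthetic hairpin evaluated directly: mature + loop + revcomp +
# 2 nt tail, embedded mid-window.
perfect_draft <- function(mature = "GCGGCCGGGCAGCCCGGCCGC",
                          loop = "AAAAAAAAAAA", tail = "AA", pad = 30) {
  # G/C-only stem inside poly(A) context: the planted stem is the unique
  # optimal structure, so the evaluation is deterministic
  pre <- paste0(mature, loop, smirna:::revcomp(mature), tail)
  win <- paste0(strrep("A", pad), pre, strrep("A", pad))
  f <- fold_rna(win)
  list(window = win, structure = f$structure, mfe = f$mfe,
       mature_start = pad + 1L, mature_end = pad + nchar(mature),
       register = "5p", contig = "chr1", window_start = 0L,
       window_end = nchar(win), strand = "+")
}

test_that("a perfect stem passes every structural condition with 2 nt overhangs", {
  d <- evaluate_conditions(perfect_draft(), support = 5)
  expect_true(all(d$condition_flags))
  # star = partner of the mature with both 2 nt 3' overhangs
  expect_equal(d$star_end - d$star_start + 1L, 21L)
  # star minus its 2 nt 3' overhang pairs mature positions 1-19
  expect_equal(substr(d$window, d$star_start, d$star_end - 2),
               smirna:::revcomp(substr(d$window, d$mature_start,
                                       d$mature_start + 18)))
  expect_lte(d$duplex_energy, -18)
})

test_that("a mature running into the terminal loop fails arm placement only", {
  base <- perfect_draft()
  d <- base
  d$mature_start <- base$mature_start + 2L
  d$mature_end <- base$mature_end + 2L   # 2 nt into the loop
  d <- evaluate_conditions(d, support = 5)
  expect_false(d$condition_flags[["arm_placement"]])
  expect_true(d$condition_flags[["star_duplex_geometry"]])
  expect_true(d$condition_flags[["loop_bulge_ok"]])
  expect_true(d$condition_flags[["energy_ok"]])
})

test_that("insufficient support fails only the support condition", {
  d <- evaluate_conditions(perfect_draft(), support = 4)
  expect_false(d$condition_flags[["support_ok"]])
  expect_true(all(d$condition_flags[c("arm_placement", "star_duplex_geometry",
                                      "loop_bulge_ok", "energy_ok")]))
  expect_true(evaluate_conditions(perfect_draft(),
                                  support = 5)$condition_flags[["support_ok"]])
})

test_that("star detection obeys the terminal tolerance with no internal mismatch", {
  d <- evaluate_conditions(perfect_draft(), support = 5)
  star <- substr(d$window, d$star_start, d$star_end)
  tags <- function(s) data.frame(sequence = s, count = 1L, library_id = "L1")
  expect_true(detect_star(d, tags(star)))
  # 3 nt shift at one end still qualifies
  shifted <- substr(d$window, d$star_start + 3, d$star_end + 3)
  expect_true(detect_star(d, tags(shifted)))
  # 4 nt shift does not
  shifted4 <- substr(d$window, d$star_start + 4, d$star_end + 4)
  expect_false(detect_star(d, tags(shifted4)))
  # one internal mismatch disqualifies
  mid <- nchar(star) %/% 2
  bad <- star
  substr(bad, mid, mid) <- setdiff(c("A", "C", "G", "T"),
                                   substr(star, mid, mid))[1]
  expect_false(detect_star(d, tags(bad)))
})

test_that("candidate expression sums qualifying tags only", {
  d <- evaluate_conditions(perfect_draft(), support = 5)
  exact <- substr(d$window, d$mature_start, d$mature_end)
  shifted <- substr(d$window, d$mature_start + 2, d$mature_end + 2)
  mism <- exact
  substr(mism, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(exact, 10, 10))[1]
  tags <- data.frame(sequence = c(exact, shifted, mism),
                     count = c(40L, 10L, 5L),
                     library_id = "L1")
  counts <- quantify_candidate(d, tags)
  expect_equal(unname(counts[["L1"]]), 50)
  # no qualifying tags -> zero
  far <- data.frame(sequence = random_seq(21), count = 9L, library_id = "L1")
  expect_equal(length(quantify_candidate(d, far)), 0L)
})

test_that("excision truncates windows at contig edges without crashing", {
  led <- small_ledger()
  hit <- list(contig = "chr1", start = 3L, end = 24L, strand = "+")
  drafts <- excise_and_fold(hit, led$genome)
  expect_true(all(vapply(drafts, function(d) d$window_start >= 0, logical(1))))
  expect_true(all(vapply(drafts, function(d)
    nchar(d$window) == d$window_end - d$window_start, logical(1))))
})

test_that("noise-free discovery recovers exactly the planted loci", {
  res <- small_results()
  led <- small_ledger()
  pn <- led$planted_mirnas[!led$planted_mirnas$known &
                             is.na(led$planted_mirnas$ablation), ]
  cands <- res$novel$candidates
  novel_mat <- cands$mature_seq[cands$id %in% res$novel$novel]
  expect_setequal(novel_mat, pn$mature_seq)
  # the study carries background and fragment noise, so chance hairpins may
  # enter the star-ungated putative set; every planted locus must be there
  expect_true(all(pn$mature_seq %in%
                    cands$mature_seq[cands$id %in% res$novel$putative]))
  # bistranded flags match the planted opposite-strand loci
  expect_setequal(cands$mature_seq[cands$bistranded & cands$pass_all],
                  pn$mature_seq[pn$bistranded])
  # per-library candidate counts track the emitted truth
  truth <- small_study()$mirna_counts
  for (i in seq_len(nrow(pn))) {
    got <- res$novel$expression
    got <- got[got$mature_seq == pn$mature_seq[i], ]
    want <- truth[truth$locus_id == pn$locus_id[i] & truth$count > 0, ]
    m <- merge(got, want, by = "library_id")
    # counting tolerance may add star/antisense reads at palindromic loci;
    # mature-anchored counts must at least reach the emitted mature counts
    expect_true(all(m$count.x >= m$count.y), info = pn$locus_id[i])
  }
})

test_that("two 1-nt-shifted matures from one precursor merge into one candidate", {
  led <- small_ledger()
  pn <- led$planted_mirnas[!led$planted_mirnas$known &
                             is.na(led$planted_mirnas$ablation) &
                             led$planted_mirnas$strand == "+", ][1, ]
  g <- led$genome[[1]]
  m1 <- pn$mature_seq
  m2 <- substr(g, pn$mature_gstart, pn$mature_gstart + 20)  # shifted -1
  star <- pn$star_seq
  tags <- data.frame(sequence = c(m1, m1, m2, star),
                     count = c(30L, 25L, 10L, 3L),
                     library_id = c("L1", "L2", "L1", "L1"))
  ref <- list(genome = led$genome, annotations = NULL, ncrna = character(0),
              ncrna_meta = NULL, precursor = character(0), mature = character(0),
              mature_meta = NULL)
  ann <- annotate_tags(tags, ref)
  out <- discover_novel(ann, led$genome)
  hit_cands <- out$candidates[out$candidates$mature_seq %in% c(m1, m2), ]
  expect_equal(nrow(hit_cands), 1L)
  expect_equal(hit_cands$mature_seq, m1)   # dominant variant kept
  expect_true(hit_cands$id %in% out$novel)
})

test_that("a hairpin present in a single library is excluded from the putative set", {
  led <- small_ledger()
  pn <- led$planted_mirnas[!led$planted_mirnas$known &
                             is.na(led$planted_mirnas$ablation) &
                             led$planted_mirnas$strand == "+", ][1, ]
  tags <- data.frame(sequence = pn$mature_seq, count = 50L, library_id = "L1")
  ref <- list(genome = led$genome, annotations = NULL, ncrna = character(0),
              ncrna_meta = NULL, precursor = character(0), mature = character(0),
              mature_meta = NULL)
  out <- discover_novel(annotate_tags(tags, ref), led$genome)
  expect_equal(length(out$putative), 0L)
  # the same locus with reads in two libraries is called
  tags2 <- data.frame(sequence = pn$mature_seq, count = c(30L, 20L),
                      library_id = c("L1", "L2"))
  out2 <- discover_novel(annotate_tags(tags2, ref), led$genome)
  expect_equal(length(out2$putative), 1L)
})
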