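test_that("TPM normalisation is count * 1e6 / total", {
  expect_equal(tpm(0, 1e6), 0)
  expect_equal(tpm(1, 1e6), 1)
  expect_equal(tpm(5, 2e6), 2.5)
  expect_error(tpm(1, 0), "positive")
  expect_error(tpm(-1, 10), "non-negative")
})

test_that("exact test matches direct summation of the conditional law", {
  cases <- expand.grid(x = c(0, 1, 5, 17, 80, 200),
                       y = c(0, 3, 5, 80, 120, 200),
                       ratio = c(0.5, 1, 2))
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; y <- cases$y[i]
    N1 <- 1e6; N2 <- cases$ratio[i] * 1e6
    expect_lt(abs(exact_pvalue(x, y, N1, N2) -
                    oracle_exact_pvalue(x, y, N1, N2)), 1e-10,
              label = sprintf("|p - oracle| for x=%d y=%d r=%g",
                              x, y, cases$ratio[i]))
  }
})

test_that("exact test is symmetric, bounded and monotone", {
  # no evidence when the normalised counts agree
  for (x in c(0, 1, 10, 1000))
    expect_gt(exact_pvalue(x, x, 1e6, 1e6), 0.05)
  # exchange symmetry
  set.seed(5)
  for (i in 1:25) {
    x <- sample(0:300, 1); y <- sample(0:300, 1)
    N1 <- sample(1e5:1e7, 1); N2 <- sample(1e5:1e7, 1)
    expect_equal(exact_pvalue(x, y, N1, N2), exact_pvalue(y, x, N2, N1),
                 tolerance = 1e-12)
  }
  # monotone decreasing in the deviation of y from its conditional mean
  x <- 50; N1 <- N2 <- 1e6
  ys <- 50:160
  ps <- exact_pvalue(rep(x, length(ys)), ys, N1, N2)
  expect_true(all(diff(ps) <= 1e-12))
  # stable for large counts
  expect_gt(exact_pvalue(1e6, 1e6, 1e7, 1e7), 0.5)
  expect_lt(exact_pvalue(1e6, 2e6, 1e7, 1e7), 1e-10)
  expect_error(exact_pvalue(1.5, 2, 1e6, 1e6), "integer")
})

make_expr <- function(x, y, ids = sprintf("m%03d", seq_along(x)),
                      variety = "tolerant_A", tissue = "leaf") {
  rbind(
    data.frame(mirna_id = ids, library_id = "ctrl", variety = variety,
               tissue = tissue, condition = "control", raw_count = x),
    data.frame(mirna_id = ids, library_id = "drt", variety = variety,
               tissue = tissue, condition = "drought", raw_count = y))
}

test_that("DE calls apply the TPM prefilter, pseudocounts and both criteria", {
  totals <- c(ctrl = 1e6, drt = 1e6)
  # both sides below 1 TPM: excluded before testing
  de <- call_de(make_expr(0, 0, "m1"), totals)
  expect_equal(nrow(de), 0L)
  # zero-count side: pseudocount 0.5 for the fold change, true zero for p
  de <- call_de(make_expr(0, 64, "m1"), totals)
  expect_equal(de$log2fc, log2(64 / 0.5))
  expect_equal(de$pvalue, exact_pvalue(0, 64, 1e6, 1e6))
  expect_true(de$significant)
  expect_equal(de$direction, "up")
  # large but sub-2-fold change: p small yet not called
  de <- call_de(make_expr(1000, 1800, "m1"), totals)
  expect_lt(de$pvalue, 0.05)
  expect_false(de$significant)
  expect_equal(de$direction, "none")
  # 4-fold down with ample counts: called down
  de <- call_de(make_expr(400, 100, "m1"), totals)
  expect_true(de$significant)
  expect_equal(de$direction, "down")
  # unpaired records error
  expr <- make_expr(5, 5, "m1")
  expect_error(call_de(expr[expr$condition == "control", ], totals), "unpaired")
})

test_that("planted 8-fold changes are detected and nulls are controlled", {
  set.seed(42)
  totals <- c(ctrl = 1e6, drt = 1e6)
  n <- 60
  x <- rnbinom(n, mu = 60, size = 100)
  y <- rnbinom(n, mu = 480, size = 100)
  de <- call_de(make_expr(x, y), totals)
  expect_gte(mean(de$significant), 0.95)
  x0 <- rnbinom(n, mu = 100, size = 100)
  y0 <- rnbinom(n, mu = 100, size = 100)
  de0 <- call_de(make_expr(x0, y0), totals)
  expect_lte(mean(de0$significant), 0.07)
})

test_that("Venn grouping keys on the mature sequence and flags cross-tissue patterns", {
  totals <- c(ctrl = 1e6, drt = 1e6)
  # two ids share one mature sequence; a third differs
  expr <- rbind(make_expr(c(100, 100, 100), c(900, 900, 120),
                          c("mirA1", "mirA2", "mirB"), "tolerant_A"),
                make_expr(c(100, 100, 100), c(900, 900, 900),
                          c("mirA1", "mirA2", "mirB"), "tolerant_B"),
                make_expr(c(100, 100, 100), c(900, 900, 900),
                          c("mirA1", "mirA2", "mirB"), "susceptible"))
  de <- call_de(expr, totals)
  seqs <- c(mirA1 = "ACGTACGTACGTACGTACGTA",
            mirA2 = "ACGTACGTACGTACGTACGTA",
            mirB = "TTTTGCATCGGATCAGGCACC")
  vg <- venn_groups(de, seqs)
  # identical matures collapse into one group
  grpA <- vg[vg$group == "ACGTACGTACGTACGTACGTA", ]
  expect_equal(nrow(grpA), 1L)
  expect_equal(grpA$members, "mirA1,mirA2")
  # DE in all three varieties, same direction: centre region
  expect_equal(grpA$region, "tolerant_A&susceptible&tolerant_B")
  # mirB reached significance only outside tolerant_A
  grpB <- vg[vg$group == seqs[["mirB"]], ]
  expect_false(grepl("tolerant_A", grpB$region))
  # region counts sum to the number of DE groups in the tissue
  expect_equal(nrow(vg), length(unique(vg$group)))

  # opposite directions between tissues are flagged
  expr2 <- rbind(make_expr(100, 900, "mirC", tissue = "leaf"),
                 make_expr(900, 100, "mirC", tissue = "stem"))
  vg2 <- venn_groups(call_de(expr2, totals), NULL,
                     varieties = "tolerant_A")
  expect_true(all(vg2$common_between_tissues))
  expect_true(all(vg2$opposite_between_tissues))
})

test_that("contrast detection requires the full tolerant/susceptible motif", {
  totals <- c(ctrl = 1e6, drt = 1e6)
  expr <- rbind(make_expr(800, 100, "mirX", "tolerant_A"),
                make_expr(800, 90, "mirX", "tolerant_B"),
                make_expr(100, 850, "mirX", "susceptible"))
  de <- call_de(expr, totals)
  ct <- contrast_patterns(de)
  expect_equal(ct$mirna_id, "mirX")
  expect_equal(ct$pattern, "tolerant_down_susceptible_up")
  expect_false(ct$sub_threshold)
  # nothing planted in the other tissue
  expect_equal(nrow(contrast_patterns(de, tissue = "stem")), 0L)
  # one tolerant variety missing the down-call breaks the motif
  expr2 <- expr
  expr2$raw_count[expr2$mirna_id == "mirX" & expr2$variety == "tolerant_B" &
                    expr2$condition == "drought"] <- 700
  expect_equal(nrow(contrast_patterns(call_de(expr2, totals))), 0L)
  # sub-threshold susceptible response (1.8-fold) only passes with relax
  expr3 <- rbind(make_expr(800, 100, "mirX", "tolerant_A"),
                 make_expr(800, 90, "mirX", "tolerant_B"),
                 make_expr(500, 900, "mirX", "susceptible"))
  de3 <- call_de(expr3, totals)
  expect_equal(nrow(contrast_patterns(de3)), 0L)
  ct3 <- contrast_patterns(de3, relax = TRUE)
  expect_equal(ct3$mirna_id, "mirX")
  expect_true(ct3$sub_threshold)
})
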