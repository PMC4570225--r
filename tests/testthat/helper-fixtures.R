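# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Small study used by module tests: 60 kb genome, 6 novel + 8 known miRNA
# loci, 12 libraries of 12k reads.
small_ledger <- function() {
  if (is.null(.fixtures$led))
    .fixtures$led <- generate_genome(length_bp = 60000, n_mirna_loci = 6,
                                     n_known_mirna = 8, n_ncrna_loci = 8,
                                     n_genes = 3, n_repeats = 3, seed = 3)
  .fixtures$led
}

small_study <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- simulate_libraries(small_ledger(),
                                          library_specs(depth = 12000),
                                          seed = 5)
  .fixtures$study
}

small_results <- function() {
  if (is.null(.fixtures$res)) {
    led <- small_ledger()
    .fixtures$res <- run_pipeline(small_study(), led$reference,
                                  transcripts = led$transcripts,
                                  degradome = simulate_degradome(led, seed = 2),
                                  annotation = led$go_annotation)
  }
  .fixtures$res
}

# Full-scale study for the acceptance tests: defaults (100 kb genome,
# 12 x 50k-read libraries).
big_ledger <- function() {
  if (is.null(.fixtures$big_led)) .fixtures$big_led <- generate_genome(seed = 17)
  .fixtures$big_led
}

big_study <- function() {
  if (is.null(.fixtures$big_study))
    .fixtures$big_study <- simulate_libraries(big_ledger(), library_specs(),
                                              seed = 19)
  .fixtures$big_study
}

# Independent folding oracles -------------------------------------------------

oracle_pair_energy <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
  if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(-2)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(-1)
  0
}

# Plain recursive enumeration of nested pairings (no memoisation): the
# minimum total energy over every legal structure. Exponential; for short
# sequences only.
oracle_fold_exhaustive <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      e <- oracle_pair_energy(s[i], s[k])
      if (e == 0) next
      inner <- if (k - i > 1) rec(i + 1, k - 1) else 0
      rest <- if (k < j) rec(k + 1, j) else 0
      best <- min(best, e + inner + rest)
    }
    best
  }
  rec(1, length(s))
}

# Memoised interval recursion in R: an independent implementation of the
# same energy model, usable up to ~60 nt.
oracle_fold_memo <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  memo <- matrix(NA_real_, n, n)
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      e <- oracle_pair_energy(s[i], s[k])
      if (e == 0) next
      inner <- if (k - i > 1) rec(i + 1, k - 1) else 0
      rest <- if (k < j) rec(k + 1, j) else 0
      best <- min(best, e + inner + rest)
    }
    memo[i, j] <<- best
    best
  }
  rec(1, n)
}

# Direct summation of the conditional law P(y | x) for the exact test, in
# log space, independent of the negative-binomial identity used by the
# implementation. The same label-invariant two-sided rule is applied: the
# more conservative doubled p over the two conditionings.
oracle_ac_doubled <- function(x, y, N1, N2, cap = 5000) {
  r <- N2 / N1
  yy <- 0:cap
  logp <- yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
    (x + yy + 1) * log(1 + r)
  p <- exp(logp)
  min(1, 2 * min(sum(p[yy <= y]), sum(p[yy >= y])))
}

oracle_exact_pvalue <- function(x, y, N1, N2, cap = 5000) {
  max(oracle_ac_doubled(x, y, N1, N2, cap), oracle_ac_doubled(y, x, N2, N1, cap))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
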