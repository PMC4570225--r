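#' Tags-per-million normalisation
#'
#' @param count Raw count (non-negative).
#' @param library_total Library clean-read total (positive).
#' @return `count * 1e6 / library_total`.
#' @export
tpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be positive", call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count * 1e6 / library_total
}

#' Exact test for a pair of digital expression counts
#'
#' Tests whether a tag count `y` (library total `N2`) is consistent with a
#' count `x` (library total `N1`) under the conditional law
#' \deqn{P(y | x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}},}
#' the sampling distribution of the second count given the first for equal
#' underlying expression. The two-sided p-value doubles the smaller tail
#' probability (capped at 1). Because the conditional law is not symmetric
#' in which count is conditioned on, the doubled p is evaluated under both
#' labelings, `(x, N1)` conditioning and `(y, N2)` conditioning, and the
#' larger (more conservative) value is reported; the test is therefore
#' invariant under exchanging the two libraries. `method = "two_tail_sum"`
#' instead sums both tail masses around the conditional mean. The law is a
#' negative binomial with size `x + 1` and success probability
#' `N1/(N1+N2)`, so tails are computed in log-space via [stats::pnbinom()]
#' and are stable for counts up to at least one million.
#'
#' @param x,y Non-negative integer counts (control, treatment).
#' @param N1,N2 Positive library totals for `x` and `y`.
#' @param method Two-sided construction: `"doubling"` (default) or
#'   `"two_tail_sum"`.
#' @return p-value in \[0, 1\]. Vectorised over `x` and `y`.
#' @examples
#' exact_pvalue(5, 80, 1e6, 1e6)
#' @export
exact_pvalue <- function(x, y, N1, N2, method = c("doubling", "two_tail_sum")) {
  method <- match.arg(method)
  if (any(x != round(x)) || any(y != round(y)))
    stop("counts must be integers", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  stopifnot(all(N1 > 0), all(N2 > 0))
  p <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = p)
  upper <- 1 - pnbinom(y - 1, size = x + 1, prob = p)
  if (method == "doubling") {
    fwd <- pmin(1, 2 * pmin(lower, upper))
    q <- N2 / (N1 + N2)
    lower2 <- pnbinom(x, size = y + 1, prob = q)
    upper2 <- 1 - pnbinom(x - 1, size = y + 1, prob = q)
    rev <- pmin(1, 2 * pmin(lower2, upper2))
    pmax(fwd, rev)
  } else {
    # sum of both tails: P(Y <= y) + P(Y >= y') mass at least as extreme on
    # the other side, measured by distance from the conditional mean
    mu <- (x + 1) * (1 - p) / p
    dev <- abs(y - mu)
    lo <- pnbinom(floor(mu - dev), size = x + 1, prob = p)
    hi <- 1 - pnbinom(ceiling(mu + dev) - 1, size = x + 1, prob = p)
    pmin(1, lo + hi)
  }
}

#' Call drought-responsive miRNAs from paired expression records
#'
#' For every miRNA within a (variety, tissue) cell, the control and drought
#' libraries are compared: counts are TPM-normalised, pairs where neither
#' side reaches `tpm_min` are excluded before testing, the log2 fold change
#' is computed with a 0.5 pseudocount on zero raw counts (display only; the
#' exact test always uses the true zeros), and a miRNA is called
#' drought-responsive when `|log2FC| >= lfc_min` and `p <= p_max`. A
#' Benjamini-Hochberg adjusted column is emitted for information only; the
#' calls deliberately use the unadjusted p-values.
#'
#' @param expression Expression records: data frame with `mirna_id`,
#'   `library_id`, `variety`, `tissue`, `condition`, `raw_count`.
#' @param library_totals Named vector of clean-read totals per `library_id`.
#' @param lfc_min Minimum absolute log2 fold change (default 2).
#' @param p_max Maximum exact-test p-value (default 0.05).
#' @param tpm_min TPM prefilter: at least one member of the pair must reach
#'   this level (default 1).
#' @return A `de_table` data frame: one row per miRNA x variety x tissue
#'   with `x`, `y`, `N1`, `N2`, `tpm_control`, `tpm_drought`, `log2fc`,
#'   `pvalue`, `padj`, `significant`, `direction`.
#' @export
call_de <- function(expression, library_totals, lfc_min = 2, p_max = 0.05,
                    tpm_min = 1) {
  cells <- unique(expression[, c("variety", "tissue")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    v <- cells$variety[i]; t <- cells$tissue[i]
    e <- expression[expression$variety == v & expression$tissue == t, , drop = FALSE]
    ctrl <- e[e$condition == "control", , drop = FALSE]
    drt <- e[e$condition == "drought", , drop = FALSE]
    if (nrow(ctrl) == 0 || nrow(drt) == 0)
      stop("unpaired expression records for (", v, ", ", t, ")", call. = FALSE)
    ids <- union(ctrl$mirna_id, drt$mirna_id)
    N1 <- unname(library_totals[[ctrl$library_id[1]]])
    N2 <- unname(library_totals[[drt$library_id[1]]])
    x <- stats::setNames(rep(0, length(ids)), ids)
    y <- x
    x[ctrl$mirna_id] <- ctrl$raw_count
    y[drt$mirna_id] <- drt$raw_count
    tpm_c <- tpm(x, N1); tpm_d <- tpm(y, N2)
    keep <- pmax(tpm_c, tpm_d) >= tpm_min
    if (!any(keep)) next
    xs <- x[keep]; ys <- y[keep]
    lfc <- log2((ifelse(ys == 0, 0.5, ys) / N2) / (ifelse(xs == 0, 0.5, xs) / N1))
    pv <- exact_pvalue(xs, ys, N1, N2)
    rows[[length(rows) + 1]] <- data.frame(
      mirna_id = ids[keep], variety = v, tissue = t,
      x = unname(xs), y = unname(ys), N1 = N1, N2 = N2,
      tpm_control = unname(tpm_c[keep]), tpm_drought = unname(tpm_d[keep]),
      log2fc = unname(lfc), pvalue = unname(pv),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(structure(data.frame(), class = c("de_table", "data.frame")))
  de <- do.call(rbind, rows)
  de$padj <- p.adjust(de$pvalue, method = "BH")
  de$significant <- abs(de$log2fc) >= lfc_min & de$pvalue <= p_max
  de$direction <- ifelse(!de$significant, "none",
                         ifelse(de$log2fc > 0, "up", "down"))
  rownames(de) <- NULL
  structure(de, class = c("de_table", "data.frame"))
}

#' @export
print.de_table <- function(x, ...) {
  if (!all(c("pvalue", "significant") %in% names(x)))
    return(print.data.frame(x, ...))
  cat("Differential expression:", nrow(x), "tested pairs,",
      sum(x$significant), "drought-responsive\n")
  if (nrow(x)) print.data.frame(head(x[order(x$pvalue), ], 10))
  invisible(x)
}

#' Venn-style grouping of drought-responsive miRNAs across varieties
#'
#' Groups miRNAs by identical mature sequence (members of a group share one
#' Venn position), records per-variety direction within each tissue, and
#' flags groups commonly or oppositely regulated between the two tissues.
#'
#' @param de A [call_de()] table over all varieties and tissues.
#' @param mature_seqs Named vector mapping `mirna_id` to mature sequence
#'   (ids absent from the map group by themselves).
#' @param varieties Display order of the varieties.
#' @return Data frame with one row per (group, tissue): member ids, the
#'   per-variety direction columns, the Venn region (which varieties show
#'   the change), and `common_between_tissues` / `opposite_between_tissues`.
#' @export
venn_groups <- function(de, mature_seqs = NULL,
                        varieties = c("tolerant_A", "susceptible", "tolerant_B")) {
  if (nrow(de) == 0) return(data.frame())
  key <- if (is.null(mature_seqs)) de$mirna_id else {
    k <- unname(mature_seqs[de$mirna_id])
    ifelse(is.na(k), de$mirna_id, k)
  }
  de$group <- key
  groups <- unique(de$group[de$significant])
  rows <- list()
  for (g in groups) {
    for (t in unique(de$tissue)) {
      sub <- de[de$group == g & de$tissue == t, , drop = FALSE]
      if (!nrow(sub) || !any(sub$significant)) next
      dir <- vapply(varieties, function(v) {
        s <- sub[sub$variety == v & sub$significant, , drop = FALSE]
        if (!nrow(s)) "absent"
        else if (all(s$direction == "up")) "up"
        else if (all(s$direction == "down")) "down" else "mixed"
      }, character(1))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, tissue = t,
        members = paste(sort(unique(sub$mirna_id)), collapse = ","),
        region = paste(varieties[dir != "absent"], collapse = "&"),
        t(dir), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  # cross-tissue flags per group
  out$common_between_tissues <- FALSE
  out$opposite_between_tissues <- FALSE
  for (g in unique(out$group)) {
    gt <- out[out$group == g, , drop = FALSE]
    if (length(unique(gt$tissue)) < 2) next
    for (v in varieties) {
      d <- gt[[v]]
      d <- d[d %in% c("up", "down")]
      if (length(d) == 2) {
        out$common_between_tissues[out$group == g] <- TRUE
        if (d[1] != d[2]) out$opposite_between_tissues[out$group == g] <- TRUE
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Detect contrasting expression patterns between tolerant and susceptible
#' varieties
#'
#' Returns miRNAs significantly down-regulated in every tolerant variety and
#' up-regulated in every susceptible variety within a tissue, plus the
#' mirror pattern. With `relax = TRUE` the susceptible-side (or
#' tolerant-side, for the mirror) response may be sub-threshold: an
#' absolute fold change above `relax_fold` in the right direction suffices,
#' and such calls are labelled `sub_threshold`.
#'
#' @param de A [call_de()] table.
#' @param tolerant,susceptible Variety labels of each class.
#' @param tissue Tissue to examine.
#' @param relax Allow a sub-threshold response on the minority side.
#' @param relax_fold Linear fold-change floor for the relaxed rule
#'   (default 1.5).
#' @return Data frame with `mirna_id`, `pattern`
#'   (`tolerant_down_susceptible_up` or its mirror) and `sub_threshold`.
#' @export
contrast_patterns <- function(de, tolerant = c("tolerant_A", "tolerant_B"),
                              susceptible = "susceptible", tissue = "leaf",
                              relax = FALSE, relax_fold = 1.5) {
  d <- de[de$tissue == tissue, , drop = FALSE]
  rows <- list()
  for (id in unique(d$mirna_id)) {
    s <- d[d$mirna_id == id, , drop = FALSE]
    dir_of <- function(v) {
      r <- s[s$variety == v, , drop = FALSE]
      if (!nrow(r)) return(list(dir = "none", lfc = 0))
      list(dir = r$direction[1], lfc = r$log2fc[1])
    }
    tol <- lapply(tolerant, dir_of)
    sus <- lapply(susceptible, dir_of)
    for (pat in c("tolerant_down_susceptible_up", "tolerant_up_susceptible_down")) {
      maj <- if (pat == "tolerant_down_susceptible_up") "down" else "up"
      minr <- if (maj == "down") "up" else "down"
      ok_tol <- all(vapply(tol, function(z) z$dir == maj, logical(1)))
      if (!ok_tol) next
      strict <- vapply(sus, function(z) z$dir == minr, logical(1))
      relaxed <- vapply(sus, function(z) {
        lf <- z$lfc
        if (minr == "up") lf >= log2(relax_fold) else lf <= -log2(relax_fold)
      }, logical(1))
      ok_sus <- all(strict) || (relax && all(strict | relaxed))
      if (!ok_sus) next
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = id, pattern = pat, sub_threshold = !all(strict),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(0), pattern = character(0),
                      sub_threshold = logical(0)))
  do.call(rbind, rows)
}
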