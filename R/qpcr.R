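#' Livak 2^-ddCt relative quantification
#'
#' For each target gene and replicate: dCt(condition) = Ct(gene, condition)
#' - Ct(reference, condition); ddCt = dCt(drought) - dCt(control); the
#' normalized fold change is 2^-ddCt. Replicates are paired by index and
#' combined by computing the fold change per replicate and then averaging
#' (the mean of triplicate fold changes, with their standard deviation), not
#' by averaging Ct values first.
#'
#' @param ct_table Data frame with columns `gene_id`, `condition`
#'   (`control`/`drought`), `replicate`, `ct`.
#' @param reference_id Reference gene id (for example a U6 snRNA assay).
#' @return Data frame with `gene_id`, `ddct` (mean over replicates),
#'   `fold_change` (mean of per-replicate 2^-ddCt), `replicate_mean`,
#'   `replicate_sd`.
#' @examples
#' ct <- data.frame(gene_id = rep(c("g1", "U6"), each = 2),
#'                  condition = rep(c("control", "drought"), 2),
#'                  replicate = 1, ct = c(24, 22, 20, 20))
#' livak(ct, "U6")
#' @export
livak <- function(ct_table, reference_id = "U6") {
  stopifnot(all(c("gene_id", "condition", "replicate", "ct") %in%
                  names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  ref <- ct_table[ct_table$gene_id == reference_id, , drop = FALSE]
  ref_ct <- function(cond, rep) {
    r <- ref[ref$condition == cond & ref$replicate == rep, , drop = FALSE]
    if (nrow(r) == 0)
      stop("missing reference Ct for sample (", cond, ", replicate ", rep, ")",
           call. = FALSE)
    r$ct[1]
  }
  genes <- setdiff(unique(ct_table$gene_id), reference_id)
  rows <- list()
  for (g in genes) {
    gt <- ct_table[ct_table$gene_id == g, , drop = FALSE]
    reps <- intersect(gt$replicate[gt$condition == "control"],
                      gt$replicate[gt$condition == "drought"])
    if (!length(reps))
      stop("gene '", g, "' lacks paired control/drought replicates",
           call. = FALSE)
    fc <- vapply(reps, function(r) {
      dct_d <- gt$ct[gt$condition == "drought" & gt$replicate == r][1] -
        ref_ct("drought", r)
      dct_c <- gt$ct[gt$condition == "control" & gt$replicate == r][1] -
        ref_ct("control", r)
      2^-(dct_d - dct_c)
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = g, ddct = mean(-log2(fc)), fold_change = mean(fc),
      replicate_mean = mean(fc),
      replicate_sd = if (length(fc) > 1) sd(fc) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
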