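#' Fold an RNA/DNA sequence into its minimum-energy nested structure
#'
#' Computes the minimum-energy pseudoknot-free secondary structure of a
#' sequence under a Nussinov-style per-pair energy model: G:C = -3, A:U = -2,
#' G:U = -1 kcal/mol, with a minimum hairpin loop of `min_loop` unpaired
#' bases. The dynamic program is exact for this model and the traceback is
#' deterministic (on ties, leaving a base unpaired is preferred, then the
#' smallest pairing partner). The model is a deliberately self-contained
#' stand-in for a full thermodynamic folder; the -18 kcal/mol stability rule
#' used in novel miRNA discovery is interpreted under it.
#'
#' @param seq A single sequence (A/C/G/T or A/C/G/U, case-insensitive),
#'   typically 50-400 nt for hairpin evaluation.
#' @param min_loop Minimum number of unpaired bases enclosed by a hairpin
#'   loop (default 3).
#' @return A list with `structure` (dot-bracket string) and `mfe`
#'   (minimum free energy, kcal/mol, <= 0).
#' @examples
#' fold_rna("GGGGGAAAACCCCC")
#' @export
fold_rna <- function(seq, min_loop = 3) {
  stopifnot(length(seq) == 1)
  s <- as_dna(seq)
  check_dna(s, "fold_rna() input")
  res <- .fold_dp(s, as.integer(min_loop))
  res$mfe <- as.numeric(res$mfe)
  res
}

# Partner vector from a dot-bracket string: partner[i] is the 1-based pairing
# partner of position i, or NA if unpaired.
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}
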