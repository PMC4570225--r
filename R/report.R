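#' Run the full analysis pipeline on a synthetic (or user) study
#'
#' Executes preprocessing, priority annotation, known-miRNA quantification,
#' differential expression with Venn grouping and contrast detection, novel
#' miRNA discovery, target prediction with degradome confirmation, and qPCR
#' analysis when a Ct table is supplied.
#'
#' @param study A `smirna_study` (from [simulate_libraries()]) or a named
#'   list of FASTQ paths keyed by library id.
#' @param reference Reference bundle (see [annotate_tags()]); for a
#'   synthetic study, `ledger$reference`.
#' @param specs Library metadata (data frame with `library_id`, `variety`,
#'   `tissue`, `condition`, `adapter3`, `adapter5`). Defaults to the study's
#'   specs.
#' @param transcripts Optional named transcript set for target prediction.
#' @param degradome Optional degradome tag data frame.
#' @param ct_table Optional qPCR Ct table.
#' @param annotation Optional functional-annotation table for target
#'   tallies.
#' @param cutoff Target-prediction expectation cutoff (default 3.5).
#' @param params_pre [preprocess_params()].
#' @param params_novel [novel_params()].
#' @return A `smirna_results` list with elements `filter_reports`, `tags`,
#'   `assignments`, `distribution`, `length_dist`, `expression`,
#'   `library_totals`, `de`, `venn`, `contrasts`, `novel`, `targets`,
#'   `target_tally`, `qpcr`.
#' @export
run_pipeline <- function(study, reference, specs = NULL, transcripts = NULL,
                         degradome = NULL, ct_table = NULL, annotation = NULL,
                         cutoff = 3.5,
                         params_pre = preprocess_params(),
                         params_novel = novel_params()) {
  if (is(study, "smirna_study")) {
    libs <- study$libraries
    if (is.null(specs)) specs <- study$specs
  } else libs <- study
  stopifnot(!is.null(specs))

  filter_reports <- list(); tag_list <- list()
  for (lib in names(libs)) {
    sp <- specs[specs$library_id == lib, , drop = FALSE]
    ft <- filter_and_trim(libs[[lib]], sp$adapter3[1], sp$adapter5[1],
                          params_pre, library_id = lib)
    filter_reports[[lib]] <- ft$report
    tag_list[[lib]] <- ft$tags
  }
  tags <- do.call(rbind, tag_list)
  rownames(tags) <- NULL
  library_totals <- vapply(filter_reports, function(r) r$clean_reads, numeric(1))

  assignments <- annotate_tags(tags, reference)
  distribution <- distribution_report(assignments)
  length_dist <- do.call(rbind, lapply(names(libs), function(lib) {
    ld <- length_distribution(tags[tags$library_id == lib, , drop = FALSE])
    if (nrow(ld)) ld$library_id <- lib
    ld
  }))

  meta <- specs[, c("library_id", "variety", "tissue", "condition")]
  meta$clean_total <- unname(library_totals[meta$library_id])
  quant <- quantify_known(assignments, meta, reference)
  expression <- quant$expression
  if (nrow(expression))
    expression$level <- classify_expression(expression$tpm)

  de <- NULL; venn <- NULL; contrasts <- NULL
  if (nrow(expression)) {
    de <- call_de(expression, library_totals)
    mat_seq <- reference$mature
    if (nrow(de)) {
      venn <- venn_groups(de, mat_seq)
      contrasts <- do.call(rbind, lapply(unique(de$tissue), function(t) {
        ct <- contrast_patterns(de, tissue = t)
        if (nrow(ct)) ct$tissue <- t
        ct
      }))
    }
  }

  novel <- discover_novel(assignments, reference$genome, params_novel)

  targets <- NULL; tally <- NULL
  if (!is.null(transcripts)) {
    novel_ids <- novel$novel
    mat <- novel$candidates$mature_seq[novel$candidates$id %in% novel_ids]
    names(mat) <- novel_ids
    if (length(mat)) {
      targets <- predict_targets(mat, transcripts, cutoff)
      targets <- confirm_degradome(targets, degradome, transcripts)
      if (!is.null(annotation) && nrow(targets))
        tally <- tally_annotations(targets, annotation)
    }
  }

  qpcr <- if (!is.null(ct_table)) livak(ct_table) else NULL

  structure(list(filter_reports = filter_reports, tags = tags,
                 assignments = assignments, distribution = distribution,
                 length_dist = length_dist, expression = expression,
                 library_totals = library_totals, de = de, venn = venn,
                 contrasts = contrasts, novel = novel, targets = targets,
                 target_tally = tally, qpcr = qpcr),
            class = "smirna_results")
}

#' @export
print.smirna_results <- function(x, ...) {
  cat("Small RNA pipeline results\n")
  cat("  libraries:", length(x$filter_reports),
      "| clean reads:", sum(x$library_totals), "\n")
  if (!is.null(x$de))
    cat("  DE pairs tested:", nrow(x$de), "| drought-responsive:",
        sum(x$de$significant), "\n")
  cat("  novel candidates: putative", length(x$novel$putative),
      "| with star", length(x$novel$novel), "\n")
  if (!is.null(x$targets))
    cat("  target sites:", nrow(x$targets), "| degradome-confirmed:",
        sum(x$targets$degradome_confirmed %in% TRUE), "\n")
  invisible(x)
}

#' Write the pipeline report bundle
#'
#' Writes every stage output as TSV into one directory with an index file;
#' sections whose inputs were absent are marked as such rather than failing.
#' Sequencing-based fold changes and qPCR fold changes are juxtaposed per
#' gene when both are present. Regeneration from identical inputs is
#' bit-identical.
#'
#' @param results A [run_pipeline()] result.
#' @param dir Output directory.
#' @param figures If `TRUE`, also write length-distribution bar charts
#'   (PDF).
#' @return The directory, invisibly.
#' @export
build_report <- function(results, dir, figures = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index <- character(0)
  emit <- function(obj, name, label) {
    if (is.null(obj) || (is.data.frame(obj) && nrow(obj) == 0)) {
      index <<- c(index, paste0(label, ": absent"))
      return()
    }
    write_tsv(obj, file.path(dir, name))
    index <<- c(index, paste0(label, ": ", name))
  }
  fr <- do.call(rbind, lapply(names(results$filter_reports), function(lib) {
    r <- results$filter_reports[[lib]]
    data.frame(library_id = lib, class = c("raw", names(r$removed), "clean"),
               count = c(r$raw_reads, unname(r$removed), r$clean_reads),
               stringsAsFactors = FALSE)
  }))
  emit(fr, "filter_report.tsv", "filter report")
  emit(results$length_dist, "length_distribution.tsv", "length distribution")
  emit(results$distribution, "annotation_distribution.tsv",
       "annotation distribution")
  emit(results$expression, "known_expression.tsv", "known miRNA expression")
  emit(results$de, "differential_expression.tsv", "differential expression")
  emit(results$venn, "venn_groups.tsv", "Venn grouping")
  emit(results$contrasts, "contrast_patterns.tsv", "contrasting patterns")
  if (!is.null(results$novel))
    emit(results$novel$candidates, "novel_candidates.tsv", "novel candidates")
  emit(results$targets, "target_sites.tsv", "target sites")
  emit(results$target_tally, "target_annotation_tally.tsv", "target annotation tally")
  emit(results$qpcr, "qpcr_fold_changes.tsv", "qPCR fold changes")
  if (!is.null(results$qpcr) && !is.null(results$de)) {
    seqfc <- results$de[results$de$mirna_id %in% results$qpcr$gene_id, ,
                        drop = FALSE]
    if (nrow(seqfc)) {
      cmp <- merge(results$qpcr[, c("gene_id", "fold_change")],
                   data.frame(gene_id = seqfc$mirna_id, tissue = seqfc$tissue,
                              variety = seqfc$variety,
                              seq_fold_change = 2^seqfc$log2fc),
                   by = "gene_id")
      emit(cmp, "qpcr_vs_sequencing.tsv", "qPCR vs sequencing fold changes")
    }
  }
  if (figures && !is.null(results$length_dist) && nrow(results$length_dist)) {
    grDevices::pdf(file.path(dir, "length_distribution.pdf"))
    for (lib in unique(results$length_dist$library_id)) {
      ld <- results$length_dist[results$length_dist$library_id == lib, ]
      graphics::barplot(ld$total, names.arg = ld$length, main = lib,
                        xlab = "tag length (nt)", ylab = "reads")
    }
    grDevices::dev.off()
    index <- c(index, "length distribution figures: length_distribution.pdf")
  }
  writeLines(index, file.path(dir, "INDEX.txt"))
  invisible(dir)
}
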