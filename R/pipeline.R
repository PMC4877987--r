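#' End-to-end binning pipeline
#'
#' Chains the stages in their methodological order on a directory of
#' plain-text inputs (the layout written by [write_community()]):
#' coverage profiling, region selection (auto-seeded or user-supplied),
#' three-stage bin extraction, marker QC, relative abundance and
#' transcriptional-activity summaries. Writes `coverage.tsv`,
#' `bin_<i>.json`, `qc.json`, `activity.tsv`, `summary.tsv` and
#' `pipeline.log` into `out_dir`. Optionally compares the two largest bins
#' by fragment ANI. The pipeline itself is deterministic: identical inputs
#' and parameters give byte-identical outputs.
#'
#' @param input_dir directory with `scaffolds.fasta`, `mapping_<sample>.tsv`
#'   files, `markers.tsv`, `genes.tsv`, `links.tsv`, `expression.tsv`.
#' @param out_dir output directory (created).
#' @param sample_pair two sample IDs spanning the coverage plane (default:
#'   the first two mapping files found, alphabetically).
#' @param regions list of [region_polygon()] / [region_ellipse()]; `NULL`
#'   auto-seeds regions with [auto_seed_regions()].
#' @param set marker set for QC (default ESCG107).
#' @param tnf_cutoff,tnf_linkage,tnf_scaling TNF refinement parameters.
#' @param min_links,max_cov_fold paired-end rescue parameters.
#' @param active_threshold MRPKM threshold for "transcribed".
#' @param bandwidth auto-seeding tree-cut height (log10 units).
#' @param compare also compute symmetric fragment ANI and a species call
#'   between the two largest bins (requires blastn; default FALSE).
#' @return list of class `pipeline_result`: `bins`, `qc`, `abundance`,
#'   `activity`, `summary` (one row per bin), `profiles`, `comparison`
#'   (NULL unless `compare`), `paths`.
#' @export
run_pipeline <- function(input_dir, out_dir, sample_pair = NULL,
                         regions = NULL, set = marker_set("ESCG107"),
                         tnf_cutoff = 0.1, tnf_linkage = "average",
                         tnf_scaling = "fraction", min_links = 2,
                         max_cov_fold = 3, active_threshold = 0,
                         bandwidth = 0.5, compare = FALSE) {
  req <- function(f) {
    p <- file.path(input_dir, f)
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    p
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)

  scaffolds <- Biostrings::readDNAStringSet(req("scaffolds.fasta"))
  maps <- sort(list.files(input_dir, "^mapping_.*\\.tsv$",
                          full.names = TRUE))
  if (length(maps) < 2) {
    stop("need at least two mapping_<sample>.tsv files in ", input_dir,
         call. = FALSE)
  }
  mappings <- lapply(maps, read_mapping_tsv)
  names(mappings) <- vapply(mappings, `[[`, "", "sample_id")
  sample_pair <- sample_pair %||% names(mappings)[1:2]
  markers <- read_tsv(req("markers.tsv"))
  genes <- read_tsv(req("genes.tsv"))
  links <- read_tsv(req("links.tsv"))
  expr <- read_tsv(req("expression.tsv"))
  logf("inputs: %d scaffolds, samples [%s], %d marker hits, %d genes",
       length(scaffolds), paste(names(mappings), collapse = ", "),
       nrow(markers), nrow(genes))

  lens <- stats::setNames(Biostrings::width(scaffolds), names(scaffolds))
  profiles <- coverage_profiles(mappings, lens)
  write_tsv(profiles, file.path(out_dir, "coverage.tsv"))
  logf("coverage: %d profiles over %s", nrow(profiles),
       paste(sample_pair, collapse = "/"))

  tnf <- tnf_vectors(scaffolds)
  if (is.null(regions)) {
    regions <- auto_seed_regions(profiles, sample_pair,
                                 bandwidth = bandwidth)
    logf("auto-seeded %d selection regions", length(regions))
  }

  bins <- list(); qc <- list(); abund <- list(); act <- list()
  activity <- activity_table(expr, genes)
  write_tsv(activity, file.path(out_dir, "activity.tsv"))
  for (i in seq_along(regions)) {
    bid <- sprintf("bin_%d", i)
    bin <- extract_bin(profiles, tnf, links, regions[[i]], sample_pair,
                       bin_id = bid, tnf_cutoff = tnf_cutoff,
                       tnf_linkage = tnf_linkage,
                       tnf_scaling = tnf_scaling, min_links = min_links,
                       max_cov_fold = max_cov_fold)
    write_bin_json(bin, file.path(out_dir, paste0(bid, ".json")))
    n_removed <- sum(bin$provenance$stage == "tnf_removed")
    n_rescued <- sum(bin$provenance$stage == "pe_rescued")
    logf("%s: %d scaffolds (tnf removed %d, pe rescued %d)", bid,
         length(bin$scaffold_ids), n_removed, n_rescued)
    bins[[bid]] <- bin
    qc[[bid]] <- qc_report(bin, markers, set)
    abund[[bid]] <- relative_abundance(bin, mappings)
    bin_genes <- genes$gene_id[genes$scaffold_id %in% bin$scaffold_ids]
    act[[bid]] <- if (length(bin_genes)) {
      bin_activity_summary(bin_genes, activity, active_threshold)
    } else {
      list(pct_transcribed = NA_real_, n_active = 0L, n_genes = 0L)
    }
  }

  summary_df <- do.call(rbind, lapply(names(bins), function(b) {
    in_bin <- profiles$scaffold_id %in% bins[[b]]$scaffold_ids
    row <- data.frame(
      bin_id = b,
      n_scaffolds = length(bins[[b]]$scaffold_ids),
      total_length_bp = sum(profiles$length[in_bin]),
      completeness_pct = qc[[b]]$completeness_pct,
      redundancy_pct = qc[[b]]$redundancy_pct,
      stringsAsFactors = FALSE)
    for (s in names(abund[[b]])) {
      row[[paste0("abundance_", s, "_pct")]] <- abund[[b]][[s]]
    }
    row$genes_transcribed_pct <- act[[b]]$pct_transcribed
    row
  }))
  write_tsv(summary_df, file.path(out_dir, "summary.tsv"))
  jsonlite::write_json(lapply(qc, unclass),
                       file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  comparison <- NULL
  if (compare && length(bins) >= 2) {
    ord <- order(-summary_df$total_length_bp)
    b1 <- bins[[summary_df$bin_id[ord[1]]]]
    b2 <- bins[[summary_df$bin_id[ord[2]]]]
    a <- ani(scaffolds[b1$scaffold_ids], scaffolds[b2$scaffold_ids])
    call <- if (is.na(a$ani)) NULL else classify_species(a$ani)
    comparison <- list(bin_a = b1$bin_id, bin_b = b2$bin_id,
                       ani = a, species_call = call)
    jsonlite::write_json(
      list(bin_a = b1$bin_id, bin_b = b2$bin_id, ani_pct = a$ani,
           verdict = if (is.null(call)) "indeterminate" else call$verdict),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    logf("comparison %s vs %s: ANI %.2f%%", b1$bin_id, b2$bin_id, a$ani)
  }
  logf("done: %d bins", length(bins))

  structure(list(bins = bins, qc = qc, abundance = abund,
                 activity = activity, summary = summary_df,
                 profiles = profiles, comparison = comparison,
                 paths = list(out_dir = out_dir)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d bins -> %s\n", length(x$bins),
              x$paths$out_dir))
  print(x$summary)
  invisible(x)
}

#' Two-dimensional coverage plot
#'
#' Log-log scatter of per-scaffold coverage in two samples: point area
#' scales with the square root of scaffold length, scaffolds shorter than
#' `min_len` (default 10 kb) are omitted, bins are coloured, and a blue
#' diagonal marks stable coverage between the samples.
#'
#' @param profiles coverage table from [coverage_profiles()].
#' @param sample_pair the two samples to plot.
#' @param bins optional named list of [genome_bin()]s for colouring.
#' @param min_len only scaffolds at least this long are drawn.
#' @param file optional output image path (written via [ggplot2::ggsave()]).
#' @return the ggplot object, with the plotted data in `$data`.
#' @export
plot_coverage <- function(profiles, sample_pair, bins = NULL,
                          min_len = 10000, file = NULL) {
  cols <- paste0("cov_", sample_pair)
  d <- profiles[profiles$length >= min_len,
                c("scaffold_id", "length", cols)]
  d$x <- log10_cov(d[[cols[1]]])
  d$y <- log10_cov(d[[cols[2]]])
  d$bin <- "unbinned"
  for (b in names(bins)) {
    d$bin[d$scaffold_id %in% bins[[b]]$scaffold_ids] <- b
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                       size = sqrt(.data$length),
                                       colour = .data$bin)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "blue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(name = "sqrt(length)") +
    ggplot2::labs(x = sprintf("log10 coverage (%s)", sample_pair[1]),
                  y = sprintf("log10 coverage (%s)", sample_pair[2]),
                  colour = "bin") +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 5)
  p
}

#' Precision/recall of a bin against generator truth
#'
#' @param bin a [genome_bin()].
#' @param scaffold_truth truth table from the generator.
#' @param genome_id the genome the bin is supposed to capture.
#' @param lengths named scaffold lengths.
#' @param min_len evaluate on scaffolds at least this long (default 5000).
#' @return list: `precision`, `recall`, `f1` (all on scaffolds >= min_len).
#' @export
bin_accuracy <- function(bin, scaffold_truth, genome_id, lengths,
                         min_len = 5000) {
  big <- scaffold_truth$scaffold_id[lengths[scaffold_truth$scaffold_id] >=
                                      min_len]
  truth_pos <- scaffold_truth$scaffold_id[
    scaffold_truth$genome_id == genome_id]
  truth_pos <- intersect(truth_pos, big)
  called <- intersect(bin$scaffold_ids, big)
  tp <- length(intersect(called, truth_pos))
  precision <- if (length(called)) tp / length(called) else NA_real_
  recall <- if (length(truth_pos)) tp / length(truth_pos) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}
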