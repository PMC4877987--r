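#' Plain-text interchange formats
#'
#' All tables are tab-separated with a header line; the mapping summary
#' additionally carries its sample ID and library size in a leading
#' comment. FASTA goes through Biostrings. A community written with
#' [write_community()] is consumed back exclusively through these public
#' readers, so the pipeline can be exercised from files alone.
#'
#' @name io
NULL

#' Write a mapping summary as TSV
#'
#' Format: a first line `# sample_id=<s> total_reads=<n>`, then a
#' tab-separated table (scaffold_id, mapped_reads, mapped_bases).
#'
#' @param mapping a [mapping_summary()].
#' @param path output file.
#' @export
write_mapping_tsv <- function(mapping, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s total_reads=%.0f", mapping$sample_id,
                     mapping$total_reads), con)
  utils::write.table(mapping$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping_tsv
#' @param path TSV file written by [write_mapping_tsv()].
#' @return a [mapping_summary()].
#' @export
read_mapping_tsv <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first,
                  regexec("# sample_id=(\\S+) total_reads=(\\d+)", first))[[1]]
  if (length(m) != 3) {
    stop("missing '# sample_id=... total_reads=...' header in ", path,
         call. = FALSE)
  }
  rec <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                           stringsAsFactors = FALSE)
  mapping_summary(m[2], rec, as.numeric(m[3]))
}

#' Write / read a genome bin as JSON
#'
#' @param bin a [genome_bin()].
#' @param path JSON file.
#' @export
write_bin_json <- function(bin, path) {
  jsonlite::write_json(list(bin_id = bin$bin_id,
                            scaffold_ids = bin$scaffold_ids,
                            provenance = bin$provenance),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_bin_json
#' @export
read_bin_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- x$provenance
  if (is.null(prov) || !length(prov)) prov <- NULL
  genome_bin(x$bin_id, x$scaffold_ids, prov)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a synthetic community to a directory of plain-text files
#'
#' Emits `scaffolds.fasta`, one `mapping_<sample>.tsv` per sample,
#' `markers.tsv` (gene_id, scaffold_id, marker_id), `genes.tsv` (gene_id,
#' scaffold_id, start, end, strand; 1-based inclusive), `links.tsv`
#' (scaffold_a, scaffold_b, n_links), `expression.tsv` (gene_id, dna_count,
#' rna_count) and `truth.json` (scaffold -> genome assignments, gene truth,
#' per-genome marker truth, model parameters).
#'
#' @param community a [simulate_community()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "synthetic_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(community$scaffolds,
                              file.path(dir, "scaffolds.fasta"))
  for (m in community$mappings) {
    write_mapping_tsv(m, file.path(dir, sprintf("mapping_%s.tsv",
                                                m$sample_id)))
  }
  write_tsv(community$marker_hits[c("gene_id", "scaffold_id", "marker_id")],
            file.path(dir, "markers.tsv"))
  write_tsv(community$genes[c("gene_id", "scaffold_id", "start", "end",
                              "strand")],
            file.path(dir, "genes.tsv"))
  write_tsv(community$links, file.path(dir, "links.tsv"))
  ex <- community$expression
  write_tsv(ex[c("gene_id", "dna_count", "rna_count")],
            file.path(dir, "expression.tsv"))
  jsonlite::write_json(list(
    scaffold_truth = community$scaffold_truth,
    gene_truth = community$genes,
    marker_truth = community$marker_truth,
    expression_totals = as.list(attr(ex, "totals")),
    models = lapply(community$models, function(m) {
      list(genome_id = m$genome_id, length = m$length,
           gc_content = m$gc_content,
           mean_coverage = as.list(m$mean_coverage),
           active_gene_fraction = m$active_gene_fraction,
           activity_mult = m$activity_mult)
    })), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
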