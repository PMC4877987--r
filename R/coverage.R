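#' Mapping summaries and coverage profiles
#'
#' A mapping summary holds, for one sample, the per-scaffold mapped-read and
#' mapped-base counts plus the library size (total reads). Coverage of a
#' scaffold in a sample is defined as the total base pairs of mapped reads
#' divided by scaffold length.
#'
#' @name coverage
NULL

#' Construct a mapping summary
#'
#' @param sample_id sample name.
#' @param records data.frame with columns `scaffold_id`, `mapped_reads`,
#'   `mapped_bases`.
#' @param total_reads library size (all reads in the sample, mapped or not).
#'   Multi-mapping means `total_reads >= sum(mapped_reads)` is not required,
#'   but no single scaffold may exceed the library size.
#' @return object of class `mapping_summary`.
#' @export
mapping_summary <- function(sample_id, records, total_reads) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  need <- c("scaffold_id", "mapped_reads", "mapped_bases")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$mapped_reads < 0) || any(records$mapped_bases < 0)) {
    stop("negative mapped_reads/mapped_bases", call. = FALSE)
  }
  if (nrow(records) && total_reads < max(records$mapped_reads)) {
    stop("total_reads smaller than a single scaffold's mapped_reads",
         call. = FALSE)
  }
  structure(list(sample_id = sample_id,
                 records = records[need],
                 total_reads = as.numeric(total_reads)),
            class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(sprintf("<mapping_summary> sample %s: %d scaffolds, %s total reads\n",
              x$sample_id, nrow(x$records),
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Coverage profiles from mapping summaries
#'
#' Builds the per-scaffold coverage table used for two-dimensional binning:
#' one row per scaffold with `cov_<sample>` (mapped_bases / length) and
#' `reads_<sample>` columns for every sample. Scaffolds absent from a
#' sample's mapping get coverage 0.
#'
#' @param mappings list of [mapping_summary()] objects (one per sample).
#' @param lengths named numeric vector: scaffold ID -> length in bp (> 0).
#' @return data.frame with columns `scaffold_id`, `length`, then
#'   `cov_<sample>` and `reads_<sample>` per sample, plus attribute
#'   `total_reads` (named vector per sample).
#' @export
coverage_profiles <- function(mappings, lengths) {
  if (inherits(mappings, "mapping_summary")) mappings <- list(mappings)
  stopifnot(length(mappings) >= 1, all(lengths > 0))
  ids <- names(lengths)
  if (is.null(ids)) stop("`lengths` must be named by scaffold ID", call. = FALSE)
  out <- data.frame(scaffold_id = ids, length = as.numeric(lengths),
                    row.names = NULL, stringsAsFactors = FALSE)
  totals <- numeric(0)
  for (m in mappings) {
    stopifnot(inherits(m, "mapping_summary"))
    unknown <- setdiff(m$records$scaffold_id, ids)
    if (length(unknown)) {
      stop("mapping for sample ", m$sample_id,
           " references scaffolds of unknown length: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    i <- match(ids, m$records$scaffold_id)
    bases <- ifelse(is.na(i), 0, m$records$mapped_bases[i])
    reads <- ifelse(is.na(i), 0, m$records$mapped_reads[i])
    out[[paste0("cov_", m$sample_id)]] <- bases / out$length
    out[[paste0("reads_", m$sample_id)]] <- reads
    totals[m$sample_id] <- m$total_reads
  }
  attr(out, "total_reads") <- totals
  out
}

#' Parse a SAM/BAM file into a mapping summary
#'
#' Counts primary, mapped records per reference scaffold; mapped bases are
#' the reference-consuming length of each alignment CIGAR (M/D/N/=/X).
#' Secondary and supplementary records are ignored so each read is counted
#' once at its primary position. `total_reads` is the number of distinct read
#' IDs in the file (unmapped records count towards the library size only).
#'
#' @param path SAM (text) or BAM file.
#' @param sample_id sample name for the summary (default: file base name).
#' @param min_mapped_fraction drop alignments whose query-consuming aligned
#'   length is below this fraction of the read length (default 0 = keep all).
#' @return a [mapping_summary()].
#' @export
parse_sam <- function(path, sample_id = NULL, min_mapped_fraction = 0) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sample_id <- sample_id %||% sub("\\.(sam|bam)$", "", basename(path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "cigar",
                                        "seq"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  total_reads <- length(unique(rec$qname))
  fl <- rec$flag
  primary_mapped <- !bitwAnd(fl, 0x4) & !bitwAnd(fl, 0x100) &
    !bitwAnd(fl, 0x800)
  keep <- primary_mapped
  if (min_mapped_fraction > 0 && any(keep)) {
    readlen <- Biostrings::width(rec$seq)[keep]
    frac <- GenomicAlignments::cigarWidthAlongQuerySpace(
      rec$cigar[keep], after.soft.clipping = TRUE) / readlen
    keep[keep] <- frac >= min_mapped_fraction
  }
  if (!any(keep)) {
    return(mapping_summary(sample_id,
                           data.frame(scaffold_id = character(),
                                      mapped_reads = integer(),
                                      mapped_bases = integer()),
                           total_reads))
  }
  ref <- as.character(rec$rname[keep])
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  records <- data.frame(
    scaffold_id = names(tapply(refw, ref, sum)),
    mapped_reads = as.integer(tapply(refw, ref, length)),
    mapped_bases = as.integer(tapply(refw, ref, sum)),
    row.names = NULL, stringsAsFactors = FALSE)
  mapping_summary(sample_id, records, total_reads)
}

#' Relative abundance of a bin in each metagenome
#'
#' The relative abundance of a genome bin in a sample is the number of reads
#' mapped to the bin's scaffolds as a percentage of the total number of reads
#' in that sample's library, reported to one decimal.
#'
#' @param bin a [genome_bin()] (or character vector of scaffold IDs).
#' @param mappings list of [mapping_summary()] objects.
#' @return named numeric vector: sample ID -> percentage (1 decimal).
#' @export
relative_abundance <- function(bin, mappings) {
  ids <- if (inherits(bin, "genome_bin")) bin$scaffold_ids else bin
  if (inherits(mappings, "mapping_summary")) mappings <- list(mappings)
  out <- numeric(0)
  for (m in mappings) {
    if (m$total_reads == 0) {
      stop("sample ", m$sample_id, " has total_reads = 0", call. = FALSE)
    }
    hit <- m$records$scaffold_id %in% ids
    out[m$sample_id] <- round_half_up(
      100 * sum(m$records$mapped_reads[hit]) / m$total_reads, 1)
  }
  out
}
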