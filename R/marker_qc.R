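#' Single-copy marker quality control
#'
#' Bin completeness is the percentage of the marker set's genes identified in
#' the bin; contamination ("redundancy") is the percentage of identified
#' markers that occur in two or more copies. Two marker sets ship with the
#' package: 107 essential single-copy genes (ESCGs, present once in >95 % of
#' bacterial genomes) and a 35-member conserved single-copy COG set used as a
#' cross-check. The shipped ID lists are synthetic placeholders of the
#' correct sizes (the canonical identifier lists are distributed with the
#' marker HMM collections, not here); any hit table whose marker IDs match a
#' loaded set works identically.
#'
#' @name marker_qc
NULL

#' Load a marker set
#'
#' @param set one of `"ESCG107"`, `"COG35"`, or a path to a text file with
#'   one marker ID per line.
#' @return object of class `marker_set` with fields `set_id`, `marker_ids`,
#'   `expected_size`.
#' @export
marker_set <- function(set = c("ESCG107", "COG35")) {
  if (length(set) == 1 && file.exists(set) &&
      !set %in% c("ESCG107", "COG35")) {
    ids <- readLines(set)
    set_id <- tools::file_path_sans_ext(basename(set))
  } else {
    set_id <- match.arg(set)
    f <- switch(set_id,
      ESCG107 = "escg107.synthetic_ids.txt",
      COG35 = "cog35.synthetic_ids.txt")
    ids <- readLines(system.file("extdata", "marker_sets", f,
                                 package = "covbinr", mustWork = TRUE))
  }
  ids <- unique(ids[nzchar(ids)])
  structure(list(set_id = set_id, marker_ids = ids,
                 expected_size = length(ids)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %s: %d markers\n", x$set_id, x$expected_size))
  invisible(x)
}

#' Marker hit table constructor
#'
#' @param gene_id,scaffold_id,marker_id character vectors (recycled to equal
#'   length); `score` optional numeric.
#' @return data.frame with one record per (gene, marker) assignment.
#' @export
marker_hits <- function(gene_id, scaffold_id, marker_id, score = NA_real_) {
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id,
                   scaffold_id = rep_len(scaffold_id, n),
                   marker_id = marker_id,
                   score = rep_len(score, n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("gene_id", "marker_id")])) {
    stop("duplicate (gene_id, marker_id) records", call. = FALSE)
  }
  df
}

#' Completeness of a bin from marker hits
#'
#' @param hits marker hit table restricted to the bin (data.frame with a
#'   `marker_id` column).
#' @param set a [marker_set()].
#' @return percentage of the set's markers identified at least once, full
#'   precision (reports round to 1 decimal via [qc_report()]).
#' @export
completeness <- function(hits, set) {
  found <- unique(hits$marker_id)
  stray <- setdiff(found, set$marker_ids)
  if (length(stray)) {
    stop("hits reference markers outside set ", set$set_id, ": ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  100 * length(found) / set$expected_size
}

#' Redundancy (contamination) of a bin from marker hits
#'
#' Duplicated markers are those present in two or more copies; redundancy is
#' duplicated markers divided by identified markers (0 when no marker is
#' identified, by convention).
#'
#' @inheritParams completeness
#' @return percentage, full precision.
#' @export
redundancy <- function(hits, set) {
  stray <- setdiff(unique(hits$marker_id), set$marker_ids)
  if (length(stray)) {
    stop("hits reference markers outside set ", set$set_id, ": ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  tab <- table(hits$marker_id)
  n_ident <- length(tab)
  if (n_ident == 0) return(0)
  100 * sum(tab >= 2) / n_ident
}

#' Quality-control report for a genome bin
#'
#' Restricts the hit table to the bin's scaffolds, computes completeness and
#' redundancy against the chosen marker set, and flags whether the bin meets
#' the draft-genome quality bar (completeness > 96 % and redundancy < 5 % by
#' default).
#'
#' @param bin a [genome_bin()] or character vector of scaffold IDs.
#' @param hits marker hit table (gene_id, scaffold_id, marker_id).
#' @param set a [marker_set()].
#' @param min_completeness,max_redundancy pass thresholds (percent).
#' @return list of class `qc_report`: `bin_id`, `marker_set_id`,
#'   `n_identified`, `n_duplicated`, `completeness_pct`, `redundancy_pct`
#'   (both rounded half away from zero to 1 decimal), `pass`.
#' @export
qc_report <- function(bin, hits, set, min_completeness = 96,
                      max_redundancy = 5) {
  ids <- if (inherits(bin, "genome_bin")) bin$scaffold_ids else bin
  bin_id <- if (inherits(bin, "genome_bin")) bin$bin_id else "bin"
  if (length(ids) == 0) {
    warning("empty bin ", bin_id, ": reporting 0/0", call. = FALSE)
    sub <- hits[0, , drop = FALSE]
  } else {
    sub <- hits[hits$scaffold_id %in% ids, , drop = FALSE]
  }
  tab <- table(sub$marker_id)
  comp <- completeness(sub, set)
  red <- redundancy(sub, set)
  structure(list(
    bin_id = bin_id,
    marker_set_id = set$set_id,
    n_identified = length(tab),
    n_duplicated = sum(tab >= 2),
    completeness_pct = round_half_up(comp, 1),
    redundancy_pct = round_half_up(red, 1),
    pass = comp > min_completeness && red < max_redundancy
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %s [%s]: completeness %.1f%% (%d markers), redundancy %.1f%% (%d duplicated) -> %s\n",
    x$bin_id, x$marker_set_id, x$completeness_pct, x$n_identified,
    x$redundancy_pct, x$n_duplicated, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Load HMMER3 per-target tabular output as a marker hit table
#'
#' Reads `hmmsearch --tblout` style whitespace-delimited output (target =
#' gene, query = marker profile), drops hits below the score threshold, and
#' keeps only the best-scoring marker per gene so a single gene never counts
#' towards two markers.
#'
#' @param path tblout file.
#' @param score_threshold minimum full-sequence bit score (default 0).
#' @return marker hit table (gene_id, scaffold_id = NA, marker_id, score);
#'   scaffold IDs must be joined from a gene table by the caller.
#' @export
load_hmmer_tblout <- function(path, score_threshold = 0) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(marker_hits(character(), character(), character(), numeric()))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(fields) < 6)
  if (length(bad)) {
    stop("malformed tblout line ", bad[1], ": fewer than 6 fields",
         call. = FALSE)
  }
  gene <- vapply(fields, `[[`, "", 1)
  marker <- vapply(fields, `[[`, "", 3)
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6)))
  if (anyNA(score)) {
    stop("malformed tblout line ", which(is.na(score))[1],
         ": non-numeric score", call. = FALSE)
  }
  keep <- score >= score_threshold
  gene <- gene[keep]; marker <- marker[keep]; score <- score[keep]
  # best-scoring marker per gene
  o <- order(gene, -score, marker)
  first <- !duplicated(gene[o])
  marker_hits(gene[o][first], NA_character_, marker[o][first], score[o][first])
}
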