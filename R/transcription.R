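#' Transcriptional activity from paired DNA/RNA counts
#'
#' RPKM (reads per kilobase of gene per million mapped reads) is computed
#' separately from the metagenome (RPKM-DNA) and the metatranscriptome
#' (RPKM-RNA); their ratio, MRPKM, measures per-gene transcriptional
#' activity normalised for gene dosage. Genes with zero DNA coverage have
#' undefined MRPKM (flagged, never silently 0): a zero MRPKM means the gene
#' is present but untranscribed, while an undefined one means dosage cannot
#' be estimated.
#'
#' @name transcription
NULL

#' Reads per kilobase per million mapped reads
#'
#' @param count mapped-read count(s) for the gene.
#' @param length_bp gene length(s) in bp (> 0).
#' @param total_mapped_reads library size (> 0).
#' @return `1e9 * count / (length_bp * total_mapped_reads)`.
#' @examples
#' rpkm(1, 1000, 1e6)  # 1
#' @export
rpkm <- function(count, length_bp, total_mapped_reads) {
  if (any(length_bp <= 0)) stop("`length_bp` must be > 0", call. = FALSE)
  if (any(total_mapped_reads <= 0)) {
    stop("`total_mapped_reads` must be > 0", call. = FALSE)
  }
  1e9 * count / (length_bp * total_mapped_reads)
}

#' MRPKM: ratio of RPKM-RNA to RPKM-DNA
#'
#' @param dna_count,rna_count per-gene mapped-read counts.
#' @param length_bp gene length(s); cancels algebraically but is accepted
#'   for interface symmetry.
#' @param dna_total,rna_total library sizes (> 0).
#' @return numeric vector; `NA` (undefined) where the DNA RPKM is zero.
#' @export
mrpkm <- function(dna_count, rna_count, length_bp, dna_total, rna_total) {
  d <- rpkm(dna_count, length_bp, dna_total)
  r <- rpkm(rna_count, length_bp, rna_total)
  ifelse(d > 0, r / d, NA_real_)
}

#' Per-gene activity table
#'
#' @param expression data.frame (gene_id, dna_count, rna_count) and either
#'   a `length_bp` column or lengths joined from `genes`.
#' @param genes optional gene table (gene_id, start, end) supplying lengths.
#' @param dna_total,rna_total library sizes; default to the column sums of
#'   the count columns.
#' @return data.frame (gene_id, length_bp, rpkm_dna, rpkm_rna, mrpkm,
#'   defined) where `defined` is FALSE iff RPKM-DNA is zero (there `mrpkm`
#'   is `NA`).
#' @export
activity_table <- function(expression, genes = NULL, dna_total = NULL,
                           rna_total = NULL) {
  ex <- expression
  if (!"length_bp" %in% names(ex)) {
    if (is.null(genes)) {
      stop("supply a `length_bp` column or a `genes` table", call. = FALSE)
    }
    i <- match(ex$gene_id, genes$gene_id)
    if (anyNA(i)) {
      stop("genes absent from the gene table: ",
           paste(utils::head(ex$gene_id[is.na(i)], 5), collapse = ", "),
           call. = FALSE)
    }
    ex$length_bp <- genes$end[i] - genes$start[i] + 1
  }
  dna_total <- dna_total %||% sum(ex$dna_count)
  rna_total <- rna_total %||% sum(ex$rna_count)
  d <- rpkm(ex$dna_count, ex$length_bp, dna_total)
  r <- rpkm(ex$rna_count, ex$length_bp, rna_total)
  data.frame(gene_id = ex$gene_id, length_bp = ex$length_bp,
             rpkm_dna = d, rpkm_rna = r,
             mrpkm = ifelse(d > 0, r / d, NA_real_),
             defined = d > 0, stringsAsFactors = FALSE)
}

#' Fraction of a bin's genes with detected transcription
#'
#' @param gene_ids genes belonging to the bin.
#' @param activity table from [activity_table()].
#' @param active_threshold a gene counts as transcribed when its MRPKM
#'   exceeds this (default 0: any detected transcript). Undefined MRPKM
#'   never counts as transcribed.
#' @return list: `pct_transcribed` (percentage of the bin's genes, 1
#'   decimal), `n_active`, `n_genes`, `genes` (the bin's activity rows).
#' @export
bin_activity_summary <- function(gene_ids, activity, active_threshold = 0) {
  sub <- activity[activity$gene_id %in% gene_ids, , drop = FALSE]
  missing_genes <- setdiff(gene_ids, activity$gene_id)
  if (length(missing_genes)) {
    stop("genes absent from the activity table: ",
         paste(utils::head(missing_genes, 5), collapse = ", "),
         call. = FALSE)
  }
  act <- !is.na(sub$mrpkm) & sub$mrpkm > active_threshold
  list(pct_transcribed = round_half_up(100 * sum(act) / nrow(sub), 1),
       n_active = sum(act), n_genes = nrow(sub), genes = sub)
}

#' Aggregate MRPKM over a gene group
#'
#' Supports gene-cluster scores (e.g. all pilin homologs of a genome as a
#' single value). The default aggregation is the sum over the group's
#' defined MRPKM values; mean is available.
#'
#' @param gene_ids non-empty group of genes.
#' @param activity table from [activity_table()].
#' @param aggregation `"sum"` (default) or `"mean"`.
#' @return single numeric; `NA` (flagged by attribute `defined = FALSE`)
#'   when every member's MRPKM is undefined.
#' @export
gene_group_activity <- function(gene_ids, activity,
                                aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  if (!length(gene_ids)) stop("empty gene group", call. = FALSE)
  sub <- activity[activity$gene_id %in% gene_ids, , drop = FALSE]
  v <- sub$mrpkm[!is.na(sub$mrpkm)]
  if (!length(v)) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(switch(aggregation, sum = sum(v), mean = mean(v)),
            defined = TRUE)
}
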