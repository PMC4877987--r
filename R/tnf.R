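#' Canonical tetranucleotide machinery
#'
#' Assembled scaffolds have arbitrary strand, so 4-mers are collapsed with
#' their reverse complements: the canonical form of a 4-mer is the
#' lexicographically smaller of the 4-mer and its reverse complement. Over the
#' 256 possible 4-mers this yields 136 canonical ones (16 reverse-complement
#' palindromes plus 240/2 collapsed pairs).
#'
#' @name tnf
NULL

#' Canonical form of a 4-mer
#'
#' @param kmer character vector of 4-letter DNA strings over A/C/G/T.
#' @return character vector: for each input, the lexicographic minimum of the
#'   4-mer and its reverse complement. Idempotent.
#' @examples
#' canonical_kmer("TTTT")  # "AAAA"
#' canonical_kmer("ACGT")  # "ACGT" (its own reverse complement)
#' @export
canonical_kmer <- function(kmer) {
  if (!is.character(kmer) || any(nchar(kmer) != 4) ||
      any(grepl("[^ACGT]", kmer))) {
    stop("`kmer` must be 4-letter strings over A/C/G/T (ambiguous bases are ",
         "skipped by callers, not canonicalised)", call. = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmer)))
  ifelse(kmer <= rc, kmer, rc)
}

#' The 136 canonical 4-mers, lexicographically ordered
#'
#' @return character vector of length 136; the fixed column order of every
#'   TNF vector produced by this package.
#' @export
canonical_kmers <- function() {
  all4 <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
  sort(unique(canonical_kmer(all4)))
}

#' Tetranucleotide frequency vector of a sequence
#'
#' Slides a 4 bp window with step 1; windows containing ambiguous bases are
#' skipped; each valid window's canonical 4-mer is counted and counts are
#' normalised to frequencies summing to 1.
#'
#' @param sequence a single DNA string or [Biostrings::DNAString].
#' @return named numeric vector of length 136 (names from
#'   [canonical_kmers()]), frequencies summing to 1.
#' @seealso [tnf_vectors()] for a whole FASTA/`DNAStringSet`.
#' @export
tnf_vector <- function(sequence) {
  seq <- if (methods::is(sequence, "DNAString")) sequence
         else Biostrings::DNAString(as.character(sequence))
  counts <- Biostrings::oligonucleotideFrequency(seq, width = 4, step = 1)
  total <- sum(counts)
  if (total == 0) {
    stop("sequence has no valid (unambiguous) 4 bp window", call. = FALSE)
  }
  canon <- canonical_kmer(names(counts))
  v <- vapply(split(counts, canon), sum, numeric(1))[canonical_kmers()]
  v / total
}

#' TNF vectors for a set of scaffolds
#'
#' @param scaffolds a named [Biostrings::DNAStringSet] (or named character
#'   vector of sequences).
#' @return numeric matrix, one row per scaffold (rownames = scaffold IDs),
#'   136 columns named by canonical 4-mer.
#' @export
tnf_vectors <- function(scaffolds) {
  if (is.character(scaffolds)) scaffolds <- Biostrings::DNAStringSet(scaffolds)
  if (is.null(names(scaffolds))) {
    stop("scaffolds must be named", call. = FALSE)
  }
  counts <- Biostrings::oligonucleotideFrequency(scaffolds, width = 4, step = 1)
  canon <- canonical_kmer(colnames(counts))
  m <- t(apply(counts, 1, function(r) {
    vapply(split(r, canon), sum, numeric(1))[canonical_kmers()]
  }))
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("scaffold(s) with no valid 4 bp window: ",
         paste(names(scaffolds)[tot == 0], collapse = ", "), call. = FALSE)
  }
  m <- m / tot
  rownames(m) <- names(scaffolds)
  colnames(m) <- canonical_kmers()
  m
}

#' Euclidean distance between two TNF vectors
#'
#' @param v1,v2 numeric vectors of length 136.
#' @return non-negative L2 distance; symmetric; zero iff equal.
#' @export
tnf_distance <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  sqrt(sum((v1 - v2)^2))
}

#' Refine a bin by TNF hierarchical clustering
#'
#' Agglomerative hierarchical clustering of the scaffolds' TNF vectors
#' (Euclidean distance), cut at height `cutoff`; the cluster with the largest
#' total scaffold length is kept as the bin core and every other cluster is
#' removed as putative contamination. Ties on total length break by scaffold
#' count, then by smallest scaffold ID.
#'
#' The distance scale on which the cutoff is applied is configurable:
#' `"fraction"` (default) uses frequencies summing to 1, `"percent"`
#' multiplies them by 100, `"zscore"` standardises each 4-mer column across
#' the input scaffolds.
#'
#' @param scaffold_ids character vector of members to refine (must be rownames
#'   of `tnf`).
#' @param tnf TNF matrix from [tnf_vectors()].
#' @param lengths named integer vector of scaffold lengths (bp).
#' @param cutoff tree-cut height; default 0.1 on the fraction scale.
#' @param linkage `"average"` (default) or `"complete"`.
#' @param scaling `"fraction"`, `"percent"` or `"zscore"`.
#' @return list with `kept` and `removed` character vectors (disjoint,
#'   exhaustive), `log` data.frame of removals with the merge height at which
#'   each removed scaffold last joined the tree, and the `hclust` object.
#' @export
tnf_refine <- function(scaffold_ids, tnf, lengths, cutoff = 0.1,
                       linkage = c("average", "complete"),
                       scaling = c("fraction", "percent", "zscore")) {
  linkage <- match.arg(linkage)
  scaling <- match.arg(scaling)
  if (length(scaffold_ids) < 2) {
    stop("refinement needs at least 2 scaffolds", call. = FALSE)
  }
  if (!is.numeric(cutoff) || cutoff <= 0) {
    stop("`cutoff` must be > 0", call. = FALSE)
  }
  missing_ids <- setdiff(scaffold_ids, rownames(tnf))
  if (length(missing_ids)) {
    stop("no TNF vector for: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  m <- tnf[scaffold_ids, , drop = FALSE]
  m <- switch(scaling,
    fraction = m,
    percent = m * 100,
    zscore = {
      s <- scale(m)
      s[, apply(m, 2, stats::sd) == 0] <- 0
      s
    })
  hc <- stats::hclust(stats::dist(m), method = linkage)
  cl <- if (is.finite(cutoff)) stats::cutree(hc, h = cutoff)
        else rep(1L, length(scaffold_ids))
  len <- lengths[scaffold_ids]
  tot <- tapply(len, cl, sum)
  cnt <- tapply(len, cl, length)
  first_id <- tapply(scaffold_ids, cl, function(x) min(x))
  ord <- order(-tot, -cnt, first_id)
  core <- as.integer(names(tot)[ord][1])
  kept <- scaffold_ids[cl == core]
  removed <- scaffold_ids[cl != core]
  log <- if (length(removed)) {
    data.frame(scaffold_id = removed,
               merge_height = vapply(removed, function(s) {
                 leaf <- match(s, scaffold_ids)
                 h <- hc$height[apply(hc$merge, 1, function(r) -leaf %in% r)]
                 if (length(h)) h[1] else NA_real_
               }, numeric(1)),
               row.names = NULL)
  } else {
    data.frame(scaffold_id = character(), merge_height = numeric())
  }
  list(kept = kept, removed = removed, log = log, hclust = hc)
}
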