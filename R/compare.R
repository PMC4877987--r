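#' Pairwise genome comparison
#'
#' Fragment-based average nucleotide identity (ANI), bidirectional-best-hit
#' (BBH) shared-gene counts, within-genome duplicated-gene counts, and
#' species-level classification against the conventional thresholds
#' (ANI 94 %, DDH 70 %).
#'
#' @name genome_compare
NULL

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

cut_fragments <- function(seqs, fragment_len) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (methods::is(seqs, "DNAString")) seqs <- Biostrings::DNAStringSet(seqs)
  frags <- Biostrings::DNAStringSet()
  for (i in seq_along(seqs)) {
    w <- Biostrings::width(seqs)[i]
    starts <- seq(1, w, by = fragment_len)
    ends <- pmin(starts + fragment_len - 1, w)
    keep <- (ends - starts + 1) >= min(fragment_len, 100)
    if (!any(keep)) next
    f <- Biostrings::DNAStringSet(seqs[[i]], start = starts[keep],
                                  end = ends[keep])
    names(f) <- sprintf("frag_%d_%d", i, which(keep))
    frags <- c(frags, f)
  }
  frags
}

#' Fragment-based average nucleotide identity
#'
#' Genome A is cut into consecutive fragments of `fragment_len`; each
#' fragment is aligned locally against genome B (best match by bit score);
#' fragments with percent identity >= `min_identity_pct` and aligned
#' fraction >= `min_frag_cov` are retained, and ANI is the mean identity of
#' the retained fragments. The symmetric ANI (default headline value)
#' averages the two directions. Alignment is delegated to NCBI blastn on
#' temporary files.
#'
#' @param genome_a,genome_b [Biostrings::DNAStringSet] (or DNAString /
#'   character) sequence sets.
#' @param fragment_len fragment size in bp (>= 100; default 1020, the
#'   classical convention).
#' @param min_identity_pct discard fragment matches below this percent
#'   identity (default 60).
#' @param min_frag_cov discard fragment matches aligned over less than this
#'   fraction of the fragment (default 0.70).
#' @return list of class `ani_result`: `ani` (symmetric, percent), `ab` and
#'   `ba` (directional), `n_fragments_used` (per direction),
#'   `indeterminate` (TRUE when no fragment survives the filters in either
#'   direction, in which case `ani` is `NA`).
#' @export
ani <- function(genome_a, genome_b, fragment_len = 1020,
                min_identity_pct = 60, min_frag_cov = 0.70) {
  if (fragment_len < 100) stop("`fragment_len` must be >= 100", call. = FALSE)
  if (!blast_available()) {
    stop("blastn/makeblastdb not found on PATH; supply precomputed ",
         "alignments via ani_from_hits()", call. = FALSE)
  }
  dir_ani <- function(qa, sb) {
    frags <- cut_fragments(qa, fragment_len)
    if (!length(frags)) return(list(ani = NA_real_, n = 0L))
    hits <- blastn_tab(frags, sb)
    ani_from_hits(hits, Biostrings::width(frags),
                  min_identity_pct = min_identity_pct,
                  min_frag_cov = min_frag_cov)
  }
  ab <- dir_ani(genome_a, genome_b)
  ba <- dir_ani(genome_b, genome_a)
  vals <- c(ab$ani, ba$ani)
  structure(list(ani = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
                 ab = ab$ani, ba = ba$ani,
                 n_fragments_used = c(ab = ab$n, ba = ba$n),
                 indeterminate = all(is.na(vals))),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  if (x$indeterminate) cat("<ani_result> indeterminate (no fragment passed filters)\n")
  else cat(sprintf("<ani_result> ANI %.1f%% (A->B %.1f, B->A %.1f; %d/%d fragments)\n",
                   x$ani, x$ab, x$ba, x$n_fragments_used[1],
                   x$n_fragments_used[2]))
  invisible(x)
}

# run blastn (task blastn, no dusting) of query set against subject set,
# returning the best hit per query as a data.frame
blastn_tab <- function(query, subject) {
  td <- tempfile("ani"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "q.fasta"); sf <- file.path(td, "s.fasta")
  if (is.null(names(subject))) names(subject) <- sprintf("subj_%d", seq_along(subject))
  Biostrings::writeXStringSet(query, qf)
  Biostrings::writeXStringSet(subject, sf)
  db <- file.path(td, "db")
  st <- system2("makeblastdb", c("-in", sf, "-dbtype", "nucl", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("makeblastdb failed", call. = FALSE)
  out <- file.path(td, "hits.tsv")
  st <- system2("blastn", c("-task", "blastn", "-dust", "no",
                            "-query", qf, "-db", db, "-out", out,
                            "-outfmt", shQuote("6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore"),
                            "-max_target_seqs", "5"),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("blastn failed", call. = FALSE)
  hits <- read_blast_tab(out)
  if (!nrow(hits)) return(hits)
  # best hit per query by bitscore
  o <- order(hits$query_id, -hits$bitscore)
  hits <- hits[o, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' ANI from precomputed fragment alignments
#'
#' @param hits data.frame of best fragment alignments with columns
#'   `query_id`, `percent_identity`, `alignment_length` (e.g. from
#'   [read_blast_tab()], one row per fragment).
#' @param fragment_lengths named (by `query_id`) or unnamed vector of
#'   fragment lengths; unnamed vectors are matched positionally to
#'   `frag_*` ids.
#' @inheritParams ani
#' @return list(ani = mean identity of retained fragments (NA if none),
#'   n = number retained).
#' @export
ani_from_hits <- function(hits, fragment_lengths, min_identity_pct = 60,
                          min_frag_cov = 0.70) {
  if (!nrow(hits)) return(list(ani = NA_real_, n = 0L))
  flen <- if (!is.null(names(fragment_lengths))) {
    fragment_lengths[hits$query_id]
  } else {
    fragment_lengths[match(hits$query_id, unique(hits$query_id))]
  }
  keep <- hits$percent_identity >= min_identity_pct &
    hits$alignment_length / flen >= min_frag_cov
  if (!any(keep)) return(list(ani = NA_real_, n = 0L))
  list(ani = mean(hits$percent_identity[keep]), n = sum(keep))
}

#' Read BLAST 12-column tabular output
#'
#' Standard outfmt 6 columns, with optional 13th/14th `qlen`/`slen` columns
#' recognised when present.
#'
#' @param path tabular alignment file.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore` and, when
#'   present, `query_length`, `subject_length`.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "mismatches", "gap_opens", "q_start",
            "q_end", "s_start", "s_end", "evalue", "bitscore")
  if (!file.size(path)) {
    out <- as.data.frame(stats::setNames(
      c(replicate(2, character(), simplify = FALSE),
        replicate(10, numeric(), simplify = FALSE)), cols))
    return(out)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected >= 12 tab-separated columns", call. = FALSE)
  extra <- c("query_length", "subject_length")
  names(df) <- c(cols, extra[seq_len(ncol(df) - 12)])
  df
}

default_bbh_filters <- function() {
  list(min_bitscore = 70, min_identity = 30, min_query_cov = 0.70)
}

apply_hit_filters <- function(hits, filters, query_lengths = NULL) {
  f <- utils::modifyList(default_bbh_filters(), filters %||% list())
  if (!nrow(hits)) return(hits)
  qlen <- hits$query_length %||% query_lengths[hits$query_id]
  if (is.null(qlen)) {
    stop("query lengths required for coverage filtering: supply a ",
         "`query_length` column or the `query_lengths` argument",
         call. = FALSE)
  }
  qcov <- (hits$query_aligned %||% hits$alignment_length) / qlen
  hits[hits$bitscore >= f$min_bitscore &
         hits$percent_identity >= f$min_identity &
         qcov >= f$min_query_cov, , drop = FALSE]
}

best_hit_per_query <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$query_id, -hits$bitscore, -hits$percent_identity,
             hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Bidirectional-best-hit shared genes between two genomes
#'
#' Both hit tables are filtered (bit score >= 70, identity >= 30 %, aligned
#' over >= 70 % of the query by default, thresholds inclusive); the best hit
#' per query is kept (bit score, then identity, then lexicographically
#' smallest subject); a gene pair (a, b) is shared iff a's best hit is b and
#' b's best hit is a.
#'
#' @param hits_ab,hits_ba alignment tables oriented A->B and B->A
#'   ([read_blast_tab()] layout; a `query_length` column, or the
#'   `*_query_lengths` arguments, supplies coverage denominators).
#' @param filters named list overriding `min_bitscore`, `min_identity`,
#'   `min_query_cov`.
#' @param ab_query_lengths,ba_query_lengths named vectors of query lengths,
#'   used when the tables carry no `query_length` column.
#' @return list: `n_shared`, `pairs` (data.frame gene_a, gene_b).
#' @export
bbh_shared_genes <- function(hits_ab, hits_ba, filters = list(),
                             ab_query_lengths = NULL,
                             ba_query_lengths = NULL) {
  ab <- best_hit_per_query(apply_hit_filters(hits_ab, filters,
                                             ab_query_lengths))
  ba <- best_hit_per_query(apply_hit_filters(hits_ba, filters,
                                             ba_query_lengths))
  if (!nrow(ab) || !nrow(ba)) {
    return(list(n_shared = 0L,
                pairs = data.frame(gene_a = character(),
                                   gene_b = character())))
  }
  back <- stats::setNames(ba$subject_id, ba$query_id)
  mutual <- !is.na(back[ab$subject_id]) & back[ab$subject_id] == ab$query_id
  pairs <- data.frame(gene_a = ab$query_id[mutual],
                      gene_b = ab$subject_id[mutual],
                      stringsAsFactors = FALSE)
  list(n_shared = nrow(pairs), pairs = pairs)
}

#' Duplicated genes within one genome
#'
#' A gene is duplicated iff it has at least one non-self alignment hit
#' passing the filters (bit score >= 70, identity >= 30 %, >= 70 % query
#' coverage by default).
#'
#' @param self_hits within-genome alignment table ([read_blast_tab()]
#'   layout); self-matches (query == subject) are ignored.
#' @param n_genes total number of protein-coding genes, the percentage
#'   denominator.
#' @param filters,query_lengths as in [bbh_shared_genes()].
#' @return list: `n_duplicated`, `pct_duplicated` (1 decimal),
#'   `duplicated_genes` (character).
#' @export
duplicated_genes <- function(self_hits, n_genes, filters = list(),
                             query_lengths = NULL) {
  h <- self_hits[self_hits$query_id != self_hits$subject_id, , drop = FALSE]
  h <- apply_hit_filters(h, filters, query_lengths)
  dup <- unique(h$query_id)
  list(n_duplicated = length(dup),
       pct_duplicated = round_half_up(100 * length(dup) / n_genes, 1),
       duplicated_genes = dup)
}

#' Species-level classification from ANI (and optional DDH)
#'
#' Two genomes represent different species when ANI < 94 % (corroborated by
#' DDH < 70 % when a DDH estimate is supplied); the same species when
#' ANI >= 94 % and DDH (if given) >= 70 %; conflicting evidence is
#' indeterminate.
#'
#' @param ani_pct ANI in `[0, 100]`.
#' @param ddh_pct optional in silico DNA-DNA hybridisation estimate (this
#'   package never computes DDH; it is an input only).
#' @param ani_threshold,ddh_threshold species boundaries (defaults 94, 70).
#' @return list of class `species_call`: `ani_pct`, `ddh_pct`, `verdict`
#'   (`"same_species"`, `"different_species"` or `"indeterminate"`).
#' @export
classify_species <- function(ani_pct, ddh_pct = NULL, ani_threshold = 94,
                             ddh_threshold = 70) {
  if (!is.numeric(ani_pct) || length(ani_pct) != 1 || is.na(ani_pct) ||
      ani_pct < 0 || ani_pct > 100) {
    stop("`ani_pct` must be a single value in [0, 100]", call. = FALSE)
  }
  if (!is.null(ddh_pct) &&
      (!is.numeric(ddh_pct) || ddh_pct < 0 || ddh_pct > 100)) {
    stop("`ddh_pct` must be in [0, 100]", call. = FALSE)
  }
  ani_low <- ani_pct < ani_threshold
  ddh_low <- if (is.null(ddh_pct)) NULL else ddh_pct < ddh_threshold
  verdict <- if (is.null(ddh_low)) {
    if (ani_low) "different_species" else "same_species"
  } else if (ani_low && ddh_low) {
    "different_species"
  } else if (!ani_low && !ddh_low) {
    "same_species"
  } else {
    "indeterminate"
  }
  structure(list(ani_pct = ani_pct, ddh_pct = ddh_pct, verdict = verdict),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("<species_call> ANI %.1f%%%s -> %s\n", x$ani_pct,
              if (is.null(x$ddh_pct)) "" else sprintf(", DDH %.1f%%", x$ddh_pct),
              x$verdict))
  invisible(x)
}
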