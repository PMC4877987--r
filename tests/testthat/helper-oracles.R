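# Independent oracles, deliberately built without the package's TNF /
# clustering / BBH code paths.

# reverse complement of 4-mers by hand
rc4 <- function(kmers) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(kmers, ""), function(x) {
    paste(rev(comp[x]), collapse = "")
  }, character(1))
}

# canonical map for all 256 4-mers, derived independently
canonical_map_oracle <- function() {
  b <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(b, b, b, b, stringsAsFactors = FALSE), 1,
                paste, collapse = "")
  stats::setNames(pmin(all4, rc4(all4)), all4)
}

# naive dictionary-count TNF vector
naive_tnf <- function(seq_chr) {
  map <- canonical_map_oracle()
  n <- nchar(seq_chr)
  kmers <- substring(seq_chr, 1:(n - 3), 4:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  counts <- table(factor(map[kmers], levels = sort(unique(map))))
  as.numeric(counts) / sum(counts)
}

# naive agglomerative average-linkage clustering: merge the closest pair of
# clusters (mean pairwise distance) until the minimum exceeds `cutoff`;
# returns cluster membership as a list of id vectors
naive_average_linkage_cut <- function(d, ids, cutoff) {
  d <- as.matrix(d)
  clusters <- as.list(ids)
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    if (best_h > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  clusters
}

# exhaustive double-loop bidirectional-best-hit oracle
bbh_oracle <- function(hits_ab, hits_ba, min_bitscore = 70,
                       min_identity = 30, min_query_cov = 0.70) {
  best <- function(h) {
    h <- h[h$bitscore >= min_bitscore & h$percent_identity >= min_identity &
             h$alignment_length / h$query_length >= min_query_cov, ]
    out <- character(0)
    for (q in unique(h$query_id)) {
      sub <- h[h$query_id == q, ]
      sub <- sub[order(-sub$bitscore, -sub$percent_identity,
                       sub$subject_id), ]
      out[q] <- sub$subject_id[1]
    }
    out
  }
  fa <- best(hits_ab); fb <- best(hits_ba)
  pairs <- list()
  for (a in names(fa)) {
    b <- fa[[a]]
    if (!is.na(fb[b]) && identical(unname(fb[b]), a)) {
      pairs[[a]] <- c(a, b)
    }
  }
  do.call(rbind, pairs)
}

# random alignment table generator for BBH tests
random_hits <- function(n_q, n_s, n_hits, seed, qprefix = "a",
                        sprefix = "b") {
  set.seed(seed)
  data.frame(
    query_id = paste0(qprefix, sample(n_q, n_hits, replace = TRUE)),
    subject_id = paste0(sprefix, sample(n_s, n_hits, replace = TRUE)),
    percent_identity = round(runif(n_hits, 20, 100), 1),
    alignment_length = sample(100:900, n_hits, replace = TRUE),
    bitscore = round(runif(n_hits, 40, 300), 1),
    query_length = 900,
    stringsAsFactors = FALSE)
}

random_dna <- function(n, gc = 0.5, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
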