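#' Synthetic metagenomic community generator
#'
#' Generates a fully labelled synthetic community — genomes, fragmented
#' scaffolds, per-sample mapping summaries, planted single-copy markers,
#' paired-end links, and DNA/RNA gene counts — with the statistical
#' structure differential-coverage binning assumes: genomes distinguished by
#' their per-sample coverage pair and by base composition. Every object
#' carries ground truth so parameter recovery can be measured exactly.
#'
#' @name synthetic_community
NULL

#' Describe one genome of a synthetic community
#'
#' @param genome_id genome name.
#' @param length genome length in bp (>= 10,000).
#' @param gc_content GC fraction in (0, 1).
#' @param mean_coverage named numeric vector, sample ID -> mean read depth
#'   (x); all > 0.
#' @param active_gene_fraction fraction of the genome's genes transcribed.
#' @param activity_mult relative transcription level of this genome's active
#'   genes (scales RNA counts).
#' @return object of class `genome_model`.
#' @export
genome_model <- function(genome_id, length, gc_content, mean_coverage,
                         active_gene_fraction = 0.3, activity_mult = 1) {
  stopifnot(is.character(genome_id), length(genome_id) == 1)
  if (!is.numeric(length) || length < 10000) {
    stop("genome `length` must be >= 10,000 bp", call. = FALSE)
  }
  assert_scalar_fraction(gc_content, "gc_content")
  if (is.null(names(mean_coverage)) || any(mean_coverage <= 0)) {
    stop("`mean_coverage` must be a named vector of positive depths",
         call. = FALSE)
  }
  assert_scalar_fraction(active_gene_fraction, "active_gene_fraction",
                         open = FALSE)
  structure(list(genome_id = genome_id, length = as.integer(length),
                 gc_content = gc_content, mean_coverage = mean_coverage,
                 active_gene_fraction = active_gene_fraction,
                 activity_mult = activity_mult),
            class = "genome_model")
}

#' Simulate a genome sequence
#'
#' Order-0 composition model: bases drawn i.i.d. with
#' P(G) + P(C) = `gc_content`, split evenly within the GC and AT pairs. An
#' order-3 Markov option (`order = 3`, homopolymer-biased) produces
#' sequences with a stronger tetranucleotide signature for harder
#' composition-refinement tests.
#'
#' @param genome_id used only for error messages.
#' @param length sequence length (>= 10,000).
#' @param gc_content GC fraction in (0, 1).
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param order 0 (default, i.i.d.) or 3 (adds a stay-probability bias that
#'   extends homopolymer runs while preserving expected GC).
#' @return a [Biostrings::DNAString].
#' @export
simulate_genome <- function(genome_id, length, gc_content, seed, order = 0) {
  if (!is.numeric(length) || length < 10000) {
    stop("genome ", genome_id, ": `length` must be >= 10,000", call. = FALSE)
  }
  assert_scalar_fraction(gc_content, "gc_content")
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  bases <- names(p)
  chars <- with_seed(seed, {
    if (order == 0) {
      sample(bases, length, replace = TRUE, prob = p)
    } else {
      # stay with the previous base w.p. `stay`, else redraw from p: the
      # stationary distribution stays p but runs lengthen, enriching
      # homopolymer 4-mers
      stay <- 0.55
      x <- sample(bases, length, replace = TRUE, prob = p)
      redraw <- stats::runif(length) >= stay
      for (i in 2:length) if (!redraw[i]) x[i] <- x[i - 1]
      x
    }
  })
  Biostrings::DNAString(paste(chars, collapse = ""))
}

#' Fragment a genome into scaffolds
#'
#' Non-overlapping tiling: scaffold lengths are min_len plus an exponential
#' excess with the requested mean; a terminal remainder shorter than
#' `min_len` is merged into the last scaffold, so concatenating the
#' scaffolds in order reconstructs the genome exactly. Adjacency (fragment
#' order) is recorded for paired-end link simulation.
#'
#' @param sequence genome sequence ([Biostrings::DNAString] or string).
#' @param genome_id genome the scaffolds descend from.
#' @param min_len minimum scaffold length (>= 1000; assemblies below 1 kb
#'   are discarded upstream of binning).
#' @param mean_len target mean scaffold length.
#' @param seed integer seed.
#' @param prefix scaffold ID prefix (default `"s_<genome_id>"`).
#' @return list: `scaffolds` (named [Biostrings::DNAStringSet]) and `truth`
#'   (data.frame scaffold_id, genome_id, ord, start, end, length).
#' @export
fragment_genome <- function(sequence, genome_id, min_len = 1000,
                            mean_len = 20000, seed = 1,
                            prefix = paste0("s_", genome_id)) {
  if (min_len < 1000) stop("`min_len` must be >= 1000", call. = FALSE)
  seq <- if (methods::is(sequence, "DNAString")) sequence
         else Biostrings::DNAString(as.character(sequence))
  n <- length(seq)
  if (n < min_len) {
    stop("genome ", genome_id, " (", n, " bp) shorter than min_len",
         call. = FALSE)
  }
  lens <- with_seed(seed, {
    out <- integer(0); left <- n
    while (left >= min_len) {
      l <- min_len + round(stats::rexp(1, rate = 1 / max(mean_len - min_len, 1)))
      l <- min(l, left)
      if (left - l < min_len) l <- left  # absorb remainder
      out <- c(out, l); left <- left - l
    }
    out
  })
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  ids <- sprintf("%s_%03d", prefix, seq_along(lens))
  scaffolds <- Biostrings::DNAStringSet(seq, start = starts, end = ends)
  names(scaffolds) <- ids
  list(scaffolds = scaffolds,
       truth = data.frame(scaffold_id = ids, genome_id = genome_id,
                          ord = seq_along(lens), start = starts, end = ends,
                          length = lens, stringsAsFactors = FALSE))
}

#' Simulate per-sample read-mapping summaries
#'
#' For scaffold s of genome g in sample t, the mapped-read count is drawn
#' Poisson with mean `coverage[g][t] * length(s) / read_len`, and mapped
#' bases are count * read_len, so downstream coverage recovers the
#' generating depth. The library size is the mapped total inflated by
#' 1 / `mapped_fraction` (real metagenome assemblies capture only part of
#' the library; 0.87 by default).
#'
#' @param scaffold_truth truth data.frame from [fragment_genome()] (rows for
#'   all genomes combined).
#' @param models list of [genome_model()] objects.
#' @param sample_ids samples to simulate (default: all samples named in the
#'   first model's coverage).
#' @param read_len read length in bp.
#' @param seed integer seed.
#' @param mapped_fraction fraction of each library mapping to the assembly.
#' @return named list of [mapping_summary()] objects, one per sample.
#' @export
simulate_mapping <- function(scaffold_truth, models, sample_ids = NULL,
                             read_len = 100, seed = 1,
                             mapped_fraction = 0.87) {
  stopifnot(read_len > 0)
  models <- stats::setNames(models, vapply(models, `[[`, "", "genome_id"))
  unknown <- setdiff(scaffold_truth$genome_id, names(models))
  if (length(unknown)) {
    stop("scaffolds reference unknown genome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sample_ids <- sample_ids %||% names(models[[1]]$mean_coverage)
  with_seed(seed, {
    out <- list()
    for (t in sample_ids) {
      cov <- vapply(models[scaffold_truth$genome_id], function(m) {
        if (!t %in% names(m$mean_coverage)) {
          stop("genome ", m$genome_id, " has no coverage for sample ", t,
               call. = FALSE)
        }
        m$mean_coverage[[t]]
      }, numeric(1))
      counts <- stats::rpois(nrow(scaffold_truth),
                             cov * scaffold_truth$length / read_len)
      rec <- data.frame(scaffold_id = scaffold_truth$scaffold_id,
                        mapped_reads = counts,
                        mapped_bases = counts * read_len,
                        stringsAsFactors = FALSE)
      out[[t]] <- mapping_summary(t, rec,
                                  ceiling(sum(counts) / mapped_fraction))
    }
    out
  })
}

#' Plant single-copy marker genes on a community's scaffolds
#'
#' Each genome receives one gene per marker of the set, minus the dropouts,
#' plus one extra copy for each duplicated marker; genes are placed on the
#' genome's scaffolds with probability proportional to scaffold length.
#' Truth completeness is (set size - dropouts) / set size and truth
#' redundancy is duplicated / (set size - dropouts), mirroring the QC
#' arithmetic downstream.
#'
#' @param scaffold_truth truth data.frame covering all genomes.
#' @param models list of [genome_model()]s.
#' @param set a [marker_set()].
#' @param dropout_map named list: genome_id -> marker IDs absent from that
#'   genome.
#' @param duplication_map named list: genome_id -> marker IDs present in two
#'   copies. A marker may not be both dropped and duplicated.
#' @param seed integer seed.
#' @param gene_len planted gene length (bp).
#' @return list: `hits` (marker hit table), `genes` (gene truth rows with
#'   `marker_id` and `active` flag), `truth` (per-genome data.frame with
#'   n_identified, n_duplicated, completeness_pct, redundancy_pct at full
#'   precision).
#' @export
plant_markers <- function(scaffold_truth, models, set,
                          dropout_map = list(), duplication_map = list(),
                          seed = 1, gene_len = 900) {
  models <- stats::setNames(models, vapply(models, `[[`, "", "genome_id"))
  bad <- setdiff(c(unlist(dropout_map), unlist(duplication_map)),
                 set$marker_ids)
  if (length(bad)) {
    stop("dropout/duplication references markers outside set: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    genes <- list(); hits <- list(); truth <- list()
    for (g in names(models)) {
      drop <- unique(dropout_map[[g]] %||% character())
      dup <- unique(duplication_map[[g]] %||% character())
      both <- intersect(drop, dup)
      if (length(both)) {
        stop("genome ", g, ": marker(s) both dropped and duplicated: ",
             paste(both, collapse = ", "), call. = FALSE)
      }
      present <- setdiff(set$marker_ids, drop)
      marker_of_gene <- c(present, dup)  # one extra copy per duplicate
      sc <- scaffold_truth[scaffold_truth$genome_id == g, , drop = FALSE]
      ok <- sc$length >= gene_len
      if (!any(ok)) {
        stop("genome ", g, ": no scaffold long enough for a ", gene_len,
             " bp marker gene", call. = FALSE)
      }
      sc <- sc[ok, , drop = FALSE]
      idx <- sample.int(nrow(sc), length(marker_of_gene), replace = TRUE,
                        prob = sc$length)
      start <- vapply(sc$length[idx] - gene_len + 1,
                      function(m) sample.int(m, 1), integer(1))
      gid <- sprintf("%s_mk%04d", g, seq_along(marker_of_gene))
      active <- stats::runif(length(gid)) < models[[g]]$active_gene_fraction
      genes[[g]] <- data.frame(
        gene_id = gid, scaffold_id = sc$scaffold_id[idx],
        start = start, end = start + gene_len - 1,
        strand = sample(c("+", "-"), length(gid), replace = TRUE),
        genome_id = g, marker_id = marker_of_gene, active = active,
        stringsAsFactors = FALSE)
      hits[[g]] <- marker_hits(gid, sc$scaffold_id[idx], marker_of_gene)
      truth[[g]] <- data.frame(
        genome_id = g,
        n_identified = length(present),
        n_duplicated = length(dup),
        completeness_pct = 100 * length(present) / set$expected_size,
        redundancy_pct = if (length(present)) 100 * length(dup) / length(present) else 0,
        stringsAsFactors = FALSE)
    }
    list(hits = do.call(rbind, c(hits, list(make.row.names = FALSE))),
         genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Simulate filler (non-marker) genes
#'
#' Adds protein-coding genes beyond the planted markers so expression
#' summaries have realistic gene counts (about one gene per kb by default).
#'
#' @inheritParams plant_markers
#' @param genes_per_kb gene density.
#' @param gene_len_min,gene_len_mean length model (uniform min..2*mean-min).
#' @return gene truth data.frame in the same layout as [plant_markers()]
#'   `genes`, with `marker_id = NA`.
#' @export
simulate_genes <- function(scaffold_truth, models, seed = 1,
                           genes_per_kb = 1, gene_len_min = 300,
                           gene_len_mean = 900) {
  models <- stats::setNames(models, vapply(models, `[[`, "", "genome_id"))
  with_seed(seed, {
    out <- list()
    for (g in intersect(names(models), unique(scaffold_truth$genome_id))) {
      sc <- scaffold_truth[scaffold_truth$genome_id == g, , drop = FALSE]
      rows <- list()
      k <- 0
      for (i in seq_len(nrow(sc))) {
        n <- round(sc$length[i] / 1000 * genes_per_kb)
        if (n < 1) next
        len <- sample(seq(gene_len_min, 2 * gene_len_mean - gene_len_min),
                      n, replace = TRUE)
        len <- pmin(len, sc$length[i])
        start <- vapply(sc$length[i] - len + 1,
                        function(m) sample.int(m, 1), integer(1))
        rows[[i]] <- data.frame(
          gene_id = sprintf("%s_fg%05d", g, k + seq_len(n)),
          scaffold_id = sc$scaffold_id[i], start = start,
          end = start + len - 1,
          strand = sample(c("+", "-"), n, replace = TRUE),
          genome_id = g, marker_id = NA_character_,
          active = stats::runif(n) < models[[g]]$active_gene_fraction,
          stringsAsFactors = FALSE)
        k <- k + n
      }
      out[[g]] <- do.call(rbind, rows)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Simulate paired-end link evidence between scaffolds
#'
#' Adjacent scaffolds of the same genome (by fragment order) share
#' `n_links_adjacent` read-pair links; `n_noise_links` single spurious links
#' are added between random scaffolds of different genomes.
#'
#' @inheritParams plant_markers
#' @param n_links_adjacent links per adjacent same-genome pair (>= 1).
#' @param n_noise_links number of random cross-genome noise links.
#' @return data.frame (scaffold_a, scaffold_b, n_links).
#' @export
simulate_pe_links <- function(scaffold_truth, n_links_adjacent = 5,
                              n_noise_links = 0, seed = 1) {
  if (n_links_adjacent < 1) stop("`n_links_adjacent` must be >= 1",
                                 call. = FALSE)
  st <- scaffold_truth[order(scaffold_truth$genome_id, scaffold_truth$ord), ]
  adj <- NULL
  same <- st$genome_id[-nrow(st)] == st$genome_id[-1]
  if (any(same)) {
    adj <- data.frame(scaffold_a = st$scaffold_id[-nrow(st)][same],
                      scaffold_b = st$scaffold_id[-1][same],
                      n_links = n_links_adjacent, stringsAsFactors = FALSE)
  }
  noise <- NULL
  if (n_noise_links > 0) {
    noise <- with_seed(seed, {
      a <- sample(st$scaffold_id, n_noise_links * 4, replace = TRUE)
      b <- sample(st$scaffold_id, n_noise_links * 4, replace = TRUE)
      cross <- st$genome_id[match(a, st$scaffold_id)] !=
        st$genome_id[match(b, st$scaffold_id)]
      i <- utils::head(which(cross), n_noise_links)
      if (!length(i)) NULL else
        data.frame(scaffold_a = a[i], scaffold_b = b[i], n_links = 1L,
                   stringsAsFactors = FALSE)
    })
  }
  out <- rbind(adj, noise)
  out %||% data.frame(scaffold_a = character(), scaffold_b = character(),
                      n_links = integer())
}

#' Simulate DNA and RNA per-gene read counts
#'
#' DNA counts are Poisson with mean proportional to gene length times the
#' genome's coverage in the expression sample, scaled so the expected mapped
#' total equals `dna_library_size`. RNA counts are zero for inactive genes;
#' for active genes they are Poisson with mean proportional to length times
#' the genome's activity multiplier, scaled to `rna_library_size`.
#'
#' @param genes gene truth data.frame ([plant_markers()] / [simulate_genes()]).
#' @param models list of [genome_model()]s.
#' @param sample sample whose coverage drives DNA counts (default: last
#'   sample of the first model, i.e. the later time point).
#' @param dna_library_size,rna_library_size expected mapped totals (> 0).
#' @param seed integer seed.
#' @return data.frame (gene_id, length_bp, dna_count, rna_count) with
#'   attribute `totals` = c(dna =, rna =) actual sums.
#' @export
simulate_expression <- function(genes, models, sample = NULL,
                                dna_library_size = 2e6,
                                rna_library_size = 2e6, seed = 1) {
  stopifnot(dna_library_size > 0, rna_library_size > 0)
  models <- stats::setNames(models, vapply(models, `[[`, "", "genome_id"))
  sample <- sample %||% utils::tail(names(models[[1]]$mean_coverage), 1)
  len <- genes$end - genes$start + 1
  cov <- vapply(models[genes$genome_id], function(m) m$mean_coverage[[sample]],
                numeric(1))
  mult <- vapply(models[genes$genome_id], `[[`, numeric(1), "activity_mult")
  w_dna <- cov * len
  lam_dna <- dna_library_size * w_dna / sum(w_dna)
  w_rna <- ifelse(genes$active, mult * len, 0)
  lam_rna <- if (sum(w_rna) > 0) rna_library_size * w_rna / sum(w_rna) else w_rna
  with_seed(seed, {
    dna <- stats::rpois(length(len), lam_dna)
    rna <- stats::rpois(length(len), lam_rna)
    out <- data.frame(gene_id = genes$gene_id, length_bp = len,
                      dna_count = dna, rna_count = rna,
                      stringsAsFactors = FALSE)
    attr(out, "totals") <- c(dna = sum(dna), rna = sum(rna))
    out
  })
}

#' Simulate a complete labelled community
#'
#' Orchestrates genome simulation, fragmentation, mapping, marker planting,
#' filler genes, paired-end links and expression with deterministic
#' per-stage seeds derived from one master seed.
#'
#' @param models list of [genome_model()]s.
#' @param set marker set to plant (default ESCG107).
#' @param dropout_map,duplication_map see [plant_markers()].
#' @param skip_markers genome IDs that receive no markers or genes (e.g.
#'   planted contaminants).
#' @param min_scaffold_len,mean_scaffold_len fragmentation parameters.
#' @param fragment_overrides named list: genome_id -> exact number of
#'   equal-sized scaffolds to cut that genome into (bypasses the random
#'   fragmenter; used to plant a fixed number of contaminant scaffolds).
#' @param read_len mapping read length.
#' @param n_links_adjacent,n_noise_links paired-end link parameters.
#' @param genes_per_kb filler gene density.
#' @param dna_library_size,rna_library_size expression library sizes.
#' @param seed master seed.
#' @return list of class `synthetic_community`: `scaffolds`
#'   ([Biostrings::DNAStringSet]), `scaffold_truth`, `genes`, `mappings`,
#'   `marker_hits`, `marker_truth`, `links`, `expression`, `models`, `set`.
#' @export
simulate_community <- function(models, set = marker_set("ESCG107"),
                               dropout_map = list(),
                               duplication_map = list(),
                               skip_markers = character(),
                               fragment_overrides = list(),
                               min_scaffold_len = 1000,
                               mean_scaffold_len = 20000,
                               read_len = 100, n_links_adjacent = 5,
                               n_noise_links = 2, genes_per_kb = 1,
                               dna_library_size = 2e6,
                               rna_library_size = 2e6, seed = 1) {
  seeds <- with_seed(seed, sample.int(1e8, 6 + length(models)))
  scaffolds <- Biostrings::DNAStringSet()
  truth <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    g <- simulate_genome(m$genome_id, m$length, m$gc_content,
                         seed = seeds[6 + i])
    k <- fragment_overrides[[m$genome_id]]
    fr <- if (is.null(k)) {
      fragment_genome(g, m$genome_id, min_len = min_scaffold_len,
                      mean_len = mean_scaffold_len, seed = seeds[6 + i])
    } else {
      cuts <- round(seq(0, length(g), length.out = k + 1))
      ids <- sprintf("s_%s_%03d", m$genome_id, seq_len(k))
      sc <- Biostrings::DNAStringSet(g, start = cuts[-(k + 1)] + 1,
                                     end = cuts[-1])
      names(sc) <- ids
      list(scaffolds = sc,
           truth = data.frame(scaffold_id = ids, genome_id = m$genome_id,
                              ord = seq_len(k), start = cuts[-(k + 1)] + 1,
                              end = cuts[-1], length = diff(cuts),
                              stringsAsFactors = FALSE))
    }
    scaffolds <- c(scaffolds, fr$scaffolds)
    truth[[i]] <- fr$truth
  }
  scaffold_truth <- do.call(rbind, truth)
  mappings <- simulate_mapping(scaffold_truth, models, read_len = read_len,
                               seed = seeds[1])
  marked <- Filter(function(m) !m$genome_id %in% skip_markers, models)
  marked_truth <- scaffold_truth[!scaffold_truth$genome_id %in% skip_markers, ]
  pm <- plant_markers(marked_truth, marked, set, dropout_map,
                      duplication_map, seed = seeds[2])
  fillers <- simulate_genes(marked_truth, marked, seed = seeds[3],
                            genes_per_kb = genes_per_kb)
  genes <- rbind(pm$genes, fillers)
  links <- simulate_pe_links(scaffold_truth, n_links_adjacent,
                             n_noise_links, seed = seeds[4])
  expr <- simulate_expression(genes, marked, seed = seeds[5],
                              dna_library_size = dna_library_size,
                              rna_library_size = rna_library_size)
  structure(list(scaffolds = scaffolds, scaffold_truth = scaffold_truth,
                 genes = genes, mappings = mappings,
                 marker_hits = pm$hits, marker_truth = pm$truth,
                 links = links, expression = expr, models = models,
                 set = set),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "<synthetic_community> %d genomes, %d scaffolds (%s bp), %d genes, %d samples\n",
    length(x$models), length(x$scaffolds),
    format(sum(Biostrings::width(x$scaffolds)), big.mark = ","),
    nrow(x$genes), length(x$mappings)))
  invisible(x)
}

#' Demonstration community matching the study design
#'
#' Four genomes with pairwise coverage separation of at least five-fold in
#' one of the two samples, GC contents 0.54 / 0.65 / 0.40 / 0.54, marker
#' dropout/duplication patterns mirroring the published quality table
#' (completeness 99.1 / 98.1 / 100.0 / 99.1 %, redundancy
#' 3.8 / 1.9 / 3.7 / 2.8 %), active-gene fractions from the published
#' "genes with transcription" row, and two planted AT-rich (GC 0.20)
#' contaminant scaffolds sharing genome A's coverage so composition
#' refinement is exercised.
#'
#' The stand-in genomes are 600 kb (desk scale, versus several Mb for the
#' real organisms) but carry the gene count of a full genome (about 6,000
#' genes each, via `genes_per_kb = 10`), so per-bin activity fractions have
#' the sampling precision real annotations would give.
#'
#' @param seed master seed.
#' @param genome_length length of each of the four genomes (bp).
#' @return a [simulate_community()] result; the contaminant genome is
#'   `"contam"` and carries no markers or genes.
#' @export
demo_community <- function(seed = 1, genome_length = 600000) {
  esc <- marker_set("ESCG107")
  mk <- function(k) esc$marker_ids[k]
  models <- list(
    genome_model("gA", genome_length, 0.54, c(SE = 100, LE = 30),
                 active_gene_fraction = 0.278),
    genome_model("gB", genome_length, 0.65, c(SE = 15, LE = 150),
                 active_gene_fraction = 0.354),
    genome_model("gC", genome_length, 0.40, c(SE = 4, LE = 20),
                 active_gene_fraction = 0.181),
    genome_model("gD", genome_length, 0.54, c(SE = 30, LE = 4),
                 active_gene_fraction = 0.028),
    genome_model("contam", 12000, 0.20, c(SE = 100, LE = 30))
  )
  simulate_community(
    models, set = esc,
    dropout_map = list(gA = mk(1), gB = mk(1:2), gD = mk(1)),
    duplication_map = list(gA = mk(3:6), gB = mk(3:4), gC = mk(3:6),
                           gD = mk(3:5)),
    skip_markers = "contam",
    fragment_overrides = list(contam = 2),
    mean_scaffold_len = 15000, min_scaffold_len = 1000,
    genes_per_kb = 10, n_noise_links = 2, seed = seed)
}
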