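test_that("simulated genomes hit the requested GC and are seed-deterministic", {
  g1 <- simulate_genome("g1", 100000, 0.54, seed = 1)
  gc <- sum(Biostrings::letterFrequency(g1, c("G", "C"))) / length(g1)
  expect_gt(gc, 0.52)
  expect_lt(gc, 0.56)
  g2 <- simulate_genome("g1", 100000, 0.54, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(g1),
                         as.character(simulate_genome("g1", 100000, 0.54,
                                                      seed = 2))))
  expect_error(simulate_genome("g", 5000, 0.54, 1), "10,000")
  expect_error(simulate_genome("g", 20000, 1.2, 1), "fraction")
})

test_that("distinct-GC genomes are farther apart in TNF space than halves of one genome", {
  a <- simulate_genome("a", 40000, 0.40, seed = 3)
  b <- simulate_genome("b", 40000, 0.65, seed = 4)
  va <- tnf_vector(a)
  vb <- tnf_vector(b)
  half <- function(s, k) Biostrings::subseq(s, ifelse(k == 1, 1, 20001),
                                            ifelse(k == 1, 20000, 40000))
  within_a <- tnf_distance(tnf_vector(half(a, 1)), tnf_vector(half(a, 2)))
  within_b <- tnf_distance(tnf_vector(half(b, 1)), tnf_vector(half(b, 2)))
  between <- tnf_distance(va, vb)
  expect_gt(between, within_a)
  expect_gt(between, within_b)
})

test_that("fragmentation conserves the genome and respects the length floor", {
  g <- simulate_genome("g1", 100000, 0.5, seed = 1)
  fr <- fragment_genome(g, "g1", min_len = 1000, mean_len = 10000, seed = 9)
  expect_equal(sum(fr$truth$length), 100000)
  expect_true(all(Biostrings::width(fr$scaffolds) >= 1000))
  expect_identical(paste(as.character(fr$scaffolds), collapse = ""),
                   as.character(g))
  fr2 <- fragment_genome(g, "g1", min_len = 1000, mean_len = 10000, seed = 9)
  expect_identical(fr$truth, fr2$truth)
  expect_error(fragment_genome(Biostrings::DNAString("ACGT"), "g", 1000),
               "shorter")
})

test_that("mapping counts are Poisson around coverage * length / read length", {
  g <- simulate_genome("g1", 100000, 0.5, seed = 1)
  fr <- fragment_genome(g, "g1", mean_len = 10000, seed = 2)
  m <- genome_model("g1", 100000, 0.5, c(s1 = 100, s2 = 100))
  maps <- simulate_mapping(fr$truth, list(m), read_len = 100, seed = 3)
  # a 10 kb scaffold at 100x with 100 bp reads expects 10,000 reads
  big <- which(fr$truth$length >= 5000)[1]
  lam <- 100 * fr$truth$length[big] / 100
  obs <- maps$s1$records$mapped_reads[
    maps$s1$records$scaffold_id == fr$truth$scaffold_id[big]]
  expect_lt(abs(obs - lam), 5 * sqrt(lam))
  # coverage recovered downstream within 3 s.d. of the generating mean
  prof <- coverage_profiles(maps, stats::setNames(fr$truth$length,
                                                  fr$truth$scaffold_id))
  cov_sd <- 100 * sqrt(lam) / fr$truth$length[big]
  expect_lt(abs(prof$cov_s1[big] - 100), 3 * cov_sd)
})

test_that("a genome with zero coverage in one sample maps nothing there", {
  g <- simulate_genome("g1", 20000, 0.5, seed = 1)
  fr <- fragment_genome(g, "g1", mean_len = 5000, seed = 1)
  m <- genome_model("g1", 20000, 0.5, c(s1 = 1e-9, s2 = 10))
  maps <- simulate_mapping(fr$truth, list(m), seed = 1)
  expect_true(all(maps$s1$records$mapped_reads == 0))
  expect_gt(sum(maps$s2$records$mapped_reads), 0)
})

test_that("planted marker truth follows the completeness/redundancy arithmetic", {
  esc <- marker_set("ESCG107")
  g <- simulate_genome("g1", 50000, 0.5, seed = 1)
  fr <- fragment_genome(g, "g1", mean_len = 10000, seed = 1)
  m <- genome_model("g1", 50000, 0.5, c(s1 = 10))
  pm <- plant_markers(fr$truth, list(m), esc,
                      dropout_map = list(g1 = esc$marker_ids[1]),
                      duplication_map = list(g1 = esc$marker_ids[2:5]),
                      seed = 4)
  expect_equal(pm$truth$n_identified, 106)
  expect_equal(pm$truth$n_duplicated, 4)
  expect_equal(round_half_up(pm$truth$completeness_pct), 99.1)
  expect_equal(round_half_up(pm$truth$redundancy_pct), 3.8)
  # no dropout / duplication: 100 % complete, 0 % redundant
  pm0 <- plant_markers(fr$truth, list(m), esc, seed = 4)
  expect_equal(pm0$truth$completeness_pct, 100)
  expect_equal(pm0$truth$redundancy_pct, 0)
  # a marker cannot be both dropped and duplicated
  expect_error(plant_markers(fr$truth, list(m), esc,
                             dropout_map = list(g1 = esc$marker_ids[1]),
                             duplication_map = list(g1 = esc$marker_ids[1]),
                             seed = 1),
               "both dropped and duplicated")
})

test_that("marker QC applied to the emitted hit table reproduces planted truth", {
  esc <- marker_set("ESCG107")
  cog <- marker_set("COG35")
  g <- simulate_genome("g1", 60000, 0.5, seed = 2)
  fr <- fragment_genome(g, "g1", mean_len = 10000, seed = 2)
  m <- genome_model("g1", 60000, 0.5, c(s1 = 10))
  cases <- list(list(set = esc, drop = 1, dup = 4),
                list(set = esc, drop = 0, dup = 0),
                list(set = cog, drop = 2, dup = 3))
  for (cs in cases) {
    ids <- cs$set$marker_ids
    pm <- plant_markers(
      fr$truth, list(m), cs$set,
      dropout_map = if (cs$drop) list(g1 = ids[seq_len(cs$drop)]) else list(),
      duplication_map = if (cs$dup) list(g1 = ids[cs$drop + seq_len(cs$dup)])
                        else list(),
      seed = 11)
    rep <- qc_report(fr$truth$scaffold_id, pm$hits, cs$set)
    expect_equal(rep$n_identified, pm$truth$n_identified)
    expect_equal(rep$n_duplicated, pm$truth$n_duplicated)
    expect_equal(rep$completeness_pct,
                 round_half_up(pm$truth$completeness_pct))
    expect_equal(rep$redundancy_pct,
                 round_half_up(pm$truth$redundancy_pct))
  }
})

test_that("paired-end links connect genomes internally unless noise is added", {
  g1 <- fragment_genome(simulate_genome("g1", 30000, 0.5, 1), "g1",
                        mean_len = 5000, seed = 1)$truth
  g2 <- fragment_genome(simulate_genome("g2", 30000, 0.5, 2), "g2",
                        mean_len = 5000, seed = 2)$truth
  truth <- rbind(g1, g2)
  links <- simulate_pe_links(truth, n_links_adjacent = 4,
                             n_noise_links = 0, seed = 1)
  genome_of <- stats::setNames(truth$genome_id, truth$scaffold_id)
  expect_true(all(genome_of[links$scaffold_a] == genome_of[links$scaffold_b]))
  expect_true(all(links$n_links == 4))
  # adjacent scaffolds of one genome each share exactly one link row
  expect_equal(sum(genome_of[links$scaffold_a] == "g1"), nrow(g1) - 1)
  noisy <- simulate_pe_links(truth, n_links_adjacent = 4,
                             n_noise_links = 3, seed = 1)
  cross <- genome_of[noisy$scaffold_a] != genome_of[noisy$scaffold_b]
  expect_equal(sum(cross), 3)
  expect_true(all(noisy$n_links[cross] == 1))
})

test_that("expression counts respect activity flags and recover the active fraction", {
  g <- simulate_genome("g1", 200000, 0.5, seed = 3)
  fr <- fragment_genome(g, "g1", mean_len = 20000, seed = 3)
  m <- genome_model("g1", 200000, 0.5, c(s1 = 50), active_gene_fraction = 0.3)
  genes <- simulate_genes(fr$truth, list(m), seed = 5, genes_per_kb = 6)
  expect_gte(nrow(genes), 1000)
  ex <- simulate_expression(genes, list(m), seed = 6)
  expect_true(all(ex$rna_count[!genes$active] == 0))
  frac <- mean(ex$rna_count > 0)
  expect_lt(abs(100 * frac - 30), 2)
  # recovery through the activity summary
  act <- activity_table(ex)
  s <- bin_activity_summary(genes$gene_id, act)
  expect_lt(abs(s$pct_transcribed - 30), 2)
})

test_that("the community orchestrator is deterministic in its master seed", {
  a <- demo_community(seed = 3, genome_length = 60000)
  b <- demo_community(seed = 3, genome_length = 60000)
  expect_identical(as.character(a$scaffolds), as.character(b$scaffolds))
  expect_identical(a$genes, b$genes)
  expect_identical(a$expression$dna_count, b$expression$dna_count)
  expect_identical(a$links, b$links)
})
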