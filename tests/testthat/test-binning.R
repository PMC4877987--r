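# a small deterministic coverage table: two genomes plus one short scaffold
toy_profiles <- function() {
  data.frame(
    scaffold_id = c("a1", "a2", "a3", "b1", "b2", "tiny"),
    length = c(8000, 9000, 7000, 8000, 6000, 500),
    cov_SE = c(100, 105, 95, 10, 11, 100),
    cov_LE = c(30, 31, 29, 120, 115, 30),
    stringsAsFactors = FALSE)
}

test_that("coverage selection recruits exactly the scaffolds in the region", {
  p <- toy_profiles()
  reg <- region_polygon(cbind(c(1.8, 2.2, 2.2, 1.8), c(1.3, 1.3, 1.6, 1.6)),
                        min_scaffold_len = 1000)
  bin <- select_by_coverage(p, reg, c("SE", "LE"))
  expect_setequal(bin$scaffold_ids, c("a1", "a2", "a3"))  # tiny filtered
  expect_error(select_by_coverage(
    p, region_polygon(cbind(c(5, 6, 6), c(5, 5, 6))), c("SE", "LE")),
    "widen")
  # boundary point is included: a1 sits exactly on log10(100) = 2
  reg_edge <- region_polygon(cbind(c(2, 2.2, 2.2, 2),
                                   c(log10(30), log10(30), 1.6, 1.6)))
  expect_true("a1" %in%
                select_by_coverage(p, reg_edge, c("SE", "LE"))$scaffold_ids)
  # ellipse regions work too
  rege <- region_ellipse(c(2, 1.48), c(0.2, 0.2))
  expect_setequal(select_by_coverage(p, rege, c("SE", "LE"))$scaffold_ids,
                  c("a1", "a2", "a3"))
})

test_that("auto-seeded regions recover well-separated coverage clusters", {
  p <- toy_profiles()
  regions <- auto_seed_regions(p, c("SE", "LE"), min_len = 5000,
                               min_cluster_len = 10000)
  expect_length(regions, 2)
  bins <- lapply(seq_along(regions), function(i) {
    select_by_coverage(p, regions[[i]], c("SE", "LE"),
                       bin_id = paste0("bin", i))
  })
  members <- lapply(bins, `[[`, "scaffold_ids")
  expect_true(any(vapply(members, setequal, logical(1),
                         y = c("a1", "a2", "a3"))))
  expect_true(any(vapply(members, setequal, logical(1), y = c("b1", "b2"))))
  # single genome -> single region
  one <- auto_seed_regions(p[1:3, ], c("SE", "LE"), min_len = 5000,
                           min_cluster_len = 10000)
  expect_length(one, 1)
})

test_that("paired-end rescue re-attaches linked scaffolds under the coverage guard", {
  p <- toy_profiles()
  links <- data.frame(scaffold_a = c("a1", "a1", "b1"),
                      scaffold_b = c("a2", "a3", "a2"),
                      n_links = c(10L, 1L, 1L))
  bin <- genome_bin("binA", c("a1"))
  r <- pe_rescue(bin, links, p, c("SE", "LE"), min_links = 2)
  expect_setequal(r$scaffold_ids, c("a1", "a2"))  # a3 has 1 link, b via a2 has 1
  expect_equal(r$provenance$detail[r$provenance$stage == "pe_rescued"],
               "links=10")
  # min_links = 1 admits a3 as well
  r1 <- pe_rescue(bin, links, p, c("SE", "LE"), min_links = 1)
  expect_true("a3" %in% r1$scaffold_ids)
  # well-linked scaffolds with uniformly low coverage fail the guard
  p_low <- rbind(p, data.frame(scaffold_id = "low1", length = 5000,
                               cov_SE = 1, cov_LE = 2))
  links_low <- rbind(links, data.frame(scaffold_a = "a1",
                                       scaffold_b = "low1", n_links = 9L))
  rlow <- pe_rescue(genome_bin("binA", c("a1", "a2", "a3")), links_low,
                    p_low, c("SE", "LE"), min_links = 2, max_cov_fold = 3)
  expect_false("low1" %in% rlow$scaffold_ids)
  # infinite threshold leaves the bin unchanged; rescue never removes
  rinf <- pe_rescue(bin, links, p, c("SE", "LE"), min_links = Inf)
  expect_identical(rinf$scaffold_ids, bin$scaffold_ids)
  expect_true(all(bin$scaffold_ids %in% r1$scaffold_ids))
})

test_that("multi-copy scaffolds above the bin's median coverage are rescued", {
  p <- rbind(toy_profiles(),
             data.frame(scaffold_id = "rep1", length = 5000,
                        cov_SE = 900, cov_LE = 280))
  links <- data.frame(scaffold_a = "a1", scaffold_b = "rep1", n_links = 5L)
  bin <- genome_bin("binA", c("a1", "a2", "a3"))
  r <- pe_rescue(bin, links, p, c("SE", "LE"), min_links = 2,
                 max_cov_fold = 3)
  expect_true("rep1" %in% r$scaffold_ids)  # 9x the median, multi-copy case
})

test_that("extract_bin composes the stages and its provenance replays", {
  fix <- demo_fixture(seed = 1)
  res <- fix$result
  cm <- fix$community
  for (b in names(res$bins)) {
    expect_setequal(replay_provenance(res$bins[[b]]),
                    res$bins[[b]]$scaffold_ids)
  }
  # contaminants were inside some coverage region but TNF-removed
  removed <- unlist(lapply(res$bins, function(b) {
    b$provenance$scaffold_id[b$provenance$stage == "tnf_removed"]
  }))
  contam <- cm$scaffold_truth$scaffold_id[
    cm$scaffold_truth$genome_id == "contam"]
  expect_setequal(removed, contam)
  in_bins <- unlist(lapply(res$bins, `[[`, "scaffold_ids"))
  expect_length(intersect(in_bins, contam), 0)
})

test_that("bin extraction is deterministic for identical inputs", {
  fix <- demo_fixture(seed = 1)
  p <- fix$result$profiles
  cm <- fix$community
  tnf <- tnf_vectors(cm$scaffolds)
  reg <- auto_seed_regions(p, c("LE", "SE"))[[1]]
  b1 <- extract_bin(p, tnf, cm$links, reg, c("LE", "SE"))
  b2 <- extract_bin(p, tnf, cm$links, reg, c("LE", "SE"))
  expect_identical(b1$scaffold_ids, b2$scaffold_ids)
  expect_identical(b1$provenance, b2$provenance)
})

test_that("bins serialise to JSON and back with provenance intact", {
  bin <- genome_bin("b7", c("x", "y"))
  bin <- genome_bin("b7", c("x", "y", "z"), rbind(
    bin$provenance,
    data.frame(stage = "pe_rescued", scaffold_id = "z", detail = "links=3")))
  f <- tempfile(fileext = ".json")
  write_bin_json(bin, f)
  b2 <- read_bin_json(f)
  expect_equal(b2$bin_id, bin$bin_id)
  expect_setequal(b2$scaffold_ids, bin$scaffold_ids)
  expect_equal(b2$provenance$stage, bin$provenance$stage)
  expect_setequal(replay_provenance(b2), bin$scaffold_ids)
})
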