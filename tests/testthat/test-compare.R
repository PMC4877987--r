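test_that("ANI of a genome with itself is exactly 100", {
  g <- Biostrings::DNAStringSet(random_dna(15000, seed = 51))
  names(g) <- "g1"
  a <- ani(g, g)
  expect_equal(a$ani, 100)
  expect_false(a$indeterminate)
})

test_that("ANI recovers a planted substitution rate and honours the identity cutoff", {
  set.seed(52)
  s <- strsplit(random_dna(30000, seed = 52), "")[[1]]
  i <- sample(length(s), round(0.05 * length(s)))
  s2 <- s
  s2[i] <- vapply(s[i], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  ga <- Biostrings::DNAStringSet(paste(s, collapse = "")); names(ga) <- "a"
  gb <- Biostrings::DNAStringSet(paste(s2, collapse = "")); names(gb) <- "b"
  a <- ani(ga, gb)
  expect_lt(abs(a$ani - 95), 1)
  expect_equal(unname(a$n_fragments_used["ab"]), 29L)
  # fragments below the identity cutoff are excluded from the mean
  hits <- data.frame(query_id = c("frag_1_1", "frag_1_2"),
                     percent_identity = c(50, 90),
                     alignment_length = c(1020, 1020))
  r <- ani_from_hits(hits, c(frag_1_1 = 1020, frag_1_2 = 1020),
                     min_identity_pct = 60)
  expect_equal(r$ani, 90)
  expect_equal(r$n, 1L)
  # nothing retained -> indeterminate
  r0 <- ani_from_hits(hits[1, ], c(frag_1_1 = 1020), min_identity_pct = 60)
  expect_true(is.na(r0$ani))
})

test_that("unrelated genomes yield no alignable fragments and an indeterminate ANI", {
  ga <- Biostrings::DNAStringSet(random_dna(8000, gc = 0.2, seed = 53))
  gb <- Biostrings::DNAStringSet(random_dna(8000, gc = 0.8, seed = 54))
  names(ga) <- "a"; names(gb) <- "b"
  a <- ani(ga, gb, fragment_len = 1000)
  expect_true(a$indeterminate)
  expect_true(is.na(a$ani))
})

test_that("BBH shared genes match an exhaustive double-loop oracle", {
  for (seed in 1:4) {
    ab <- random_hits(25, 25, 120, seed = seed, qprefix = "a",
                      sprefix = "b")
    ba <- random_hits(25, 25, 120, seed = seed + 100, qprefix = "b",
                      sprefix = "a")
    got <- bbh_shared_genes(ab, ba)
    want <- bbh_oracle(ab, ba)
    expect_equal(got$n_shared, if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      expect_setequal(paste(got$pairs$gene_a, got$pairs$gene_b),
                      paste(want[, 1], want[, 2]))
    }
    # symmetry and the min-cardinality bound
    rev <- bbh_shared_genes(ba, ab)
    expect_equal(rev$n_shared, got$n_shared)
    expect_lte(got$n_shared, 25)
  }
})

test_that("BBH filters are inclusive at the threshold and identical genomes share everything", {
  mk <- function(bitscore) {
    data.frame(query_id = "a1", subject_id = "b1", percent_identity = 90,
               alignment_length = 900, bitscore = bitscore,
               query_length = 900, stringsAsFactors = FALSE)
  }
  back <- data.frame(query_id = "b1", subject_id = "a1",
                     percent_identity = 90, alignment_length = 900,
                     bitscore = 200, query_length = 900,
                     stringsAsFactors = FALSE)
  expect_equal(bbh_shared_genes(mk(69.9), back)$n_shared, 0L)
  expect_equal(bbh_shared_genes(mk(70), back)$n_shared, 1L)
  # identical gene sets: every gene pairs with itself
  n <- 10
  self <- data.frame(query_id = paste0("g", 1:n),
                     subject_id = paste0("g", 1:n),
                     percent_identity = 100, alignment_length = 900,
                     bitscore = 500, query_length = 900,
                     stringsAsFactors = FALSE)
  expect_equal(bbh_shared_genes(self, self)$n_shared, n)
})

test_that("tightening any BBH filter never increases the shared count", {
  ab <- random_hits(30, 30, 200, seed = 9)
  ba <- random_hits(30, 30, 200, seed = 10, qprefix = "b", sprefix = "a")
  base <- bbh_shared_genes(ab, ba)$n_shared
  for (f in list(list(min_bitscore = 120), list(min_identity = 60),
                 list(min_query_cov = 0.9))) {
    expect_lte(bbh_shared_genes(ab, ba, filters = f)$n_shared, base)
  }
})

test_that("duplicated genes require a passing non-self hit", {
  hits <- data.frame(
    query_id = c("g1", "g2", "g2", "g3"),
    subject_id = c("g1", "g2", "g5", "g4"),
    percent_identity = c(100, 100, 80, 20),
    alignment_length = c(900, 900, 800, 900),
    bitscore = c(999, 999, 150, 90),
    query_length = 900, stringsAsFactors = FALSE)
  r <- duplicated_genes(hits, n_genes = 10)
  # g1's only hit is itself; g3 fails the identity filter; g2 qualifies
  expect_equal(r$duplicated_genes, "g2")
  expect_equal(r$pct_duplicated, 10)
  # two identical genes are both duplicated
  two <- data.frame(query_id = c("x", "y"), subject_id = c("y", "x"),
                    percent_identity = 100, alignment_length = 900,
                    bitscore = 500, query_length = 900,
                    stringsAsFactors = FALSE)
  expect_equal(duplicated_genes(two, n_genes = 2)$n_duplicated, 2)
})

test_that("species classification applies the ANI 94 / DDH 70 thresholds", {
  expect_equal(classify_species(79.3, 17.7)$verdict, "different_species")
  expect_equal(classify_species(100, 100)$verdict, "same_species")
  expect_equal(classify_species(95, 60)$verdict, "indeterminate")
  expect_equal(classify_species(80)$verdict, "different_species")
  expect_equal(classify_species(94)$verdict, "same_species")  # inclusive
  expect_error(classify_species(120), "\\[0, 100\\]")
})

test_that("BLAST tabular files read back with optional length columns", {
  f <- tempfile()
  writeLines(c("q1\ts1\t98.5\t900\t10\t2\t1\t900\t1\t900\t1e-100\t450",
               "q2\ts2\t75.0\t500\t50\t5\t1\t500\t1\t500\t1e-20\t120"), f)
  h <- read_blast_tab(f)
  expect_equal(nrow(h), 2)
  expect_equal(h$percent_identity, c(98.5, 75))
  f13 <- tempfile()
  writeLines("q1\ts1\t98.5\t900\t10\t2\t1\t900\t1\t900\t1e-100\t450\t950",
             f13)
  expect_equal(read_blast_tab(f13)$query_length, 950)
})
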