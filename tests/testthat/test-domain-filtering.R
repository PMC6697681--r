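test_that("domtblout parsing hand-checks against a fixture row", {
  fixture <- c(
    "# comment",
    paste("PEP_mutase PF13714.18 100 protA - 400 1.2e-80 260.5 0.1 1 2",
          "3e-40 4e-40 130.2 0.05 5 90 10 101 8 105 0.92 PEP mutase domain"),
    paste("NTP_transf_3 PF12804.10 180 protA - 400 1e-30 110.0 0.2 2 2",
          "2e-15 3e-15 55.5 0.1 1 160 200 360 198 362 0.88 -"))
  hits <- read_domtblout(fixture)
  expect_equal(nrow(hits), 2)
  # hand-parsed values from the first data row
  expect_equal(hits$protein_id[1], "protA")
  expect_equal(hits$pfam_accession[1], "PF13714")
  expect_equal(hits$model_length[1], 100L)
  expect_equal(hits$hmm_from[1], 5L)
  expect_equal(hits$hmm_to[1], 90L)
  expect_equal(hits$ali_from[1], 10L)
  expect_equal(hits$ali_to[1], 101L)
  expect_equal(hits$domain_bit_score[1], 130.2)
  expect_equal(hits$description[1], "PEP mutase domain")
  expect_true(all(hits$meets_ga))

  expect_equal(nrow(read_domtblout(c("# only", "# comments"))), 0)
  expect_error(read_domtblout("PEP_mutase PF13714 100 p - 400"), "23")
  bad <- sub("^PEP_mutase PF13714.18 100", "PEP_mutase PF13714.18 xx",
             fixture[2])
  expect_error(read_domtblout(bad), "non-numeric")
})

test_that("parsing a generated bundle yields one hit per planted row", {
  ppm <- data.frame(replicon_id = "c", gene_index = c(1, 4),
                    has_motif = TRUE)
  ppm$partners <- list(c("PF12804", "PF01467"), character())
  b <- generate_bundle(genome_spec(
    "G", replicons = data.frame(replicon_id = "c", n_genes = 8),
    planted_ppm = ppm, seed = 2))
  hits <- read_domtblout(paste(b$domain_hits, collapse = "\n"))
  expect_equal(nrow(hits), 4) # PF13714 x2 + two partners on the first
})

test_that("GA table computes meets_ga from domain scores", {
  row <- paste("PEP_mutase PF13714.18 100 p1 - 400 1e-10 50 0.1 1 1",
               "1e-10 1e-10 21.0 0.1 1 80 1 90 1 90 0.9 -")
  ga <- c(PF13714 = 22.5)
  expect_false(read_domtblout(row, ga_table = ga)$meets_ga)
  ga2 <- c(PF13714 = 20.0)
  expect_true(read_domtblout(row, ga_table = ga2)$meets_ga)
})

test_that("coverage arithmetic and the inclusive 60% bound", {
  expect_equal(hit_coverage(data.frame(hmm_from = 1, hmm_to = 100,
                                       model_length = 100)), 1.0)
  expect_equal(hit_coverage(data.frame(hmm_from = 21, hmm_to = 80,
                                       model_length = 100)), 0.60)
  h <- tibble::tibble(protein_id = "p", pfam_accession = "PF13714",
                      model_length = 100L,
                      hmm_from = c(21L, 1L), hmm_to = c(80L, 59L),
                      ali_from = c(1L, 1L), ali_to = c(60L, 59L),
                      domain_bit_score = c(50, 50), meets_ga = TRUE)
  kept <- filter_hits(h)
  # 0.60 kept (inclusive), 0.59 removed
  expect_equal(kept$hmm_to, 80L)
  # GA requirement
  h$meets_ga <- c(FALSE, TRUE)
  expect_equal(nrow(filter_hits(h)), 0)
  expect_equal(nrow(filter_hits(h, require_ga = FALSE)), 1)
})

test_that("filter matches a brute-force predicate scan on random fixtures", {
  for (seed in 1:4) {
    h <- random_hits(50, seed = seed)
    got <- filter_hits(h)
    want <- oracle_filter(h)
    expect_equal(got[names(want)], want)
  }
})

test_that("filter is idempotent, subset-of-input, monotone in coverage", {
  h <- random_hits(80, seed = 9)
  f1 <- filter_hits(h)
  expect_equal(filter_hits(f1), f1)
  expect_true(all(f1$protein_id %in% h$protein_id))
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(mc) nrow(filter_hits(h, min_coverage = mc)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pooled split-domain coverage keeps fragmented families", {
  # two fragments of 35% each: dropped per-domain, kept pooled (70%)
  h <- tibble::tibble(protein_id = "p", pfam_accession = "PF13714",
                      model_length = 100L,
                      hmm_from = c(1L, 51L), hmm_to = c(35L, 85L),
                      ali_from = c(1L, 60L), ali_to = c(35L, 94L),
                      domain_bit_score = 40, meets_ga = TRUE)
  expect_equal(nrow(filter_hits(h)), 0)
  expect_equal(nrow(filter_hits(h, coverage_by = "protein")), 2)
})

test_that("overlap resolution keeps the highest-scoring of overlapping hits", {
  h <- tibble::tibble(protein_id = "p", pfam_accession = c("A", "B"),
                      model_length = 100L, hmm_from = 1L, hmm_to = 90L,
                      ali_from = c(1L, 50L), ali_to = c(100L, 150L),
                      domain_bit_score = c(80, 40), meets_ga = TRUE)
  kept <- resolve_overlaps(h)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$domain_bit_score, 80)
  # disjoint hits are both kept
  h$ali_from <- c(1L, 101L); h$ali_to <- c(100L, 200L)
  expect_equal(nrow(resolve_overlaps(h)), 2)
  # a configurable overlap tolerance admits small overlaps
  h$ali_from <- c(1L, 99L); h$ali_to <- c(100L, 200L)
  expect_equal(nrow(resolve_overlaps(h)), 1)
  expect_equal(nrow(resolve_overlaps(h, max_overlap = 2)), 2)
})

test_that("overlap resolution equals the brute-force greedy oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- 20
    from <- sample(1:300, n, replace = TRUE)
    h <- tibble::tibble(protein_id = "p", pfam_accession = "PFX",
                        model_length = 100L, hmm_from = 1L, hmm_to = 80L,
                        ali_from = as.integer(from),
                        ali_to = as.integer(from + sample(1:80, n, TRUE)),
                        domain_bit_score = round(runif(n, 1, 100), 1),
                        meets_ga = TRUE)
    got <- resolve_overlaps(h)
    want <- h[oracle_resolve_one(h), , drop = FALSE]
    expect_setequal(
      paste(got$ali_from, got$ali_to, got$domain_bit_score),
      paste(want$ali_from, want$ali_to, want$domain_bit_score))
    # kept intervals pairwise disjoint; total score >= any single hit
    if (nrow(got) > 1) {
      o <- got[order(got$ali_from), ]
      expect_true(all(o$ali_from[-1] > head(o$ali_to, -1)))
    }
    expect_gte(sum(got$domain_bit_score), max(h$domain_bit_score))
  }
})
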