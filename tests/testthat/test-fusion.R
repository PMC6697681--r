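test_that("deduplication keeps one representative per distinct sequence", {
  d <- deduplicate_sequences(c(b = "MKV", a = "mkv", c = "MDD"))
  expect_equal(sum(d$is_representative), 2)
  # case-insensitive; representative is first by sorted id
  expect_equal(d$representative_id[d$protein_id == "b"], "a")
  # all distinct: identity mapping
  d2 <- deduplicate_sequences(c(x = "AA", y = "AC"))
  expect_equal(d2$representative_id, d2$protein_id)
  expect_error(deduplicate_sequences(c(x = "")), "empty")
})

test_that("deduplication matches a set-of-strings oracle on bundles", {
  dup <- list(c(locus_protein_id("G", "c", 0), locus_protein_id("G", "c", 2),
                locus_protein_id("G", "c", 5)))
  b <- generate_bundle(genome_spec(
    "G", replicons = data.frame(replicon_id = "c", n_genes = 8),
    duplicate_groups = dup, seed = 21))
  prot <- read_protein_fasta(paste(b$proteins_fasta, collapse = "\n"))
  d <- deduplicate_sequences(prot)
  expect_equal(sum(d$is_representative),
               length(unique(toupper(prot$sequence))))
  expect_equal(sum(d$is_representative), b$truth$n_distinct_sequences)
  expect_equal(b$truth$n_distinct_sequences, 8 - 2)
})

test_that("fusion categories follow the partner-accession mapping", {
  mk <- function(accs) tibble::tibble(
    protein_id = "p", pfam_accession = accs, model_length = 100L,
    hmm_from = 1L, hmm_to = 90L,
    ali_from = as.integer(seq(1, by = 200, length.out = length(accs))),
    ali_to = as.integer(seq(150, by = 200, length.out = length(accs))),
    domain_bit_score = 50, meets_ga = TRUE)
  expect_equal(classify_fusion(mk("PF13714"))$category, "ALONE")
  expect_equal(classify_fusion(mk(c("PF13714", "PF12804")))$category,
               "NTP_TRANSF_3")
  expect_equal(classify_fusion(mk(c("PF13714", "PF01467")))$category,
               "CTP_TRANSF_LIKE")
  expect_equal(
    classify_fusion(mk(c("PF13714", "PF12804", "PF01467")))$category,
    "TRIPLE")
  expect_equal(classify_fusion(mk(c("PF13714", "PF02775")))$category,
               "OTHER")
  # named partner takes precedence over an unrelated extra by default
  expect_equal(classify_fusion(mk(c("PF13714", "PF12804", "PF02775")))$category,
               "NTP_TRANSF_3")
  expect_equal(classify_fusion(mk(c("PF13714", "PF12804", "PF02775")),
                               strict_other = TRUE)$category, "OTHER")
  # ALONE iff no partners
  expect_false(classify_fusion(mk("PF13714"))$is_fused)
  expect_error(classify_fusion(mk("PF12804")), "PF13714")
})

test_that("inventory summary reproduces the funnel arithmetic", {
  inv <- inventory_summary(
    per_category_counts = c(ALONE = 602, NTP_TRANSF_3 = 489,
                            CTP_TRANSF_LIKE = 350, TRIPLE = 42, OTHER = 2),
    n_nonredundant = 27716, n_fused = 905)
  expect_equal(inv$n_motif, 1485)
  expect_equal(inv$n_motif_fused, 883)
  expect_equal(inv$pct_fused_of_motif, 59.5)
  expect_equal(inv$pct_fused_of_nonredundant, 3.3)
  expect_equal(unname(inv$per_category_pct["ALONE"]), 40.5)
  expect_equal(unname(inv$per_category_pct["TRIPLE"]), 2.8)
  expect_equal(inv$n_removed, 26231)
  expect_equal(inv$n_removed_fused, 22)
  # percentages sum to 100 within rounding slack
  expect_lt(abs(sum(inv$per_category_pct) - 100), 0.3)
  # empty input: counts zero, percentages undefined (not zero)
  inv0 <- inventory_summary(integer(), n_nonredundant = 0, n_fused = 0)
  expect_equal(inv0$n_motif, 0)
  expect_true(is.na(inv0$pct_fused_of_motif))
  expect_true(all(is.na(inv0$per_category_pct)))
})

test_that("summarize_inventory aggregates a classification table", {
  cl <- tibble::tibble(
    protein_id = paste0("p", 1:6),
    category = c("ALONE", "ALONE", "NTP_TRANSF_3", "TRIPLE",
                 "CTP_TRANSF_LIKE", "ALONE"),
    partner_accessions = list(character(), character(), "PF12804",
                              c("PF12804", "PF01467"), "PF01467",
                              character()),
    is_fused = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    has_motif = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  inv <- summarize_inventory(cl)
  expect_equal(inv$n_nonredundant, 6)
  expect_equal(inv$n_motif, 4)
  expect_equal(inv$n_fused, 3)
  expect_equal(inv$n_motif_fused, 2)
  expect_equal(unname(inv$per_category_counts[c("ALONE", "TRIPLE")]),
               c(2L, 1L))
  expect_equal(sum(inv$per_category_counts), inv$n_motif)
  td <- tidy(inv)
  expect_equal(sum(td$count), 4)
  expect_equal(glance(inv)$n_removed, 2)
})

test_that("classification proportions are stable under exact duplication", {
  mkhits <- function(ids, withpartner) dplyr::bind_rows(lapply(seq_along(ids),
    function(i) tibble::tibble(
      protein_id = ids[i],
      pfam_accession = c("PF13714", if (withpartner[i]) "PF12804"),
      model_length = 100L, hmm_from = 1L, hmm_to = 90L,
      ali_from = c(1L, if (withpartner[i]) 200L),
      ali_to = c(150L, if (withpartner[i]) 350L),
      domain_bit_score = 50, meets_ga = TRUE)))
  ids <- paste0("p", 1:4)
  hits <- mkhits(ids, c(TRUE, TRUE, FALSE, FALSE))
  cl1 <- classify_fusion(hits)
  # duplicate every protein: proportions of categories unchanged
  hits2 <- hits
  hits2$protein_id <- paste0(hits2$protein_id, "_dup")
  cl2 <- classify_fusion(dplyr::bind_rows(hits, hits2))
  expect_equal(prop.table(table(cl1$category)),
               prop.table(table(cl2$category)))
})
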