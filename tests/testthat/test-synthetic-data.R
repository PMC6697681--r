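test_that("bundle construction realises planted facts and is deterministic", {
  spec <- genome_spec(
    "G1", replicons = data.frame(replicon_id = "chr", n_genes = 10),
    planted_ppm = data.frame(replicon_id = "chr", gene_index = 3,
                             has_motif = TRUE),
    planted_ntf_distances = data.frame(replicon_id = "chr",
                                       ppm_gene_index = 3, distance = 2),
    seed = 11)
  b <- generate_bundle(spec)
  expect_equal(b$truth$nearest_distance, 2)
  expect_equal(nrow(b$truth$ppm), 1)
  expect_equal(nrow(b$truth$ntf), 1)
  expect_equal(b$truth$ntf$gene_index, 5)

  # same spec, same seed: byte-identical
  b2 <- generate_bundle(spec)
  expect_identical(b$proteins_fasta, b2$proteins_fasta)
  expect_identical(b$gene_table, b2$gene_table)
  expect_identical(b$domain_hits, b2$domain_hits)
  expect_identical(b$genome_fasta, b2$genome_fasta)

  # distinct seeds give distinct sequences
  b3 <- generate_bundle(genome_spec(
    "G1", replicons = data.frame(replicon_id = "chr", n_genes = 10),
    planted_ppm = data.frame(replicon_id = "chr", gene_index = 3,
                             has_motif = TRUE),
    planted_ntf_distances = data.frame(replicon_id = "chr",
                                       ppm_gene_index = 3, distance = 2),
    seed = 12))
  expect_false(identical(b$proteins_fasta, b3$proteins_fasta))
})

test_that("motif presence in emitted proteins matches has_motif exactly", {
  for (seed in 1:10) {
    for (motif in c(TRUE, FALSE)) {
      b <- generate_bundle(genome_spec(
        "G", replicons = data.frame(replicon_id = "c", n_genes = 4),
        planted_ppm = data.frame(replicon_id = "c", gene_index = 1,
                                 has_motif = motif), seed = seed))
      prot <- read_protein_fasta(paste(b$proteins_fasta, collapse = "\n"))
      ppm_seq <- prot$sequence[prot$protein_id == b$truth$ppm$protein_id]
      # brute-force sliding-window scan, independent of the package scanner
      expect_equal(length(oracle_find_motif(ppm_seq)) > 0, motif,
                   info = sprintf("seed %d motif %s", seed, motif))
      # background proteins never carry an accidental motif
      for (s in prot$sequence[prot$protein_id != b$truth$ppm$protein_id]) {
        expect_length(oracle_find_motif(s), 0)
      }
    }
  }
})

test_that("spec validation rejects bad layouts", {
  reps <- data.frame(replicon_id = "chr", n_genes = 5)
  expect_error(genome_spec("G", reps,
    planted_ppm = data.frame(replicon_id = "chr", gene_index = 5,
                             has_motif = TRUE)), "outside")
  # two planted genes at the same locus collide
  expect_error(genome_spec("G", reps,
    planted_ppm = data.frame(replicon_id = "chr", gene_index = 2,
                             has_motif = TRUE),
    planted_ntf_distances = data.frame(replicon_id = "chr",
                                       ppm_gene_index = 2, distance = 0,
                                       accession = "PF12804"),
    seed = 1)$planted_ntf, NA) # distance 0 becomes a fusion, no collision
  expect_error(genome_spec("G", reps,
    planted_ppm = data.frame(replicon_id = "chr",
                             gene_index = c(2, 2),
                             has_motif = c(TRUE, FALSE))), "collision")
})

test_that("planted distance 0 is realised as a fusion, not a separate gene", {
  sp <- genome_spec(
    "G", replicons = data.frame(replicon_id = "chr", n_genes = 6),
    planted_ppm = data.frame(replicon_id = "chr", gene_index = 2,
                             has_motif = TRUE),
    planted_ntf_distances = data.frame(replicon_id = "chr",
                                       ppm_gene_index = 2, distance = 0,
                                       accession = "PF01467"),
    seed = 3)
  expect_equal(nrow(sp$planted_ntf), 0)
  b <- generate_bundle(sp)
  expect_equal(b$truth$ppm$partners[[1]], "PF01467")
  expect_equal(b$truth$nearest_distance, 0)
})

test_that("mutate_genome substitutes at the requested rate", {
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
             collapse = "")
  expect_identical(unname(mutate_genome(s, 0, seed = 5)), s)
  all_a <- strrep("A", 50)
  m <- mutate_genome(all_a, 1, seed = 5)
  expect_false(grepl("A", m))
  expect_equal(nchar(m), 50)
  expect_error(mutate_genome("ACGN", 0.1), "ACGT")

  # rate 0.05 on 100 kb: substitution count within 3 binomial sd of 5000
  set.seed(42)
  big <- paste(sample(c("A", "C", "G", "T"), 100000, replace = TRUE),
               collapse = "")
  mut <- mutate_genome(big, 0.05, seed = 9)
  n_sub <- sum(strsplit(big, "")[[1]] != strsplit(mut, "")[[1]])
  expect_lt(abs(n_sub - 5000), 3 * sqrt(100000 * 0.05 * 0.95))
})

test_that("kinetic datasets follow the rate law", {
  # half-saturation identity: at S = KM (no inhibition), v = kcat*E0/2
  d <- generate_kinetic_dataset(2, 0.5, Inf, 1e-8, S_grid = 0.5,
                                noise_sd = 0)
  expect_equal(d$v, 2 * 1e-8 / 2)
  # saturation asymptote
  d2 <- generate_kinetic_dataset(2, 0.5, Inf, 1e-8, S_grid = 5e4,
                                 noise_sd = 0)
  expect_equal(d2$v, 2e-8, tolerance = 1e-4)
  # AEP-like parameters: table equals direct hand evaluation of the law
  S <- c(0.002, 0.005, 0.012, 0.03, 0.1, 0.5)
  d3 <- generate_kinetic_dataset(3.7, 0.012, Inf, 2e-8, S_grid = S,
                                 noise_sd = 0)
  expect_equal(d3$v, 3.7 * 2e-8 * S / (0.012 + S))
  # substrate-inhibition term
  d4 <- generate_kinetic_dataset(3.7, 0.012, 4, 2e-8, S_grid = S,
                                 noise_sd = 0)
  expect_equal(d4$v, 3.7 * 2e-8 * S / (0.012 + S * (1 + S / 4)))
  # noise is seeded and reproducible
  a <- generate_kinetic_dataset(1, 1, Inf, 1e-8, S, noise_sd = 0.05,
                                seed = 3)
  b <- generate_kinetic_dataset(1, 1, Inf, 1e-8, S, noise_sd = 0.05,
                                seed = 3)
  expect_identical(a, b)
})
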