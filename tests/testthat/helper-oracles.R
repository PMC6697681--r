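# Independent brute-force oracles, re-implemented from the stated rules
# (not from the package code), plus random-fixture builders.

# sliding-window motif check: E,D,K, any 5, N,S
oracle_find_motif <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  starts <- integer()
  if (n >= 10) {
    for (i in 1:(n - 9)) {
      w <- chars[i:(i + 9)]
      if (w[1] == "E" && w[2] == "D" && w[3] == "K" &&
          w[9] == "N" && w[10] == "S") {
        starts <- c(starts, i)
      }
    }
  }
  starts
}

# predicate scan for the coverage/GA filter
oracle_filter <- function(hits, min_coverage = 0.6, require_ga = TRUE) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cov <- (hits$hmm_to[i] - hits$hmm_from[i] + 1) / hits$model_length[i]
    keep[i] <- cov >= min_coverage && (!require_ga || hits$meets_ga[i])
  }
  hits[keep, , drop = FALSE]
}

# greedy overlap resolution for one protein, re-derived from the rule:
# descending domain score, ties by smaller ali_from then input order; keep
# iff no residue shared with any kept hit
oracle_resolve_one <- function(h) {
  ord <- order(-h$domain_bit_score, h$ali_from, seq_len(nrow(h)))
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      lo <- max(h$ali_from[i], h$ali_from[k])
      hi <- min(h$ali_to[i], h$ali_to[k])
      if (hi - lo + 1 >= 1) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# dictionary 3-mer count over each sequence and its reverse complement,
# skipping windows with non-ACGT characters
oracle_trinuc <- function(seqs) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- setNames(numeric(64), phosmine:::TRINUCLEOTIDES)
  add <- function(s) {
    chars <- strsplit(s, "")[[1]]
    if (length(chars) < 3) return()
    for (i in 1:(length(chars) - 2)) {
      w <- chars[i:(i + 2)]
      if (all(w %in% names(comp))) {
        k <- paste(w, collapse = "")
        counts[k] <<- counts[k] + 1
      }
    }
  }
  for (s in seqs) {
    s <- toupper(s)
    add(s)
    rc <- paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
    add(rc)
  }
  counts / sum(counts)
}

random_hits <- function(n, n_proteins = 5, seed = 1) {
  set.seed(seed)
  model_length <- sample(80:300, n, replace = TRUE)
  hmm_from <- mapply(function(L) sample(1:L, 1), model_length)
  hmm_to <- mapply(function(a, L) sample(a:L, 1), hmm_from, model_length)
  ali_from <- sample(1:400, n, replace = TRUE)
  tibble::tibble(
    protein_id = paste0("p", sample(n_proteins, n, replace = TRUE)),
    pfam_accession = sample(c("PF13714", "PF12804", "PF01467", "PF02775"),
                            n, replace = TRUE),
    model_length = model_length,
    hmm_from = as.integer(hmm_from), hmm_to = as.integer(hmm_to),
    ali_from = as.integer(ali_from),
    ali_to = as.integer(ali_from + sample(5:120, n, replace = TRUE)),
    domain_bit_score = round(runif(n, 10, 300), 1),
    bit_score = round(runif(n, 10, 300), 1),
    meets_ga = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.8, 0.2))
  )
}

random_aa <- function(n) paste(sample(phosmine:::AA20, n, replace = TRUE),
                               collapse = "")

# a varied multi-genome study set with planted motifs, fusions, separate
# NTF genes at controlled distances, and exact duplicates
make_suite_specs <- function(n_genomes = 20, base_seed = 100) {
  partner_cycle <- list(character(), "PF12804", "PF01467",
                        c("PF12804", "PF01467"))
  lapply(seq_len(n_genomes), function(i) {
    gid <- sprintf("G%02d", i)
    n_genes <- 15 + (i %% 6)
    partners <- partner_cycle[[(i %% 4) + 1]]
    has_motif <- (i %% 7) != 0
    ppm_idx <- 3 + (i %% 5)
    ppm <- data.frame(replicon_id = "chr", gene_index = ppm_idx,
                      has_motif = has_motif)
    ppm$partners <- list(partners)
    ntf <- if (length(partners) == 0) {
      data.frame(replicon_id = "chr", ppm_gene_index = ppm_idx,
                 distance = (i %% 4) + 1,
                 accession = if (i %% 2) "PF12804" else "PF01467")
    } else NULL
    dup <- if (i %% 5 == 0) {
      list(c(phosmine::locus_protein_id(gid, "chr", 0),
             phosmine::locus_protein_id(gid, "chr", 1)))
    } else NULL
    phosmine::genome_spec(gid,
      replicons = data.frame(replicon_id = "chr", n_genes = n_genes),
      planted_ppm = ppm, planted_ntf_distances = ntf,
      duplicate_groups = dup, seed = base_seed + i)
  })
}

write_suite <- function(specs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- lapply(specs, function(sp) {
    b <- phosmine::generate_bundle(sp)
    p <- phosmine::write_bundle(b, file.path(dir, sp$genome_id))
    list(bundle = b, paths = p)
  })
  list(
    bundles = lapply(paths, `[[`, "bundle"),
    proteins = vapply(paths, function(x) x$paths[["proteins"]], character(1)),
    gff = vapply(paths, function(x) x$paths[["gff"]], character(1)),
    domtblout = vapply(paths, function(x) x$paths[["domtblout"]], character(1)),
    genomes = vapply(paths, function(x) x$paths[["genome"]], character(1))
  )
}
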