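# Synthetic genomes with planted ground truth.
#
# The generator emulates the inputs of a RefSeq-scale mining run at bench
# scale: replicons carrying ordered genes, Ppm-like proteins with or without
# the EDKXXXXXNS catalytic motif, fusion architectures (PF13714 alone,
# +PF12804, +PF01467, or triple), separate nucleotidyltransferase genes at
# controlled gene distances, exact-duplicate protein sequences, and genome
# nucleotide sequences for signature work. Every planted fact is recorded in
# a truth object so downstream stages can be checked exactly.

# evaluate code under a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Protein id of a synthetic gene locus
#'
#' @param genome_id,replicon_id,gene_index Locus coordinates as used in
#'   [genome_spec()].
#' @return Character id of the form `genome|replicon|gNNNN`.
#' @export
locus_protein_id <- function(genome_id, replicon_id, gene_index) {
  sprintf("%s|%s|g%04d", genome_id, replicon_id, gene_index)
}

#' Specify a synthetic genome
#'
#' Declares the layout of one synthetic genome: its replicons, the Ppm-like
#' proteins to plant (with motif status, fusion partners, and HMM-hit model
#' coverage), separate nucleotidyltransferase (NTF) genes at controlled gene
#' distances from a planted Ppm, and groups of genes that receive identical
#' protein sequences. The spec is validated here; [generate_bundle()] turns
#' it into FASTA/GFF3/domtblout text plus a truth record.
#'
#' @param genome_id Genome identifier (no `|` characters).
#' @param replicons Data frame with columns `replicon_id`, `n_genes`
#'   (positive integer) and optionally `circular` (logical, default FALSE).
#' @param planted_ppm Data frame with columns `replicon_id`, `gene_index`
#'   (0-based, within `[0, n_genes)`), `has_motif` (logical), and optionally
#'   `partners` (list-column of character vectors drawn from
#'   `c("PF12804", "PF01467")`) and `coverage` (fraction of the PF13714
#'   model covered by the emitted hit; default 0.8, set below 0.6 for
#'   negative controls). May be NULL.
#' @param planted_ntf_distances Data frame with columns `replicon_id`,
#'   `ppm_gene_index`, `distance` (non-negative integer gene distance) and
#'   optionally `accession` (`"PF12804"` or `"PF01467"`). A distance of 0 is
#'   realised as a fusion partner on the Ppm protein itself, never as a
#'   separate gene. May be NULL.
#' @param duplicate_groups List of character vectors of protein ids (see
#'   [locus_protein_id()]) that receive identical sequences. May be NULL.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `genome_spec`.
#' @examples
#' spec <- genome_spec(
#'   "G1",
#'   replicons = data.frame(replicon_id = "chr", n_genes = 10),
#'   planted_ppm = data.frame(replicon_id = "chr", gene_index = 3,
#'                            has_motif = TRUE),
#'   planted_ntf_distances = data.frame(replicon_id = "chr",
#'                                      ppm_gene_index = 3, distance = 2),
#'   seed = 1
#' )
#' @export
genome_spec <- function(genome_id, replicons, planted_ppm = NULL,
                        planted_ntf_distances = NULL,
                        duplicate_groups = NULL, seed = 1L) {
  stopifnot(is.character(genome_id), length(genome_id) == 1)
  if (grepl("|", genome_id, fixed = TRUE)) {
    abort("`genome_id` must not contain '|' (reserved as field separator)")
  }
  replicons <- as_tibble(replicons)
  if (!all(c("replicon_id", "n_genes") %in% names(replicons))) {
    abort("`replicons` needs columns replicon_id, n_genes")
  }
  if (!"circular" %in% names(replicons)) replicons$circular <- FALSE
  if (any(replicons$n_genes < 1)) abort("each replicon needs n_genes >= 1")
  if (anyDuplicated(replicons$replicon_id)) abort("duplicate replicon_id")

  ppm <- if (is.null(planted_ppm) || nrow(as_tibble(planted_ppm)) == 0) {
    tibble(replicon_id = character(), gene_index = integer(),
           has_motif = logical(), partners = list(), coverage = numeric())
  } else {
    p <- as_tibble(planted_ppm)
    if (!"partners" %in% names(p)) p$partners <- rep(list(character()), nrow(p))
    if (!is.list(p$partners)) p$partners <- as.list(p$partners)
    p$partners <- map(p$partners, function(x) sort(unique(as.character(x[!is.na(x)]))))
    if (!"coverage" %in% names(p)) p$coverage <- 0.8
    bad <- unlist(p$partners)
    if (!all(bad %in% NTF_ACCESSIONS)) {
      abort("fusion partners must be among PF12804, PF01467")
    }
    p
  }

  ntf <- if (is.null(planted_ntf_distances) ||
             nrow(as_tibble(planted_ntf_distances)) == 0) {
    tibble(replicon_id = character(), ppm_gene_index = integer(),
           distance = integer(), accession = character())
  } else {
    d <- as_tibble(planted_ntf_distances)
    if (!"accession" %in% names(d)) d$accession <- "PF12804"
    if (any(d$distance < 0)) abort("distances must be non-negative")
    d
  }

  # distance 0 means "fused": move it onto the ppm protein as a partner
  zero <- ntf$distance == 0
  if (any(zero)) {
    for (k in which(zero)) {
      i <- which(ppm$replicon_id == ntf$replicon_id[k] &
                 ppm$gene_index == ntf$ppm_gene_index[k])
      if (length(i) != 1) {
        abort("planted distance 0 must reference a planted ppm gene")
      }
      ppm$partners[[i]] <- sort(unique(c(ppm$partners[[i]], ntf$accession[k])))
    }
    ntf <- ntf[!zero, , drop = FALSE]
  }

  # resolve ntf gene placement: ppm_index + distance, falling back to the
  # other side when the replicon end is hit
  nmap <- setNames(replicons$n_genes, replicons$replicon_id)
  place <- function(rep_id, i, d) {
    n <- nmap[[rep_id]]
    if (is.null(n)) abort(sprintf("unknown replicon '%s'", rep_id))
    if (i + d < n) i + d else if (i - d >= 0) i - d else
      abort(sprintf("distance %d does not fit on replicon '%s'", d, rep_id))
  }
  ntf$gene_index <- if (nrow(ntf)) {
    as.integer(pmap(list(ntf$replicon_id, ntf$ppm_gene_index, ntf$distance),
                    place))
  } else integer()

  for (tb in list(ppm[c("replicon_id", "gene_index")],
                  ntf[c("replicon_id", "gene_index")])) {
    if (nrow(tb) && any(is.na(match(tb$replicon_id, replicons$replicon_id)))) {
      abort("planted gene references unknown replicon")
    }
  }
  all_idx <- bind_rows(ppm[c("replicon_id", "gene_index")],
                       ntf[c("replicon_id", "gene_index")])
  if (nrow(all_idx)) {
    n_at <- nmap[all_idx$replicon_id]
    if (any(all_idx$gene_index < 0 | all_idx$gene_index >= n_at)) {
      abort("planted gene_index outside [0, n_genes)")
    }
    if (anyDuplicated(all_idx)) {
      abort("index collision: two planted genes at the same locus")
    }
  }

  structure(
    list(genome_id = genome_id, replicons = replicons, planted_ppm = ppm,
         planted_ntf = ntf,
         duplicate_groups = duplicate_groups %||% list(),
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# remove accidental catalytic-motif occurrences by breaking the 'D' anchor;
# keeps planted occurrences intact via `keep_at` (1-based motif starts)
scrub_motif <- function(seq, keep_at = integer()) {
  repeat {
    hits <- gregexpr("(?=EDK.{5}NS)", seq, perl = TRUE)[[1]]
    hits <- hits[hits > 0 & !(hits %in% keep_at)]
    if (length(hits) == 0) return(seq)
    substr(seq, hits[1] + 1, hits[1] + 1) <- "G"
  }
}

DOMAIN_MODELS <- tibble::tibble(
  accession = c("PF13714", "PF12804", "PF01467"),
  name = c("PEP_mutase", "NTP_transf_3", "CTP_transf_like"),
  model_length = c(290L, 180L, 130L),
  version = c("PF13714.18", "PF12804.10", "PF01467.29")
)

domtbl_row <- function(name, accession, tlen, protein_id, qlen, score,
                       hmm_from, hmm_to, ali_from, ali_to, dom_i, dom_n) {
  paste(name, accession, tlen, protein_id, "-", qlen,
        format(10^(-score / 5), digits = 2, scientific = TRUE), score, "0.1",
        dom_i, dom_n,
        format(10^(-score / 5), digits = 2, scientific = TRUE),
        format(10^(-score / 5), digits = 2, scientific = TRUE), score, "0.1",
        hmm_from, hmm_to, ali_from, ali_to, ali_from, ali_to, "0.95",
        "synthetic domain hit", sep = " ")
}

#' Generate a synthetic bundle from a genome spec
#'
#' Emits, as plain text, one protein per gene (FASTA), a GFF3 gene table
#' whose ascending start coordinates define the gene ordinal index, an
#' HMMER3-style domtblout table containing one PF13714 row per planted Ppm
#' (model coverage as configured) plus one row per fusion-partner domain on
#' non-overlapping alignment coordinates and one row per separate NTF gene,
#' and a random nucleotide sequence per replicon. Ppm proteins contain the
#' literal motif `E, D, K, 5 arbitrary residues, N, S` iff `has_motif`;
#' accidental motif occurrences elsewhere are scrubbed so motif truth is
#' exact. Generation is deterministic given the spec's seed.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `synthetic_bundle`: a list with character-line
#'   elements `proteins_fasta`, `gene_table`, `domain_hits`, `genome_fasta`
#'   and a `truth` list recording every planted fact (protein table, ppm
#'   table with fusion category, ntf table, expected nearest ppm-NTF
#'   distance, duplicate map, distinct-sequence count).
#' @seealso [write_bundle()] to materialise the bundle on disk.
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    gid <- spec$genome_id
    prot_tab <- list(); fasta <- character(); gff <- "##gff-version 3"
    dom <- c("#", "# synthetic hmmscan --domtblout (phosmine generator)", "#")
    genome_fa <- character()

    ppm_key <- sprintf("%s:%d", spec$planted_ppm$replicon_id,
                       spec$planted_ppm$gene_index)
    ntf_key <- sprintf("%s:%d", spec$planted_ntf$replicon_id,
                       spec$planted_ntf$gene_index)
    ppm_truth <- list(); motif_starts <- integer()

    for (r in seq_len(nrow(spec$replicons))) {
      rid <- spec$replicons$replicon_id[r]
      n <- spec$replicons$n_genes[r]
      pos <- 1L
      for (g in seq_len(n) - 1L) {
        pid <- locus_protein_id(gid, rid, g)
        key <- sprintf("%s:%d", rid, g)
        kind <- "background"
        if (key %in% ppm_key) {
          k <- match(key, ppm_key)
          has_motif <- isTRUE(spec$planted_ppm$has_motif[k])
          partners <- spec$planted_ppm$partners[[k]]
          cov <- spec$planted_ppm$coverage[k]
          ppm_len <- 290L
          core <- random_protein(ppm_len)
          motif_at <- NA_integer_
          if (has_motif) {
            motif_at <- sample(20:(ppm_len - 30), 1)
            motif <- paste0("EDK", random_protein(5), "NS")
            substr(core, motif_at, motif_at + 9) <- motif
          }
          segs <- core; bounds <- tibble(accession = "PF13714",
                                         from = 1L, to = ppm_len)
          for (acc in partners) {
            m <- DOMAIN_MODELS[DOMAIN_MODELS$accession == acc, ]
            start <- nchar(paste(segs, collapse = "")) + 11L
            segs <- c(segs, random_protein(10), random_protein(m$model_length))
            bounds <- bind_rows(bounds, tibble(
              accession = acc, from = start,
              to = start + m$model_length - 1L))
          }
          seq <- paste(segs, collapse = "")
          seq <- scrub_motif(seq, keep_at = if (has_motif) motif_at else integer())
          qlen <- nchar(seq)
          n_dom <- nrow(bounds)
          for (b in seq_len(n_dom)) {
            m <- DOMAIN_MODELS[DOMAIN_MODELS$accession == bounds$accession[b], ]
            covb <- if (bounds$accession[b] == "PF13714") cov else 0.85
            span <- max(1L, ceiling(covb * m$model_length))
            dom <- c(dom, domtbl_row(
              m$name, m$version, m$model_length, pid, qlen,
              score = if (bounds$accession[b] == "PF13714") 250 else 150,
              hmm_from = 1L, hmm_to = span,
              ali_from = bounds$from[b],
              ali_to = min(bounds$from[b] + span - 1L, bounds$to[b]),
              dom_i = b, dom_n = n_dom))
          }
          category <- fusion_category(partners)
          ppm_truth[[length(ppm_truth) + 1]] <- tibble(
            protein_id = pid, replicon_id = rid, gene_index = g,
            has_motif = has_motif, partners = list(partners),
            category = category, coverage = cov)
          kind <- "ppm"
        } else if (key %in% ntf_key) {
          k <- match(key, ntf_key)
          acc <- spec$planted_ntf$accession[k]
          m <- DOMAIN_MODELS[DOMAIN_MODELS$accession == acc, ]
          seq <- scrub_motif(random_protein(m$model_length + 60L))
          span <- ceiling(0.85 * m$model_length)
          dom <- c(dom, domtbl_row(m$name, m$version, m$model_length, pid,
                                   nchar(seq), score = 150,
                                   hmm_from = 1L, hmm_to = span,
                                   ali_from = 31L, ali_to = 30L + span,
                                   dom_i = 1L, dom_n = 1L))
          kind <- "ntf"
        } else {
          seq <- scrub_motif(random_protein(sample(200:400, 1)))
        }
        glen <- 3L * nchar(seq) + 3L
        gff <- c(gff, paste(rid, "phosmine", "gene", pos, pos + glen - 1L,
                            ".", "+", ".",
                            sprintf("ID=%s;genome_id=%s", pid, gid),
                            sep = "\t"))
        prot_tab[[length(prot_tab) + 1]] <- tibble(
          protein_id = pid, genome_id = gid, replicon_id = rid,
          gene_index = g, kind = kind, sequence = seq)
        pos <- pos + glen + sample(20:200, 1)
      }
      genome_len <- pos + 100L
      genome_fa <- c(genome_fa, sprintf(">%s|%s", gid, rid),
                     paste(sample(c("A", "C", "G", "T"), genome_len,
                                  replace = TRUE), collapse = ""))
    }

    proteins <- bind_rows(prot_tab)

    # duplicate groups: every member gets the first member's sequence
    for (grp in spec$duplicate_groups) {
      grp <- as.character(grp)
      miss <- setdiff(grp, proteins$protein_id)
      if (length(miss)) abort(sprintf("duplicate group names unknown protein %s",
                                      miss[1]))
      src <- proteins$sequence[match(grp[1], proteins$protein_id)]
      proteins$sequence[proteins$protein_id %in% grp[-1]] <- src
    }

    fasta <- as.vector(rbind(paste0(">", proteins$protein_id),
                             proteins$sequence))

    ppm_tb <- if (length(ppm_truth)) bind_rows(ppm_truth) else
      tibble(protein_id = character(), replicon_id = character(),
             gene_index = integer(), has_motif = logical(),
             partners = list(), category = character(), coverage = numeric())

    # expected nearest ppm<->NTF gene distance for this genome, over
    # motif-positive ppm loci: 0 for any fusion, else index differences to
    # planted NTF genes on the same replicon
    cand <- numeric()
    act <- ppm_tb[ppm_tb$has_motif, , drop = FALSE]
    if (nrow(act)) {
      if (any(lengths(act$partners) > 0)) cand <- c(cand, 0)
      if (nrow(spec$planted_ntf)) {
        for (i in seq_len(nrow(act))) {
          same <- spec$planted_ntf$replicon_id == act$replicon_id[i]
          cand <- c(cand, abs(spec$planted_ntf$gene_index[same] -
                              act$gene_index[i]))
        }
      }
    }
    truth <- list(
      genome_id = gid,
      proteins = proteins[c("protein_id", "genome_id", "replicon_id",
                            "gene_index", "kind")],
      ppm = ppm_tb,
      ntf = if (nrow(spec$planted_ntf)) {
        tibble(protein_id = locus_protein_id(gid, spec$planted_ntf$replicon_id,
                                             spec$planted_ntf$gene_index),
               replicon_id = spec$planted_ntf$replicon_id,
               gene_index = spec$planted_ntf$gene_index,
               accession = spec$planted_ntf$accession)
      } else tibble(protein_id = character(), replicon_id = character(),
                    gene_index = integer(), accession = character()),
      nearest_distance = if (length(cand)) min(cand) else NA_real_,
      duplicate_groups = spec$duplicate_groups,
      n_distinct_sequences = length(unique(toupper(proteins$sequence)))
    )

    structure(list(proteins_fasta = fasta, gene_table = gff,
                   domain_hits = dom, genome_fasta = genome_fa,
                   truth = truth, spec = spec),
              class = "synthetic_bundle")
  })
}

fusion_category <- function(partners) {
  named <- intersect(partners, NTF_ACCESSIONS)
  if (length(partners) == 0) "ALONE"
  else if (setequal(named, NTF_ACCESSIONS)) "TRIPLE"
  else if (identical(named, "PF12804")) "NTP_TRANSF_3"
  else if (identical(named, "PF01467")) "CTP_TRANSF_LIKE"
  else "OTHER"
}

#' Write a synthetic bundle to a directory
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths plus `truth.json`,
#'   invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(proteins = file.path(dir, "proteins.faa"),
             gff = file.path(dir, "genes.gff3"),
             domtblout = file.path(dir, "hits.domtblout"),
             genome = file.path(dir, "genome.fna"),
             truth = file.path(dir, "truth.json"))
  write_lines_to(bundle$proteins_fasta, paths[["proteins"]])
  write_lines_to(bundle$gene_table, paths[["gff"]])
  write_lines_to(bundle$domain_hits, paths[["domtblout"]])
  write_lines_to(bundle$genome_fasta, paths[["genome"]])
  tr <- bundle$truth
  tr$ppm$partners <- map_chr(tr$ppm$partners, paste, collapse = ",")
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Mutate a nucleotide sequence by random substitution
#'
#' Each position is independently substituted with probability
#' `substitution_rate`; a substituted base is drawn uniformly from the three
#' other bases, so the sequence length is preserved and `rate = 1`
#' guarantees every position changes. Used to create genome replicates at a
#' controlled trinucleotide-signature divergence.
#'
#' @param genome_seq Character vector of ACGT sequences (one string per
#'   replicon) or a [Biostrings::DNAStringSet].
#' @param substitution_rate Per-position substitution probability in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return Character vector of mutated sequences (names preserved).
#' @examples
#' mutate_genome("ACGTACGT", 0.5, seed = 1)
#' @export
mutate_genome <- function(genome_seq, substitution_rate, seed = 1L) {
  if (inherits(genome_seq, "DNAStringSet")) {
    genome_seq <- setNames(as.character(genome_seq), names(genome_seq))
  }
  stopifnot(is.numeric(substitution_rate), substitution_rate >= 0,
            substitution_rate <= 1)
  if (any(grepl("[^ACGT]", genome_seq))) {
    abort("mutate_genome() accepts ACGT sequences only")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- map_chr(genome_seq, function(s) {
      v <- strsplit(s, "")[[1]]
      hit <- runif(length(v)) < substitution_rate
      if (any(hit)) {
        v[hit] <- map_chr(v[hit], function(b) sample(setdiff(bases, b), 1))
      }
      paste(v, collapse = "")
    })
    setNames(out, names(genome_seq))
  })
}

#' Simulate an initial-rate kinetic dataset
#'
#' Velocities follow the substrate-inhibition rate law
#' \deqn{v(S) = \frac{k_{cat} E_0 S}{K_M + S (1 + S/K_S)}}{
#'   v(S) = kcat E0 S / (KM + S (1 + S/KS))}
#' which reduces to Michaelis-Menten when `KS = Inf`. Noise is
#' multiplicative Gaussian with relative standard deviation `noise_sd`;
#' a draw that would make a velocity negative is clamped at 0 and flagged.
#'
#' @param kcat Turnover number (per second).
#' @param KM Michaelis constant, in the same concentration unit as `S_grid`
#'   (conventionally mM).
#' @param KS Substrate-inhibition constant (same unit); `Inf` for pure
#'   Michaelis-Menten behaviour.
#' @param E0 Total enzyme concentration (molar).
#' @param S_grid Non-empty numeric vector of substrate concentrations.
#' @param noise_sd Relative standard deviation of multiplicative noise.
#' @param seed Integer seed (ignored when `noise_sd = 0`).
#' @return A tibble with columns `S`, `v` (observed), `v_true` (noiseless)
#'   and `clamped`.
#' @examples
#' generate_kinetic_dataset(kcat = 3.7, KM = 0.012, E0 = 1e-8,
#'                          S_grid = c(0.003, 0.012, 0.05, 0.2))
#' @export
generate_kinetic_dataset <- function(kcat, KM, KS = Inf, E0,
                                     S_grid, noise_sd = 0, seed = 1L) {
  stopifnot(kcat > 0, KM > 0, KS > 0, E0 > 0, length(S_grid) > 0,
            all(S_grid >= 0), noise_sd >= 0)
  v_true <- kcat * E0 * S_grid / (KM + S_grid * (1 + S_grid / KS))
  v <- if (noise_sd > 0) {
    with_seed(seed, v_true * (1 + rnorm(length(S_grid), 0, noise_sd)))
  } else v_true
  clamped <- v < 0
  v[clamped] <- 0
  tibble(S = S_grid, v = v, v_true = v_true, clamped = clamped)
}
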