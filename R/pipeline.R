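# End-to-end orchestration: dereplicate genomes, filter domain hits, split
# by catalytic motif, deduplicate, inventory fusions, tabulate ppm-NTF gene
# distances, and (optionally) fit kinetic datasets. Every filtering
# decision is counted in the run log so the funnel is reconstructable.

#' Read protein sequences from FASTA
#'
#' @param paths Character vector of protein FASTA paths (or FASTA text).
#' @return Tibble with columns `protein_id` (header up to the first space)
#'   and `sequence`.
#' @export
read_protein_fasta <- function(paths) {
  one <- function(p) {
    if (length(p) == 1 && !grepl("\n", p, fixed = TRUE) && file.exists(p)) {
      aa <- Biostrings::readAAStringSet(p)
    } else {
      tf <- tempfile(fileext = ".faa")
      on.exit(unlink(tf), add = TRUE)
      writeLines(input_lines(p), tf)
      aa <- Biostrings::readAAStringSet(tf)
    }
    tibble(protein_id = sub(" .*$", "", names(aa)),
           sequence = as.character(aa))
  }
  bind_rows(map(paths, one))
}

#' Pipeline configuration
#'
#' Collects input paths, thresholds and accession sets for
#' [run_ppm_pipeline()] and validates them up front, before any work is
#' done.
#'
#' @param proteins,gff,domtblout,genomes Character vectors of input paths
#'   (protein FASTA, GFF3 gene tables, HMMER3 domtblout tables, genome
#'   nucleotide FASTA). `genomes` may be NULL to skip dereplication.
#' @param kinetics Optional named list of kinetic datasets, each a list
#'   with elements `data` (TSV path or data frame with columns `S`, `v`),
#'   `E0` (molar) and `model` (`"MM"` or `"SI"`).
#' @param min_coverage Minimum HMM model coverage for a domain hit
#'   (default 0.6).
#' @param require_ga Require gathering-threshold membership (default TRUE).
#' @param delta Trinucleotide-signature dereplication cutoff (default
#'   0.03).
#' @param within_k Distance bound for the "within k genes" summary
#'   (default 5).
#' @param ppm_accession Pfam accession marking Ppm (default PF13714).
#' @param ntf_accessions Accessions conferring the nucleotidyltransferase
#'   role (default PF12804, PF01467).
#' @param motif Restricted motif pattern (default `"EDKx{5}NS"`).
#' @param circular Treat replicons as circular when computing distances.
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed funnels into any stochastic helper).
#' @param output_dir Optional directory for per-stage TSV/JSON outputs.
#' @return Validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, gff, domtblout, genomes = NULL,
                            kinetics = NULL, min_coverage = 0.6,
                            require_ga = TRUE, delta = 0.03, within_k = 5,
                            ppm_accession = PPM_ACCESSION,
                            ntf_accessions = NTF_ACCESSIONS,
                            motif = "EDKx{5}NS", circular = FALSE,
                            seed = 1L, output_dir = NULL) {
  if (min_coverage < 0 || min_coverage > 1) {
    abort("min_coverage must lie in [0, 1]")
  }
  if (delta < 0) abort("delta must be non-negative")
  if (within_k < 0) abort("within_k must be non-negative")
  accs <- c(ppm_accession, ntf_accessions)
  if (!all(grepl("^PF\\d{5}$", accs))) {
    abort("Pfam accessions must look like PF13714")
  }
  motif_pattern(motif)  # validates
  structure(list(proteins = proteins, gff = gff, domtblout = domtblout,
                 genomes = genomes, kinetics = kinetics,
                 min_coverage = min_coverage, require_ga = require_ga,
                 delta = delta, within_k = within_k,
                 ppm_accession = ppm_accession,
                 ntf_accessions = ntf_accessions, motif = motif,
                 circular = circular, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the genome-mining pipeline
#'
#' Executes the full workflow: trinucleotide-signature dereplication of the
#' genome set; domtblout parsing with coverage/GA filtering and
#' highest-score overlap resolution; motif splitting of PF13714 matches;
#' sequence deduplication; fusion classification and inventory; per-genome
#' nearest ppm-NTF gene distances restricted to representative genomes; and
#' kinetic fits for any configured rate tables. Per-stage record counts are
#' accumulated in `log`, and TSV/JSON artifacts are written when
#' `output_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `ppm_report`: a list with `derep`, `hits`
#'   (filtered + resolved), `motif_split` counts, `dedup`,
#'   `classifications`, `inventory` (a `ppm_inventory`), `distances`,
#'   `distribution` (a `distance_distribution`), `kinetic_fits`, `summary`
#'   (plain list mirroring the headline statistics) and `log`.
#' @export
run_ppm_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(seed = config$seed, min_coverage = config$min_coverage,
              delta = config$delta, within_k = config$within_k)

  derep <- NULL
  keep_genomes <- NULL
  if (!is.null(config$genomes)) {
    derep <- dereplicate_genomes(config$genomes, delta = config$delta)
    keep_genomes <- derep$genome_id[derep$is_representative]
    log$n_genomes_in <- nrow(derep)
    log$n_genomes_representative <- length(keep_genomes)
  }

  raw_hits <- bind_rows(map(config$domtblout, read_domtblout))
  log$n_hits_raw <- nrow(raw_hits)
  hits <- filter_hits(raw_hits, min_coverage = config$min_coverage,
                      require_ga = config$require_ga)
  log$n_hits_filtered <- nrow(hits)
  hits <- resolve_overlaps(hits)
  log$n_hits_resolved <- nrow(hits)

  proteins <- read_protein_fasta(config$proteins)
  log$n_proteins <- nrow(proteins)

  ppm_ids_all <- unique(hits$protein_id[hits$pfam_accession ==
                                          config$ppm_accession])
  candidates <- proteins[proteins$protein_id %in% ppm_ids_all, , drop = FALSE]
  log$n_pf13714_proteins <- nrow(candidates)

  dedup <- deduplicate_sequences(candidates)
  nr <- dedup[dedup$is_representative, , drop = FALSE]
  log$n_nonredundant <- nrow(nr)

  split <- split_by_motif(nr[c("protein_id", "sequence")],
                          pattern = config$motif)
  log$n_motif_positive <- unname(split$counts[["n_ppm"]])
  log$n_motif_removed <- unname(split$counts[["n_removed"]])

  cls <- classify_fusion(hits[hits$protein_id %in% nr$protein_id, ,
                              drop = FALSE],
                         motif = bind_rows(split$ppm, split$removed))
  inventory <- summarize_inventory(cls, n_total = nrow(candidates))

  # distances use all motif-positive ppm proteins (duplicates included:
  # each genome keeps its own loci), restricted to representative genomes
  motif_all <- split_by_motif(candidates[c("protein_id", "sequence")],
                              pattern = config$motif)
  loci <- read_gene_table(config$gff)
  if (!is.null(keep_genomes)) {
    loci <- loci[loci$genome_id %in% keep_genomes, , drop = FALSE]
  }
  loci <- assign_roles(loci, ppm_ids = motif_all$ppm$protein_id,
                       hits = hits, ntf_accessions = config$ntf_accessions)
  distances <- nearest_ntf_distance(loci, circular = config$circular)
  log$n_genomes_with_distance <- nrow(distances)
  distribution <- build_distribution(distances, within_k = config$within_k)

  kinetic_fits <- NULL
  if (!is.null(config$kinetics)) {
    kinetic_fits <- imap(config$kinetics, function(k, nm) {
      d <- if (is.data.frame(k$data)) as_tibble(k$data) else
        as_tibble(utils::read.delim(k$data))
      if (identical(k$model, "SI")) {
        fit_substrate_inhibition(d, E0 = k$E0)
      } else {
        fit_michaelis_menten(d, E0 = k$E0)
      }
    })
  }

  summary <- list(
    n_genomes_representative = log$n_genomes_representative,
    n_pf13714_proteins = log$n_pf13714_proteins,
    n_nonredundant = inventory$n_nonredundant,
    n_fused = inventory$n_fused,
    n_motif = inventory$n_motif,
    n_motif_fused = inventory$n_motif_fused,
    n_removed = inventory$n_removed,
    n_removed_fused = inventory$n_removed_fused,
    pct_fused_of_nonredundant = inventory$pct_fused_of_nonredundant,
    pct_fused_of_motif = inventory$pct_fused_of_motif,
    per_category_pct = as.list(inventory$per_category_pct),
    n_genomes_with_distance = distribution$n,
    fraction_at_zero = distribution$fraction_at_zero,
    fraction_within_k = distribution$fraction_within_k,
    within_k = config$within_k
  )

  report <- structure(
    list(config = config, derep = derep, hits = hits, dedup = dedup,
         motif_split = split$counts, classifications = cls,
         inventory = inventory, distances = distances,
         distribution = distribution, kinetic_fits = kinetic_fits,
         summary = summary, log = log),
    class = "ppm_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write pipeline report artifacts
#'
#' Writes the per-protein inventory TSV, distances and histogram TSVs, the
#' dereplication table, the JSON summary, and a run log listing every
#' stage's record counts and the thresholds used.
#'
#' @param report A `ppm_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cls <- report$classifications
  cls$partner_accessions <- map_chr(cls$partner_accessions, paste,
                                    collapse = ",")
  utils::write.table(cls, file.path(dir, "inventory.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$distances, file.path(dir, "distances.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$distribution$histogram,
                     file.path(dir, "histogram.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(report$derep)) {
    utils::write.table(report$derep, file.path(dir, "representatives.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c("phosmine run log",
               sprintf("%s: %s", names(report$log),
                       vapply(report$log, function(v)
                         paste(format(v), collapse = ","), character(1)))),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.ppm_report <- function(x, ...) {
  cat("phosmine pipeline report\n")
  print(x$inventory)
  print(x$distribution)
  invisible(x)
}
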