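# Genome dereplication by trinucleotide DNA signature: a 64-component
# vector of 3-mer relative frequencies counted on both strands is a coarse,
# assembly-robust species-level fingerprint; greedy leader clustering at a
# small signature distance reduces a genome set to roughly one
# representative per species.

TRINUCLEOTIDES <- apply(expand.grid(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"))[, 3:1],
                        1, paste, collapse = "")

#' Trinucleotide signature of a genome
#'
#' Counts all overlapping 3-mers over every sequence record and its reverse
#' complement (windows containing non-ACGT characters are skipped), then
#' normalises to relative frequencies. Counting both strands makes the
#' signature invariant under reverse-complementing the assembly.
#'
#' @param genome_seq A [Biostrings::DNAStringSet], a character vector of
#'   nucleotide sequences, or a path to a nucleotide FASTA file.
#' @return Named numeric vector of 64 frequencies in lexicographic 3-mer
#'   order (AAA ... TTT), summing to 1, with attributes `genome_id` (when
#'   derived from a file) and `total_length`.
#' @examples
#' trinucleotide_signature("AAAA")
#' @export
trinucleotide_signature <- function(genome_seq) {
  if (is.character(genome_seq) && length(genome_seq) == 1 &&
      file.exists(genome_seq)) {
    genome_seq <- Biostrings::readDNAStringSet(genome_seq)
  }
  if (!inherits(genome_seq, "DNAStringSet")) {
    genome_seq <- Biostrings::DNAStringSet(toupper(genome_seq))
  }
  both <- c(genome_seq, Biostrings::reverseComplement(genome_seq))
  counts <- colSums(Biostrings::oligonucleotideFrequency(both, width = 3))
  counts <- counts[TRINUCLEOTIDES]
  total <- sum(counts)
  if (total == 0) abort("no valid ACGT 3-mer window in input")
  structure(counts / total,
            total_length = sum(Biostrings::width(genome_seq)))
}

#' Signature distance between two genomes
#'
#' Mean absolute difference of the 64 signature components, multiplied by
#' `scale` (default 100) so that the conventional species-level cutoff
#' `delta = 0.03` operates on the scaled value.
#'
#' @param a,b Signature vectors from [trinucleotide_signature()].
#' @param scale Scaling factor applied to the mean absolute difference.
#' @return Non-negative real; 0 iff the signatures are identical.
#' @export
signature_distance <- function(a, b, scale = 100) {
  stopifnot(length(a) == 64, length(b) == 64)
  mean(abs(as.numeric(a) - as.numeric(b))) * scale
}

#' Compute signatures for a set of genomes
#'
#' @param genomes Named list of genome sequences (each element a character
#'   vector, `DNAStringSet`, or FASTA path), or a character vector of FASTA
#'   paths. When a FASTA record name contains `|`, the part before the
#'   first `|` is taken as the genome id and records are grouped by it, so
#'   one multi-genome FASTA can hold a whole genome set.
#' @return Tibble with columns `genome_id`, `total_length`, `signature`
#'   (list-column of 64-vectors).
#' @export
genome_signatures <- function(genomes) {
  if (is.character(genomes) && is.null(names(genomes)) &&
      all(file.exists(genomes))) {
    sets <- map(genomes, Biostrings::readDNAStringSet)
    all_seq <- do.call(c, sets)
    ids <- sub("\\|.*$", "", sub(" .*$", "", names(all_seq)))
    genomes <- map(split(seq_along(all_seq), ids), function(ii) all_seq[ii])
  }
  if (is.null(names(genomes))) {
    names(genomes) <- paste0("genome", seq_along(genomes))
  }
  sig <- map(genomes, trinucleotide_signature)
  tibble(genome_id = names(genomes),
         total_length = map_dbl(sig, function(s) attr(s, "total_length")),
         signature = map(sig, as.numeric))
}

#' Dereplicate genomes by signature distance
#'
#' Greedy leader clustering: genomes are visited in order of decreasing
#' total length (ties broken by `genome_id`); each genome joins the first
#' existing representative within `delta`, otherwise it founds a new
#' cluster. Every non-representative therefore lies within `delta` of its
#' representative, and the output is deterministic.
#'
#' @param genomes Input accepted by [genome_signatures()], or its tibble
#'   output.
#' @param delta Signature-distance cutoff (on the scaled distance); the
#'   default 0.03 corresponds roughly to species.
#' @param scale Passed to [signature_distance()].
#' @return Tibble with one row per genome: `genome_id`, `total_length`,
#'   `representative_id`, `distance_to_representative`,
#'   `is_representative`.
#' @export
dereplicate_genomes <- function(genomes, delta = 0.03, scale = 100) {
  stopifnot(delta >= 0)
  sigs <- if (is.data.frame(genomes) && "signature" %in% names(genomes)) {
    as_tibble(genomes)
  } else {
    genome_signatures(genomes)
  }
  if (nrow(sigs) == 0) abort("at least one genome is required")
  ord <- order(-sigs$total_length, sigs$genome_id)
  sigs <- sigs[ord, , drop = FALSE]
  reps <- integer(0)
  rep_id <- character(nrow(sigs)); dist_to <- numeric(nrow(sigs))
  for (i in seq_len(nrow(sigs))) {
    assigned <- FALSE
    for (r in reps) {
      d <- signature_distance(sigs$signature[[i]], sigs$signature[[r]],
                              scale = scale)
      if (d <= delta) {
        rep_id[i] <- sigs$genome_id[r]; dist_to[i] <- d
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      rep_id[i] <- sigs$genome_id[i]; dist_to[i] <- 0
    }
  }
  tibble(genome_id = sigs$genome_id, total_length = sigs$total_length,
         representative_id = rep_id, distance_to_representative = dist_to,
         is_representative = sigs$genome_id == rep_id)
}
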