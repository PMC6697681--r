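# Gene-neighborhood distances between ppm and nucleotidyltransferase genes.
# Distances are counted in genes: the absolute difference of gene ordinal
# indices along a replicon (assigned by ascending start coordinate, strand
# ignored), so adjacent genes are 1 apart and a nucleotidyltransferase
# domain fused onto the Ppm polypeptide itself is at distance 0.

#' Read a GFF3 gene table into ordered gene loci
#'
#' Imports gene rows and assigns each gene a 0-based ordinal index along
#' its replicon by ascending start coordinate (strand ignored). The genome
#' a replicon belongs to is taken from a `genome_id` attribute when present
#' (as written by [generate_bundle()]), otherwise from the file name.
#'
#' @param paths Character vector of GFF3 file paths (or GFF3 text).
#' @return Tibble with columns `genome_id`, `replicon_id`, `protein_id`
#'   (the gene's `ID` attribute), `start`, `end`, `gene_index`.
#' @export
read_gene_table <- function(paths) {
  one <- function(p) {
    lines <- input_lines(p)
    src <- if (length(p) == 1 && !grepl("\n", p, fixed = TRUE) &&
               file.exists(p)) p else NULL
    tf <- tempfile(fileext = ".gff3")
    on.exit(unlink(tf), add = TRUE)
    writeLines(lines, tf)
    gr <- rtracklayer::import(tf, format = "gff3")
    mc <- as.data.frame(gr)
    gid <- if ("genome_id" %in% names(mc)) as.character(mc$genome_id) else
      rep(if (is.null(src)) "genome" else
        sub("\\.[^.]*$", "", basename(src)), nrow(mc))
    tibble(genome_id = gid,
           replicon_id = as.character(mc$seqnames),
           protein_id = as.character(mc$ID),
           start = mc$start, end = mc$end)
  }
  tab <- bind_rows(map(paths, one))
  tab <- tab[order(tab$genome_id, tab$replicon_id, tab$start), , drop = FALSE]
  tab <- group_by(tab, .data$genome_id, .data$replicon_id)
  tab <- mutate(tab, gene_index = row_number() - 1L)
  ungroup(tab)
}

#' Annotate gene loci with Ppm and nucleotidyltransferase roles
#'
#' A locus carries the PPM role when its protein is a motif-positive,
#' filter-surviving PF13714 match, and the NTF role when its resolved hits
#' include one of the nucleotidyltransferase families (PF12804 / PF01467 by
#' default; extendable to the wider PntC retrieval set PF00483 / PF01129).
#' A fused protein carries both roles.
#'
#' @param loci Gene-locus tibble from [read_gene_table()].
#' @param ppm_ids Character vector of motif-positive Ppm protein ids.
#' @param hits Resolved, filtered domain-hit tibble.
#' @param ntf_accessions Accessions conferring the NTF role.
#' @return `loci` with logical columns `is_ppm` and `is_ntf`.
#' @export
assign_roles <- function(loci, ppm_ids, hits,
                         ntf_accessions = NTF_ACCESSIONS) {
  ntf_ids <- unique(hits$protein_id[hits$pfam_accession %in% ntf_accessions])
  mutate(as_tibble(loci),
         is_ppm = .data$protein_id %in% ppm_ids,
         is_ntf = .data$protein_id %in% ntf_ids)
}

#' Gene distance between two loci
#'
#' Absolute difference of gene ordinal indices; 0 when both roles sit on
#' the same gene (a fusion). On a circular replicon the distance is the
#' smaller of the two arc distances.
#'
#' @param a,b One-row gene-locus data frames (same replicon).
#' @param circular Treat the replicon as circular.
#' @param n_genes Total genes on the replicon (required when `circular`).
#' @return Non-negative integer gene distance.
#' @examples
#' gene_distance(10, 12)
#' @export
pair_distance <- function(a, b, circular = FALSE, n_genes = NULL) {
  if (!identical(a$replicon_id, b$replicon_id) ||
      !identical(a$genome_id, b$genome_id)) {
    abort("loci lie on different replicons: no gene distance is defined")
  }
  gene_distance(a$gene_index, b$gene_index, circular = circular,
                n_genes = n_genes)
}

#' @rdname pair_distance
#' @param i,j Gene ordinal indices (vectorised).
#' @export
gene_distance <- function(i, j, circular = FALSE, n_genes = NULL) {
  d <- abs(i - j)
  if (circular) {
    if (is.null(n_genes)) abort("circular distance needs n_genes")
    d <- pmin(d, n_genes - d)
  }
  as.integer(d)
}

#' Nearest ppm-NTF gene distance per genome
#'
#' For each genome, the minimum gene distance over all PPM x NTF locus
#' pairs sharing a replicon; a locus carrying both roles (fusion) yields 0
#' immediately. When several ppm or NTF genes are present only the closest
#' pair is tabulated. Genomes lacking either role contribute no record.
#'
#' @param loci Role-annotated locus tibble (see [assign_roles()]).
#' @param circular Treat replicons as circular (minimum arc distance).
#' @return Tibble with columns `genome_id`, `distance`.
#' @export
nearest_ntf_distance <- function(loci, circular = FALSE) {
  loci <- as_tibble(loci)
  per_genome <- map(split(loci, loci$genome_id), function(g) {
    if (!any(g$is_ppm) || !any(g$is_ntf)) return(NULL)
    if (any(g$is_ppm & g$is_ntf)) return(0L)
    best <- Inf
    for (rep_id in unique(g$replicon_id)) {
      gr <- g[g$replicon_id == rep_id, , drop = FALSE]
      pi <- gr$gene_index[gr$is_ppm]
      ni <- gr$gene_index[gr$is_ntf]
      if (length(pi) == 0 || length(ni) == 0) next
      d <- abs(outer(pi, ni, "-"))
      if (circular) d <- pmin(d, nrow(gr) - d)
      best <- min(best, d)
    }
    if (is.finite(best)) as.integer(best) else NULL
  })
  per_genome <- per_genome[!vapply(per_genome, is.null, logical(1))]
  if (length(per_genome) == 0) {
    return(tibble(genome_id = character(), distance = integer()))
  }
  tibble(genome_id = names(per_genome),
         distance = unlist(per_genome, use.names = FALSE))
}

#' Build the ppm-NTF distance distribution
#'
#' Summarises per-genome nearest distances as a histogram with log10
#' counts, the cumulative fraction of genomes at or below each distance,
#' and the headline fractions at distance 0 (fused) and within `within_k`
#' genes.
#'
#' @param records Tibble with a `distance` column (e.g. from
#'   [nearest_ntf_distance()]) or a bare numeric vector of distances.
#' @param within_k Distance bound for the "within k genes" summary
#'   (default 5).
#' @return Object of class `distance_distribution` with elements `records`,
#'   `histogram` (tibble `distance`, `count`, `log10_count`,
#'   `cumulative_fraction`; zero-count distances omitted), `n`,
#'   `fraction_at_zero`, `fraction_within_k`, `within_k`.
#' @examples
#' build_distribution(c(0, 0, 2, 5))
#' @export
build_distribution <- function(records, within_k = 5) {
  if (is.data.frame(records)) {
    d <- records$distance
  } else {
    d <- as.numeric(records)
    records <- tibble(genome_id = paste0("g", seq_along(d)), distance = d)
  }
  n <- length(d)
  if (n == 0) {
    hist <- tibble(distance = integer(), count = integer(),
                   log10_count = numeric(), cumulative_fraction = numeric())
    return(structure(list(records = as_tibble(records), histogram = hist,
                          n = 0L, fraction_at_zero = NA_real_,
                          fraction_within_k = NA_real_, within_k = within_k),
                     class = "distance_distribution"))
  }
  tb <- table(d)
  hist <- tibble(distance = as.integer(names(tb)),
                 count = as.integer(tb))
  hist <- hist[order(hist$distance), , drop = FALSE]
  hist$log10_count <- log10(hist$count)
  hist$cumulative_fraction <- cumsum(hist$count) / n
  structure(list(records = as_tibble(records), histogram = hist, n = n,
                 fraction_at_zero = sum(d == 0) / n,
                 fraction_within_k = sum(d <= within_k) / n,
                 within_k = within_k),
            class = "distance_distribution")
}

#' Fraction of genomes with nearest distance at most k
#'
#' @param x A `distance_distribution`.
#' @param k Gene-distance bound.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_within <- function(x, k) {
  stopifnot(inherits(x, "distance_distribution"))
  if (x$n == 0) return(NA_real_)
  sum(x$records$distance <= k) / x$n
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("ppm-NTF nearest gene distances: %d genomes\n", x$n))
  if (x$n > 0) {
    cat(sprintf("  fused (distance 0):   %.1f%%\n", 100 * x$fraction_at_zero))
    cat(sprintf("  within %d genes:       %.1f%%\n", x$within_k,
                100 * x$fraction_within_k))
  }
  invisible(x)
}

#' @rdname tidiers
#' @method tidy distance_distribution
#' @export
tidy.distance_distribution <- function(x, ...) x$histogram

#' @rdname tidiers
#' @method glance distance_distribution
#' @export
glance.distance_distribution <- function(x, ...) {
  tibble(n_genomes = x$n, fraction_at_zero = x$fraction_at_zero,
         fraction_within_k = x$fraction_within_k, within_k = x$within_k)
}

#' Plot table for the distance distribution
#'
#' One row per observed distance with `distance`, `count`, `log10_count`
#' and `cumulative_fraction`; distances with zero count are omitted. This
#' is the tabular form behind the standard log-count / cumulative-fraction
#' distance figure.
#'
#' @param x A `distance_distribution`.
#' @return A tibble.
#' @export
distance_plot_table <- function(x) {
  stopifnot(inherits(x, "distance_distribution"))
  if (x$n == 0) abort("empty distribution has no plot table")
  x$histogram
}
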