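# HMMER3 per-domain hit tables and the hit-quality filters used for
# Ppm/PntC retrieval: gathering-threshold membership, >= 60% model
# coverage, and highest-score overlap resolution.

#' Read an HMMER3 domtblout table
#'
#' Parses the fixed 23-column per-domain tabular output of `hmmscan`
#' (`--domtblout`). Comment lines start with `#`; the free-text description
#' field is preserved as the trailing remainder of each row. One row is
#' returned per domain hit.
#'
#' Gathering-threshold (GA) status is not encoded in domtblout. Searches
#' run with `--cut_ga` emit only passing rows, so `meets_ga` defaults to
#' `TRUE`; when the table comes from an unthresholded search, supply
#' `ga_table` (named numeric vector, Pfam accession -> GA domain bit score)
#' and `meets_ga` is computed as `domain_bit_score >= GA`.
#'
#' @param x Path to a domtblout file, or its text (single string or
#'   character vector of lines).
#' @param ga_table Optional named numeric vector of per-family GA domain
#'   bit-score cutoffs.
#' @return A tibble with one row per domain hit: `protein_id` (the query),
#'   `pfam_accession` (version suffix stripped), `model_name`,
#'   `model_length`, `protein_length`, `evalue` (full-sequence E-value),
#'   `bit_score` (full-sequence), `domain_bit_score`, `hmm_from`, `hmm_to`,
#'   `ali_from`, `ali_to`, `env_from`, `env_to`, `meets_ga`, `description`.
#' @examples
#' row <- paste("PEP_mutase PF13714.18 290 prot1 - 420 1e-50 250 0.1 1 1",
#'              "1e-50 1e-50 250 0.1 5 290 10 300 10 300 0.95 example hit")
#' read_domtblout(row)
#' @export
read_domtblout <- function(x, ga_table = NULL) {
  lines <- input_lines(x)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  rows <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (length(rows) == 0) {
    return(tibble(protein_id = character(), pfam_accession = character(),
                  model_name = character(), model_length = integer(),
                  protein_length = integer(), evalue = numeric(),
                  bit_score = numeric(), domain_bit_score = numeric(),
                  hmm_from = integer(), hmm_to = integer(),
                  ali_from = integer(), ali_to = integer(),
                  env_from = integer(), env_to = integer(),
                  meets_ga = logical(), description = character()))
  }
  parsed <- map(seq_along(rows), function(i) {
    tok <- strsplit(trimws(rows[i]), "[ \t]+")[[1]]
    if (length(tok) < 23) {
      abort(sprintf("domtblout line %d: expected >= 23 fields, found %d",
                    lineno[i], length(tok)))
    }
    num_idx <- c(3, 6, 7, 8, 12, 14, 16:21)
    vals <- suppressWarnings(as.numeric(tok[num_idx]))
    if (anyNA(vals)) {
      abort(sprintf("domtblout line %d: non-numeric value in column %d",
                    lineno[i], num_idx[which(is.na(vals))[1]]))
    }
    tibble(
      protein_id = tok[4],
      pfam_accession = sub("\\.\\d+$", "", tok[2]),
      model_name = tok[1],
      model_length = as.integer(vals[1]),
      protein_length = as.integer(vals[2]),
      evalue = vals[3], bit_score = vals[4],
      domain_bit_score = vals[6],
      hmm_from = as.integer(vals[7]), hmm_to = as.integer(vals[8]),
      ali_from = as.integer(vals[9]), ali_to = as.integer(vals[10]),
      env_from = as.integer(vals[11]), env_to = as.integer(vals[12]),
      description = paste(tok[23:length(tok)], collapse = " ")
    )
  })
  hits <- bind_rows(parsed)
  bad <- with(hits, hmm_from < 1 | hmm_from > hmm_to |
                hmm_to > model_length | ali_from < 1 | ali_from > ali_to)
  if (any(bad)) {
    abort(sprintf("domtblout line %d: inconsistent coordinates",
                  lineno[which(bad)[1]]))
  }
  hits$meets_ga <- if (is.null(ga_table)) TRUE else {
    ga <- unname(ga_table[hits$pfam_accession])
    ifelse(is.na(ga), FALSE, hits$domain_bit_score >= ga)
  }
  hits[c("protein_id", "pfam_accession", "model_name", "model_length",
         "protein_length", "evalue", "bit_score", "domain_bit_score",
         "hmm_from", "hmm_to", "ali_from", "ali_to", "env_from", "env_to",
         "meets_ga", "description")]
}

#' Model coverage of a domain hit
#'
#' Fraction of the profile-HMM model covered by the hit:
#' `(hmm_to - hmm_from + 1) / model_length`. The denominator is the model
#' length, not the query length, because family membership is judged by
#' alignment to the HMM.
#'
#' @param hits A domain-hit tibble (from [read_domtblout()]) or any data
#'   frame with `hmm_from`, `hmm_to`, `model_length`.
#' @return Numeric vector of coverages in `(0, 1]`.
#' @examples
#' hit_coverage(data.frame(hmm_from = 21, hmm_to = 80, model_length = 100))
#' @export
hit_coverage <- function(hits) {
  (hits$hmm_to - hits$hmm_from + 1) / hits$model_length
}

#' Filter domain hits by model coverage and gathering threshold
#'
#' Keeps a hit iff its model coverage is at least `min_coverage`
#' (inclusive: a hit at exactly 60% survives the default) and, when
#' `require_ga`, it passed the family's gathering threshold. Row order is
#' preserved and a `coverage` column is added.
#'
#' With `coverage_by = "protein"`, split domains are handled by pooling:
#' coverage is the fraction of model columns covered by the union of all
#' hmm intervals of the same protein x family, and the rule keeps or drops
#' the group as a whole.
#'
#' @param hits Domain-hit tibble.
#' @param min_coverage Minimum model coverage (default 0.6).
#' @param require_ga Require `meets_ga` (default TRUE).
#' @param coverage_by `"domain"` (default) applies the rule per hit;
#'   `"protein"` pools split domains per protein x accession.
#' @return Filtered tibble with an added `coverage` column.
#' @export
filter_hits <- function(hits, min_coverage = 0.6, require_ga = TRUE,
                        coverage_by = c("domain", "protein")) {
  coverage_by <- match.arg(coverage_by)
  stopifnot(min_coverage >= 0, min_coverage <= 1)
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(mutate(hits, coverage = numeric(0)))
  hits$coverage <- hit_coverage(hits)
  if (coverage_by == "protein") {
    grp <- paste(hits$protein_id, hits$pfam_accession, sep = "\r")
    pooled <- vapply(split(seq_len(nrow(hits)), grp), function(ii) {
      cols <- unique(unlist(map(ii, function(i)
        seq(hits$hmm_from[i], hits$hmm_to[i]))))
      length(cols) / hits$model_length[ii[1]]
    }, numeric(1))
    keep_cov <- pooled[grp] >= min_coverage
  } else {
    keep_cov <- hits$coverage >= min_coverage
  }
  keep <- keep_cov & (!require_ga | hits$meets_ga)
  hits[keep, , drop = FALSE]
}

#' Resolve overlapping domain hits by score
#'
#' Within each protein, hits are considered in order of decreasing
#' per-domain bit score (ties: smaller `ali_from`, then input order) and a
#' hit is kept iff its protein-coordinate interval `[ali_from, ali_to]`
#' shares at most `max_overlap` residues with every already-kept hit
#' (default 0: any shared residue discards the lower-scoring hit). The
#' result is a mutually non-overlapping domain architecture per protein.
#'
#' @param hits Domain-hit tibble (any number of proteins; resolution is per
#'   protein).
#' @param max_overlap Maximum number of shared residues tolerated between
#'   two kept hits (default 0).
#' @return Tibble of kept hits, ordered by protein then `ali_from`.
#' @export
resolve_overlaps <- function(hits, max_overlap = 0) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(hits)
  parts <- split(hits, hits$protein_id)
  kept <- map(parts, function(h) {
    ord <- order(-h$domain_bit_score, h$ali_from, seq_len(nrow(h)))
    h <- h[ord, , drop = FALSE]
    sel <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      ov <- pmin(h$ali_to[sel], h$ali_to[i]) -
        pmax(h$ali_from[sel], h$ali_from[i]) + 1
      if (!any(ov > max_overlap)) sel[i] <- TRUE
    }
    h <- h[sel, , drop = FALSE]
    h[order(h$ali_from), , drop = FALSE]
  })
  out <- bind_rows(kept)
  out[order(match(out$protein_id, unique(hits$protein_id))), , drop = FALSE]
}
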