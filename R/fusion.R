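# Sequence deduplication and the Ppm fusion-architecture inventory:
# which Pfam domains ride on the same polypeptide as the PEP mutase domain.

#' Deduplicate protein sequences
#'
#' Collapses exact duplicates (case-insensitive residue-string identity) to
#' one representative each. The representative of a duplicate group is the
#' first member by sorted `protein_id`, so the result is deterministic.
#'
#' @param proteins Data frame with columns `protein_id` and `sequence`, or
#'   a named character vector / [Biostrings::AAStringSet].
#' @return Tibble with one row per input protein: `protein_id`, `sequence`,
#'   `representative_id`, `is_representative`. Filter on
#'   `is_representative` for the non-redundant set.
#' @examples
#' deduplicate_sequences(c(b = "MKV", a = "mkv", c = "MDD"))
#' @export
deduplicate_sequences <- function(proteins) {
  if (!is.data.frame(proteins)) {
    if (inherits(proteins, "AAStringSet")) {
      proteins <- tibble(protein_id = names(proteins),
                         sequence = as.character(proteins))
    } else {
      proteins <- tibble(protein_id = names(proteins),
                         sequence = unname(proteins))
    }
  }
  proteins <- as_tibble(proteins)
  if (any(!nzchar(proteins$sequence) | is.na(proteins$sequence))) {
    abort("empty protein sequence")
  }
  key <- toupper(proteins$sequence)
  rep_of <- vapply(split(proteins$protein_id, key), function(ids)
    sort(ids)[1], character(1))
  proteins$representative_id <- unname(rep_of[key])
  proteins$is_representative <- proteins$protein_id == proteins$representative_id
  proteins
}

#' Classify the fusion architecture of Ppm proteins
#'
#' Given coverage/GA-filtered, overlap-resolved domain hits, assigns each
#' PF13714-carrying protein a fusion category from its partner domains
#' (the non-PF13714 accessions among its resolved hits):
#' none -> `ALONE`; PF12804 only -> `NTP_TRANSF_3` (MobA-like NTP
#' transferase); PF01467 only -> `CTP_TRANSF_LIKE`
#' (cytidylyltransferase-like); both -> `TRIPLE`; anything else -> `OTHER`.
#'
#' By default a named nucleotidyltransferase partner takes precedence over
#' additional unrelated domains (a protein with PF12804 plus an unrelated
#' extra is still `NTP_TRANSF_3`); with `strict_other = TRUE` any unrelated
#' extra domain sends the protein to `OTHER`.
#'
#' @param hits Resolved domain-hit tibble (see [resolve_overlaps()]).
#' @param motif Optional tibble `protein_id`, `has_motif` (e.g. derived
#'   from [split_by_motif()]); merged into the result when given.
#' @param strict_other If TRUE, proteins carrying any accession outside
#'   PF13714/PF12804/PF01467 are classified `OTHER` even when a named
#'   partner is present.
#' @return Tibble with one row per PF13714-carrying protein: `protein_id`,
#'   `category`, `partner_accessions` (list-column), `is_fused`, and
#'   `has_motif` when `motif` is supplied.
#' @export
classify_fusion <- function(hits, motif = NULL, strict_other = FALSE) {
  hits <- as_tibble(hits)
  ppm_ids <- unique(hits$protein_id[hits$pfam_accession == PPM_ACCESSION])
  if (length(ppm_ids) == 0 && nrow(hits) > 0) {
    abort("no PF13714 hit among the supplied proteins")
  }
  sub <- hits[hits$protein_id %in% ppm_ids, , drop = FALSE]
  cls <- map(split(sub$pfam_accession, sub$protein_id), function(acc) {
    partners <- sort(unique(setdiff(acc, PPM_ACCESSION)))
    named <- intersect(partners, NTF_ACCESSIONS)
    extra <- setdiff(partners, NTF_ACCESSIONS)
    category <-
      if (length(partners) == 0) "ALONE"
      else if (strict_other && length(extra) > 0) "OTHER"
      else if (setequal(named, NTF_ACCESSIONS)) "TRIPLE"
      else if (identical(named, "PF12804")) "NTP_TRANSF_3"
      else if (identical(named, "PF01467")) "CTP_TRANSF_LIKE"
      else "OTHER"
    tibble(category = category, partner_accessions = list(partners),
           is_fused = length(partners) > 0)
  })
  out <- bind_rows(cls, .id = "protein_id")
  out <- out[match(intersect(unique(hits$protein_id), ppm_ids),
                   out$protein_id), , drop = FALSE]
  if (!is.null(motif)) {
    out <- left_join(out, as_tibble(motif)[c("protein_id", "has_motif")],
                     by = "protein_id")
  }
  out
}

FUSION_CATEGORIES <- c("ALONE", "NTP_TRANSF_3", "CTP_TRANSF_LIKE",
                       "TRIPLE", "OTHER")

#' Build the inventory summary from raw counts
#'
#' Low-level constructor computing every funnel and pie statistic from
#' counts alone; [summarize_inventory()] derives the counts from a
#' classification table and calls this. Percentages are rounded half away
#' from zero to one decimal; unrounded values are reported alongside.
#'
#' @param per_category_counts Named integer vector over the categories
#'   `ALONE`, `NTP_TRANSF_3`, `CTP_TRANSF_LIKE`, `TRIPLE`, `OTHER`, counted
#'   over motif-positive non-redundant Ppm proteins.
#' @param n_nonredundant Non-redundant PF13714-matching sequences (the
#'   pre-motif denominator).
#' @param n_fused Fused proteins among the non-redundant set.
#' @param n_total Raw PF13714 matches before deduplication (optional).
#' @return Object of class `ppm_inventory`: a list of counts, percentage
#'   tables (`per_category_pct` over the motif-positive denominator,
#'   `pct_fused_of_nonredundant`, `pct_fused_of_motif`), and the funnel
#'   quantities `n_removed` (motif-negative sequences removed) and
#'   `n_removed_fused`.
#' @export
inventory_summary <- function(per_category_counts, n_nonredundant,
                              n_fused, n_total = NA_integer_) {
  cc <- setNames(integer(length(FUSION_CATEGORIES)), FUSION_CATEGORIES)
  cc[names(per_category_counts)] <- as.integer(per_category_counts)
  n_motif <- sum(cc)
  n_motif_fused <- sum(cc[setdiff(FUSION_CATEGORIES, "ALONE")])
  pct <- function(num, den) if (is.na(den) || den == 0) NA_real_ else
    100 * num / den
  per_category_pct_raw <- vapply(cc, pct, numeric(1), den = n_motif)
  out <- list(
    n_total_pf13714 = n_total,
    n_nonredundant = n_nonredundant,
    n_fused = n_fused,
    n_motif = n_motif,
    n_motif_fused = n_motif_fused,
    n_removed = n_nonredundant - n_motif,
    n_removed_fused = n_fused - n_motif_fused,
    per_category_counts = cc,
    per_category_pct_raw = per_category_pct_raw,
    per_category_pct = round_half_away(per_category_pct_raw, 1),
    pct_fused_of_nonredundant_raw = pct(n_fused, n_nonredundant),
    pct_fused_of_nonredundant = round_half_away(pct(n_fused, n_nonredundant), 1),
    pct_fused_of_motif_raw = pct(n_motif_fused, n_motif),
    pct_fused_of_motif = round_half_away(pct(n_motif_fused, n_motif), 1)
  )
  structure(out, class = "ppm_inventory")
}

#' Summarise a fusion classification table
#'
#' Produces the full inventory: total and non-redundant sequence counts,
#' fused counts before and after the motif filter, how many presumed
#' non-Ppm sequences the motif filter removed, and per-category counts and
#' percentages over the motif-positive denominator ("all Ppm proteins").
#'
#' @param classifications Tibble from [classify_fusion()] including a
#'   `has_motif` column; rows should be non-redundant (post
#'   [deduplicate_sequences()]) PF13714-carrying proteins.
#' @param n_total Optional raw PF13714 match count before deduplication.
#' @return A `ppm_inventory` object; see [inventory_summary()].
#' @export
summarize_inventory <- function(classifications, n_total = NA_integer_) {
  cl <- as_tibble(classifications)
  if (!"has_motif" %in% names(cl)) {
    abort("classifications must carry a has_motif column")
  }
  pos <- cl[cl$has_motif, , drop = FALSE]
  cc <- table(factor(pos$category, levels = FUSION_CATEGORIES))
  inventory_summary(per_category_counts = setNames(as.integer(cc), names(cc)),
                    n_nonredundant = nrow(cl),
                    n_fused = sum(cl$is_fused),
                    n_total = n_total)
}

#' @export
print.ppm_inventory <- function(x, ...) {
  cat("Ppm fusion inventory\n")
  if (!is.na(x$n_total_pf13714)) {
    cat(sprintf("  PF13714 matches (raw):       %d\n", x$n_total_pf13714))
  }
  cat(sprintf("  non-redundant sequences:     %d\n", x$n_nonredundant))
  cat(sprintf("  fused (non-redundant):       %d (%.1f%%)\n",
              x$n_fused, x$pct_fused_of_nonredundant))
  cat(sprintf("  motif-positive (Ppm):        %d\n", x$n_motif))
  cat(sprintf("  removed by motif filter:     %d (of which fused: %d)\n",
              x$n_removed, x$n_removed_fused))
  cat(sprintf("  fused among Ppm:             %d (%.1f%%)\n",
              x$n_motif_fused, x$pct_fused_of_motif))
  cat("  categories (% of Ppm):\n")
  for (k in names(x$per_category_counts)) {
    cat(sprintf("    %-16s %6d  %6.1f%%\n", k, x$per_category_counts[[k]],
                x$per_category_pct[[k]]))
  }
  invisible(x)
}

#' @rdname tidiers
#' @method tidy ppm_inventory
#' @export
tidy.ppm_inventory <- function(x, ...) {
  tibble(category = names(x$per_category_counts),
         count = unname(x$per_category_counts),
         pct = unname(x$per_category_pct),
         pct_raw = unname(x$per_category_pct_raw))
}

#' @rdname tidiers
#' @method glance ppm_inventory
#' @export
glance.ppm_inventory <- function(x, ...) {
  tibble(n_total_pf13714 = x$n_total_pf13714,
         n_nonredundant = x$n_nonredundant, n_fused = x$n_fused,
         n_motif = x$n_motif, n_motif_fused = x$n_motif_fused,
         n_removed = x$n_removed, n_removed_fused = x$n_removed_fused,
         pct_fused_of_nonredundant = x$pct_fused_of_nonredundant,
         pct_fused_of_motif = x$pct_fused_of_motif)
}
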