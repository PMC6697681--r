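# The Ppm catalytic motif EDKXXXXXNS: PF13714 covers both PEP mutase and
# isocitrate lyase, so family membership alone over-calls Ppm; the
# conserved catalytic motif distinguishes bona fide PEP mutases.

#' Compile a restricted motif pattern
#'
#' Patterns are anchors plus wildcard runs, e.g. the default `"EDKx{5}NS"`:
#' literal amino-acid letters are anchors and `x{n}` means n arbitrary
#' residues. Anchors match only their literal residue, so an ambiguous `X`
#' in a query sequence never satisfies an anchor; wildcard positions accept
#' any residue including `X`.
#'
#' @param pattern Restricted pattern string.
#' @return List with the compiled lookahead regex (`regex`, for overlapping
#'   matches) and the motif `width`.
#' @keywords internal
#' @export
motif_pattern <- function(pattern = "EDKx{5}NS") {
  if (!grepl("^([ACDEFGHIKLMNPQRSTVWY]|x\\{\\d+\\})+$", pattern)) {
    abort("motif pattern must be amino-acid anchors and x{n} wildcards")
  }
  parts <- regmatches(pattern,
                      gregexpr("[ACDEFGHIKLMNPQRSTVWY]|x\\{\\d+\\}",
                               pattern))[[1]]
  rx <- ""
  width <- 0L
  for (p in parts) {
    if (startsWith(p, "x")) {
      n <- as.integer(sub("x\\{(\\d+)\\}", "\\1", p))
      rx <- paste0(rx, sprintf(".{%d}", n))
      width <- width + n
    } else {
      rx <- paste0(rx, p)
      width <- width + 1L
    }
  }
  list(regex = sprintf("(?=%s)", rx), width = width)
}

#' Find the Ppm catalytic motif in protein sequences
#'
#' Scans amino-acid sequences for every occurrence (including overlapping
#' ones) of the conserved catalytic motif `E, D, K, 5 arbitrary residues,
#' N, S` that distinguishes PEP mutase within the PF13714 family. The scan
#' covers the full protein; restrict the input to a hit envelope upstream
#' if a localized search is wanted.
#'
#' @param sequences Named character vector of protein sequences (names are
#'   protein ids), or a data frame with columns `protein_id` and
#'   `sequence`, or a [Biostrings::AAStringSet].
#' @param pattern Restricted pattern string, default `"EDKx{5}NS"`.
#' @return Tibble with one row per match: `protein_id`, `start` (1-based
#'   position of the motif's first anchor) and `matched_span`.
#' @examples
#' find_ppm_motif(c(p1 = "MAAEDKLLLLLNSGG"))
#' @export
find_ppm_motif <- function(sequences, pattern = "EDKx{5}NS") {
  if (inherits(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$protein_id)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequences)
  if (any(bad)) {
    abort(sprintf("sequence '%s' contains non-amino-acid characters",
                  names(sequences)[bad][1]))
  }
  pat <- motif_pattern(pattern)
  res <- imap(sequences, function(s, id) {
    st <- gregexpr(pat$regex, s, perl = TRUE)[[1]]
    st <- st[st > 0]
    if (length(st) == 0) return(NULL)
    tibble(protein_id = id, start = as.integer(st),
           matched_span = substr(rep(s, length(st)), st, st + pat$width - 1L))
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(protein_id = character(), start = integer(),
                  matched_span = character())
  }
  out
}

#' Split PF13714-matching proteins by motif status
#'
#' Partitions candidate Ppm proteins (those whose filtered hits include
#' PF13714) into motif-positive bona fide Ppm sequences and the presumed
#' non-Ppm remainder that the motif filter removes.
#'
#' @param proteins Data frame with columns `protein_id` and `sequence`
#'   (or a named character vector / `AAStringSet`).
#' @param pattern Restricted motif pattern, default `"EDKx{5}NS"`.
#' @return List with tibbles `ppm` (motif-positive) and `removed`, each
#'   carrying `protein_id`, `sequence`, `has_motif`; plus integer `counts`
#'   `(n_input, n_ppm, n_removed)`.
#' @export
split_by_motif <- function(proteins, pattern = "EDKx{5}NS") {
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
  hits <- find_ppm_motif(proteins, pattern = pattern)
  proteins$has_motif <- proteins$protein_id %in% hits$protein_id
  ppm <- proteins[proteins$has_motif, , drop = FALSE]
  removed <- proteins[!proteins$has_motif, , drop = FALSE]
  list(ppm = ppm, removed = removed,
       counts = c(n_input = nrow(proteins), n_ppm = nrow(ppm),
                  n_removed = nrow(removed)))
}
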