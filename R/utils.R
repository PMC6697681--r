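#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 2.85 -> 2.9 at one
#' decimal), as used for the reported inventory percentages. Base R's
#' `round()` rounds ties to even, which would print 2.8 for 2.85.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_away(c(2.85, -2.85), 1)
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Round to significant figures, half away from zero
#'
#' @param x Numeric vector (non-zero entries rounded; zeros pass through).
#' @param sig_figs Number of significant figures.
#' @return Numeric vector of the same length.
#' @examples
#' signif_half_away(195.65, 2) # 200
#' @export
signif_half_away <- function(x, sig_figs = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  m <- floor(log10(abs(x[nz])))
  out[nz] <- round_half_away(x[nz], digits = sig_figs - 1 - m)
  out
}

# Accept either a path to a text file or literal text (single string with
# embedded newlines, or a character vector of lines); return lines.
input_lines <- function(x, what = "input") {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}

# Write lines; returns path invisibly.
write_lines_to <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
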