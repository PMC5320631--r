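# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
AA_BASES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Reverse complement of DNA strings
#'
#' Vectorised base implementation (complement via [chartr()], then string
#' reversal); kept dependency-light because it sits in the inner loops of
#' scanning and refinement. Tests cross-check it against
#' [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(ch)
    paste(rev(ch), collapse = ""), "", USE.NAMES = FALSE)
}

# Round half away from zero ("half-up" for positive values), the convention
# that reproduces all checkable printed means in the bundled summary tables.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Map a DNA string to integer codes 1..4 (A,C,G,T); N and anything else -> NA.
base_ints <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

# Vectorised substring extraction of all windows of width w starting at `starts`.
windows_at <- function(s, starts, w) {
  substring(s, starts, starts + w - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dna <- function(s) !grepl("[^ACGTN]", s)
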