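# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

#' @noRd
complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# Reverse-complement of short character sequences (vectorized).
# Chromosome-scale sequences go through Biostrings instead.
#' @noRd
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""),
         character(1))
}

#' @noRd
is_purine <- function(x) x %in% PURINES

# 0-based half-open substring of a chromosome string.
#' @noRd
subseq0 <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Empty variant table with canonical column set.
#' @noRd
empty_variants <- function() {
  data.frame(line_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             vclass = character(0), indel_len = integer(0),
             stringsAsFactors = FALSE)
}
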