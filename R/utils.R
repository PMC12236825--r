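# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> base sets
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_acgt <- function(x) {
  grepl("^[ACGT]+$", x)
}

is_iupac <- function(x) {
  grepl(sprintf("^[%s]+$", paste(names(IUPAC_CODES), collapse = "")), x)
}

assert_acgt <- function(x, what = "sequence") {
  bad <- !is_acgt(x)
  if (any(bad)) {
    abort(sprintf("%s must contain only A/C/G/T (offending value: '%s')",
                  what, x[which(bad)[1]]))
  }
  invisible(x)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

revcomp <- function(x) {
  vapply(x, function(s) {
    chars_seq(rev(seq_chars(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s))))
  }, character(1), USE.NAMES = FALSE)
}

# Reproducible RNG scope: run `expr` under `seed` without disturbing the
# caller's RNG state; a NULL seed uses (and advances) the current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Hamming distance between two equal-length strings
#' @param a,b character scalars of equal length
#' @return integer count of mismatching positions
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(seq_chars(a) != seq_chars(b))
}
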