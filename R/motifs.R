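#' Transcription-factor motif sets
#'
#' A motif set is a tibble with columns `name` (unique short label),
#' `consensus` (IUPAC nucleotide string) and `length` (consensus width in
#' bp). [liver_tf_motifs()] returns the nine liver-expressed TF motifs used
#' in the synthetic-enhancer grammar library (CEBPA, CTCF, FOXA1, HNF1A,
#' NR2F2, ONECUT1, PPARA, REST, XBP1). The consensus strings are
#' package-curated A/C/G/T representatives of the canonical binding motifs;
#' every design-count and statistical property downstream depends only on
#' motif identity and width, not on the exact bases.
#'
#' @param motifs a data frame with columns `name` and `consensus`
#' @return a validated motif tibble with columns `name`, `consensus`,
#'   `length`
#' @export
#' @examples
#' liver_tf_motifs()
tf_motifs <- function(motifs) {
  m <- tibble::as_tibble(motifs)
  if (!all(c("name", "consensus") %in% names(m))) {
    abort("motif set needs columns 'name' and 'consensus'")
  }
  m$consensus <- toupper(m$consensus)
  bad <- !is_iupac(m$consensus)
  if (any(bad)) {
    abort(sprintf("consensus '%s' contains non-IUPAC characters",
                  m$consensus[which(bad)[1]]))
  }
  if (anyDuplicated(m$name)) {
    abort("motif names must be unique within a set")
  }
  m$length <- nchar(m$consensus)
  m[, c("name", "consensus", "length")]
}

#' @rdname tf_motifs
#' @export
liver_tf_motifs <- function() {
  tf_motifs(tibble::tribble(
    ~name,      ~consensus,
    "CEBPA",    "ATTGCGCAAT",
    "CTCF",     "CCGCGCGGCGGCAG",
    "FOXA1",    "TGTTTAC",
    "HNF1A",    "GTTAATGATTAAC",
    "NR2F2",    "TGACCTTTGACCT",
    "ONECUT1",  "AATCAATAA",
    "PPARA",    "AGGTCAAAGGTCA",
    "REST",     "TTCAGCACCACGGACAGCGCC",
    "XBP1",     "TGACGTGG"
  ))
}

#' Read a motif set from a two-column TSV
#'
#' @param path TSV file with columns `name` and `consensus`
#' @return motif tibble (see [tf_motifs()])
#' @export
read_motifs_tsv <- function(path) {
  tf_motifs(readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), consensus = readr::col_character()
  )))
}

iupac_regex <- function(consensus) {
  paste(vapply(seq_chars(consensus), function(ch) {
    bases <- IUPAC_CODES[[ch]]
    if (length(bases) == 1) bases else sprintf("[%s]", paste(bases, collapse = ""))
  }, character(1)), collapse = "")
}

scan_one_strand <- function(sequence, consensus) {
  # all (overlapping) starts where the IUPAC consensus matches exactly
  rx <- iupac_regex(consensus)
  starts <- integer(0)
  from <- 1
  repeat {
    m <- regexpr(rx, substr(sequence, from, nchar(sequence)), perl = TRUE)
    if (m == -1) break
    starts <- c(starts, from + as.integer(m) - 1L)
    from <- from + as.integer(m)
  }
  starts
}

#' Scan a sequence for motif consensus matches on both strands
#'
#' Exact IUPAC-consensus matching: a motif position matches a sequence base
#' iff the base is in the IUPAC set of the consensus character. This is the
#' built-in stand-in for an external PWM scanner; pass a different
#' `hit_caller` to plug one in.
#'
#' @param sequence A/C/G/T string
#' @param motifs motif tibble (see [tf_motifs()])
#' @param hit_caller optional function `(sequence, motifs) -> tibble(name,
#'   start, strand)` overriding the consensus matcher
#' @return tibble with columns `name`, `start` (1-based, position on the
#'   forward strand of the leftmost matched base), `strand` (`"+"`/`"-"`),
#'   ordered by (start, name, strand)
#' @export
#' @examples
#' scan_motifs("AAATGACGTGGAAA", liver_tf_motifs())
scan_motifs <- function(sequence, motifs, hit_caller = NULL) {
  assert_acgt(sequence)
  if (!is.null(hit_caller)) {
    hits <- tibble::as_tibble(hit_caller(sequence, motifs))
  } else {
    motifs <- tf_motifs(motifs)
    hits <- purrr::pmap_dfr(motifs, function(name, consensus, length) {
      fwd <- scan_one_strand(sequence, consensus)
      rev <- scan_one_strand(sequence, revcomp(consensus))
      tibble::tibble(
        name = name,
        start = c(fwd, rev),
        strand = rep(c("+", "-"), c(base::length(fwd), base::length(rev)))
      )
    })
  }
  dplyr::arrange(hits, .data$start, .data$name, .data$strand)
}
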