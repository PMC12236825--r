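#' Write a design as FASTA plus a TSV manifest
#'
#' The FASTA holds one record per element (header = `element_id`); the
#' manifest holds all annotation columns.
#'
#' @param designs design tibble
#' @param prefix output path prefix; writes `<prefix>.fa` and
#'   `<prefix>_manifest.tsv`
#' @return invisibly, the two paths written
#' @export
write_design <- function(designs, prefix) {
  fa <- Biostrings::DNAStringSet(setNames(designs$sequence, designs$element_id))
  fa_path <- paste0(prefix, ".fa")
  tsv_path <- paste0(prefix, "_manifest.tsv")
  Biostrings::writeXStringSet(fa, fa_path)
  readr::write_tsv(designs, tsv_path)
  invisible(c(fasta = fa_path, manifest = tsv_path))
}

#' Read a design manifest TSV
#'
#' @param path manifest written by [write_design()]
#' @return design tibble
#' @export
read_design_manifest <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    element_id = readr::col_character(),
    library = readr::col_character(),
    category = readr::col_character(),
    template_id = readr::col_character(),
    sequence = readr::col_character(),
    arrangement = readr::col_character(),
    variant_pos = readr::col_integer(),
    variant_ref = readr::col_character(),
    variant_alt = readr::col_character(),
    window_start = readr::col_integer(),
    window_rep = readr::col_integer()
  ))
}

#' Write / read a count table TSV
#'
#' @param table count tibble (`element_id`, `replicate`, `channel`,
#'   `count`, optionally `n_barcodes`)
#' @param path TSV path
#' @return `read_count_table()` returns the count tibble
#' @export
write_count_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    element_id = readr::col_character(),
    replicate = readr::col_integer(),
    channel = readr::col_character(),
    count = readr::col_integer(),
    .default = readr::col_guess()
  ))
}
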