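# Read-level counting: mismatch-free assignment, barcode association and
# UMI deduplication. This is a simplified re-implementation of the
# exact-match alignment + dedup logic of the external MPRA tool chain:
# reads are matched to full-length design sequences only (no clipping, no
# reverse-complement search -- library orientation is fixed by
# construction), so a single mismatch anywhere leaves a read unassigned.

MPRA_CHANNELS <- c("dna_bc", "rna_bc")
FRAGMENT_CHANNELS <- c("inserted", "enriched_ATAC", "enriched_H3K27ac")

#' Construct a read-record tibble
#'
#' @param insert element-insert sequence of the read
#' @param channel one of `assoc`, `dna_bc`, `rna_bc`, `inserted`,
#'   `enriched_ATAC`, `enriched_H3K27ac`
#' @param replicate replicate index (>= 1)
#' @param barcode 15-mer barcode (`NA` for fragment channels)
#' @param umi unique molecular identifier (`NA` for association reads)
#' @return tibble of read records
#' @export
read_records <- function(insert, channel, replicate = 1L,
                         barcode = NA_character_, umi = NA_character_) {
  tibble::tibble(insert = insert, barcode = barcode, umi = umi,
                 channel = channel, replicate = as.integer(replicate))
}

#' Read read-level fixtures from FASTQ or TSV
#'
#' FASTQ headers carry the barcode and/or UMI as colon-separated fields
#' appended to the read id: `@id:<barcode>:<umi>` for barcode channels
#' (`assoc` headers may omit the UMI: `@id:<barcode>`), `@id:<umi>` for
#' fragment channels. TSV input must have columns `insert`, `channel`,
#' `replicate` and (as applicable) `barcode`, `umi`; both routes parse to
#' identical read records.
#'
#' @param path FASTQ file
#' @param channel channel of every read in the file
#' @param replicate replicate index of the file
#' @return read-record tibble
#' @export
read_reads_fastq <- function(path, channel, replicate = 1L) {
  fq <- Biostrings::readDNAStringSet(path, format = "fastq")
  headers <- names(fq)
  fields <- strsplit(sub(" .*$", "", headers), ":", fixed = TRUE)
  nfield <- lengths(fields)
  last <- vapply(fields, function(f) f[[length(f)]], character(1))
  penult <- ifelse(nfield >= 3,
                   vapply(fields, function(f) if (length(f) >= 2) f[[length(f) - 1]] else NA_character_,
                          character(1)),
                   NA_character_)
  inserts <- unname(as.character(fq))
  if (channel %in% FRAGMENT_CHANNELS) {
    read_records(inserts, channel, replicate, umi = last)
  } else if (channel == "assoc") {
    bc <- ifelse(nfield >= 3, penult, last)
    read_records(inserts, channel, replicate, barcode = bc)
  } else {
    read_records(inserts, channel, replicate, barcode = penult, umi = last)
  }
}

#' @rdname read_reads_fastq
#' @export
read_reads_tsv <- function(path) {
  r <- readr::read_tsv(path, col_types = readr::cols(
    insert = readr::col_character(), channel = readr::col_character(),
    replicate = readr::col_integer(), .default = readr::col_character()
  ))
  if (!"barcode" %in% names(r)) r$barcode <- NA_character_
  if (!"umi" %in% names(r)) r$umi <- NA_character_
  r[, c("insert", "barcode", "umi", "channel", "replicate")]
}

#' Associate barcodes with design elements
#'
#' A read is assigned only when its insert matches a design sequence
#' exactly over the full length. Barcodes whose assigned reads point to
#' more than one element are discarded, as are barcodes supported by fewer
#' than `min_cov` assigned reads.
#'
#' @param reads association read records
#' @param designs design tibble (sequences must be unique)
#' @param min_cov minimum assigned-read support per barcode (default 3)
#' @return barcode map tibble (`barcode`, `element_id`, `support`);
#'   attribute `n_unassigned` counts reads matching no design
#' @export
associate_barcodes <- function(reads, designs, min_cov = 3) {
  dup <- designs$element_id[duplicated(designs$sequence) |
                              duplicated(designs$sequence, fromLast = TRUE)]
  if (length(dup) > 0) {
    abort(sprintf("designs contain duplicate sequences (%s)",
                  paste(sort(dup), collapse = ", ")))
  }
  assigned <- dplyr::inner_join(
    dplyr::filter(reads, !is.na(.data$barcode)),
    designs[, c("element_id", "sequence")],
    by = c(insert = "sequence")
  )
  map <- assigned |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(n_elements = dplyr::n_distinct(.data$element_id),
                     element_id = .data$element_id[1],
                     support = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_elements == 1, .data$support >= min_cov) |>
    dplyr::select("barcode", "element_id", "support")
  attr(map, "n_unassigned") <- nrow(reads) - nrow(assigned)
  map
}

# Distinct-UMI count with optional directional one-mismatch collapse
# (greedy cluster from the most frequent UMI; an edge u -> v requires
# Hamming distance 1 and count(u) >= 2 * count(v) - 1).
umi_count <- function(umis, mode = c("unique", "directional")) {
  mode <- match.arg(mode)
  umis <- umis[!is.na(umis)]
  if (length(umis) == 0) return(0L)
  tab <- sort(table(umis), decreasing = TRUE)
  if (mode == "unique" || length(tab) == 1) return(length(tab))
  labels <- names(tab)
  counts <- as.integer(tab)
  merged <- rep(FALSE, length(labels))
  n_clusters <- 0L
  for (i in seq_along(labels)) {
    if (merged[i]) next
    n_clusters <- n_clusters + 1L
    queue <- i
    merged[i] <- TRUE
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (j in seq_along(labels)) {
        if (!merged[j] && nchar(labels[j]) == nchar(labels[u]) &&
            hamming(labels[u], labels[j]) == 1 &&
            counts[u] >= 2L * counts[j] - 1L) {
          merged[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  n_clusters
}

#' Count MPRA barcodes from DNA and RNA reads
#'
#' UMI-deduplicated counts per (barcode, channel, replicate); only barcodes
#' observed in both the DNA and RNA channel within a replicate are kept.
#' Reads with barcodes absent from the barcode map are skipped and tallied
#' in the `n_unknown` attribute.
#'
#' @param dna,rna read records of the `dna_bc` / `rna_bc` channels
#' @param map barcode map from [associate_barcodes()]
#' @param dedup UMI deduplication mode (see [count_fragment_umis()])
#' @return barcode-level count tibble (`element_id`, `barcode`,
#'   `replicate`, `dna`, `rna`); convert with [mpra_count_table()]
#' @export
count_mpra_barcodes <- function(dna, rna, map, dedup = c("unique", "directional")) {
  dedup <- match.arg(dedup)
  if (nrow(map) == 0) abort("barcode map is empty")
  reads <- dplyr::bind_rows(dna, rna)
  known <- reads$barcode %in% map$barcode
  counts <- reads[known, ] |>
    dplyr::group_by(.data$replicate, .data$barcode, .data$channel) |>
    dplyr::summarise(count = umi_count(.data$umi, dedup), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "count") |>
    dplyr::rename(dna = "dna_bc", rna = "rna_bc")
  out <- counts |>
    dplyr::filter(!is.na(.data$dna), !is.na(.data$rna)) |>
    dplyr::left_join(map[, c("barcode", "element_id")], by = "barcode") |>
    dplyr::select("element_id", "barcode", "replicate", "dna", "rna") |>
    dplyr::arrange(.data$element_id, .data$replicate, .data$barcode)
  attr(out, "n_unknown") <- sum(!known)
  out
}

#' Summarise barcode-level counts to an element-level count table
#'
#' @param barcode_counts output of [count_mpra_barcodes()]
#' @return count tibble with channels `dna_bc`, `rna_bc` and a
#'   `n_barcodes` column (distinct barcodes per element and replicate)
#' @export
mpra_count_table <- function(barcode_counts) {
  barcode_counts |>
    dplyr::group_by(.data$element_id, .data$replicate) |>
    dplyr::summarise(dna_bc = sum(.data$dna), rna_bc = sum(.data$rna),
                     n_barcodes = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_longer(c("dna_bc", "rna_bc"), names_to = "channel",
                        values_to = "count") |>
    dplyr::select("element_id", "replicate", "channel", "count", "n_barcodes")
}

#' Count fragment UMIs per element
#'
#' Exact-match assignment of read inserts to design sequences, then
#' distinct-UMI counts per (element, replicate, channel). `dedup =
#' "directional"` additionally collapses one-mismatch UMIs whose counts are
#' consistent with PCR errors of a more abundant UMI (count ratio >= 2:1).
#'
#' @param reads read records of fragment channels (`inserted`,
#'   `enriched_ATAC`, `enriched_H3K27ac`)
#' @param designs design tibble
#' @param dedup deduplication mode
#' @return count tibble (`element_id`, `replicate`, `channel`, `count`);
#'   attribute `n_unassigned` tallies reads matching no design
#' @export
count_fragment_umis <- function(reads, designs, dedup = c("unique", "directional")) {
  dedup <- match.arg(dedup)
  assigned <- dplyr::inner_join(
    reads, designs[, c("element_id", "sequence")], by = c(insert = "sequence")
  )
  out <- assigned |>
    dplyr::group_by(.data$element_id, .data$replicate, .data$channel) |>
    dplyr::summarise(count = umi_count(.data$umi, dedup), .groups = "drop") |>
    dplyr::arrange(.data$element_id, .data$replicate, .data$channel)
  attr(out, "n_unassigned") <- nrow(reads) - nrow(assigned)
  out
}

#' Filter elements by barcode support
#'
#' Removes element/replicate combinations backed by fewer than
#' `min_barcodes` unique barcodes. Accepts either the barcode-level tibble
#' of [count_mpra_barcodes()] (barcodes are counted per element and
#' replicate) or an element-level count table carrying an `n_barcodes`
#' column (only MPRA channels are filtered).
#'
#' @param table barcode-level or element-level count tibble
#' @param min_barcodes minimum unique barcodes (default 5; elements with
#'   fewer are excluded)
#' @return filtered tibble; attribute `n_removed` counts dropped
#'   element/replicate combinations
#' @export
filter_elements <- function(table, min_barcodes = 5) {
  if ("barcode" %in% names(table)) {
    out <- table |>
      dplyr::group_by(.data$element_id, .data$replicate) |>
      dplyr::filter(dplyr::n() >= min_barcodes) |>
      dplyr::ungroup()
    removed <- dplyr::n_distinct(paste(table$element_id, table$replicate)) -
      dplyr::n_distinct(paste(out$element_id, out$replicate))
  } else {
    if (!"n_barcodes" %in% names(table)) {
      abort("element-level input needs an n_barcodes column")
    }
    keep <- !(table$channel %in% MPRA_CHANNELS) | table$n_barcodes >= min_barcodes
    out <- table[keep, ]
    removed <- sum(!keep)
  }
  attr(out, "n_removed") <- removed
  out
}
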