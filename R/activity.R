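# Activity scoring: CPM + negative-control-anchored TMM normalization,
# per-replicate and replicate-pooled log2 activity, QC and category tests.

#' Counts-per-million normalization
#'
#' Adds a `cpm` column: `count * 1e6 / total` within each (replicate,
#' channel); the normalized values of every channel sum to 1e6.
#'
#' @param table count tibble (`element_id`, `replicate`, `channel`, `count`)
#' @return the table with a `cpm` column
#' @export
cpm_normalize <- function(table) {
  out <- table |>
    dplyr::group_by(.data$replicate, .data$channel) |>
    dplyr::mutate(.total = sum(.data$count)) |>
    dplyr::ungroup()
  if (any(out$.total <= 0)) {
    bad <- out[out$.total <= 0, ][1, ]
    abort(sprintf("zero total count in replicate %s, channel %s",
                  bad$replicate, bad$channel))
  }
  out$cpm <- out$count * 1e6 / out$.total
  out$.total <- NULL
  out
}

#' TMM scaling factor from negative-control elements
#'
#' Unweighted doubly-trimmed mean of M-values. For control elements with
#' both values positive, `M = log2(enriched/inserted)` and
#' `A = 0.5 * log2(enriched * inserted)`; values in the extreme `trim_m`
#' fraction of M-ranks or `trim_a` fraction of A-ranks (each side) are
#' discarded and `f = 2^mean(M)` over the rest. Dividing the enriched
#' values by `f` makes the trimmed mean of control M-values zero, so the
#' expected control log2 activity is anchored at 0.
#'
#' @param enriched,inserted CPM values of the negative-control elements
#' @param trim_m,trim_a trim fractions on M and A (defaults 0.30, 0.05)
#' @return scaling factor `f > 0`
#' @export
tmm_factor <- function(enriched, inserted, trim_m = 0.30, trim_a = 0.05) {
  ok <- !is.na(enriched) & !is.na(inserted) & enriched > 0 & inserted > 0
  e <- enriched[ok]; i <- inserted[ok]
  n <- length(e)
  if (n < 3) abort("TMM needs at least 3 controls with positive counts in both channels")
  m <- log2(e / i)
  a <- 0.5 * log2(e * i)
  keep_rank <- function(x, trim) {
    lo <- floor(n * trim) + 1
    hi <- n + 1 - lo
    r <- rank(x, ties.method = "first")
    r >= lo & r <= hi
  }
  keep <- keep_rank(m, trim_m) & keep_rank(a, trim_a)
  2^mean(m[keep])
}

trimmed_mean_log <- function(enriched, inserted, trim_m, trim_a) {
  log2(tmm_factor(enriched, inserted, trim_m, trim_a))
}

# One activity block: given element-level raw counts and CPMs for an
# enriched/inserted channel pair, anchor on the controls and return log2
# activity per element. Elements with zero inserted are NA; zero enriched
# with positive inserted gets +0.5 raw-count pseudocounts on both channels
# (converted to the CPM scale) so zero-enrichment elements stay in the
# distributions.
activity_block <- function(df, controls, trim_m, trim_a) {
  ctrl <- df[df$element_id %in% controls, ]
  f_log <- trimmed_mean_log(ctrl$cpm_e, ctrl$cpm_i, trim_m, trim_a)
  scale_e <- ifelse(df$n_e > 0, df$cpm_e / df$n_e, 1e6 / sum(df$n_e))
  scale_i <- ifelse(df$n_i > 0, df$cpm_i / df$n_i, 1e6 / sum(df$n_i))
  e_val <- ifelse(df$n_e == 0 & df$n_i > 0, 0.5 * scale_e, df$cpm_e)
  i_val <- ifelse(df$n_e == 0 & df$n_i > 0, (df$n_i + 0.5) * scale_i, df$cpm_i)
  ifelse(df$n_i > 0, log2(e_val / i_val) - f_log, NA_real_)
}

#' Epigenetic activity scores (enriched / inserted)
#'
#' Per replicate, the log2 ratio of the CPM-normalized enriched UMI count
#' to the inserted UMI count, with the enriched channel divided by the
#' control-anchored TMM factor. The pooled score sums the raw counts of
#' each channel across replicates first and then computes the same
#' normalized ratio (pooled rows have `replicate = NA`). Elements with
#' pooled inserted count below `min_inserted` get a missing pooled score.
#'
#' @param table count tibble with the `inserted` channel and one or both of
#'   `enriched_ATAC`, `enriched_H3K27ac`
#' @param controls element ids of the negative-control (random genomic)
#'   elements used for TMM anchoring
#' @param pool also compute replicate-pooled scores (default TRUE)
#' @param min_inserted minimum pooled inserted count for a pooled score
#'   (default 10)
#' @param trim_m,trim_a TMM trim fractions
#' @return activity tibble: `element_id`, `assay` (`ATAC` / `H3K27ac`),
#'   `replicate` (`NA` = pooled), `log2_activity`, `n_enriched`,
#'   `n_inserted`
#' @export
epigenetic_activity <- function(table, controls, pool = TRUE,
                                min_inserted = 10, trim_m = 0.30,
                                trim_a = 0.05) {
  enr_channels <- intersect(unique(table$channel),
                            c("enriched_ATAC", "enriched_H3K27ac"))
  if (!"inserted" %in% table$channel || length(enr_channels) == 0) {
    abort("table needs the inserted channel and at least one enriched channel")
  }
  score_tbl <- function(tbl, pooled) {
    tbl <- cpm_normalize(tbl)
    purrr::map_dfr(enr_channels, function(ch) {
      wide <- tbl |>
        dplyr::filter(.data$channel %in% c(ch, "inserted")) |>
        tidyr::pivot_wider(id_cols = c("element_id", "replicate"),
                           names_from = "channel",
                           values_from = c("count", "cpm"), values_fill = 0)
      df <- tibble::tibble(
        element_id = wide$element_id, replicate = wide$replicate,
        n_e = wide[[paste0("count_", ch)]], n_i = wide$count_inserted,
        cpm_e = wide[[paste0("cpm_", ch)]], cpm_i = wide$cpm_inserted
      )
      act <- df |>
        dplyr::group_by(.data$replicate) |>
        dplyr::group_modify(function(g, key) {
          g$log2_activity <- activity_block(g, controls, trim_m, trim_a)
          g
        }) |>
        dplyr::ungroup()
      if (pooled) {
        act$log2_activity[act$n_i < min_inserted] <- NA_real_
        act$replicate <- NA_integer_
      }
      tibble::tibble(
        element_id = act$element_id, assay = sub("enriched_", "", ch),
        replicate = act$replicate, log2_activity = act$log2_activity,
        n_enriched = act$n_e, n_inserted = act$n_i
      )
    })
  }
  out <- score_tbl(table, pooled = FALSE)
  if (pool) {
    pooled_tbl <- table |>
      dplyr::group_by(.data$element_id, .data$channel) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(replicate = 1L)
    out <- dplyr::bind_rows(out, score_tbl(pooled_tbl, pooled = TRUE))
  }
  dplyr::arrange(out, .data$assay, .data$element_id, .data$replicate)
}

#' Transcriptional (MPRA) activity scores
#'
#' Per replicate: each barcode's RNA/DNA ratio is computed on the CPM
#' scale, aggregated across an element's barcodes (default: mean of log2
#' ratios, i.e. the log geometric mean; `"ratio_of_sums"` divides summed
#' RNA CPM by summed DNA CPM instead), and anchored by subtracting the
#' control trimmed-mean M-value so the expected control activity is 0. The
#' pooled score sums each barcode's counts across replicates (keeping
#' barcodes seen in both channels after pooling) and repeats the same
#' computation; pooled rows have `replicate = NA`.
#'
#' @param barcode_counts barcode-level counts from [count_mpra_barcodes()]
#'   (after [filter_elements()])
#' @param controls element ids of negative-control elements
#' @param aggregate per-element barcode aggregation
#' @param pool also compute pooled scores (default TRUE)
#' @param trim_m,trim_a TMM trim fractions
#' @return activity tibble: `element_id`, `assay = "MPRA"`, `replicate`
#'   (`NA` = pooled), `log2_activity`, `n_barcodes`
#' @export
mpra_activity <- function(barcode_counts, controls,
                          aggregate = c("mean_log", "ratio_of_sums"),
                          pool = TRUE, trim_m = 0.30, trim_a = 0.05) {
  aggregate <- match.arg(aggregate)
  score_rep <- function(bc, rep_label) {
    depth_d <- sum(bc$dna); depth_r <- sum(bc$rna)
    bc$dna_cpm <- bc$dna * 1e6 / depth_d
    bc$rna_cpm <- bc$rna * 1e6 / depth_r
    per_elem <- bc |>
      dplyr::group_by(.data$element_id) |>
      dplyr::summarise(
        raw = if (aggregate == "mean_log") {
          mean(log2(.data$rna_cpm / .data$dna_cpm))
        } else {
          log2(sum(.data$rna_cpm) / sum(.data$dna_cpm))
        },
        sum_rna = sum(.data$rna_cpm), sum_dna = sum(.data$dna_cpm),
        n_barcodes = dplyr::n(), .groups = "drop"
      )
    ctrl <- per_elem[per_elem$element_id %in% controls, ]
    f_log <- trimmed_mean_log(ctrl$sum_rna, ctrl$sum_dna, trim_m, trim_a)
    tibble::tibble(
      element_id = per_elem$element_id, assay = "MPRA",
      replicate = rep_label, log2_activity = per_elem$raw - f_log,
      n_barcodes = per_elem$n_barcodes
    )
  }
  out <- barcode_counts |>
    dplyr::group_split(.data$replicate) |>
    purrr::map_dfr(function(bc) score_rep(bc, bc$replicate[1]))
  if (pool) {
    pooled <- barcode_counts |>
      dplyr::group_by(.data$element_id, .data$barcode) |>
      dplyr::summarise(dna = sum(.data$dna), rna = sum(.data$rna),
                       .groups = "drop") |>
      dplyr::filter(.data$dna > 0, .data$rna > 0)
    out <- dplyr::bind_rows(out, score_rep(pooled, NA_integer_))
  }
  dplyr::arrange(out, .data$element_id, .data$replicate)
}

#' Category tests against the negative-control reference
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum test of each category's pooled
#' activities against the reference category, Benjamini-Hochberg adjusted
#' within each assay.
#'
#' @param records activity tibble (pooled rows are used)
#' @param categories tibble with `element_id`, `category` (a design tibble
#'   works)
#' @param reference reference category (default `"random_genomic"`)
#' @return tibble: `assay`, `category`, `n`, `statistic` (U), `p_value`,
#'   `adj_p_value`
#' @export
category_tests <- function(records, categories, reference = "random_genomic") {
  pooled <- records |>
    dplyr::filter(is.na(.data$replicate), !is.na(.data$log2_activity)) |>
    dplyr::left_join(categories[, c("element_id", "category")],
                     by = "element_id")
  if (!reference %in% pooled$category) {
    abort(sprintf("reference category '%s' has no scored elements", reference))
  }
  purrr::map_dfr(split(pooled, pooled$assay), function(a) {
    ref <- a$log2_activity[a$category == reference]
    cats <- setdiff(unique(a$category), reference)
    res <- purrr::map_dfr(cats, function(cat) {
      x <- a$log2_activity[a$category == cat]
      if (length(x) < 2) {
        warn(sprintf("category '%s' has <2 elements in assay %s; skipped",
                     cat, a$assay[1]))
        return(tibble::tibble())
      }
      w <- suppressWarnings(wilcox.test(x, ref, alternative = "two.sided"))
      tibble::tibble(assay = a$assay[1], category = cat, n = length(x),
                     statistic = unname(w$statistic), p_value = w$p.value)
    })
    res$adj_p_value <- p.adjust(res$p_value, method = "BH")
    res
  })
}

#' Replicate correlation QC
#'
#' Spearman correlation of per-replicate activities between every
#' replicate pair, per assay, over the elements scored in both.
#'
#' @param records activity tibble
#' @return tibble: `assay`, `rep1`, `rep2`, `rho`, `n`
#' @export
replicate_qc <- function(records) {
  reps <- records |>
    dplyr::filter(!is.na(.data$replicate), !is.na(.data$log2_activity))
  purrr::map_dfr(split(reps, reps$assay), function(a) {
    rs <- sort(unique(a$replicate))
    if (length(rs) < 2) return(tibble::tibble())
    purrr::map_dfr(utils::combn(rs, 2, simplify = FALSE), function(pr) {
      x <- a[a$replicate == pr[1], c("element_id", "log2_activity")]
      y <- a[a$replicate == pr[2], c("element_id", "log2_activity")]
      m <- dplyr::inner_join(x, y, by = "element_id")
      tibble::tibble(
        assay = a$assay[1], rep1 = pr[1], rep2 = pr[2],
        rho = suppressWarnings(
          stats::cor(m$log2_activity.x, m$log2_activity.y,
                     method = "spearman")),
        n = nrow(m)
      )
    })
  })
}
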