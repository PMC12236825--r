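# Grammar statistics for the synthetic enhancer library: homotypic trend,
# pairwise synergy regression, motif-order ANOVA, positional enrichment.
# Regressions and tests use per-replicate activity scores; the two
# templates count as additional replicates, so a complete design
# contributes templates x infection-replicates observations per
# arrangement.

rep_activities <- function(records) {
  dplyr::filter(records, !is.na(.data$replicate), !is.na(.data$log2_activity))
}

pooled_activities <- function(records) {
  dplyr::filter(records, is.na(.data$replicate), !is.na(.data$log2_activity))
}

#' Homotypic copy-number trend
#'
#' Spearman correlation between motif copy number and per-replicate log2
#' activity for each (motif, assay) over the Class 1 elements, BH-adjusted
#' within each assay.
#'
#' @param records activity tibble (per-replicate rows are used)
#' @param designs design tibble (Class 1 rows are used)
#' @param fdr significance threshold on the adjusted p-value (default 0.05)
#' @return tibble: `motif`, `assay`, `rho`, `p_value`, `adj_p_value`,
#'   `n_obs`, `significant`; a motif with constant activities reports
#'   missing `rho`
#' @export
homotypic_trend <- function(records, designs, fdr = 0.05) {
  c1 <- dplyr::filter(designs, .data$category == "class1")
  counts <- motif_counts(c1)
  obs <- rep_activities(records) |>
    dplyr::inner_join(counts, by = "element_id")
  if (dplyr::n_distinct(obs$copies) < 2) {
    abort("homotypic trend needs data at >=2 distinct copy numbers")
  }
  res <- obs |>
    dplyr::group_by(.data$motif, .data$assay) |>
    dplyr::group_modify(function(g, key) {
      if (sd(g$log2_activity) == 0 || dplyr::n_distinct(g$copies) < 2) {
        return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                              n_obs = nrow(g)))
      }
      ct <- suppressWarnings(
        cor.test(g$copies, g$log2_activity, method = "spearman",
                 exact = FALSE))
      tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                     n_obs = nrow(g))
    }) |>
    dplyr::ungroup()
  res |>
    dplyr::group_by(.data$assay) |>
    dplyr::mutate(adj_p_value = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$adj_p_value) &
                    .data$adj_p_value < fdr)
}

#' Pairwise synergy regression
#'
#' For each unordered motif pair, ordinary least squares of per-replicate
#' log2 activity on the two motif copy counts plus an interaction term `k`
#' (`k = 0` for Class 1 elements; for Class 2 elements the per-motif copy
#' count under `k_mode = "copies"`, i.e. 2 under the default 2:2 patterns,
#' or 1 under `k_mode = "indicator"`). The two-sided t-test p-value of the
#' `k` coefficient is BH-adjusted across pairs within each assay; a
#' positive significant `beta_k` is synergy, a negative one antagonism.
#'
#' @param records activity tibble
#' @param designs design tibble (Class 1 and 2 rows are used)
#' @param k_mode encoding of the interaction term
#' @param fdr significance threshold (default 0.01)
#' @return tibble: `motif1`, `motif2`, `assay`, `beta_count1`,
#'   `beta_count2`, `beta_k`, `p_k`, `adj_p_k`, `n_obs`, `significant`,
#'   `direction`
#' @export
synergy_regression <- function(records, designs,
                               k_mode = c("copies", "indicator"), fdr = 0.01) {
  k_mode <- match.arg(k_mode)
  d12 <- dplyr::filter(designs, .data$category %in% c("class1", "class2"))
  counts <- motif_counts(d12)
  obs <- rep_activities(records) |>
    dplyr::inner_join(d12[, c("element_id", "category")], by = "element_id")
  c2_counts <- dplyr::semi_join(
    counts, dplyr::filter(d12, .data$category == "class2"),
    by = "element_id")
  if (nrow(c2_counts) == 0) {
    abort("no Class 2 elements: interaction term k is constant (not identifiable)")
  }
  c2_pairs <- c2_counts |>
    dplyr::group_by(.data$element_id) |>
    dplyr::summarise(motif1 = min(.data$motif), motif2 = max(.data$motif),
                     .groups = "drop")
  pairs <- dplyr::distinct(c2_pairs, .data$motif1, .data$motif2)
  wide <- tidyr::pivot_wider(counts, names_from = "motif",
                             values_from = "copies", values_fill = 0)
  res <- purrr::pmap_dfr(pairs, function(motif1, motif2) {
    pair_ids <- c2_pairs$element_id[c2_pairs$motif1 == motif1 &
                                      c2_pairs$motif2 == motif2]
    c1_ids <- d12$element_id[d12$category == "class1" &
                               d12$element_id %in% counts$element_id[
                                 counts$motif %in% c(motif1, motif2)]]
    dat <- obs |>
      dplyr::filter(.data$element_id %in% c(pair_ids, c1_ids)) |>
      dplyr::left_join(wide, by = "element_id")
    dat$c1 <- dat[[motif1]] %||% 0
    dat$c2 <- dat[[motif2]] %||% 0
    dat$c1[is.na(dat$c1)] <- 0
    dat$c2[is.na(dat$c2)] <- 0
    dat$k <- ifelse(dat$category == "class2",
                    if (k_mode == "copies") pmin(dat$c1, dat$c2) else 1, 0)
    purrr::map_dfr(split(dat, dat$assay), function(a) {
      if (var(a$k) == 0) {
        warn(sprintf("pair %s-%s (%s): k constant, skipped",
                     motif1, motif2, a$assay[1]))
        return(tibble::tibble())
      }
      fit <- lm(log2_activity ~ c1 + c2 + k, data = a)
      sm <- summary(fit)$coefficients
      tibble::tibble(
        motif1 = motif1, motif2 = motif2, assay = a$assay[1],
        beta_count1 = sm["c1", "Estimate"], beta_count2 = sm["c2", "Estimate"],
        beta_k = sm["k", "Estimate"], p_k = sm["k", "Pr(>|t|)"],
        n_obs = nrow(a)
      )
    })
  })
  res |>
    dplyr::group_by(.data$assay) |>
    dplyr::mutate(adj_p_k = p.adjust(.data$p_k, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$adj_p_k < fdr,
                  direction = sign(.data$beta_k))
}

#' Motif-order ANOVA on Class 3 arrangements
#'
#' One-way ANOVA per (4-motif set, assay) with the 24 orderings as the
#' factor and per-replicate activities (both templates) as observations;
#' BH-adjusted across sets within each assay. Also records the activity
#' range: max minus min of per-ordering mean activity.
#'
#' @param records activity tibble
#' @param designs design tibble (Class 3 rows are used)
#' @param fdr significance threshold on the adjusted p-value (default 0.01)
#' @return tibble: `motif_set`, `assay`, `f_statistic`, `p_value`,
#'   `adj_p_value`, `activity_range`, `n_obs`, `significant`
#' @export
order_anova <- function(records, designs, fdr = 0.01) {
  slots <- motif_slot_order(designs)
  meta <- slots |>
    dplyr::group_by(.data$element_id) |>
    dplyr::summarise(
      motif_set = paste(sort(.data$motif), collapse = "+"),
      ordering = paste(.data$motif[order(.data$slot)], collapse = ">"),
      .groups = "drop")
  obs <- rep_activities(records) |>
    dplyr::inner_join(meta, by = "element_id")
  res <- obs |>
    dplyr::group_by(.data$motif_set, .data$assay) |>
    dplyr::group_modify(function(g, key) {
      sizes <- table(g$ordering)
      if (sum(sizes >= 2) < 2) {
        warn(sprintf("motif set %s: fewer than two orderings with >=2 observations; skipped",
                     key$motif_set))
        return(tibble::tibble())
      }
      rng <- diff(range(tapply(g$log2_activity, g$ordering, mean)))
      if (var(g$log2_activity) == 0) {
        return(tibble::tibble(f_statistic = 0, p_value = 1,
                              activity_range = rng, n_obs = nrow(g)))
      }
      fit <- stats::oneway.test(log2_activity ~ ordering, data = g,
                                var.equal = TRUE)
      tibble::tibble(f_statistic = unname(fit$statistic),
                     p_value = fit$p.value, activity_range = rng,
                     n_obs = nrow(g))
    }) |>
    dplyr::ungroup()
  res |>
    dplyr::group_by(.data$assay) |>
    dplyr::mutate(adj_p_value = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$adj_p_value < fdr)
}

#' Positional enrichment of motifs in top/bottom-ranked Class 3 sequences
#'
#' Ranks all Class 3 elements by pooled transcriptional (MPRA) activity,
#' selects the top and bottom `n_select`, and tests each (motif, slot
#' position 1-4) for over-representation in each tail with an upper-tail
#' hypergeometric test; BH adjustment is across motif x position within
#' each tail. Ties at the selection boundary are broken by `element_id`.
#'
#' @param records activity tibble (pooled MPRA rows are used)
#' @param designs design tibble (Class 3 rows are used)
#' @param n_select tail size (default 200)
#' @return tibble: `motif`, `position`, `tail`, `x`, `n`, `big_k`, `big_n`,
#'   `odds_ratio`, `p_value`, `adj_p_value`, `stars`
#' @export
positional_enrichment <- function(records, designs, n_select = 200) {
  slots <- motif_slot_order(designs)
  ranked <- pooled_activities(records) |>
    dplyr::filter(.data$assay == "MPRA",
                  .data$element_id %in% unique(slots$element_id)) |>
    dplyr::arrange(dplyr::desc(.data$log2_activity), .data$element_id)
  if (nrow(ranked) < n_select) {
    abort(sprintf("only %d ranked elements; n_select = %d", nrow(ranked),
                  n_select))
  }
  sel <- list(top = head(ranked$element_id, n_select),
              bottom = tail(ranked$element_id, n_select))
  big_n <- nrow(ranked)
  slots <- dplyr::filter(slots, .data$element_id %in% ranked$element_id)
  grid <- tidyr::expand_grid(motif = sort(unique(slots$motif)),
                             position = 1:4, tail = c("top", "bottom"))
  res <- purrr::pmap_dfr(grid, function(motif, position, tail) {
    at <- slots$element_id[slots$motif == motif & slots$slot == position]
    x <- sum(sel[[tail]] %in% at)
    big_k <- length(at)
    n <- n_select
    or <- if (x == 0) {
      0
    } else if (n - x == 0 || big_k - x == 0) {
      Inf
    } else {
      (x / (n - x)) / ((big_k - x) / ((big_n - big_k) - (n - x)))
    }
    tibble::tibble(
      motif = motif, position = position, tail = tail,
      x = x, n = n, big_k = big_k, big_n = big_n, odds_ratio = or,
      p_value = phyper(x - 1, big_k, big_n - big_k, n, lower.tail = FALSE)
    )
  })
  res |>
    dplyr::group_by(.data$tail) |>
    dplyr::mutate(adj_p_value = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(stars = as.character(cut(
      .data$adj_p_value, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))))
}

#' Drop motifs unobserved in the inserted channel
#'
#' Motifs whose elements have a median pooled inserted count below the
#' threshold (e.g. never amplified from genomic DNA) are removed wholesale:
#' every element containing such a motif is dropped from both the design
#' and the activity records.
#'
#' @param records activity tibble carrying `n_inserted` on pooled rows
#' @param designs design tibble (grammar rows are used)
#' @param min_inserted inclusion threshold on the median pooled inserted
#'   count (default 10)
#' @return list with `designs`, `records` (filtered) and `dropped` (motif
#'   names removed)
#' @export
exclude_unobserved_motifs <- function(records, designs, min_inserted = 10) {
  counts <- motif_counts(designs)
  pooled <- records |>
    dplyr::filter(is.na(.data$replicate)) |>
    dplyr::distinct(.data$element_id, .data$n_inserted)
  cover <- counts |>
    dplyr::inner_join(pooled, by = "element_id") |>
    dplyr::group_by(.data$motif) |>
    dplyr::summarise(median_inserted = median(.data$n_inserted),
                     .groups = "drop")
  dropped <- cover$motif[cover$median_inserted < min_inserted]
  if (length(dropped) > 0) {
    bad_ids <- unique(counts$element_id[counts$motif %in% dropped])
    designs <- dplyr::filter(designs, !.data$element_id %in% bad_ids)
    records <- dplyr::filter(records, !.data$element_id %in% bad_ids)
    inform(sprintf("dropped motifs with insufficient inserted coverage: %s",
                   paste(dropped, collapse = ", ")))
  }
  list(designs = designs, records = records, dropped = dropped)
}
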