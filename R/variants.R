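# Variant-effect regression for saturation single-nucleotide substitution
# libraries: a count-level linear model per (CRE, assay).

assay_channels <- function(assay) {
  switch(assay,
    MPRA = c(enriched = "rna_bc", inserted = "dna_bc"),
    ATAC = c(enriched = "enriched_ATAC", inserted = "inserted"),
    H3K27ac = c(enriched = "enriched_H3K27ac", inserted = "inserted"),
    abort(sprintf("unknown assay '%s'", assay))
  )
}

#' Variant-effect regression on UMI counts
#'
#' Fits, per CRE and assay, a single joint ordinary-least-squares model
#' over all (element, replicate) observations:
#' `log2(enriched + 0.5) ~ log2(inserted + 0.5) + N`, where `N` is one 0/1
#' indicator column per variant (the wild type is the baseline). The
#' "offset" of the model is a free intercept by default; `offset_mode =
#' "exposure"` instead fixes the coefficient of `log2(inserted)` at 1 and
#' moves it to the left-hand side. For the MPRA assay the enriched/inserted
#' channels are the per-element RNA/DNA barcode totals. Each indicator's
#' estimate and two-sided t-test p-value are reported; variants flagged
#' significant at raw `p < 0.01` (no multiple-testing correction).
#'
#' @param counts count tibble for one CRE's substitution library
#' @param designs design tibble from [build_snv_library()] (identifies the
#'   WT row and the variant annotations)
#' @param assay `"MPRA"`, `"ATAC"` or `"H3K27ac"`
#' @param offset_mode free intercept (default) or fixed unit coefficient on
#'   `log2(inserted)`
#' @param pseudocount added to both channels before the log (default 0.5)
#' @param alpha significance threshold on the raw p-value (default 0.01)
#' @return an object of class `snv_fit`; `tidy()` returns the per-variant
#'   effect tibble (`cre_id`, `position`, `ref`, `alt`, `assay`, `beta`,
#'   `se`, `p_value`, `significant`), `glance()` the model summary
#'   (including the fitted slope on `log2(inserted)`)
#' @export
snv_regression <- function(counts, designs, assay,
                           offset_mode = c("intercept", "exposure"),
                           pseudocount = 0.5, alpha = 0.01) {
  offset_mode <- match.arg(offset_mode)
  ch <- assay_channels(assay)
  d <- dplyr::filter(designs, .data$category %in% c("WT", "snv"))
  wt_id <- d$element_id[d$category == "WT"]
  if (length(wt_id) != 1) abort("designs must contain exactly one WT element")
  reps <- sort(unique(counts$replicate))
  wt_seen <- unique(counts$replicate[counts$element_id == wt_id &
                                       counts$channel %in% ch])
  if (!all(reps %in% wt_seen)) {
    abort("WT element missing from a replicate: indicators are confounded")
  }
  wide <- counts |>
    dplyr::filter(.data$channel %in% ch,
                  .data$element_id %in% d$element_id) |>
    tidyr::pivot_wider(id_cols = c("element_id", "replicate"),
                       names_from = "channel", values_from = "count") |>
    tidyr::complete(element_id = d$element_id, replicate = reps) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(unname(ch)),
                                ~ tidyr::replace_na(.x, 0L)))
  enr <- wide[[ch[["enriched"]]]]
  ins <- wide[[ch[["inserted"]]]]
  if (all(enr == 0)) abort(sprintf("enriched channel all zero for assay %s", assay))
  y <- log2(enr + pseudocount)
  x <- log2(ins + pseudocount)
  elem <- factor(wide$element_id, levels = c(wt_id, setdiff(d$element_id, wt_id)))
  dat <- data.frame(y = y, x = x, elem = elem)
  fit <- if (offset_mode == "intercept") {
    lm(y ~ x + elem, data = dat)
  } else {
    lm(I(y - x) ~ elem, data = dat)
  }
  sm <- summary(fit)$coefficients
  variant_rows <- dplyr::filter(d, .data$category == "snv")
  term <- paste0("elem", variant_rows$element_id)
  idx <- match(term, rownames(sm))
  effects <- tibble::tibble(
    cre_id = variant_rows$template_id,
    element_id = variant_rows$element_id,
    position = variant_rows$variant_pos,
    ref = variant_rows$variant_ref, alt = variant_rows$variant_alt,
    assay = assay,
    beta = ifelse(is.na(idx), NA_real_, sm[idx, "Estimate"]),
    se = ifelse(is.na(idx), NA_real_, sm[idx, "Std. Error"]),
    p_value = ifelse(is.na(idx), NA_real_, sm[idx, "Pr(>|t|)"])
  )
  effects$significant <- !is.na(effects$p_value) & effects$p_value < alpha
  n_dropped <- sum(is.na(effects$beta))
  if (n_dropped > 0) {
    warn(sprintf("%d variant indicator(s) rank-deficient; reported missing",
                 n_dropped))
  }
  structure(
    list(effects = effects, model = fit, assay = assay,
         cre_id = variant_rows$template_id[1], offset_mode = offset_mode,
         slope = if (offset_mode == "intercept") unname(coef(fit)["x"]) else 1,
         alpha = alpha),
    class = "snv_fit"
  )
}

#' @export
print.snv_fit <- function(x, ...) {
  cat(sprintf("<snv_fit> CRE %s, assay %s: %d variants, %d significant (p < %g)\n",
              x$cre_id, x$assay, nrow(x$effects), sum(x$effects$significant),
              x$alpha))
  invisible(x)
}

#' @rdname snv_regression
#' @param x an `snv_fit` object
#' @param ... unused
#' @method tidy snv_fit
#' @export
tidy.snv_fit <- function(x, ...) x$effects

#' @rdname snv_regression
#' @method glance snv_fit
#' @export
glance.snv_fit <- function(x, ...) {
  sm <- summary(x$model)
  tibble::tibble(
    cre_id = x$cre_id, assay = x$assay, offset_mode = x$offset_mode,
    slope_inserted = x$slope, r_squared = sm$r.squared,
    sigma = sm$sigma, n_obs = length(sm$residuals),
    n_variants = nrow(x$effects),
    n_significant = sum(x$effects$significant)
  )
}

#' Winsorize wild-type counts
#'
#' Caps the WT element's counts at the given quantile of the variant
#' counts, per (replicate, channel), symmetrically for the enriched and
#' inserted channels. Counters the amplification anomaly where the WT
#' sequence yields far more UMIs than any variant. Off by default in the
#' regression (apply beforehand if wanted); `quantile = 1` is the identity.
#'
#' @param counts count tibble of a substitution library
#' @param designs design tibble identifying the WT row
#' @param quantile cap quantile of the variant counts (default 0.99)
#' @return the count tibble with capped WT counts
#' @export
winsorize_wt <- function(counts, designs, quantile = 0.99) {
  if (quantile >= 1) return(counts)
  wt_id <- designs$element_id[designs$category == "WT"]
  counts |>
    dplyr::group_by(.data$replicate, .data$channel) |>
    dplyr::mutate(count = {
      cap <- stats::quantile(.data$count[!.data$element_id %in% wt_id],
                             probs = quantile, names = FALSE, type = 7)
      ifelse(.data$element_id %in% wt_id, pmin(.data$count, floor(cap)),
             .data$count)
    }) |>
    dplyr::ungroup()
}
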