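# Functional-site calling from 6-bp window perturbation scans: positional
# effect profile, MAD scoring against a wild-type-derived reference, and a
# one-dimensional Canny-style edge detector.

#' Positional effect profile from window perturbation activities
#'
#' For each position `i` of the CRE, the positional effect is the median
#' pooled activity over all window elements whose window covers `i` (up to
#' width x replicates sequences for interior positions; boundary positions
#' use the windows available there). `coverage = "per_replicate"` restricts
#' to one randomization replicate, reproducing a width-sequences-per-position
#' reading. Positions covered by no surviving variant are missing and are
#' linearly interpolated before smoothing downstream (logged via message).
#'
#' @param records activity tibble (pooled rows are used)
#' @param designs design tibble from [build_window_library()]
#' @param assay assay to profile
#' @param width window width used in the design (default 6)
#' @param coverage use all covering sequences (default) or a single
#'   randomization replicate
#' @param which_rep replicate used when `coverage = "per_replicate"`
#' @return tibble: `position`, `effect`, `n_variants`
#' @export
positional_effect <- function(records, designs, assay, width = 6,
                              coverage = c("all", "per_replicate"),
                              which_rep = 1L) {
  coverage <- match.arg(coverage)
  win <- dplyr::filter(designs, .data$category == "window")
  if (nrow(win) == 0) abort("no window elements in designs")
  if (coverage == "per_replicate") {
    win <- dplyr::filter(win, .data$window_rep == which_rep)
  }
  len <- nchar(win$sequence[1])
  act <- pooled_activities(records) |>
    dplyr::filter(.data$assay == !!assay) |>
    dplyr::inner_join(win[, c("element_id", "window_start")],
                      by = "element_id")
  purrr::map_dfr(seq_len(len), function(i) {
    covering <- act$log2_activity[act$window_start <= i &
                                    act$window_start + width - 1 >= i]
    tibble::tibble(
      position = i,
      effect = if (length(covering) > 0) median(covering) else NA_real_,
      n_variants = length(covering)
    )
  })
}

#' MAD score of a positional-effect profile
#'
#' `mad = median(|effect - reference|)` over the covered positions and
#' `score = (effect - reference) / mad` (no normality constant). The
#' reference is the wild-type activity baseline; where the WT count is
#' anomalous (epigenetic assays), use the median of the single-nucleotide
#' substitution activities instead ([snv_median_reference()]).
#'
#' @param effect positional-effect vector (may contain `NA`)
#' @param reference scalar reference activity (log2 units)
#' @return list with `score` (vector), `mad` (scalar) and `reference`
#' @export
mad_score <- function(effect, reference) {
  dev <- effect - reference
  m <- median(abs(dev), na.rm = TRUE)
  if (!is.finite(m) || m == 0) {
    abort("degenerate profile: every position equals the reference (mad = 0)")
  }
  list(score = dev / m, mad = m, reference = reference)
}

#' Reference value from single-nucleotide substitution activities
#'
#' @param records activity tibble of the SNV library (pooled rows)
#' @param assay assay name
#' @return median pooled log2 activity of the substitution variants
#' @export
snv_median_reference <- function(records, assay) {
  x <- pooled_activities(records)
  median(x$log2_activity[x$assay == assay])
}

# linear interpolation over missing interior values; ends carried over
interpolate_na <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) < 2) abort("profile has fewer than 2 covered positions")
  inform(sprintf("interpolating %d uncovered position(s)", sum(is.na(x))))
  approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

gaussian_smooth <- function(x, sigma) {
  h <- ceiling(4 * sigma)
  w <- dnorm(-h:h, sd = sigma)
  w <- w / sum(w)
  n <- length(x)
  # reflect padding: index i < 1 maps to 2 - i, i > n maps to 2n - i
  idx <- function(i) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  vapply(seq_len(n), function(i) {
    sum(w * x[idx((i - h):(i + h))])
  }, numeric(1))
}

central_derivative <- function(x) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

# non-maximum suppression on |d|: position survives iff its magnitude is
# >= both neighbours (single neighbour at the ends)
nms_1d <- function(d) {
  a <- abs(d)
  n <- length(a)
  left <- c(-Inf, a[-n])
  right <- c(a[-1], -Inf)
  a >= left & a >= right
}

#' One-dimensional Canny-style functional-site detection
#'
#' The pipeline: (1) Gaussian-smooth the MAD scores (reflect padding,
#' kernel truncated at 4 sigma); (2) central-difference derivative; (3)
#' non-maximum suppression on the absolute derivative; (4) hysteresis:
#' strong edges are NMS survivors whose |derivative| exceeds the median
#' absolute derivative, weak edges are all positions exceeding that median,
#' and weak edges adjacent (distance 1) to a strong edge are promoted
#' recursively; (5) peak candidates are local extrema of the smoothed
#' scores with |smoothed| above `peak_threshold`; (6) each peak is extended
#' to the nearest strong edge on each side (to the vector end if a side has
#' none) and overlapping sites are merged. A constant input yields no
#' sites.
#'
#' @param score MAD-score vector (length >= 7, no missing values; run
#'   [interpolate_na()] first if needed)
#' @param sigma Gaussian smoothing bandwidth in positions (default 1.5)
#' @param peak_threshold minimum |smoothed score| of a peak candidate
#'   (default 0.75)
#' @return object of class `canny_sites`: `sites` tibble (`start`, `end`,
#'   `direction`, `peak`) plus diagnostics (`smoothed`, `derivative`,
#'   `strong`, `weak`, `peaks`, `median_abs_derivative`); `tidy()` returns
#'   the sites, `glance()` a one-row summary
#' @export
canny_1d <- function(score, sigma = 1.5, peak_threshold = 0.75) {
  if (length(score) < 7) abort("score vector must have length >= 7")
  if (anyNA(score)) abort("score vector contains missing values; interpolate first")
  smoothed <- gaussian_smooth(score, sigma)
  d <- central_derivative(smoothed)
  ad <- abs(d)
  med <- median(ad)
  nms <- nms_1d(d)
  strong <- nms & ad > med
  weak <- ad > med
  # hysteresis: promote weak positions adjacency-connected to a strong one
  repeat {
    grow <- weak & !strong &
      (c(FALSE, strong[-length(strong)]) | c(strong[-1], FALSE))
    if (!any(grow)) break
    strong <- strong | grow
  }
  n <- length(score)
  prev <- c(Inf, smoothed[-n])
  nxt <- c(smoothed[-1], Inf)
  is_extremum <- (smoothed - prev) * (nxt - smoothed) <= 0
  is_extremum[1] <- TRUE
  is_extremum[n] <- TRUE
  peaks <- which(is_extremum & abs(smoothed) > peak_threshold)
  strong_pos <- which(strong)
  # without any strong edge no site can be delimited (constant input lands
  # here: the strict median inequality fails everywhere)
  if (length(strong_pos) == 0) peaks <- integer(0)
  sites <- purrr::map_dfr(peaks, function(p) {
    lefts <- strong_pos[strong_pos <= p]
    rights <- strong_pos[strong_pos >= p]
    tibble::tibble(
      start = if (length(lefts)) max(lefts) else 1L,
      end = if (length(rights)) min(rights) else n,
      direction = sign(smoothed[p]), peak = p
    )
  })
  if (nrow(sites) > 0) {
    sites <- dplyr::arrange(sites, .data$start, .data$end)
    merged <- sites[1, ]
    for (i in seq_len(nrow(sites))[-1]) {
      last <- nrow(merged)
      if (sites$start[i] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], sites$end[i])
        # keep the direction/peak of the larger |smoothed| extremum
        if (abs(smoothed[sites$peak[i]]) > abs(smoothed[merged$peak[last]])) {
          merged$direction[last] <- sites$direction[i]
          merged$peak[last] <- sites$peak[i]
        }
      } else {
        merged <- dplyr::bind_rows(merged, sites[i, ])
      }
    }
    sites <- merged
  }
  structure(
    list(sites = sites, smoothed = smoothed, derivative = d,
         strong = which(strong), weak = which(weak), peaks = peaks,
         median_abs_derivative = med, sigma = sigma,
         peak_threshold = peak_threshold, score = score),
    class = "canny_sites"
  )
}

#' @export
print.canny_sites <- function(x, ...) {
  cat(sprintf("<canny_sites> %d site(s), %d strong edge(s), %d peak(s)\n",
              nrow(x$sites), length(x$strong), length(x$peaks)))
  if (nrow(x$sites) > 0) print(x$sites)
  invisible(x)
}

#' @rdname canny_1d
#' @param x a `canny_sites` object
#' @param ... unused
#' @method tidy canny_sites
#' @export
tidy.canny_sites <- function(x, ...) x$sites

#' @rdname canny_1d
#' @method glance canny_sites
#' @export
glance.canny_sites <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$sites), n_strong = length(x$strong),
    n_peaks = length(x$peaks),
    median_abs_derivative = x$median_abs_derivative,
    sigma = x$sigma, peak_threshold = x$peak_threshold
  )
}

#' Perturbation profile and functional sites for one CRE and assay
#'
#' Convenience wrapper chaining [positional_effect()], [mad_score()],
#' interpolation and [canny_1d()].
#'
#' @inheritParams positional_effect
#' @param reference reference activity: a number, or `"snv_median"` to use
#'   [snv_median_reference()] on `snv_records`
#' @param snv_records SNV-library activity tibble (needed for
#'   `reference = "snv_median"`)
#' @param sigma,peak_threshold passed to [canny_1d()]
#' @return object of class `perturbation_profile` with `profile` tibble
#'   (`position`, `effect`, `score`, `smoothed`, `derivative`),
#'   `sites`, `mad`, `reference`; `tidy()` returns the profile,
#'   `glance()` a summary row
#' @export
perturbation_profile <- function(records, designs, assay, reference,
                                 snv_records = NULL, width = 6, sigma = 1.5,
                                 peak_threshold = 0.75, ...) {
  if (identical(reference, "snv_median")) {
    if (is.null(snv_records)) abort("reference = 'snv_median' needs snv_records")
    reference <- snv_median_reference(snv_records, assay)
  }
  eff <- positional_effect(records, designs, assay, width = width, ...)
  ms <- mad_score(interpolate_na(eff$effect), reference)
  cs <- canny_1d(ms$score, sigma = sigma, peak_threshold = peak_threshold)
  cre <- unique(designs$template_id[designs$category == "window"])[1]
  structure(
    list(
      profile = tibble::tibble(
        position = eff$position, effect = eff$effect, score = ms$score,
        smoothed = cs$smoothed, derivative = cs$derivative
      ),
      sites = dplyr::mutate(cs$sites, cre_id = cre, assay = assay,
                            .before = 1),
      canny = cs, mad = ms$mad, reference = ms$reference,
      cre_id = cre, assay = assay
    ),
    class = "perturbation_profile"
  )
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat(sprintf("<perturbation_profile> CRE %s, assay %s: mad = %.3g, %d site(s)\n",
              x$cre_id, x$assay, x$mad, nrow(x$sites)))
  invisible(x)
}

#' @rdname perturbation_profile
#' @param x a `perturbation_profile`
#' @method tidy perturbation_profile
#' @export
tidy.perturbation_profile <- function(x, ...) x$profile

#' @rdname perturbation_profile
#' @method glance perturbation_profile
#' @export
glance.perturbation_profile <- function(x, ...) {
  tibble::tibble(cre_id = x$cre_id, assay = x$assay, mad = x$mad,
                 reference = x$reference, n_sites = nrow(x$sites))
}

#' Write functional sites as a BED-like TSV
#'
#' Coordinates are 1-based inclusive (noted in a header comment line).
#'
#' @param sites site tibble (e.g. the `sites` component of a
#'   [perturbation_profile()])
#' @param path output path
#' @export
write_sites_tsv <- function(sites, path) {
  writeLines("# coordinates are 1-based inclusive", path)
  readr::write_tsv(sites, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
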