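#' Random A/C/G/T sequences
#'
#' @param n number of sequences
#' @param length sequence length in bp
#' @param seed optional RNG seed
#' @return character vector
#' @export
random_dna <- function(n, length = 100, seed = NULL) {
  with_seed_(seed, {
    vapply(seq_len(n), function(i) {
      chars_seq(sample(DNA_BASES, length, replace = TRUE))
    }, character(1))
  })
}

#' Scramble a sequence
#'
#' Returns a uniform random permutation of the input characters (base
#' composition is preserved exactly).
#'
#' @param sequence A/C/G/T string
#' @param seed optional RNG seed
#' @return scrambled string
#' @export
scramble_sequence <- function(sequence, seed = NULL) {
  assert_acgt(sequence)
  with_seed_(seed, chars_seq(sample(seq_chars(sequence))))
}

#' Build a saturation single-nucleotide substitution library
#'
#' Every position of the wild-type sequence is replaced with each of the
#' other three nucleotides, giving 3 x length variants plus the wild type
#' itself as a separate element.
#'
#' @param wt a one-row design tibble (or list) with `element_id` and
#'   `sequence`; the id is used as the CRE id prefix
#' @return design tibble: one `WT` row plus one `snv` row per variant, with
#'   `variant_pos`, `variant_ref`, `variant_alt` populated
#' @export
build_snv_library <- function(wt) {
  wt <- tibble::as_tibble(wt)
  seq <- wt$sequence[1]
  cre <- wt$element_id[1]
  if (!is_acgt(seq)) abort("WT sequence contains ambiguous bases")
  chars <- seq_chars(seq)
  variants <- purrr::map_dfr(seq_along(chars), function(pos) {
    ref <- chars[pos]
    purrr::map_dfr(setdiff(DNA_BASES, ref), function(alt) {
      mut <- chars
      mut[pos] <- alt
      design_element(
        element_id = sprintf("%s_p%03d%sto%s", cre, pos, ref, alt),
        library = "perturbation", category = "snv", template_id = cre,
        sequence = chars_seq(mut),
        variant_pos = pos, variant_ref = ref, variant_alt = alt
      )
    })
  })
  dplyr::bind_rows(
    design_element(element_id = sprintf("%s_WT", cre), library = "perturbation",
                   category = "WT", template_id = cre, sequence = seq),
    variants
  )
}

#' Build a 6-bp sliding-window perturbation library
#'
#' Windows of `width` bp shifted by 1 bp tile the wild-type sequence; each
#' window is fully randomized (every window position is redrawn uniformly
#' from the three non-wild-type bases, so all window positions differ from
#' the wild type). To prevent randomization from creating new TF binding
#' sites, the mutated site plus `width` bp of flanking context on each side
#' (truncated at the sequence ends) is scanned against the `screen` motif
#' set on both strands; a candidate with any hit is rejected and redrawn,
#' up to `max_attempts` times per window. The whole randomization is
#' repeated `replicates` times.
#'
#' @inheritParams build_snv_library
#' @param width window width in bp (default 6)
#' @param replicates independent randomizations per window (default 2)
#' @param screen motif tibble used for the motif-creation rejection scan
#'   (may have zero rows to disable screening)
#' @param seed RNG seed (generation is reproducible given the seed)
#' @param max_attempts redraw cap per window before erroring
#' @param hit_caller optional scanner override passed to [scan_motifs()]
#' @return design tibble: one `WT` row plus `(length - width + 1) x
#'   replicates` `window` rows with `window_start`, `window_rep` populated
#' @export
build_window_library <- function(wt, width = 6, replicates = 2,
                                 screen = liver_tf_motifs(), seed = NULL,
                                 max_attempts = 1000, hit_caller = NULL) {
  wt <- tibble::as_tibble(wt)
  seq <- wt$sequence[1]
  cre <- wt$element_id[1]
  assert_acgt(seq, "WT sequence")
  len <- nchar(seq)
  if (width > len) abort("window width exceeds sequence length")
  screen <- if (nrow(screen) > 0) tf_motifs(screen) else screen
  chars <- seq_chars(seq)
  with_seed_(seed, {
    grid <- tidyr::expand_grid(rep = seq_len(replicates),
                               start = seq_len(len - width + 1))
    rows <- purrr::pmap_dfr(grid, function(rep, start) {
      win <- start:(start + width - 1)
      ctx <- max(1, start - width):min(len, start + width - 1 + width)
      for (attempt in seq_len(max_attempts)) {
        mut <- chars
        mut[win] <- vapply(chars[win], function(b) {
          sample(setdiff(DNA_BASES, b), 1)
        }, character(1))
        ok <- nrow(screen) == 0 ||
          nrow(scan_motifs(chars_seq(mut[ctx]), screen,
                           hit_caller = hit_caller)) == 0
        if (ok) {
          return(design_element(
            element_id = sprintf("%s_w%03d_r%d", cre, start, rep),
            library = "perturbation", category = "window", template_id = cre,
            sequence = chars_seq(mut), window_start = start, window_rep = rep
          ))
        }
      }
      abort(sprintf(
        "window at position %d (replicate %d): motif-screen rejection exceeded %d attempts",
        start, rep, max_attempts))
    })
    dplyr::bind_rows(
      design_element(element_id = sprintf("%s_WT", cre),
                     library = "perturbation", category = "WT",
                     template_id = cre, sequence = seq),
      rows
    )
  })
}

#' Build a pilot library design
#'
#' Reproduces the six-category pilot structure: 50 random genomic, 100
#' scrambled, 100 active genomic, 50 inactive genomic, 50 active synthetic
#' and 50 inactive synthetic elements (400 total by default). Source
#' sequences may be supplied per category; otherwise random sequences are
#' generated, and the scrambled category is always derived by scrambling
#' the active-genomic sequences (recycled as needed). Selecting real
#' top/bottom MPRA sequences is outside this generator's scope.
#'
#' @param counts named integer vector of per-category element counts
#' @param source_sequences optional named list of character vectors giving
#'   sequences for categories other than `scrambled`
#' @param length element length (default 100)
#' @param seed RNG seed
#' @return design tibble with `library = "pilot"` and `category` set
#' @export
build_pilot_library <- function(counts = c(random_genomic = 50, scrambled = 100,
                                           active_genomic = 100,
                                           inactive_genomic = 50,
                                           active_synthetic = 50,
                                           inactive_synthetic = 50),
                                source_sequences = NULL, length = 100,
                                seed = NULL) {
  with_seed_(seed, {
    get_seqs <- function(cat, n) {
      src <- source_sequences[[cat]]
      if (!is.null(src)) {
        assert_acgt(src, cat)
        rep(src, length.out = n)
      } else {
        random_dna(n, length)
      }
    }
    active <- get_seqs("active_genomic", counts[["active_genomic"]])
    seqs <- list(
      random_genomic = get_seqs("random_genomic", counts[["random_genomic"]]),
      scrambled = vapply(
        rep(active, length.out = counts[["scrambled"]]),
        function(s) scramble_sequence(s), character(1), USE.NAMES = FALSE),
      active_genomic = active,
      inactive_genomic = get_seqs("inactive_genomic", counts[["inactive_genomic"]]),
      active_synthetic = get_seqs("active_synthetic", counts[["active_synthetic"]]),
      inactive_synthetic = get_seqs("inactive_synthetic", counts[["inactive_synthetic"]])
    )
    purrr::imap_dfr(seqs, function(s, cat) {
      design_element(
        element_id = sprintf("%s_%03d", cat, seq_along(s)),
        library = "pilot", category = cat, template_id = NA_character_,
        sequence = s
      )
    })
  })
}
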