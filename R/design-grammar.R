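#' Neutral template sequences for synthetic enhancer design
#'
#' Two fixed 100-bp neutral backbones on which motif arrangements are
#' placed. These are synthetic stand-ins for the neutral genomic templates
#' used in the original assay design (the real hg19 bases are not
#' reproduced); they are fixed A/C/G/T strings verified to contain no match
#' to any default motif on either strand.
#'
#' @return tibble with columns `template_id`, `sequence`
#' @export
neutral_templates <- function() {
  tibble::tibble(
    template_id = c("templateA", "templateB"),
    sequence = c(
      "GACCAATGTCAAAATATCGGGCGACAATAGTTAGTCATAAAGCATCACGAATGTCGGCTATGCCGGATACTCCTACGTTTGAAATTTTAGCGTTATTACC",
      "ATTTATCCCCCGCACAGTAGGTTTCGCTACCCATCGGGGAGGAGTGTTTCATCTATAAAAATCAAAGTTTGAAGCTTTAACAGCAAGTTTGGTTCTGCTC"
    )
  )
}

#' Specification of a synthetic enhancer grammar library
#'
#' Bundles the inputs of the three grammar design classes: the motif set,
#' the neutral templates, the homotypic copy numbers, and the pairwise
#' (Class 2) arrangement patterns. The default patterns place two copies of
#' each motif of a pair into the four Class-1 `n = 4` slots (a 2:2 ratio):
#' `AABB`, `ABAB`, `ABBA`, `BBAA`.
#'
#' @param motifs motif tibble (see [tf_motifs()])
#' @param templates tibble with `template_id`, `sequence` (100-bp A/C/G/T)
#' @param copy_numbers homotypic copy numbers (default 1, 2, 4)
#' @param patterns Class 2 slot patterns, strings over `A`/`B` of length 4
#' @param element_length element length in bp (fixed at 100)
#' @return an object of class `grammar_design_spec`
#' @export
grammar_design_spec <- function(motifs = liver_tf_motifs(),
                                templates = neutral_templates(),
                                copy_numbers = c(1, 2, 4),
                                patterns = c("AABB", "ABAB", "ABBA", "BBAA"),
                                element_length = 100) {
  motifs <- tf_motifs(motifs)
  templates <- tibble::as_tibble(templates)
  assert_acgt(templates$sequence, "template sequence")
  if (any(nchar(templates$sequence) != element_length)) {
    abort(sprintf("all templates must be %d bp", element_length))
  }
  if (any(copy_numbers < 1) || any(copy_numbers != round(copy_numbers))) {
    abort("copy_numbers must be positive integers")
  }
  if (any(!grepl("^[AB]{4}$", patterns))) {
    abort("Class 2 patterns must be length-4 strings over A/B")
  }
  structure(
    list(motifs = motifs, templates = templates,
         copy_numbers = sort(unique(as.integer(copy_numbers))),
         patterns = patterns, element_length = as.integer(element_length)),
    class = "grammar_design_spec"
  )
}

# Evenly spaced placement: n copies of a width-L motif on an element of
# length len get centers round(len * (i - 1/2) / n); the motif footprint is
# [center - floor((L-1)/2), ... + L - 1]. Template bases outside footprints
# are retained.
motif_slots <- function(n, len = 100) {
  round(len * (seq_len(n) - 0.5) / n)
}

place_motifs <- function(template_seq, names, widths, centers, len = 100) {
  starts <- centers - floor((widths - 1) / 2)
  ends <- starts + widths - 1
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  names <- names[ord]; widths <- widths[ord]
  if (any(starts < 1) || any(ends > len) ||
      (length(starts) > 1 && any(starts[-1] <= ends[-length(ends)]))) {
    abort(sprintf(
      "cannot place %d motif copies (%s): footprints overlap or exceed the %d-bp element",
      length(starts), paste(unique(names), collapse = ","), len))
  }
  list(starts = starts, ends = ends, names = names)
}

apply_arrangement <- function(template_seq, motifs, names, centers, len = 100) {
  widths <- motifs$length[match(names, motifs$name)]
  pl <- place_motifs(template_seq, names, widths, centers, len)
  chars <- seq_chars(template_seq)
  copy_idx <- integer(length(pl$names))
  seen <- list()
  for (i in seq_along(pl$names)) {
    nm <- pl$names[i]
    seen[[nm]] <- (seen[[nm]] %||% 0L) + 1L
    copy_idx[i] <- seen[[nm]]
    cons <- motifs$consensus[motifs$name == nm]
    chars[pl$starts[i]:pl$ends[i]] <- seq_chars(cons)
  }
  list(
    sequence = chars_seq(chars),
    arrangement = paste(sprintf("%s:%d:%d", pl$names, copy_idx, pl$starts),
                        collapse = ";")
  )
}

design_element <- function(element_id, library, category, template_id,
                           sequence, arrangement = NA_character_,
                           variant_pos = NA_integer_, variant_ref = NA_character_,
                           variant_alt = NA_character_,
                           window_start = NA_integer_, window_rep = NA_integer_) {
  tibble::tibble(
    element_id = element_id, library = library, category = category,
    template_id = template_id, sequence = sequence, arrangement = arrangement,
    variant_pos = as.integer(variant_pos), variant_ref = variant_ref,
    variant_alt = variant_alt, window_start = as.integer(window_start),
    window_rep = as.integer(window_rep)
  )
}

#' Build the Class 1 (homotypic) grammar designs
#'
#' One element per (motif, copy number, template): `n` evenly spaced copies
#' of a single motif on a neutral template.
#'
#' @param spec a [grammar_design_spec()]
#' @return a design tibble (one row per element); `arrangement` encodes the
#'   placed copies as `name:copy:start` triples joined by `;`
#' @export
build_class1 <- function(spec) {
  stopifnot(inherits(spec, "grammar_design_spec"))
  if (nrow(spec$motifs) < 1) abort("Class 1 needs at least one motif")
  grid <- tidyr::expand_grid(
    motif = spec$motifs$name, copies = spec$copy_numbers,
    template_id = spec$templates$template_id
  )
  purrr::pmap_dfr(grid, function(motif, copies, template_id) {
    tmpl <- spec$templates$sequence[spec$templates$template_id == template_id]
    arr <- apply_arrangement(
      tmpl, spec$motifs, rep(motif, copies),
      motif_slots(copies, spec$element_length), spec$element_length
    )
    design_element(
      element_id = sprintf("c1_%s_x%d_%s", motif, copies, template_id),
      library = "grammar", category = "class1", template_id = template_id,
      sequence = arr$sequence, arrangement = arr$arrangement
    )
  })
}

#' Build the Class 2 (pairwise heterotypic) grammar designs
#'
#' For every unordered motif pair and every template, one element per
#' arrangement pattern. Under the default four 2:2 patterns with nine
#' motifs and two templates this yields 36 x 4 x 2 = 288 elements.
#'
#' @inheritParams build_class1
#' @return design tibble
#' @export
build_class2 <- function(spec) {
  stopifnot(inherits(spec, "grammar_design_spec"))
  if (nrow(spec$motifs) < 2) abort("Class 2 needs at least two motifs")
  pairs <- utils::combn(sort(spec$motifs$name), 2)
  slots <- motif_slots(4, spec$element_length)
  grid <- tidyr::expand_grid(
    pair = seq_len(ncol(pairs)), pattern = spec$patterns,
    template_id = spec$templates$template_id
  )
  purrr::pmap_dfr(grid, function(pair, pattern, template_id) {
    a <- pairs[1, pair]; b <- pairs[2, pair]
    names <- ifelse(seq_chars(pattern) == "A", a, b)
    tmpl <- spec$templates$sequence[spec$templates$template_id == template_id]
    arr <- apply_arrangement(tmpl, spec$motifs, names, slots,
                             spec$element_length)
    design_element(
      element_id = sprintf("c2_%s-%s_%s_%s", a, b, pattern, template_id),
      library = "grammar", category = "class2", template_id = template_id,
      sequence = arr$sequence, arrangement = arr$arrangement
    )
  })
}

#' Build the Class 3 (four-motif permutation) grammar designs
#'
#' For every 4-motif subset, all 4! = 24 orderings of one copy of each
#' motif in the four slots, on every template. Slot 1 is distal and slot 4
#' proximal to the minimal promoter. Nine motifs on two templates yield
#' C(9,4) x 24 x 2 = 6048 elements.
#'
#' @inheritParams build_class1
#' @return design tibble
#' @export
build_class3 <- function(spec) {
  stopifnot(inherits(spec, "grammar_design_spec"))
  if (nrow(spec$motifs) < 4) abort("Class 3 needs at least four motifs")
  subsets <- utils::combn(sort(spec$motifs$name), 4, simplify = FALSE)
  perms <- permutations_4()
  slots <- motif_slots(4, spec$element_length)
  orderings <- do.call(rbind, lapply(subsets, function(set) {
    matrix(set[t(perms)], ncol = 4, byrow = TRUE)
  }))
  n_ord <- nrow(orderings)
  n_tmpl <- nrow(spec$templates)
  ids <- character(n_ord * n_tmpl)
  seqs <- character(n_ord * n_tmpl)
  arrs <- character(n_ord * n_tmpl)
  tmpl_ids <- character(n_ord * n_tmpl)
  k <- 0L
  for (ti in seq_len(n_tmpl)) {
    tmpl <- spec$templates$sequence[ti]
    template_id <- spec$templates$template_id[ti]
    for (p in seq_len(n_ord)) {
      names <- orderings[p, ]
      arr <- apply_arrangement(tmpl, spec$motifs, names, slots,
                               spec$element_length)
      k <- k + 1L
      ids[k] <- sprintf("c3_%s_%s", paste(names, collapse = "-"), template_id)
      seqs[k] <- arr$sequence
      arrs[k] <- arr$arrangement
      tmpl_ids[k] <- template_id
    }
  }
  design_element(element_id = ids, library = "grammar", category = "class3",
                 template_id = tmpl_ids, sequence = seqs, arrangement = arrs)
}

permutations_4 <- function() {
  idx <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 4), ]
  as.matrix(idx[order(idx$a, idx$b, idx$c, idx$d), , drop = FALSE])
}

#' Build the full grammar library (Classes 1-3)
#'
#' @inheritParams build_class1
#' @return design tibble combining [build_class1()], [build_class2()] and
#'   [build_class3()]
#' @export
build_grammar_library <- function(spec = grammar_design_spec()) {
  dplyr::bind_rows(build_class1(spec), build_class2(spec), build_class3(spec))
}

#' Per-element motif copy counts
#'
#' Parses the `arrangement` column of a design tibble into long form.
#'
#' @param designs design tibble
#' @return tibble with columns `element_id`, `motif`, `copies`
#' @export
motif_counts <- function(designs) {
  d <- dplyr::filter(designs, !is.na(.data$arrangement), .data$arrangement != "")
  parts <- strsplit(d$arrangement, ";", fixed = TRUE)
  long <- tibble::tibble(
    element_id = rep(d$element_id, lengths(parts)),
    motif = sub(":.*$", "", unlist(parts))
  )
  dplyr::count(long, .data$element_id, .data$motif, name = "copies")
}

#' Motif slot order of Class 3 elements
#'
#' @param designs design tibble (Class 3 rows are used)
#' @return tibble with `element_id`, `motif`, `slot` (1 = distal, 4 =
#'   proximal to the minimal promoter)
#' @export
motif_slot_order <- function(designs) {
  d <- dplyr::filter(designs, .data$category == "class3")
  parts <- strsplit(d$arrangement, ";", fixed = TRUE)
  flat <- unlist(parts)
  # arrangement strings are built in start order, so within-element rank
  # equals position in the string
  tibble::tibble(
    element_id = rep(d$element_id, lengths(parts)),
    motif = sub(":.*$", "", flat),
    slot = sequence(lengths(parts))
  )
}
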