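# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# a small motif set that fits four slots comfortably
toy_motifs <- function(n = 4) {
  tf_motifs(tibble::tibble(
    name = paste0("M", seq_len(n)),
    consensus = c("ACGTAC", "GGATCC", "TTGACA", "CATCAT", "GCGCGC",
                  "ATATAT", "CCAACC", "GTGTGA", "TAGTAG")[seq_len(n)]
  ))
}

toy_spec <- function(n_motifs = 4, n_templates = 2, ...) {
  grammar_design_spec(
    motifs = toy_motifs(n_motifs),
    templates = neutral_templates()[seq_len(n_templates), ],
    ...
  )
}

# random-genomic control design rows for TMM anchoring
control_designs <- function(n = 50, seed = 99) {
  tibble::tibble(
    element_id = sprintf("ctrl_%03d", seq_len(n)),
    library = "pilot", category = "random_genomic",
    template_id = NA_character_,
    sequence = random_dna(n, 100, seed = seed),
    arrangement = NA_character_, variant_pos = NA_integer_,
    variant_ref = NA_character_, variant_alt = NA_character_,
    window_start = NA_integer_, window_rep = NA_integer_
  )
}

# per-replicate activity records drawn directly around planted latent
# values (fast path for statistical calibration tests)
direct_activities <- function(latent, replicates = 6, sd = 0.2, seed = 1,
                              assay = "MPRA") {
  withr::with_seed(seed, {
    out <- tidyr::expand_grid(element_id = latent$element_id,
                              replicate = seq_len(replicates))
    out$assay <- assay
    out$log2_activity <- latent$latent[match(out$element_id,
                                             latent$element_id)] +
      stats::rnorm(nrow(out), 0, sd)
    out
  })
}

# additive latent activities from per-copy motif effects (no interaction)
additive_latent <- function(designs, effects) {
  mc <- motif_counts(designs)
  mc$add <- effects[mc$motif] * mc$copies
  lat <- dplyr::summarise(dplyr::group_by(mc, element_id),
                          latent = sum(add), .groups = "drop")
  missing <- setdiff(designs$element_id, lat$element_id)
  dplyr::bind_rows(lat, tibble::tibble(element_id = missing, latent = 0))
}

# tiny deterministic count table
toy_counts <- function(elements, replicates, channels, counts) {
  tidyr::expand_grid(element_id = elements, replicate = replicates,
                     channel = channels) |>
    dplyr::mutate(count = counts)
}
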