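# Synthetic-data generator: plants latent activities and effects on a
# design, then draws barcode- and UMI-level counts with the error
# structure the scoring assumes (overdispersed lentiviral integration
# counts, Poisson enrichment conditional on integration). Negative
# controls have latent activity exactly zero. Default depth scales follow
# the assay's reported orders of magnitude: ~80 barcodes per element,
# ~300 inserted UMIs per element, enrichment rate ~0.25 (so tens of
# enriched UMIs per element at baseline).

SIM_ASSAYS <- c("MPRA", "ATAC", "H3K27ac")

#' Simulation effect configuration
#'
#' @param motif_effects named list per assay of named numeric vectors: the
#'   additive log2-activity effect of one motif copy
#' @param synergy tibble (`motif1`, `motif2`, `assay`, `delta`): extra
#'   log2 activity added when both motifs co-occur (Class 2/3 elements)
#' @param variant_effects tibble (`element_id`, `assay`, `effect`)
#' @param window_effects tibble (`cre_id`, `assay`, `start`, `end`,
#'   `effect`): effect applied to window elements whose window overlaps
#'   `[start, end]`
#' @param noise_sd element-level latent noise sd (log2 units)
#' @param control_categories categories whose latent activity is forced to
#'   exactly zero
#' @param depth_inserted mean inserted UMIs per element
#' @param ratio_enriched baseline enriched/inserted rate
#' @param barcodes_mean mean barcodes per element (truncated at >= 1)
#' @param dna_mean mean DNA UMIs per barcode
#' @param dispersion negative-binomial dispersion of integration counts
#' @param replicate_sd sd of the per-replicate log2 depth offset
#' @return a `sim_config` list
#' @export
sim_config <- function(motif_effects = list(), synergy = NULL,
                       variant_effects = NULL, window_effects = NULL,
                       noise_sd = 0.1,
                       control_categories = c("random_genomic", "scrambled"),
                       depth_inserted = 300, ratio_enriched = 0.25,
                       barcodes_mean = 80, dna_mean = 20, dispersion = 0.15,
                       replicate_sd = 0.05) {
  if (depth_inserted <= 0 || barcodes_mean <= 0 || dna_mean <= 0) {
    abort("depth parameters must be positive")
  }
  structure(
    list(motif_effects = motif_effects, synergy = synergy,
         variant_effects = variant_effects, window_effects = window_effects,
         noise_sd = noise_sd, control_categories = control_categories,
         depth_inserted = depth_inserted, ratio_enriched = ratio_enriched,
         barcodes_mean = barcodes_mean, dna_mean = dna_mean,
         dispersion = dispersion, replicate_sd = replicate_sd),
    class = "sim_config"
  )
}

#' Plant latent activities and effects on a design
#'
#' The latent log2 activity of an element is the sum of its motif effects
#' times copy numbers, plus synergy deltas for co-occurring pairs, plus
#' variant/window effects, plus element-level Gaussian noise; elements in
#' the control categories are forced to exactly zero. All planted values
#' are recorded before any count is sampled; the result is deterministic
#' given the seed.
#'
#' @param designs design tibble
#' @param config a [sim_config()]
#' @param seed RNG seed
#' @return object of class `sim_truth`: `latent` tibble (`element_id`,
#'   `assay`, `latent`), plus `seed`, `config`
#' @export
plant_effects <- function(designs, config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  counts <- motif_counts(designs)
  known_motifs <- unique(counts$motif)
  for (a in names(config$motif_effects)) {
    missing <- setdiff(names(config$motif_effects[[a]]), known_motifs)
    if (length(missing) > 0) {
      abort(sprintf("motif effect(s) for %s name motifs absent from the design: %s",
                    a, paste(missing, collapse = ", ")))
    }
  }
  with_seed_(seed, {
    latent <- tidyr::expand_grid(element_id = designs$element_id,
                                 assay = SIM_ASSAYS)
    latent$latent <- 0
    # motif main effects
    for (a in names(config$motif_effects)) {
      eff <- config$motif_effects[[a]]
      contrib <- counts |>
        dplyr::filter(.data$motif %in% names(eff)) |>
        dplyr::mutate(add = eff[.data$motif] * .data$copies) |>
        dplyr::group_by(.data$element_id) |>
        dplyr::summarise(add = sum(.data$add), .groups = "drop")
      i <- match(paste(latent$element_id, latent$assay),
                 paste(contrib$element_id, a))
      latent$latent <- latent$latent + ifelse(is.na(i), 0, contrib$add[i])
    }
    # synergy for co-occurring pairs
    if (!is.null(config$synergy) && nrow(config$synergy) > 0) {
      present <- split(counts$motif, counts$element_id)
      for (r in seq_len(nrow(config$synergy))) {
        s <- config$synergy[r, ]
        hit <- names(present)[vapply(present, function(m) {
          all(c(s$motif1, s$motif2) %in% m)
        }, logical(1))]
        sel <- latent$element_id %in% hit & latent$assay == s$assay
        latent$latent[sel] <- latent$latent[sel] + s$delta
      }
    }
    # variant effects
    if (!is.null(config$variant_effects) && nrow(config$variant_effects) > 0) {
      i <- match(paste(latent$element_id, latent$assay),
                 paste(config$variant_effects$element_id,
                       config$variant_effects$assay))
      latent$latent <- latent$latent +
        ifelse(is.na(i), 0, config$variant_effects$effect[i])
    }
    # window effects: applied when the element's window overlaps the region
    if (!is.null(config$window_effects) && nrow(config$window_effects) > 0) {
      win <- dplyr::filter(designs, .data$category == "window")
      for (r in seq_len(nrow(config$window_effects))) {
        w <- config$window_effects[r, ]
        hit <- win$element_id[win$template_id == w$cre_id &
                                win$window_start <= w$end &
                                win$window_start + 5 >= w$start]
        sel <- latent$element_id %in% hit & latent$assay == w$assay
        latent$latent[sel] <- latent$latent[sel] + w$effect
      }
    }
    # element-level noise, independent per assay
    if (config$noise_sd > 0) {
      latent$latent <- latent$latent + rnorm(nrow(latent), 0, config$noise_sd)
    }
    # controls pinned to zero
    ctrl_ids <- designs$element_id[designs$category %in%
                                     config$control_categories]
    latent$latent[latent$element_id %in% ctrl_ids] <- 0
    structure(list(latent = latent, seed = seed, config = config,
                   designs = designs[, c("element_id", "category")]),
              class = "sim_truth")
  })
}

#' Simulate count data from planted truth
#'
#' Fragment channels: per element and replicate, `inserted ~ NB(mean
#' depth, dispersion)` and `enriched ~ Poisson(inserted x rate x
#' 2^(latent + replicate offset))`. MPRA channels: each element gets a
#' fixed barcode set (`~ Poisson(mean barcodes)` truncated at >= 1), and
#' per barcode and replicate `dna ~ NB(dna mean, dispersion)`, `rna ~
#' Poisson(dna x 2^(latent + offset))`.
#'
#' @param truth a `sim_truth` from [plant_effects()]
#' @param replicates number of replicates (default 3)
#' @param seed RNG seed
#' @param channels which channel groups to draw (`"fragment"`, `"mpra"`)
#' @return object of class `mpra_sim`: `counts` (fragment count tibble),
#'   `barcodes` (barcode-level MPRA tibble), `truth`
#' @export
simulate_counts <- function(truth, replicates = 3, seed = 1,
                            channels = c("fragment", "mpra")) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  lat <- tidyr::pivot_wider(truth$latent, names_from = "assay",
                            values_from = "latent")
  n <- nrow(lat)
  with_seed_(seed, {
    counts <- NULL
    barcodes <- NULL
    if ("fragment" %in% channels) {
      counts <- purrr::map_dfr(seq_len(replicates), function(r) {
        off <- rnorm(2, 0, cfg$replicate_sd) # per-channel depth offset
        inserted <- rnbinom(n, mu = cfg$depth_inserted,
                            size = 1 / cfg$dispersion)
        atac <- rpois(n, inserted * cfg$ratio_enriched *
                        2^(lat$ATAC + off[1]))
        k27 <- rpois(n, inserted * cfg$ratio_enriched *
                       2^(lat$H3K27ac + off[2]))
        tibble::tibble(
          element_id = rep(lat$element_id, 3),
          replicate = r,
          channel = rep(c("inserted", "enriched_ATAC", "enriched_H3K27ac"),
                        each = n),
          count = c(inserted, atac, k27)
        )
      })
    }
    if ("mpra" %in% channels) {
      n_bc <- pmax(1L, rpois(n, cfg$barcodes_mean))
      bc_tbl <- tibble::tibble(
        element_id = rep(lat$element_id, n_bc),
        latent = rep(lat$MPRA, n_bc)
      )
      bc_tbl$barcode <- sprintf("%s_bc%03d", bc_tbl$element_id,
                                unlist(lapply(n_bc, seq_len)))
      barcodes <- purrr::map_dfr(seq_len(replicates), function(r) {
        off <- rnorm(1, 0, cfg$replicate_sd)
        dna <- rnbinom(nrow(bc_tbl), mu = cfg$dna_mean,
                       size = 1 / cfg$dispersion)
        rna <- rpois(nrow(bc_tbl), dna * 2^(bc_tbl$latent + off))
        tibble::tibble(element_id = bc_tbl$element_id,
                       barcode = bc_tbl$barcode, replicate = r,
                       dna = dna, rna = rna)
      }) |>
        dplyr::filter(.data$dna > 0, .data$rna > 0)
    }
    structure(list(counts = counts, barcodes = barcodes, truth = truth),
              class = "mpra_sim")
  })
}

#' Inflate wild-type counts to mimic the WT amplification anomaly
#'
#' Multiplies the fragment-channel counts of WT elements by `factor`
#' (e.g. 20x turns hundreds of UMIs into the ~10,000 range), exercising
#' the SNV-median reference path and WT winsorization.
#'
#' @param counts fragment count tibble
#' @param designs design tibble identifying WT rows
#' @param factor inflation factor (1 = identity)
#' @return modified count tibble
#' @export
simulate_wt_anomaly <- function(counts, designs, factor = 20) {
  wt_id <- designs$element_id[designs$category == "WT"]
  dplyr::mutate(counts, count = ifelse(
    .data$element_id %in% wt_id, as.integer(round(.data$count * factor)),
    .data$count))
}

#' Expand counts to read records with unique UMIs
#'
#' Each unit of count becomes one read with a distinct UMI, so re-counting
#' the reads reproduces the source table exactly (round-trip identity).
#'
#' @param sim an `mpra_sim` (or a fragment count tibble)
#' @param designs design tibble supplying element sequences
#' @return read-record tibble (fragment channels, plus `dna_bc`/`rna_bc`
#'   channels when barcode-level counts are present)
#' @export
counts_to_reads <- function(sim, designs) {
  seqs <- setNames(designs$sequence, designs$element_id)
  counts <- if (inherits(sim, "mpra_sim")) sim$counts else sim
  reads <- NULL
  if (!is.null(counts)) {
    expanded <- counts[rep(seq_len(nrow(counts)), counts$count), ]
    expanded <- expanded |>
      dplyr::group_by(.data$element_id, .data$replicate, .data$channel) |>
      dplyr::mutate(umi = sprintf("u%06d", dplyr::row_number())) |>
      dplyr::ungroup()
    reads <- read_records(unname(seqs[expanded$element_id]),
                          expanded$channel, expanded$replicate,
                          umi = expanded$umi)
  }
  if (inherits(sim, "mpra_sim") && !is.null(sim$barcodes)) {
    bc <- tidyr::pivot_longer(sim$barcodes, c("dna", "rna"),
                              names_to = "channel", values_to = "count")
    bc$channel <- paste0(bc$channel, "_bc")
    expanded <- bc[rep(seq_len(nrow(bc)), bc$count), ]
    expanded <- expanded |>
      dplyr::group_by(.data$barcode, .data$replicate, .data$channel) |>
      dplyr::mutate(umi = sprintf("u%06d", dplyr::row_number())) |>
      dplyr::ungroup()
    reads <- dplyr::bind_rows(
      reads,
      read_records(unname(seqs[expanded$element_id]), expanded$channel,
                   expanded$replicate, barcode = expanded$barcode,
                   umi = expanded$umi))
  }
  reads
}
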