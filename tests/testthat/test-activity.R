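# Activity scoring: CPM, TMM anchoring, MPRA and epigenetic scores,
# category tests and replicate QC.

test_that("CPM normalization rescales each channel to one million", {
  tab <- toy_counts(c("a", "b"), 1L, "inserted", c(1L, 1L))
  expect_equal(cpm_normalize(tab)$cpm, c(5e5, 5e5))
  tab2 <- toy_counts(c("a", "b"), 1L, "inserted", c(1L, 3L))
  expect_equal(cpm_normalize(tab2)$cpm, c(2.5e5, 7.5e5))
  tab10 <- dplyr::mutate(tab2, count = count * 10L)
  expect_equal(cpm_normalize(tab10)$cpm, cpm_normalize(tab2)$cpm)
  zero <- toy_counts("a", 1L, "inserted", 0L)
  expect_error(cpm_normalize(zero), "zero total")
})

test_that("TMM factor recovers constant ratios and is idempotent", {
  ins <- c(100, 200, 300, 150, 80)
  expect_equal(tmm_factor(ins, ins), 1)
  expect_equal(tmm_factor(3 * ins, ins), 3)
  withr::with_seed(2, {
    e <- ins * 2^rnorm(5, 0.5, 0.3)
  })
  f <- tmm_factor(e, ins)
  expect_equal(tmm_factor(e / f, ins), 1, tolerance = 1e-12)
  expect_error(tmm_factor(c(1, 2), c(1, 2)), "at least 3")
})

test_that("TMM trimming matches a brute-force sort-and-average oracle", {
  withr::with_seed(9, {
    ins <- runif(20, 50, 500)
    e <- ins * 2^rnorm(20, 0.3, 0.5)
  })
  m <- log2(e / ins)
  a <- 0.5 * log2(e * ins)
  n <- length(m)
  keep <- function(x, trim) {
    lo <- floor(n * trim) + 1
    hi <- n + 1 - lo
    r <- rank(x, ties.method = "first")
    r >= lo & r <= hi
  }
  oracle <- 2^mean(m[keep(m, 0.3) & keep(a, 0.05)])
  expect_equal(tmm_factor(e, ins), oracle)
})

test_that("epigenetic activity is zero for balanced counts and pools by summed counts", {
  ctrl <- paste0("c", 1:3)
  mk <- function(enr1, enr2, ins) {
    dplyr::bind_rows(
      toy_counts(ctrl, 1:2, c("inserted", "enriched_ATAC"), 100L),
      tibble::tibble(element_id = "x", replicate = c(1L, 2L, 1L, 2L),
                     channel = rep(c("enriched_ATAC", "inserted"), each = 2),
                     count = c(enr1, enr2, ins, ins)),
      tibble::tibble(element_id = "fill", replicate = c(1L, 2L, 1L, 2L),
                     channel = rep(c("enriched_ATAC", "inserted"), each = 2),
                     count = c(8L, 4L, 6L, 6L))
    )
  }
  # equal enriched and inserted everywhere -> activity 0
  bal <- toy_counts(c(ctrl, "x"), 1:2, c("inserted", "enriched_ATAC"), 50L)
  act <- epigenetic_activity(bal, ctrl, min_inserted = 0)
  expect_equal(act$log2_activity, rep(0, nrow(act)))
  # replicate pairs (2,4) and (6,4) with balancing filler: pooled 8/8 -> 0
  act2 <- epigenetic_activity(mk(2L, 6L, 4L), ctrl, min_inserted = 0)
  pooled_x <- dplyr::filter(act2, element_id == "x", is.na(replicate))
  expect_equal(pooled_x$log2_activity, 0, tolerance = 1e-12)
  expect_equal(pooled_x$n_enriched, 8L)
  # inserted = 0 in all replicates -> missing
  z <- dplyr::mutate(mk(2L, 6L, 4L), count = ifelse(
    element_id == "x" & channel == "inserted", 0L, count))
  actz <- epigenetic_activity(z, ctrl, min_inserted = 0)
  expect_true(all(is.na(
    dplyr::filter(actz, element_id == "x")$log2_activity)))
})

test_that("activities are invariant to channel-wide count scaling", {
  designs <- control_designs(30)
  truth <- plant_effects(designs, sim_config(noise_sd = 0.3,
                                             control_categories = character(0)),
                         seed = 8)
  sim <- simulate_counts(truth, replicates = 2, seed = 9)
  ctrl <- designs$element_id[1:10]
  a1 <- epigenetic_activity(sim$counts, ctrl, min_inserted = 0)
  scaled <- dplyr::mutate(sim$counts, count = ifelse(
    channel == "enriched_ATAC", count * 7L, count))
  a2 <- epigenetic_activity(scaled, ctrl, min_inserted = 0)
  expect_equal(a1$log2_activity, a2$log2_activity, tolerance = 1e-9)
})

test_that("pooled equals per-replicate activity when replicates are identical", {
  designs <- control_designs(20)
  truth <- plant_effects(designs, sim_config(noise_sd = 0.5,
                                             control_categories = character(0)),
                         seed = 12)
  sim <- simulate_counts(truth, replicates = 1, seed = 13)
  twice <- dplyr::bind_rows(sim$counts,
                            dplyr::mutate(sim$counts, replicate = 2L))
  ctrl <- designs$element_id[1:8]
  act <- epigenetic_activity(twice, ctrl, min_inserted = 0)
  per_rep <- dplyr::filter(act, replicate == 1, assay == "ATAC")
  pooled <- dplyr::filter(act, is.na(replicate), assay == "ATAC")
  expect_equal(pooled$log2_activity, per_rep$log2_activity, tolerance = 1e-12)
})

test_that("MPRA activity averages per-barcode log ratios and anchors on controls", {
  ctrl_bc <- tidyr::expand_grid(element_id = paste0("c", 1:4),
                                barcode = paste0("b", 1:5)) |>
    dplyr::mutate(barcode = paste(element_id, barcode), replicate = 1L,
                  dna = 10L, rna = 10L)
  x <- tibble::tibble(element_id = "x", barcode = c("x1", "x2"),
                      replicate = 1L, dna = c(4L, 1L), rna = c(8L, 8L))
  act <- mpra_activity(dplyr::bind_rows(ctrl_bc, x), paste0("c", 1:4),
                       pool = FALSE)
  expect_equal(act$log2_activity[act$element_id == "x"], 2)  # (1+3)/2
  expect_equal(act$log2_activity[act$element_id != "x"], rep(0, 4))
  ros <- mpra_activity(dplyr::bind_rows(ctrl_bc, x), paste0("c", 1:4),
                       aggregate = "ratio_of_sums", pool = FALSE)
  expect_equal(ros$log2_activity[ros$element_id == "x"], log2(16 / 5))
})

test_that("MPRA and epigenetic scorers agree on one-barcode degenerate input", {
  n <- 12
  ids <- sprintf("e%02d", seq_len(n))
  withr::with_seed(31, {
    dna <- rpois(n, 200) + 1L
    rna <- rpois(n, 300) + 1L
  })
  ctrl <- ids[1:5]
  bc <- tibble::tibble(element_id = ids, barcode = paste0(ids, "_b"),
                       replicate = 1L, dna = dna, rna = rna)
  counts <- dplyr::bind_rows(
    tibble::tibble(element_id = ids, replicate = 1L, channel = "inserted",
                   count = dna),
    tibble::tibble(element_id = ids, replicate = 1L, channel = "enriched_ATAC",
                   count = rna)
  )
  am <- mpra_activity(bc, ctrl, pool = FALSE)
  ae <- dplyr::filter(epigenetic_activity(counts, ctrl, pool = FALSE),
                      assay == "ATAC")
  m <- dplyr::inner_join(am, ae, by = "element_id")
  expect_equal(m$log2_activity.x, m$log2_activity.y, tolerance = 1e-12)
})

test_that("category tests compare against the reference with BH within assay", {
  ids <- c(sprintf("r%02d", 1:50), sprintf("s%02d", 1:50),
           sprintf("n%02d", 1:50))
  cats <- tibble::tibble(
    element_id = ids,
    category = rep(c("random_genomic", "shifted", "null_like"), each = 50))
  withr::with_seed(17, {
    act <- tibble::tibble(
      element_id = ids, assay = "MPRA", replicate = NA_integer_,
      log2_activity = c(rnorm(50), rnorm(50, 3), rnorm(50)))
  })
  res <- category_tests(act, cats)
  expect_lt(res$adj_p_value[res$category == "shifted"], 1e-4)
  expect_gt(res$p_value[res$category == "null_like"], 0.01)
  # identical category -> p near 1
  same <- dplyr::mutate(act, log2_activity = rep(act$log2_activity[1:50], 3))
  res2 <- category_tests(same, cats)
  expect_true(all(res2$p_value > 0.9))
})

test_that("BH adjustment matches the hand-computed step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * n / seq_len(n))))
    pmin(1, adj)[order(o)]
  }
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  withr::with_seed(5, {
    p <- runif(25)
  })
  expect_equal(p.adjust(p, "BH"), bh_oracle(p))
})

test_that("replicate QC reports Spearman correlations over shared elements", {
  ids <- sprintf("e%02d", 1:30)
  withr::with_seed(23, {
    base <- rnorm(30)
  })
  self <- tibble::tibble(
    element_id = rep(ids, 2), assay = "MPRA",
    replicate = rep(1:2, each = 30), log2_activity = rep(base, 2))
  expect_equal(replicate_qc(self)$rho, 1)
  anti <- dplyr::mutate(self, log2_activity = c(base, -base))
  expect_equal(replicate_qc(anti)$rho, -1)
  # independent replicate noise around strong latent signal: high rho
  designs <- control_designs(60)
  truth <- plant_effects(
    designs, sim_config(noise_sd = 1.5, control_categories = character(0),
                        depth_inserted = 2000),
    seed = 19)
  sim <- simulate_counts(truth, replicates = 2, seed = 20)
  act <- epigenetic_activity(sim$counts, designs$element_id[1:15],
                             min_inserted = 0)
  qc <- replicate_qc(act)
  expect_true(all(qc$rho > 0.9))
  expect_true(all(qc$n == 60))
})
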