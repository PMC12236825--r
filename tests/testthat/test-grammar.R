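# Grammar statistics: homotypic trend, synergy regression, motif-order
# ANOVA, positional enrichment, motif exclusion.

grammar_fixture <- function() {
  spec <- toy_spec(4)
  designs <- dplyr::bind_rows(build_class1(spec), build_class2(spec))
  list(spec = spec, designs = designs)
}

test_that("homotypic trend finds monotone copy-number relationships", {
  fx <- grammar_fixture()
  eff <- c(M1 = 0.5, M2 = 0, M3 = 0, M4 = 0)
  lat <- additive_latent(fx$designs, eff)
  # strictly increasing with copies, no noise -> rho = 1 for M1
  act <- direct_activities(lat, replicates = 3, sd = 0, seed = 1)
  # jitter to avoid all-constant groups for null motifs
  act2 <- direct_activities(lat, replicates = 6, sd = 0.2, seed = 2)
  tr0 <- homotypic_trend(act, fx$designs)
  expect_equal(tr0$rho[tr0$motif == "M1"], 1)
  tr <- homotypic_trend(act2, fx$designs)
  expect_true(tr$significant[tr$motif == "M1"])
  expect_false(any(tr$significant[tr$motif != "M1"]))
  # constant activities -> rho reported missing
  expect_true(is.na(tr0$rho[tr0$motif == "M2"]))
})

test_that("homotypic trend has power for a planted 0.5 log2/copy slope", {
  fx <- grammar_fixture()
  lat <- additive_latent(fx$designs, c(M1 = 0.5, M2 = 0, M3 = 0, M4 = 0))
  hits <- vapply(1:60, function(i) {
    act <- direct_activities(lat, replicates = 6, sd = 0.3, seed = 100 + i)
    tr <- homotypic_trend(act, fx$designs)
    tr$significant[tr$motif == "M1"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("synergy regression recovers a planted pairwise interaction", {
  fx <- grammar_fixture()
  eff <- c(M1 = 0.3, M2 = 0.2, M3 = 0.1, M4 = 0.4)
  lat <- additive_latent(fx$designs, eff)
  # add delta = 1 to all Class 2 elements of the pair M1-M2
  mc <- motif_counts(fx$designs)
  pair_ids <- intersect(mc$element_id[mc$motif == "M1"],
                        mc$element_id[mc$motif == "M2"])
  pair_ids <- intersect(pair_ids, fx$designs$element_id[
    fx$designs$category == "class2"])
  lat$latent[lat$element_id %in% pair_ids] <-
    lat$latent[lat$element_id %in% pair_ids] + 1
  act <- direct_activities(lat, replicates = 6, sd = 0.2, seed = 31)
  sy <- synergy_regression(act, fx$designs)
  hit <- dplyr::filter(sy, motif1 == "M1", motif2 == "M2")
  # k = 2 encoding: delta enters as beta_k * 2
  expect_equal(hit$beta_k, 0.5, tolerance = 0.1)
  expect_true(hit$significant)
  expect_false(any(sy$significant[sy$motif1 != "M1" | sy$motif2 != "M2"]))
  # indicator encoding absorbs the full delta
  sy1 <- synergy_regression(act, fx$designs, k_mode = "indicator")
  hit1 <- dplyr::filter(sy1, motif1 == "M1", motif2 == "M2")
  expect_equal(hit1$beta_k, 1, tolerance = 0.2)
})

test_that("synergy regression errors without Class 2 data", {
  fx <- grammar_fixture()
  c1 <- dplyr::filter(fx$designs, category == "class1")
  lat <- additive_latent(c1, c(M1 = 0.3, M2 = 0, M3 = 0, M4 = 0))
  act <- direct_activities(lat, replicates = 3, sd = 0.1, seed = 5)
  expect_error(synergy_regression(act, c1), "not identifiable")
})

test_that("null synergy calibration stays at the nominal FDR", {
  fx <- grammar_fixture()
  eff <- c(M1 = 0.3, M2 = 0.2, M3 = 0.1, M4 = 0.4)
  lat <- additive_latent(fx$designs, eff)
  calls <- vapply(1:60, function(i) {
    act <- direct_activities(lat, replicates = 6, sd = 0.2, seed = 500 + i)
    mean(synergy_regression(act, fx$designs)$significant)
  }, numeric(1))
  expect_lte(mean(calls), 0.02 + 0.015)  # nominal 0.01 + Monte-Carlo margin
})

test_that("order ANOVA tests permutation identity per four-motif set", {
  spec <- toy_spec(5, 1)
  c3 <- build_class3(spec)
  lat <- tibble::tibble(element_id = c3$element_id, latent = 0)
  # shift one ordering of one set by 3 sd
  shifted <- c3$element_id[grepl("^c3_M1-M2-M3-M4_", c3$element_id)][1]
  lat$latent[lat$element_id == shifted] <- 0.6  # 3 x sd below
  act <- direct_activities(lat, replicates = 6, sd = 0.2, seed = 41)
  res <- order_anova(act, c3)
  expect_equal(nrow(res), choose(5, 4))
  hit <- res[res$motif_set == "M1+M2+M3+M4", ]
  expect_lt(hit$adj_p_value, 0.01)
  expect_gt(hit$activity_range, 0.3)
  # all-constant input -> F = 0, p = 1
  act0 <- direct_activities(tibble::tibble(element_id = c3$element_id,
                                           latent = 1),
                            replicates = 2, sd = 0, seed = 1)
  res0 <- order_anova(act0, c3)
  expect_true(all(res0$f_statistic == 0))
  expect_true(all(res0$p_value == 1))
})

test_that("ANOVA F on two groups equals the squared t statistic", {
  withr::with_seed(3, {
    x <- rnorm(12)
    g <- rep(c("a", "b"), each = 6)
  })
  f <- stats::oneway.test(x ~ g, var.equal = TRUE)$statistic
  t <- stats::t.test(x ~ g, var.equal = TRUE)$statistic
  expect_equal(unname(f), unname(t)^2, tolerance = 1e-12)
})

test_that("positional enrichment matches the brute-force hypergeometric oracle", {
  # exhaustive enumeration over all C(20,5) draws
  brute_upper_tail <- function(N, K, n, x) {
    draws <- utils::combn(N, n)
    marked <- seq_len(K)
    hits <- apply(draws, 2, function(d) sum(d %in% marked))
    mean(hits >= x)
  }
  for (case in list(c(20, 5, 5, 3), c(18, 6, 4, 2), c(25, 10, 6, 5))) {
    expect_equal(
      phyper(case[4] - 1, case[2], case[1] - case[2], case[3],
             lower.tail = FALSE),
      brute_upper_tail(case[1], case[2], case[3], case[4]),
      tolerance = 1e-12
    )
  }
})

test_that("positional enrichment flags a motif planted at one slot", {
  spec <- toy_spec(5)
  c3 <- build_class3(spec)
  slots <- motif_slot_order(c3)
  # M1 at the promoter-proximal slot boosts activity strongly
  boosted <- slots$element_id[slots$motif == "M1" & slots$slot == 4]
  lat <- tibble::tibble(element_id = unique(c3$element_id), latent = 0)
  lat$latent[lat$element_id %in% boosted] <- 2
  withr::with_seed(51, {
    act <- tibble::tibble(
      element_id = lat$element_id, assay = "MPRA", replicate = NA_integer_,
      log2_activity = lat$latent + rnorm(nrow(lat), 0, 0.3))
  })
  res <- positional_enrichment(act, c3, n_select = 40)
  top_hit <- dplyr::filter(res, motif == "M1", position == 4, tail == "top")
  expect_lt(top_hit$adj_p_value, 1e-4)
  expect_gt(top_hit$odds_ratio, 3)
  expect_equal(top_hit$stars, "****")
  # x = 0 with K > 0: odds ratio 0 and upper-tail p = 1
  bottom_zero <- dplyr::filter(res, p_value == 1, x == 0)
  expect_true(all(bottom_zero$odds_ratio == 0))
})

test_that("random selection gives odds ratios centred on 1", {
  spec <- toy_spec(5)
  c3 <- build_class3(spec)
  ors <- vapply(1:40, function(i) {
    withr::with_seed(700 + i, {
      act <- tibble::tibble(
        element_id = unique(c3$element_id), assay = "MPRA",
        replicate = NA_integer_,
        log2_activity = rnorm(dplyr::n_distinct(c3$element_id)))
    })
    res <- positional_enrichment(act, c3, n_select = 40)
    median(res$odds_ratio[is.finite(res$odds_ratio)])
  }, numeric(1))
  expect_equal(median(ors), 1, tolerance = 0.15)
})

test_that("BH-adjusted p-values are monotone in the raw p-values", {
  fx <- grammar_fixture()
  lat <- additive_latent(fx$designs, c(M1 = 0.4, M2 = 0.1, M3 = 0, M4 = 0.2))
  act <- direct_activities(lat, replicates = 6, sd = 0.3, seed = 61)
  sy <- synergy_regression(act, fx$designs)
  o <- order(sy$p_k)
  expect_true(all(diff(sy$adj_p_k[o]) >= -1e-15))
  expect_true(all(sy$adj_p_k >= sy$p_k))
})

test_that("motifs invisible in the inserted channel are dropped wholesale", {
  spec <- grammar_design_spec()
  c1 <- build_class1(spec)
  mc <- motif_counts(c1)
  pooled <- tibble::tibble(
    element_id = c1$element_id, assay = "ATAC", replicate = NA_integer_,
    log2_activity = 0,
    n_inserted = ifelse(c1$element_id %in%
                          mc$element_id[mc$motif == "NR2F2"], 0L, 500L))
  out <- suppressMessages(exclude_unobserved_motifs(pooled, c1))
  expect_equal(out$dropped, "NR2F2")
  remaining <- unique(motif_counts(out$designs)$motif)
  expect_length(remaining, 8)
  expect_false("NR2F2" %in% remaining)
  # well-covered input is the identity
  ok <- dplyr::mutate(pooled, n_inserted = 500L)
  out2 <- exclude_unobserved_motifs(ok, c1)
  expect_equal(nrow(out2$designs), nrow(c1))
  expect_length(out2$dropped, 0)
  out3 <- exclude_unobserved_motifs(pooled, c1, min_inserted = 0)
  expect_length(out3$dropped, 0)
})

test_that("eight analyzed motifs yield seventy ANOVA sets", {
  spec <- toy_spec(8, 2)
  c3 <- build_class3(spec)
  act <- direct_activities(
    tibble::tibble(element_id = unique(c3$element_id), latent = 0),
    replicates = 2, sd = 0.3, seed = 71)
  res <- order_anova(act, c3)
  expect_equal(nrow(res), 70)  # C(8,4)
})
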