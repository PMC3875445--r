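totals2 <- c(L1 = 1e6, L2 = 1e6)

test_that("fold changes are symmetric ratios with explicit direction", {
  counts <- tibble::tibble(
    feature_id = c("eq", "up8", "zero_t"), length_nt = 22,
    L1 = c(100L, 22L, 40L), L2 = c(100L, 176L, 0L)
  )
  fc <- fold_changes(counts, totals2, "L1", "L2")
  expect_equal(fc$fold_change[1], 1)
  expect_equal(fc$direction[1], "unchanged")
  # control RPKM 10, treated 80 in the tumour-boost regime
  expect_equal(fc$fold_change[2], 8)
  expect_equal(fc$direction[2], "up")
  # zero treated count: pseudocount keeps the fold finite
  expect_true(is.finite(fc$fold_change[3]))
  expect_equal(fc$direction[3], "down")
  expect_equal(fc$fold_change[3], 40.5 / 0.5)
})

test_that("swapping control and treated flips direction, preserves magnitude", {
  set.seed(21)
  counts <- tibble::tibble(
    feature_id = paste0("f", 1:50), length_nt = sample(18:25, 50, TRUE),
    L1 = rpois(50, 60), L2 = rpois(50, 120)
  )
  ab <- fold_changes(counts, totals2, "L1", "L2")
  ba <- fold_changes(counts, totals2, "L2", "L1")
  expect_equal(ab$fold_change, ba$fold_change)
  flip <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_equal(unname(flip[ab$direction]), ba$direction)
})

test_that("identical counts at equal depths give p = 1", {
  counts <- tibble::tibble(feature_id = "a", length_nt = 22, L1 = 57L, L2 = 57L)
  st <- significance_test(counts, totals2, "L1", "L2")
  expect_equal(st$p_value, 1)
})

test_that("the exact test agrees with the hypergeometric oracle at small totals", {
  set.seed(31)
  cases <- data.frame(
    x1 = sample(0:40, 120, TRUE), x2 = sample(0:40, 120, TRUE),
    d1 = sample(60:500, 120, TRUE), d2 = sample(60:500, 120, TRUE)
  )
  cases$x1 <- pmin(cases$x1, cases$d1)
  cases$x2 <- pmin(cases$x2, cases$d2)
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      p_ref <- fisher.test(matrix(c(x1, d1 - x1, x2, d2 - x2), 2))$p.value
      p_my <- mirshift:::exact_count_test(x1, x2, d1, d2)
      expect_equal(p_my, p_ref, tolerance = 1e-7)
    })
  }
})

test_that("the exact test stays correct for large library depths", {
  # spot-check against the cumulative hypergeometric at sequencing scale
  p <- mirshift:::exact_count_test(100, 200, 1e7, 1e7)
  expect_lt(p, 1e-8)
  expect_equal(mirshift:::exact_count_test(0, 0, 1e7, 2e7), 1)
  p_sym <- mirshift:::exact_count_test(150, 150, 5e6, 5e6)
  expect_equal(p_sym, 1)
})

test_that("q-values are monotone in p-values and significance uses q", {
  cfg <- small_sim_config(seed = 41, depth = 1e6)
  expt <- simulate_counts(generate_catalog(cfg), cfg)
  st <- significance_test(expt$counts, expt$library_totals, "L1", "L2")
  ord <- order(st$p_value)
  expect_true(all(diff(st$q_value[ord]) >= -1e-12))
  expect_true(all(st$significant == (st$q_value <= 0.05)))
})

test_that("significance_test rejects non-integer input and zero depths", {
  counts <- tibble::tibble(feature_id = "a", length_nt = 22, L1 = 1.5, L2 = 2)
  expect_error(significance_test(counts, totals2, "L1", "L2"), "integer")
  counts$L1 <- 2
  expect_error(
    significance_test(counts, c(L1 = 0, L2 = 1e6), "L1", "L2"),
    "depth"
  )
})

test_that("differential table flags low-evidence features", {
  counts <- tibble::tibble(
    feature_id = c("low", "high"), length_nt = 22,
    L1 = c(3L, 4000L), L2 = c(8L, 9000L)
  )
  dt <- differential_table(counts, totals2, "L1", "L2", "tumour")
  expect_true(dt$low_evidence[1])
  expect_false(dt$low_evidence[2])
  expect_equal(dt$compartment, c("tumour", "tumour"))
})

test_that("overlap partition reproduces set arithmetic", {
  part <- overlap_partition(c("a", "b", "c"), c("b", "c", "d", "e"))
  counts <- table(part$partition)
  expect_equal(unname(counts[["common"]]), 2)
  expect_equal(unname(counts[["tumour_only"]]), 1)
  expect_equal(unname(counts[["serum_only"]]), 2)
  expect_false(any(duplicated(part$feature_id)))

  disjoint <- overlap_partition(c("a"), c("b"))
  expect_false("common" %in% disjoint$partition)

  nested <- overlap_partition(c("a", "b"), c("a", "b", "c"))
  expect_equal(sum(nested$partition == "tumour_only"), 0)
  expect_equal(sum(nested$partition == "serum_only"), 1)
})

test_that("abundant designed effects are recovered as significant calls", {
  cfg <- sim_config(seed = 51, dispersion = 0)
  expt <- simulate_counts(generate_catalog(cfg), cfg)
  dt <- differential_table(expt$counts, expt$library_totals, "L1", "L2", "tumour")
  joined <- dplyr::inner_join(dt, expt$truth, by = "feature_id")
  ups <- dplyr::filter(joined, .data$tumour_fold >= 2)
  hit <- ups$significant & ups$direction == "up"
  expect_gte(mean(hit), 0.9)
})
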