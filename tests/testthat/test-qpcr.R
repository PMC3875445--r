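std_series <- function(spacing, gene = "g") {
  dil <- c(1, 1e-2, 1e-3, 1e-4)
  tibble::tibble(
    gene_id = gene, dilution = dil,
    Ct = 20 - spacing * log10(dil)
  )
}

test_that("dilution-series efficiency follows the closed form", {
  perfect <- glance(fit_dilution_series(std_series(log2(10))))
  expect_equal(perfect$efficiency, 1, tolerance = 1e-12)
  expect_equal(perfect$slope, -log2(10), tolerance = 1e-12)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)

  slow <- glance(fit_dilution_series(std_series(3.6)))
  expect_equal(slow$efficiency, 10^(1 / 3.6) - 1, tolerance = 1e-12)

  two_only <- std_series(3.3)[1:2, ]
  expect_error(fit_dilution_series(two_only), "at least 3")

  inverted <- std_series(-3.3)
  inv <- glance(fit_dilution_series(inverted))
  expect_false(inv$valid)
  expect_true(is.na(inv$efficiency))
})

test_that("dilution fits expose tidy() and per-gene glance() rows", {
  wells <- dplyr::bind_rows(std_series(3.32, "g1"), std_series(3.5, "g2"))
  wells$Ct <- wells$Ct + rep(c(0.05, -0.05), 4) # keep the fits non-degenerate
  fits <- fit_dilution_series(wells)
  g <- glance(fits)
  expect_equal(sort(g$gene_id), c("g1", "g2"))
  td <- tidy(fits)
  expect_equal(nrow(td), 4) # intercept + slope per gene
})

test_that("M-values equal the brute-force pairwise recomputation", {
  set.seed(91)
  for (i in 1:10) {
    genes <- paste0("g", 1:4)
    samples <- paste0("s", 1:8)
    ct <- tidyr::expand_grid(sample_id = samples, gene_id = genes)
    ct$Ct <- rnorm(nrow(ct), 25, 2)
    stab <- reference_stability(ct)
    logq <- -matrix(ct$Ct, nrow = 8, byrow = TRUE,
      dimnames = list(samples, genes))
    expected <- m_value_oracle(logq)
    got <- setNames(stab$ranking$m_value, stab$ranking$gene_id)
    expect_equal(got[genes], expected[genes], tolerance = 1e-12)
  }
})

test_that("a perfectly covarying pair attains minimal M", {
  samples <- paste0("s", 1:6)
  shift <- rnorm(6, 0, 1.5)
  ct <- dplyr::bind_rows(
    tibble::tibble(sample_id = samples, gene_id = "co1", Ct = 24 + shift),
    tibble::tibble(sample_id = samples, gene_id = "co2", Ct = 27 + shift),
    tibble::tibble(sample_id = samples, gene_id = "lone", Ct = 25 + rnorm(6, 0, 2))
  )
  stab <- reference_stability(ct)
  expect_setequal(stab$best_pair, c("co1", "co2"))
})

test_that("M-ranking is invariant under per-gene additive Ct offsets", {
  set.seed(92)
  genes <- paste0("g", 1:5)
  ct <- tidyr::expand_grid(sample_id = paste0("s", 1:7), gene_id = genes)
  ct$Ct <- rnorm(nrow(ct), 26, 1.5)
  base_rank <- reference_stability(ct)$ranking
  offsets <- setNames(runif(5, -4, 4), genes)
  shifted <- dplyr::mutate(ct, Ct = Ct + offsets[gene_id])
  shifted_rank <- reference_stability(shifted)$ranking
  expect_equal(shifted_rank$gene_id, base_rank$gene_id)
  expect_equal(shifted_rank$m_value, base_rank$m_value, tolerance = 1e-12)
})

test_that("efficiency correction reduces to 2^-ddCt when all E = 1", {
  set.seed(93)
  genes <- c("target", "ref")
  ct <- tidyr::expand_grid(
    sample_id = paste0("s", 1:8),
    gene_id = genes
  )
  ct$condition <- ifelse(as.integer(sub("s", "", ct$sample_id)) <= 4,
    "control", "treated")
  ct$Ct <- rnorm(nrow(ct), 25, 3)
  res <- relative_expression(ct, references = "ref")
  wide <- tidyr::pivot_wider(ct, names_from = "gene_id", values_from = "Ct")
  dct <- wide$target - wide$ref
  ddct <- mean(dct[wide$condition == "treated"]) - mean(dct[wide$condition == "control"])
  expect_equal(res$ratio, 2^(-ddct), tolerance = 1e-12)
})

test_that("two references with identical shifts equal one reference", {
  ct <- tidyr::expand_grid(
    sample_id = paste0("s", 1:6),
    gene_id = c("t", "r1", "r2")
  )
  ct$condition <- ifelse(as.integer(sub("s", "", ct$sample_id)) <= 3,
    "control", "treated")
  set.seed(94)
  base <- rnorm(6, 24, 0.5)
  ct$Ct <- NA_real_
  ct$Ct[ct$gene_id == "t"] <- base - ifelse(ct$condition[ct$gene_id == "t"] == "treated", 1, 0)
  ct$Ct[ct$gene_id == "r1"] <- base + 2
  ct$Ct[ct$gene_id == "r2"] <- base + 2
  both <- relative_expression(ct, references = c("r1", "r2"))
  one <- relative_expression(
    dplyr::filter(ct, gene_id != "r2"),
    references = "r1"
  )
  expect_equal(both$ratio, one$ratio, tolerance = 1e-12)
  expect_equal(both$ratio, 2, tolerance = 1e-12)
})

test_that("all-zero delta Ct gives ratio 1 and a missing reference errors", {
  ct <- tidyr::expand_grid(
    sample_id = paste0("s", 1:4),
    gene_id = c("t", "ref")
  )
  ct$condition <- ifelse(as.integer(sub("s", "", ct$sample_id)) <= 2,
    "control", "treated")
  ct$Ct <- 25
  res <- relative_expression(ct, references = "ref")
  expect_equal(res$ratio, 1)
  expect_equal(res$p_value, 1)

  broken <- ct[!(ct$sample_id == "s1" & ct$gene_id == "ref"), ]
  expect_error(relative_expression(broken, references = "ref"), "missing in sample")
})

test_that("serum volume normalization divides quantities by volume", {
  ct <- tidyr::expand_grid(
    sample_id = paste0("s", 1:6),
    gene_id = "t"
  )
  ct$condition <- ifelse(as.integer(sub("s", "", ct$sample_id)) <= 3,
    "control", "treated")
  # treated one cycle later = half the quantity
  ct$Ct <- ifelse(ct$condition == "treated", 26, 25)
  res <- relative_expression(ct, volumes = 0.1)
  expect_equal(res$ratio, 0.5, tolerance = 1e-12)
  expect_equal(res$normalizer, "serum volume")
  # doubling treated volumes halves the volume-normalized ratio again
  vols <- setNames(c(0.1, 0.1, 0.1, 0.2, 0.2, 0.2), paste0("s", 1:6))
  res2 <- relative_expression(ct, volumes = vols)
  expect_equal(res2$ratio, 0.25, tolerance = 1e-12)
})

test_that("group comparison matches the textbook Student t", {
  x <- c(12.1, 11.8, 12.5)
  y <- c(13.0, 13.4, 12.9)
  cmp <- compare_groups(x, y)
  oracle <- student_t_oracle(y, x)
  expect_equal(cmp$statistic, oracle$t, tolerance = 1e-12)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(cmp$df, 4)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("significance stars follow the 0.05/0.01/0.001 thresholds", {
  expect_equal(mirshift:::star_labels(c(0.2, 0.04, 0.008, 0.0005)),
    c("ns", "*", "**", "***"))
})

test_that("a designed two-fold effect is recovered within tolerance", {
  folds <- tibble::tibble(gene_id = "val", fold = 2)
  spec <- qpcr_sim_spec(ct_sd = 0.2, n_samples = 6)
  wells <- simulate_qpcr(folds, spec, seed = 7)
  stab <- reference_stability(dplyr::filter(wells, gene_type == "reference"))
  eff <- glance(fit_dilution_series(wells))
  res <- relative_expression(
    dplyr::filter(wells, gene_id %in% c("val", stab$best_pair)),
    references = stab$best_pair,
    efficiencies = setNames(eff$efficiency, eff$gene_id)
  )
  expect_gt(res$ratio, 1.6)
  expect_lt(res$ratio, 2.4)
})

test_that("qPCR plate tables round-trip through CSV", {
  wells <- simulate_qpcr(
    tibble::tibble(gene_id = "t", fold = 2),
    qpcr_sim_spec(n_samples = 2), seed = 5
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(wells, path)
  back <- read_qpcr(path)
  expect_equal(as.data.frame(back), as.data.frame(wells))
})
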