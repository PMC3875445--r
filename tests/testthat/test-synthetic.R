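test_that("catalog honours detectable totals and the affected partition", {
  cfg <- sim_config(seed = 1)
  catalog <- generate_catalog(cfg)

  expect_equal(sum(catalog$tumour_detectable), 615)
  expect_equal(sum(catalog$serum_detectable), 617)
  expect_true(all(catalog$length_nt >= 15 & catalog$length_nt <= 30))
  expect_false(any(duplicated(catalog$feature_id)))
  expect_true(all(catalog$tumour_effect > 0 & catalog$serum_effect > 0))

  t_aff <- catalog$feature_id[catalog$tumour_effect != 1]
  s_aff <- catalog$feature_id[catalog$serum_effect != 1]
  expect_length(t_aff, 116 + 7)
  expect_length(s_aff, 137 + 2)
  expect_length(intersect(t_aff, s_aff), 81)
  # direction split within each compartment
  expect_equal(sum(catalog$tumour_effect > 1), 116)
  expect_equal(sum(catalog$tumour_effect < 1), 7)
  expect_equal(sum(catalog$serum_effect < 1), 137)
  expect_equal(sum(catalog$serum_effect > 1), 2)
  # affected features only on detectable compartments
  expect_true(all(catalog$tumour_detectable[catalog$tumour_effect != 1]))
  expect_true(all(catalog$serum_detectable[catalog$serum_effect != 1]))
  # annotation semantics: neutral <=> both effects 1
  neutral <- catalog$annotation == "neutral"
  expect_true(all(catalog$tumour_effect[neutral] == 1 & catalog$serum_effect[neutral] == 1))
  expect_true(all(catalog$tumour_effect[!neutral] != 1 | catalog$serum_effect[!neutral] != 1))
})

test_that("all-zero effect configuration gives a fully neutral catalog", {
  cfg <- sim_config(
    seed = 3, n_tumour_up = 0, n_tumour_down = 0,
    n_serum_down = 0, n_serum_up = 0, n_common_affected = 0
  )
  catalog <- generate_catalog(cfg)
  expect_true(all(catalog$tumour_effect == 1))
  expect_true(all(catalog$serum_effect == 1))
  expect_true(all(catalog$annotation == "neutral"))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_tumour_up = 700), "exceed")
  expect_error(sim_config(n_common_affected = 200), "common")
  expect_error(sim_config(library_depths = c(L1 = 0, L2 = 1, L3 = 1, L4 = 1)), "positive")
  bad_fr <- default_composition_fractions()
  bad_fr[1, 1] <- bad_fr[1, 1] + 1e-3
  expect_error(sim_config(composition_fractions = bad_fr), "sum to 1")
})

test_that("simulation is bit-identical for a fixed seed and differs across seeds", {
  cfg <- small_sim_config(seed = 5)
  e1 <- simulate_counts(generate_catalog(cfg), cfg)
  e2 <- simulate_counts(generate_catalog(cfg), cfg)
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$compositions, e2$compositions)
  cfg2 <- small_sim_config(seed = 6)
  e3 <- simulate_counts(generate_catalog(cfg2), cfg2)
  expect_false(identical(e1$counts$L1, e3$counts$L1))
})

test_that("undetectable features get exactly zero counts", {
  cfg <- small_sim_config(seed = 2)
  expt <- simulate_counts(generate_catalog(cfg), cfg)
  no_serum <- !expt$catalog$serum_detectable
  expect_true(all(expt$counts$L3[no_serum] == 0))
  expect_true(all(expt$counts$L4[no_serum] == 0))
  no_tumour <- !expt$catalog$tumour_detectable
  expect_true(all(expt$counts$L1[no_tumour] == 0))
  expect_true(all(expt$counts$L2[no_tumour] == 0))
})

test_that("realized RPKM matches base abundance in the low-dispersion limit", {
  cfg <- sim_config(
    seed = 4, dispersion = 0,
    library_depths = c(L1 = 1e7, L2 = 1e7, L3 = 1e7, L4 = 1e7),
    n_tumour_up = 0, n_tumour_down = 0, n_serum_down = 0, n_serum_up = 0,
    n_common_affected = 0
  )
  catalog <- generate_catalog(cfg)
  expt <- simulate_counts(catalog, cfg)
  rpkm <- compute_rpkm(expt$counts, expt$library_totals)
  top <- which.max(catalog$base_abundance)
  expect_gt(catalog$base_abundance[top], 2000) # deep enough for a 5% LLN check
  expect_lt(abs(rpkm$L1[top] / catalog$base_abundance[top] - 1), 0.05)
})

test_that("class totals sum to the depth and track the configured fractions", {
  cfg <- small_sim_config(seed = 7)
  expt <- simulate_counts(generate_catalog(cfg), cfg)
  totals <- tapply(expt$compositions$count, expt$compositions$library, sum)
  expect_true(all(totals == round(cfg$library_depths[names(totals)])))
  # every class within 3 multinomial standard deviations
  for (i in seq_len(4)) {
    lib <- names(cfg$library_depths)[i]
    obs <- expt$compositions$count[expt$compositions$library == lib]
    pr <- cfg$composition_fractions[i, expt$compositions$class[expt$compositions$library == lib]]
    depth <- cfg$library_depths[i]
    sds <- sqrt(depth * pr * (1 - pr))
    expect_true(all(abs(obs - depth * pr) <= 3 * sds + 1))
  }
})

test_that("estimated fold changes recover the designed truth at counting noise", {
  cfg <- sim_config(seed = 8, dispersion = 0)
  expt <- simulate_counts(generate_catalog(cfg), cfg)
  dt <- differential_table(expt$counts, expt$library_totals, "L1", "L2", "tumour")
  joined <- dplyr::inner_join(dt, expt$truth, by = "feature_id")
  aff <- dplyr::filter(joined, .data$tumour_affected)
  est <- ifelse(aff$direction == "down", 1 / aff$fold_change, aff$fold_change)
  expect_lt(median(abs(log2(est) - log2(aff$tumour_fold))), 0.3)
})

test_that("simulated qPCR obeys its closed-form Ct model", {
  folds <- tibble::tibble(gene_id = c("gA", "gB"), fold = c(2, 0.5))
  wells <- simulate_qpcr(folds, noiseless_qpcr_spec(n_samples = 3), seed = 1)

  samp <- dplyr::filter(wells, .data$well_type == "sample")
  dct <- function(g) {
    w <- dplyr::filter(samp, .data$gene_id == g)
    mean(w$Ct[w$condition == "treated"]) - mean(w$Ct[w$condition == "control"])
  }
  expect_equal(dct("gA"), -1) # two-fold up = one cycle earlier at E = 1
  expect_equal(dct("gB"), 1)

  std <- dplyr::filter(wells, .data$well_type == "standard", .data$gene_id == "gA")
  std <- dplyr::arrange(std, dplyr::desc(.data$dilution))
  spacing <- diff(std$Ct) / diff(-log10(std$dilution))
  expect_equal(unname(spacing), rep(log2(10), 3), tolerance = 1e-12)
})

test_that("qPCR simulation rejects out-of-range efficiencies", {
  expect_error(qpcr_sim_spec(efficiencies = c(g = 1.5)), "0, 1.2")
  expect_error(qpcr_sim_spec(efficiencies = c(g = 0)), "0, 1.2")
})

test_that("the designed stable reference pair is recovered end-to-end", {
  folds <- tibble::tibble(gene_id = "t1", fold = 2)
  wells <- simulate_qpcr(folds, qpcr_sim_spec(), seed = 3)
  stab <- reference_stability(dplyr::filter(wells, .data$gene_type == "reference"))
  expect_setequal(stab$best_pair, c("hprt1", "rpl30"))
})

test_that("experiment tables round-trip through the TSV writers", {
  cfg <- small_sim_config(seed = 9, depth = 1e5)
  expt <- simulate_counts(generate_catalog(cfg), cfg)
  dir <- withr::local_tempdir()
  paths <- write_experiment(expt, dir)
  back <- read_count_table(paths[["counts"]])
  expect_equal(as.data.frame(back), as.data.frame(expt$counts))
  totals <- readr::read_tsv(paths[["library_totals"]], show_col_types = FALSE)
  expect_equal(setNames(totals$total_reads, totals$library), expt$library_totals)
})
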