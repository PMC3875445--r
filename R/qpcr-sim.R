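#' Noise specification for simulated stem-loop qPCR data
#'
#' Parameters of the Ct model used by [simulate_qpcr()]:
#' `Ct = intercept - log2(quantity) / log2(1 + E) + N(0, ct_sd)`.
#'
#' @param n_samples Biological samples per condition (default 6).
#' @param n_replicates Technical replicates per well (default 1).
#' @param ct_sd Per-well Gaussian Ct noise, cycles.
#' @param intercept Ct of one quantity unit at efficiency 1.
#' @param base_log2q_range Range of per-gene baseline log2 quantities.
#' @param efficiencies Named per-gene amplification efficiencies in `(0, 1.2]`;
#'   genes not listed default to `default_efficiency`.
#' @param default_efficiency Efficiency for unlisted genes (default 1, perfect
#'   doubling).
#' @param loading_sd SD of the shared per-sample loading factor (log2 scale);
#'   models RNA input differences that all genes of a sample share.
#' @param reference_genes Candidate reference genes (defaults to the common
#'   six-gene panel gapdh, ubc, rn18s, rpl30, hprt1, ywhaz).
#' @param stable_refs Subset of `reference_genes` simulated as stable
#'   (small gene-specific noise); the rest get `unstable_ref_sd`.
#' @param stable_ref_sd,unstable_ref_sd Gene-specific log2 noise SDs for the
#'   two reference tiers.
#' @param dilution_factors Serial dilution factors of the standard-curve
#'   wells (defaults 1e-2, 1e-3, 1e-4; an undiluted well is always included).
#' @param volume_ml Serum input volume per sample, ml (used by volume
#'   normalization).
#' @return A list of class `qpcr_sim_spec`.
#' @export
qpcr_sim_spec <- function(n_samples = 6L,
                          n_replicates = 1L,
                          ct_sd = 0.2,
                          intercept = 36,
                          base_log2q_range = c(8, 14),
                          efficiencies = numeric(),
                          default_efficiency = 1,
                          loading_sd = 0.3,
                          reference_genes = c("gapdh", "ubc", "rn18s", "rpl30", "hprt1", "ywhaz"),
                          stable_refs = c("hprt1", "rpl30"),
                          stable_ref_sd = 0.05,
                          unstable_ref_sd = 0.8,
                          dilution_factors = c(1e-2, 1e-3, 1e-4),
                          volume_ml = 0.1) {
  eff <- c(efficiencies, default = default_efficiency)
  if (any(eff <= 0) || any(eff > 1.2)) {
    abort("Amplification efficiencies must lie in (0, 1.2].")
  }
  if (!all(stable_refs %in% reference_genes)) {
    abort("`stable_refs` must be a subset of `reference_genes`.")
  }
  if (any(dilution_factors <= 0) || any(dilution_factors > 1)) {
    abort("`dilution_factors` must lie in (0, 1].")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_replicates = as.integer(n_replicates),
      ct_sd = ct_sd,
      intercept = intercept,
      base_log2q_range = base_log2q_range,
      efficiencies = efficiencies,
      default_efficiency = default_efficiency,
      loading_sd = loading_sd,
      reference_genes = reference_genes,
      stable_refs = stable_refs,
      stable_ref_sd = stable_ref_sd,
      unstable_ref_sd = unstable_ref_sd,
      dilution_factors = dilution_factors,
      volume_ml = volume_ml
    ),
    class = "qpcr_sim_spec"
  )
}

gene_efficiency <- function(gene, spec) {
  e <- spec$efficiencies[gene]
  ifelse(is.na(e), spec$default_efficiency, e)
}

#' Simulate a stem-loop RT-qPCR validation dataset
#'
#' Generates Ct values for target miRNAs under a treated-versus-control
#' contrast, six candidate reference genes of which two are simulated stable,
#' and serial-dilution standard-curve wells per gene. The Ct model is
#' `Ct = intercept - log2(q) / log2(1 + E) + noise` with
#' `log2(q) = base + treated * log2(fold) + loading + tier noise`, so with
#' `E = 1` and zero noise a two-fold expression difference is exactly one Ct
#' cycle.
#'
#' @param fold_changes Tibble with columns `gene_id`, `fold`
#'   (treated/control quantity ratio) and optionally `compartment`
#'   (`cells` or `serum`; default `cells`).
#' @param spec A [qpcr_sim_spec()].
#' @param seed Integer seed (the qPCR stage stream is derived from it).
#' @return A tibble of wells: `sample_id`, `condition`, `compartment`,
#'   `gene_id`, `gene_type`, `well_type`, `dilution`, `replicate`, `Ct`,
#'   `volume_ml`.
#' @export
#' @examples
#' wells <- simulate_qpcr(
#'   tibble::tibble(gene_id = "miR-21", fold = 2),
#'   qpcr_sim_spec(ct_sd = 0), seed = 1
#' )
#' dplyr::count(wells, gene_id, condition)
simulate_qpcr <- function(fold_changes, spec = qpcr_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "qpcr_sim_spec"))
  if (!all(c("gene_id", "fold") %in% names(fold_changes))) {
    abort("`fold_changes` must have columns `gene_id` and `fold`.")
  }
  if (any(fold_changes$fold <= 0)) abort("Fold changes must be positive.")
  if (!"compartment" %in% names(fold_changes)) fold_changes$compartment <- "cells"
  set.seed(stage_seed(seed, "qpcr"))

  genes <- c(fold_changes$gene_id, spec$reference_genes)
  base_log2q <- setNames(
    runif(length(genes), spec$base_log2q_range[1], spec$base_log2q_range[2]),
    genes
  )
  gene_compartment <- setNames(
    c(fold_changes$compartment, rep("cells", length(spec$reference_genes))),
    genes
  )
  fold <- setNames(
    c(fold_changes$fold, rep(1, length(spec$reference_genes))),
    genes
  )
  ref_sd <- setNames(
    ifelse(spec$reference_genes %in% spec$stable_refs,
      spec$stable_ref_sd, spec$unstable_ref_sd
    ),
    spec$reference_genes
  )

  samples <- tibble(
    sample_id = c(
      sprintf("ctrl_%02d", seq_len(spec$n_samples)),
      sprintf("trt_%02d", seq_len(spec$n_samples))
    ),
    condition = rep(c("control", "treated"), each = spec$n_samples),
    loading = rnorm(2 * spec$n_samples, 0, spec$loading_sd)
  )

  wells <- tidyr::expand_grid(
    samples,
    gene_id = genes,
    replicate = seq_len(spec$n_replicates)
  )
  wells <- dplyr::mutate(wells,
    gene_type = ifelse(.data$gene_id %in% spec$reference_genes, "reference", "target"),
    compartment = gene_compartment[.data$gene_id],
    dilution = 1,
    well_type = "sample",
    tier_noise = rnorm(
      dplyr::n(), 0,
      ifelse(.data$gene_type == "reference", ref_sd[.data$gene_id], 0)
    ),
    log2q = base_log2q[.data$gene_id] +
      (.data$condition == "treated") * log2(fold[.data$gene_id]) +
      .data$loading + .data$tier_noise,
    efficiency = gene_efficiency(.data$gene_id, spec),
    Ct = spec$intercept - .data$log2q / log2(1 + .data$efficiency) +
      rnorm(dplyr::n(), 0, spec$ct_sd)
  )

  standards <- tidyr::expand_grid(
    gene_id = genes,
    dilution = c(1, spec$dilution_factors)
  )
  standards <- dplyr::mutate(standards,
    sample_id = "std",
    condition = "control",
    compartment = gene_compartment[.data$gene_id],
    gene_type = ifelse(.data$gene_id %in% spec$reference_genes, "reference", "target"),
    well_type = "standard",
    replicate = 1L,
    efficiency = gene_efficiency(.data$gene_id, spec),
    Ct = spec$intercept -
      (base_log2q[.data$gene_id] + log2(.data$dilution)) / log2(1 + .data$efficiency) +
      rnorm(dplyr::n(), 0, spec$ct_sd)
  )

  out <- dplyr::bind_rows(
    dplyr::select(
      wells, "sample_id", "condition", "compartment", "gene_id",
      "gene_type", "well_type", "dilution", "replicate", "Ct"
    ),
    dplyr::select(
      standards, "sample_id", "condition", "compartment", "gene_id",
      "gene_type", "well_type", "dilution", "replicate", "Ct"
    )
  )
  dplyr::mutate(out, volume_ml = spec$volume_ml)
}
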