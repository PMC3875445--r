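#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Unknown
#' keys are rejected. Configurations can also be read from YAML with
#' [read_pipeline_config()].
#'
#' @param seed Master seed for all stage streams.
#' @param stages Character vector of stages to run, a subset of
#'   `simulate`, `quantify`, `differential`, `select`, `cluster`, `qpcr`.
#' @param sim Named list of [sim_config()] overrides (the seed is supplied
#'   automatically).
#' @param alpha,min_fold,pseudocount,low_count Differential-stage parameters
#'   (see [differential_table()]).
#' @param top_n,ts_tf_max,min_tf,top_by Selection-stage parameters (see
#'   [prioritize_candidates()]).
#' @param qpcr_spec Named list of [qpcr_sim_spec()] overrides for the
#'   simulated validation arm.
#' @param n_validation Number of top-ranked selected candidates carried into
#'   the qPCR stage (default 9).
#' @param paths Named list of input paths (`counts`, `library_totals`,
#'   `compositions`, `qpcr`) used when the `simulate` stage is off.
#' @param outdir Default output directory for [run_pipeline()] (optional).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c(
                              "simulate", "quantify", "differential",
                              "select", "cluster", "qpcr"
                            ),
                            sim = list(),
                            alpha = 0.05, min_fold = 1.5, pseudocount = 0.5,
                            low_count = 10,
                            top_n = 100, ts_tf_max = 20, min_tf = 4,
                            top_by = "L1",
                            qpcr_spec = list(),
                            n_validation = 9L,
                            paths = list(),
                            outdir = NULL) {
  known <- c(
    "simulate", "quantify", "differential", "select", "cluster", "qpcr"
  )
  if (length(stages) > 0 && !all(stages %in% known)) {
    abort(sprintf("Unknown stage(s): %s.",
      paste(setdiff(stages, known), collapse = ", ")))
  }
  structure(
    list(
      seed = as.integer(seed), stages = stages, sim = sim,
      alpha = alpha, min_fold = min_fold, pseudocount = pseudocount,
      low_count = low_count, top_n = top_n, ts_tf_max = ts_tf_max,
      min_tf = min_tf, top_by = top_by, qpcr_spec = qpcr_spec,
      n_validation = as.integer(n_validation), paths = paths, outdir = outdir
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file with keys matching the arguments of
#'   [pipeline_config()]; unknown keys raise an error.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "...")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s.", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, quantify, differential,
#' select, cluster, qpcr — and returns a machine-readable report with the
#' summary numbers of every stage (class percentages, affected counts, the
#' overlap partition, selected candidates, qPCR efficiencies and ratios).
#' With an output directory, every stage table is written as TSV/CSV, the
#' dendrograms as Newick, the report as JSON and the resolved configuration
#' as YAML, with stable column order. Reports are byte-identical across
#' reruns with the same seed and configuration.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (overrides `config$outdir`; optional —
#'   without one, nothing is written).
#' @return The report, an object of class `pipeline_report` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config(
#'   seed = 1,
#'   stages = c("simulate", "quantify", "differential"),
#'   sim = list(library_depths = c(L1 = 1e6, L2 = 1e6, L3 = 1e6, L4 = 1e6))
#' )
#' report <- run_pipeline(cfg)
#' report$differential$tumour_affected
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- outdir %||% config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  on_stage <- function(s) s %in% config$stages
  report <- list(seed = config$seed, stages = config$stages)
  artifacts <- list()

  expt <- NULL
  if (on_stage("simulate")) {
    sim_cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    catalog <- generate_catalog(sim_cfg)
    expt <- simulate_counts(catalog, sim_cfg)
    report$simulate <- list(
      n_features = nrow(catalog),
      tumour_detectable = sum(catalog$tumour_detectable),
      serum_detectable = sum(catalog$serum_detectable),
      tumour_affected_true = sum(expt$truth$tumour_affected),
      serum_affected_true = sum(expt$truth$serum_affected)
    )
  } else if (length(config$paths) > 0) {
    counts <- read_count_table(config$paths$counts)
    totals_df <- readr::read_tsv(config$paths$library_totals, show_col_types = FALSE)
    expt <- list(
      counts = counts,
      library_totals = setNames(totals_df$total_reads, totals_df$library),
      compositions = if (!is.null(config$paths$compositions)) {
        readr::read_tsv(config$paths$compositions, show_col_types = FALSE)
      }
    )
  }

  rpkm <- NULL
  if (on_stage("quantify")) {
    if (is.null(expt)) abort("Stage `quantify` failed: no counts (enable `simulate` or give paths).")
    rpkm <- compute_rpkm(expt$counts, expt$library_totals)
    artifacts$rpkm <- rpkm
    if (!is.null(expt$compositions)) {
      comp <- summarize_composition(expt$compositions)
      artifacts$composition <- comp
      report$quantify <- list(composition = as.data.frame(
        comp[c("library", "class", "percent")]
      ))
    }
  }

  diff_tables <- NULL
  if (on_stage("differential")) {
    if (is.null(expt)) abort("Stage `differential` failed: no counts available.")
    diff_t <- differential_table(expt$counts, expt$library_totals, "L1", "L2",
      "tumour",
      alpha = config$alpha, min_fold = config$min_fold,
      pseudocount = config$pseudocount, low_count = config$low_count
    )
    diff_s <- differential_table(expt$counts, expt$library_totals, "L3", "L4",
      "serum",
      alpha = config$alpha, min_fold = config$min_fold,
      pseudocount = config$pseudocount, low_count = config$low_count
    )
    part <- overlap_partition(
      diff_t$feature_id[diff_t$affected],
      diff_s$feature_id[diff_s$affected]
    )
    diff_tables <- list(tumour = diff_t, serum = diff_s, partition = part)
    artifacts$differential_tumour <- diff_t
    artifacts$differential_serum <- diff_s
    artifacts$overlap <- part
    report$differential <- list(
      tumour_affected = sum(diff_t$affected),
      tumour_up = sum(diff_t$affected & diff_t$direction == "up"),
      tumour_down = sum(diff_t$affected & diff_t$direction == "down"),
      serum_affected = sum(diff_s$affected),
      serum_up = sum(diff_s$affected & diff_s$direction == "up"),
      serum_down = sum(diff_s$affected & diff_s$direction == "down"),
      common = sum(part$partition == "common"),
      tumour_only = sum(part$partition == "tumour_only"),
      serum_only = sum(part$partition == "serum_only")
    )
  }

  candidates <- NULL
  if (on_stage("select")) {
    if (is.null(rpkm)) abort("Stage `select` failed: no RPKM (enable `quantify`).")
    candidates <- prioritize_candidates(rpkm,
      top_n = config$top_n, ts_tf_max = config$ts_tf_max,
      min_tf = config$min_tf, top_by = config$top_by
    )
    artifacts$candidates <- candidates
    report$select <- list(
      n_ranked = nrow(candidates),
      n_selected = sum(candidates$selected),
      selected = candidates$feature_id[candidates$selected],
      annotated_selected = candidates$feature_id[
        candidates$selected & candidates$annotation != "unknown"
      ]
    )
  }

  if (on_stage("cluster")) {
    if (is.null(rpkm)) abort("Stage `cluster` failed: no RPKM (enable `quantify`).")
    subset <- if (!is.null(diff_tables)) {
      dplyr::filter(rpkm, .data$feature_id %in% diff_tables$partition$feature_id)
    } else {
      rpkm
    }
    if (nrow(subset) >= 2) {
      clust <- cluster_profiles(subset)
      artifacts$clustering <- clust
      report$cluster <- list(
        n_features = nrow(subset),
        library_leaf_order = clust$library_dendrogram$labels[
          clust$library_dendrogram$order
        ],
        max_merge_height = max(clust$feature_dendrogram$height)
      )
    }
  }

  if (on_stage("qpcr")) {
    if (is.null(expt) || is.null(expt$truth)) {
      abort("Stage `qpcr` failed: needs the simulated truth (enable `simulate`).")
    }
    targets <- if (!is.null(candidates) && any(candidates$selected)) {
      head(candidates$feature_id[candidates$selected], config$n_validation)
    } else {
      head(expt$truth$feature_id[expt$truth$tumour_affected], config$n_validation)
    }
    truth_folds <- dplyr::filter(expt$truth, .data$feature_id %in% targets)
    folds <- tibble(
      gene_id = truth_folds$feature_id,
      fold = truth_folds$tumour_fold,
      compartment = "cells"
    )
    spec <- do.call(qpcr_sim_spec, config$qpcr_spec)
    wells <- simulate_qpcr(folds, spec, seed = config$seed)
    artifacts$qpcr_wells <- wells
    fits <- glance(fit_dilution_series(wells))
    stab <- reference_stability(
      dplyr::filter(wells, .data$gene_type == "reference")
    )
    eff <- setNames(fits$efficiency, fits$gene_id)
    rel <- relative_expression(
      dplyr::filter(
        wells,
        .data$gene_id %in% c(folds$gene_id, stab$best_pair)
      ),
      references = stab$best_pair, efficiencies = eff
    )
    artifacts$qpcr_results <- rel
    report$qpcr <- list(
      reference_pair = stab$best_pair,
      mean_efficiency = mean(fits$efficiency, na.rm = TRUE),
      ratios = as.data.frame(rel[c("gene_id", "ratio", "p_value", "stars")])
    )
  }

  report <- structure(report, class = "pipeline_report")
  if (!is.null(outdir)) {
    write_pipeline_outputs(report, artifacts, config, outdir)
  }
  report
}

write_pipeline_outputs <- function(report, artifacts, config, outdir) {
  tsv <- function(x, name) readr::write_tsv(x, file.path(outdir, name))
  if (!is.null(artifacts$rpkm)) tsv(artifacts$rpkm, "rpkm.tsv")
  if (!is.null(artifacts$composition)) tsv(artifacts$composition, "composition.tsv")
  if (!is.null(artifacts$differential_tumour)) {
    tsv(artifacts$differential_tumour, "differential_tumour.tsv")
    tsv(artifacts$differential_serum, "differential_serum.tsv")
    tsv(artifacts$overlap, "overlap_partition.tsv")
  }
  if (!is.null(artifacts$candidates)) tsv(artifacts$candidates, "candidates.tsv")
  if (!is.null(artifacts$clustering)) {
    write_dendrogram_newick(
      artifacts$clustering$feature_dendrogram,
      file.path(outdir, "feature_dendrogram.nwk")
    )
    write_dendrogram_newick(
      artifacts$clustering$library_dendrogram,
      file.path(outdir, "library_dendrogram.nwk")
    )
  }
  if (!is.null(artifacts$qpcr_wells)) {
    readr::write_csv(artifacts$qpcr_wells, file.path(outdir, "qpcr_wells.csv"))
    tsv(artifacts$qpcr_results, "qpcr_results.tsv")
  }
  jsonlite::write_json(
    unclass(report), file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE
  )
  resolved <- config
  resolved$sim <- lapply(config$sim, identity)
  yaml::write_yaml(
    lapply(unclass(resolved), function(x) if (is.matrix(x)) as.data.frame(x) else x),
    file.path(outdir, "config_resolved.yaml")
  )
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>  seed", x$seed, "\n")
  cat("  stages:", paste(x$stages, collapse = " > "), "\n")
  if (!is.null(x$differential)) {
    cat(
      "  affected: tumour", x$differential$tumour_affected,
      sprintf("(%d up / %d down)", x$differential$tumour_up, x$differential$tumour_down),
      "| serum", x$differential$serum_affected,
      sprintf("(%d up / %d down)", x$differential$serum_up, x$differential$serum_down), "\n"
    )
    cat(
      "  overlap: common", x$differential$common,
      "tumour-only", x$differential$tumour_only,
      "serum-only", x$differential$serum_only, "\n"
    )
  }
  if (!is.null(x$select)) {
    cat("  selected candidates:", x$select$n_selected, "\n")
  }
  if (!is.null(x$qpcr)) {
    cat("  qPCR reference pair:", paste(x$qpcr$reference_pair, collapse = ", "), "\n")
  }
  invisible(x)
}
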