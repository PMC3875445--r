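#' Generate a synthetic miRNA catalog
#'
#' Draws the simulation ground truth: one row per miRNA with its mature
#' length, base abundance (expected RPKM in the control tumour library),
#' compartment detectability flags, treated-compartment effect multipliers and
#' an effect annotation. The affected sets are constructed so that the
#' common / tumour-only / serum-only partition matches the configured counts
#' exactly (defaults 81/42/58), with affected features sampled
#' abundance-weighted (see [sim_config()]). Deterministic for a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `feature_id`, `length_nt`, `base_abundance`,
#'   `tumour_detectable`, `serum_detectable`, `tumour_effect`, `serum_effect`,
#'   `annotation` (`oncomir`/`suppressor` for affected features, `neutral`
#'   otherwise; neutral features have both effects equal to 1).
#' @export
#' @examples
#' catalog <- generate_catalog(sim_config(seed = 1))
#' sum(catalog$tumour_detectable)
#' sum(catalog$tumour_effect > 1)
generate_catalog <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "catalog"))

  n_both <- config$n_shared_detectable
  n_t_only <- config$n_tumour_detectable - n_both
  n_s_only <- config$n_serum_detectable - n_both
  n <- n_both + n_t_only + n_s_only

  feature_id <- sprintf("mir-%04d", seq_len(n))
  length_nt <- sample(19:24, n,
    replace = TRUE,
    prob = c(0.05, 0.10, 0.25, 0.35, 0.15, 0.10)
  )
  base_abundance <- rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  tumour_detectable <- rep(c(TRUE, TRUE, FALSE), c(n_both, n_t_only, n_s_only))
  serum_detectable <- rep(c(TRUE, FALSE, TRUE), c(n_both, n_t_only, n_s_only))

  w <- base_abundance^config$affected_weight_power
  draw <- function(pool, k) {
    if (k == 0L) return(integer())
    if (length(pool) < k) {
      abort("Not enough detectable features to place the configured affected counts.")
    }
    if (k == length(pool)) return(pool)
    pool[sample.int(length(pool), k, prob = w[pool])]
  }

  n_t_aff <- config$n_tumour_up + config$n_tumour_down
  n_s_aff <- config$n_serum_down + config$n_serum_up
  # The serum-only set is drawn before the tumour-only set: serum drops
  # (2-6x) need far more coverage to be callable than tumour boosts (2-10x),
  # so serum claims the abundant pool first.
  common <- draw(which(tumour_detectable & serum_detectable), config$n_common_affected)
  s_extra <- draw(
    setdiff(which(serum_detectable), common),
    n_s_aff - config$n_common_affected
  )
  t_extra <- draw(
    setdiff(which(tumour_detectable), c(common, s_extra)),
    n_t_aff - config$n_common_affected
  )
  t_aff <- c(common, t_extra)
  s_aff <- c(common, s_extra)

  pick <- function(pool, k) if (k == 0L) integer() else pool[sample.int(length(pool), k)]
  t_down <- pick(t_aff, config$n_tumour_down)
  s_up <- pick(s_aff, config$n_serum_up)

  # Fold magnitudes are coupled to abundance by rank: the smallest folds go
  # to the most abundant features. An affected list is the output of a
  # detectability-filtered call, so modest changes only occur on miRNAs
  # covered well enough for the change to be callable.
  rank_coupled_effects <- function(idx, range) {
    mags <- sort(runif(length(idx), range[1], range[2]))
    out <- numeric(length(idx))
    out[order(-base_abundance[idx], idx)] <- mags
    out
  }
  tumour_effect <- rep(1, n)
  t_up <- setdiff(t_aff, t_down)
  tumour_effect[t_up] <- rank_coupled_effects(t_up, config$tumour_up_range)
  tumour_effect[t_down] <- 1 / rank_coupled_effects(t_down, config$tumour_down_range)
  serum_effect <- rep(1, n)
  s_down <- setdiff(s_aff, s_up)
  serum_effect[s_down] <- 1 / rank_coupled_effects(s_down, config$serum_down_range)
  serum_effect[s_up] <- rank_coupled_effects(s_up, config$serum_up_range)

  affected <- union(t_aff, s_aff)
  annotation <- rep("neutral", n)
  annotation[affected] <- sample(c("oncomir", "suppressor"), length(affected), replace = TRUE)

  tibble(
    feature_id = feature_id,
    length_nt = length_nt,
    base_abundance = base_abundance,
    tumour_detectable = tumour_detectable,
    serum_detectable = serum_detectable,
    tumour_effect = tumour_effect,
    serum_effect = serum_effect,
    annotation = annotation
  )
}

#' Simulate a four-library sequencing experiment from a catalog
#'
#' Draws per-feature read counts for the four libraries and per-library
#' read-class totals. Counts are negative-binomial with mean
#' `base_abundance * effect * (length_nt/1000) * depth/1e6`, so the expected
#' RPKM of a feature equals `base_abundance * effect`; effects apply in the
#' treated libraries only (`L2` for tumour, `L4` for serum) and features not
#' detectable in a compartment get exactly zero counts there. Class totals are
#' a multinomial draw of the library depth over the configured composition
#' fractions.
#'
#' @param catalog Output of [generate_catalog()].
#' @param config The [sim_config()] used to generate the catalog.
#' @return An object of class `synthetic_experiment`: a list with
#'   * `counts`: tibble `feature_id`, `length_nt`, then one count column per library;
#'   * `library_totals`: named vector of total reads per library;
#'   * `compositions`: long tibble (`library`, `class`, `count`);
#'   * `truth`: tibble of per-feature true fold changes and affected flags;
#'   * `catalog`, `config`: the inputs.
#' @export
#' @examples
#' cfg <- sim_config(seed = 2, library_depths = c(L1 = 1e6, L2 = 1e6, L3 = 1e6, L4 = 1e6))
#' expt <- simulate_counts(generate_catalog(cfg), cfg)
#' head(expt$counts)
simulate_counts <- function(catalog, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  required <- c(
    "feature_id", "length_nt", "base_abundance",
    "tumour_detectable", "serum_detectable", "tumour_effect", "serum_effect"
  )
  if (!all(required %in% names(catalog))) {
    abort("`catalog` is missing required columns; see generate_catalog().")
  }
  if (any(config$library_depths <= 0)) abort("Library depths must be positive.")
  set.seed(stage_seed(config$seed, "counts"))

  depths <- config$library_depths
  libs <- names(depths)
  compartment <- c("tumour", "tumour", "serum", "serum")
  treated <- c(FALSE, TRUE, FALSE, TRUE)

  n <- nrow(catalog)
  counts <- tibble(feature_id = catalog$feature_id, length_nt = catalog$length_nt)
  for (i in seq_along(libs)) {
    detect <- if (compartment[i] == "tumour") catalog$tumour_detectable else catalog$serum_detectable
    effect <- if (!treated[i]) {
      rep(1, n)
    } else if (compartment[i] == "tumour") {
      catalog$tumour_effect
    } else {
      catalog$serum_effect
    }
    mu <- catalog$base_abundance * effect * (catalog$length_nt / 1000) *
      (depths[i] / 1e6) * as.numeric(detect)
    counts[[libs[i]]] <- if (config$dispersion > 0) {
      ifelse(mu == 0, 0L, rnbinom(n, mu = mu, size = 1 / config$dispersion))
    } else {
      rpois(n, mu)
    }
  }

  compositions <- purrr::map_dfr(seq_along(libs), function(i) {
    cls <- rmultinom(1, size = round(depths[i]), prob = config$composition_fractions[i, ])[, 1]
    tibble(library = libs[i], class = read_classes(), count = cls)
  })

  truth <- tibble(
    feature_id = catalog$feature_id,
    tumour_fold = catalog$tumour_effect,
    serum_fold = catalog$serum_effect,
    tumour_affected = catalog$tumour_effect != 1,
    serum_affected = catalog$serum_effect != 1,
    tumour_direction = dplyr::case_when(
      catalog$tumour_effect > 1 ~ "up",
      catalog$tumour_effect < 1 ~ "down",
      TRUE ~ "unchanged"
    ),
    serum_direction = dplyr::case_when(
      catalog$serum_effect > 1 ~ "up",
      catalog$serum_effect < 1 ~ "down",
      TRUE ~ "unchanged"
    )
  )

  structure(
    list(
      counts = counts,
      library_totals = depths,
      compositions = compositions,
      truth = truth,
      catalog = catalog,
      config = config
    ),
    class = "synthetic_experiment"
  )
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment>\n")
  cat(" ", nrow(x$counts), "features x", length(x$library_totals), "libraries\n")
  cat("  depths:", paste(sprintf("%s=%.3g", names(x$library_totals), x$library_totals),
    collapse = " "
  ), "\n")
  cat(
    "  affected: tumour", sum(x$truth$tumour_affected),
    "serum", sum(x$truth$serum_affected), "\n"
  )
  invisible(x)
}

#' Write a synthetic experiment to plain-text tables
#'
#' Writes the count matrix, library totals, read-class compositions, catalog
#' and truth table as TSV files into `dir` (UTF-8, header row, stable column
#' order), matching the dialect read back by [read_count_table()].
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    library_totals = file.path(dir, "library_totals.tsv"),
    compositions = file.path(dir, "compositions.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(experiment$counts, paths["counts"])
  readr::write_tsv(
    tibble(
      library = names(experiment$library_totals),
      total_reads = unname(experiment$library_totals)
    ),
    paths["library_totals"]
  )
  readr::write_tsv(experiment$compositions, paths["compositions"])
  readr::write_tsv(experiment$catalog, paths["catalog"])
  readr::write_tsv(experiment$truth, paths["truth"])
  invisible(paths)
}

#' Read a count matrix TSV
#'
#' Reads the tab-separated count-matrix dialect written by
#' [write_experiment()]: columns `feature_id`, `length_nt`, then one integer
#' column per library.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_count_table <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("feature_id", "length_nt") %in% names(counts))) {
    abort("Count table must have `feature_id` and `length_nt` columns.")
  }
  counts
}
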