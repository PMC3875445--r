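#' Fit qPCR standard curves from serial dilutions
#'
#' For each gene, regresses Ct on log10(dilution) over the standard-curve
#' wells and derives the amplification efficiency
#' `E = 10^(-1/slope) - 1`; a slope of `-log2(10) ~ -3.3219` cycles per
#' decade corresponds to perfect doubling (`E = 1`). Fits with a positive
#' slope are flagged invalid.
#'
#' @param wells Tibble of standard-curve wells with columns `gene_id`,
#'   `dilution` (positive, <= 1) and `Ct`. Rows with `well_type` other than
#'   `"standard"` are dropped if that column is present.
#' @return An object of class `dilution_fits`: use [tidy()] for per-gene
#'   coefficients, [glance()] for the per-gene slope / efficiency / r-squared
#'   summary, [autoplot()] for the standard curves.
#' @export
#' @examples
#' wells <- tibble::tibble(
#'   gene_id = "g", dilution = c(1, 1e-2, 1e-3, 1e-4),
#'   Ct = 20 - log2(dilution)
#' )
#' glance(fit_dilution_series(wells))
fit_dilution_series <- function(wells) {
  if (!all(c("gene_id", "dilution", "Ct") %in% names(wells))) {
    abort("`wells` must have columns `gene_id`, `dilution`, `Ct`.")
  }
  if ("well_type" %in% names(wells)) {
    wells <- dplyr::filter(wells, .data$well_type == "standard")
  }
  if (any(wells$dilution <= 0)) abort("Dilutions must be positive.")

  fits <- lapply(split(wells, wells$gene_id), function(w) {
    if (length(unique(w$dilution)) < 3) {
      abort(sprintf(
        "Gene %s has %d distinct dilution(s); at least 3 are required.",
        w$gene_id[1], length(unique(w$dilution))
      ))
    }
    fit <- lm(Ct ~ log10(dilution), data = w)
    slope <- unname(coef(fit)[2])
    list(
      gene_id = w$gene_id[1],
      model = fit,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      efficiency = if (slope < 0) 10^(-1 / slope) - 1 else NA_real_,
      # noiseless standards fit exactly; silence the perfect-fit note
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n_dilutions = length(unique(w$dilution)),
      valid = slope < 0
    )
  })
  structure(list(fits = fits), class = "dilution_fits")
}

#' @export
print.dilution_fits <- function(x, ...) {
  cat("<dilution_fits>", length(x$fits), "gene(s)\n")
  print(glance(x))
  invisible(x)
}

#' @rdname fit_dilution_series
#' @param x A `dilution_fits` object.
#' @param ... Unused.
#' @export
tidy.dilution_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    s <- summary(f$model)$coefficients
    tibble(
      gene_id = f$gene_id,
      term = rownames(s),
      estimate = s[, "Estimate"],
      std.error = s[, "Std. Error"]
    )
  })
}

#' @rdname fit_dilution_series
#' @export
glance.dilution_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble(
      gene_id = f$gene_id,
      slope = f$slope,
      intercept = f$intercept,
      efficiency = f$efficiency,
      r_squared = f$r_squared,
      n_dilutions = f$n_dilutions,
      valid = f$valid
    )
  })
}

# Per-well log2 relative quantity under efficiency correction:
# q = (1+E)^(-Ct), log2 q = -Ct * log2(1+E); with E = 1 this is -Ct.
log2_quantity <- function(ct, efficiency) {
  -ct * log2(1 + efficiency)
}

lookup_efficiency <- function(genes, efficiencies) {
  if (is.null(efficiencies)) return(rep(1, length(genes)))
  e <- efficiencies[genes]
  out <- ifelse(is.na(e), 1, e)
  if (any(out <= 0 | out > 1.2)) abort("Efficiencies must lie in (0, 1.2].")
  unname(out)
}

#' Reference-gene stability by the geNorm M-value
#'
#' Computes, for every candidate reference gene, the geNorm stability
#' measure: the arithmetic mean, over all other candidates, of the standard
#' deviation across samples of the pairwise log2 expression ratios. Stable
#' genes (small M) covary with the rest of the panel; the two genes with
#' minimal M are the recommended reference pair. Single-pass M by default;
#' `iterate = TRUE` repeatedly drops the least stable gene (geNorm's stepwise
#' exclusion) and records the exclusion order.
#'
#' @param ct_table Tibble with `sample_id`, `gene_id`, `Ct` (technical
#'   replicates are averaged per sample/gene first). Standard-curve wells are
#'   dropped if a `well_type` column is present.
#' @param efficiencies Optional named per-gene efficiencies; default 1 for
#'   all (classic 2^-Ct quantities).
#' @param iterate Use stepwise exclusion instead of single-pass M.
#' @return An object of class `stability_ranking` wrapping a tibble
#'   `gene_id`, `m_value`, `rank` (ascending in M); `tidy()` returns it,
#'   `glance()` a one-row summary, and `$best_pair` holds the two minimal-M
#'   genes.
#' @export
reference_stability <- function(ct_table, efficiencies = NULL, iterate = FALSE) {
  if (!all(c("sample_id", "gene_id", "Ct") %in% names(ct_table))) {
    abort("`ct_table` must have columns `sample_id`, `gene_id`, `Ct`.")
  }
  if ("well_type" %in% names(ct_table)) {
    ct_table <- dplyr::filter(ct_table, .data$well_type != "standard")
  }
  ct_table <- dplyr::summarise(
    dplyr::group_by(ct_table, .data$sample_id, .data$gene_id),
    Ct = mean(.data$Ct), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(ct_table,
    names_from = "gene_id", values_from = "Ct")
  genes <- setdiff(names(wide), "sample_id")
  if (length(genes) < 3) {
    if (length(genes) < 2) abort("Need at least 2 candidate genes.")
    warn("Only two candidate genes: M-values are pairwise-degenerate (equal).")
  }
  if (nrow(wide) < 2) abort("Need Ct values for at least 2 samples.")
  if (anyNA(wide[genes])) abort("Missing Ct values; complete the table or impute first.")

  eff <- lookup_efficiency(genes, efficiencies)
  logq <- as.matrix(wide[genes])
  for (g in seq_along(genes)) logq[, g] <- log2_quantity(logq[, g], eff[g])

  m_of <- function(mat) {
    k <- ncol(mat)
    vapply(seq_len(k), function(j) {
      mean(vapply(setdiff(seq_len(k), j), function(l) sd(mat[, j] - mat[, l]),
        numeric(1)))
    }, numeric(1))
  }

  exclusion_order <- character()
  if (iterate) {
    remaining <- logq
    while (ncol(remaining) > 2) {
      m <- m_of(remaining)
      worst <- which.max(m)
      exclusion_order <- c(exclusion_order, colnames(remaining)[worst])
      remaining <- remaining[, -worst, drop = FALSE]
    }
  }

  m <- m_of(logq)
  ranking <- dplyr::arrange(
    tibble(gene_id = genes, m_value = m),
    .data$m_value, .data$gene_id
  )
  ranking$rank <- seq_len(nrow(ranking))
  best_pair <- if (iterate && length(exclusion_order) > 0) {
    setdiff(genes, exclusion_order)
  } else {
    ranking$gene_id[1:2]
  }
  structure(
    list(
      ranking = ranking,
      best_pair = best_pair,
      exclusion_order = exclusion_order,
      n_samples = nrow(wide)
    ),
    class = "stability_ranking"
  )
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("<stability_ranking>  best pair:", paste(x$best_pair, collapse = ", "), "\n")
  print(x$ranking)
  invisible(x)
}

#' @rdname reference_stability
#' @param x A `stability_ranking` object.
#' @param ... Unused.
#' @export
tidy.stability_ranking <- function(x, ...) x$ranking

#' @rdname reference_stability
#' @export
glance.stability_ranking <- function(x, ...) {
  tibble(
    n_genes = nrow(x$ranking),
    n_samples = x$n_samples,
    best_pair = paste(x$best_pair, collapse = "+"),
    min_m = min(x$ranking$m_value)
  )
}

#' Normalized relative expression with group comparison
#'
#' Computes, per target gene, the treated/control expression ratio from Ct
#' values. Quantities are efficiency-corrected
#' (`log2 q = -Ct * log2(1 + E)`, reducing to the classic `2^-Ct` at
#' `E = 1`); normalization subtracts, per sample, either the mean log2
#' quantity of the reference genes (geometric-mean normalization) or
#' `log2(volume)` for volume-normalized serum measurements. The group ratio
#' is the back-transformed difference of mean log2 normalized quantities,
#' with an unpaired two-tailed t-test (see [compare_groups()]).
#'
#' @param ct_table Tibble with `sample_id`, `condition`
#'   (`control`/`treated`), `gene_id`, `Ct`; technical replicates averaged
#'   per well group. Standard wells (`well_type == "standard"`) are dropped.
#' @param references Character vector of reference gene ids (reference mode).
#' @param volumes Either a single volume or a named per-sample vector of
#'   input volumes in ml (volume mode); used when `references` is `NULL`. If
#'   the table has a `volume_ml` column it is used as the default.
#' @param efficiencies Optional named per-gene efficiencies (default 1).
#' @param var_equal Classic equal-variance t-test (`TRUE`, default) or Welch.
#' @return A tibble per target gene: `gene_id`, `normalizer`, `n_control`,
#'   `n_treated`, `log2_ratio`, `ratio`, `p_value`, `stars`.
#' @export
relative_expression <- function(ct_table, references = NULL, volumes = NULL,
                                efficiencies = NULL, var_equal = TRUE) {
  needed <- c("sample_id", "condition", "gene_id", "Ct")
  if (!all(needed %in% names(ct_table))) {
    abort(sprintf("`ct_table` must have columns: %s.", paste(needed, collapse = ", ")))
  }
  if ("well_type" %in% names(ct_table)) {
    ct_table <- dplyr::filter(ct_table, .data$well_type != "standard")
  }
  if (is.null(volumes) && "volume_ml" %in% names(ct_table)) {
    volumes <- setNames(ct_table$volume_ml, ct_table$sample_id)
    volumes <- volumes[!duplicated(names(volumes))]
  }
  ct_table <- dplyr::summarise(
    dplyr::group_by(ct_table, .data$sample_id, .data$condition, .data$gene_id),
    Ct = mean(.data$Ct), .groups = "drop"
  )
  ct_table <- dplyr::mutate(ct_table,
    log2q = log2_quantity(.data$Ct, lookup_efficiency(.data$gene_id, efficiencies))
  )

  if (!is.null(references)) {
    normalizer <- "reference genes"
    refs <- dplyr::filter(ct_table, .data$gene_id %in% references)
    missing <- dplyr::anti_join(
      tidyr::expand_grid(
        sample_id = unique(ct_table$sample_id),
        gene_id = references
      ),
      refs[c("sample_id", "gene_id")],
      by = c("sample_id", "gene_id")
    )
    if (nrow(missing) > 0) {
      abort(sprintf(
        "Reference gene %s missing in sample %s.",
        missing$gene_id[1], missing$sample_id[1]
      ))
    }
    norm <- dplyr::summarise(
      dplyr::group_by(refs, .data$sample_id),
      norm_log2 = mean(.data$log2q), .groups = "drop"
    )
    targets <- dplyr::filter(ct_table, !.data$gene_id %in% references)
    targets <- dplyr::left_join(targets, norm, by = "sample_id")
  } else {
    normalizer <- "serum volume"
    if (is.null(volumes)) {
      abort("Provide `references` or per-sample `volumes` (or a `volume_ml` column).")
    }
    targets <- ct_table
    vol <- if (length(volumes) == 1 && is.null(names(volumes))) {
      rep(volumes, nrow(targets))
    } else {
      v <- volumes[targets$sample_id]
      if (anyNA(v)) abort("Missing volume for at least one sample.")
      unname(v)
    }
    targets <- dplyr::mutate(targets, norm_log2 = log2(vol))
  }

  targets <- dplyr::mutate(targets, delta = .data$log2q - .data$norm_log2)
  purrr::map_dfr(split(targets, targets$gene_id), function(g) {
    ctrl <- g$delta[g$condition == "control"]
    trt <- g$delta[g$condition == "treated"]
    cmp <- compare_groups(ctrl, trt, var_equal = var_equal)
    tibble(
      gene_id = g$gene_id[1],
      normalizer = normalizer,
      n_control = length(ctrl),
      n_treated = length(trt),
      log2_ratio = mean(trt) - mean(ctrl),
      ratio = 2^(mean(trt) - mean(ctrl)),
      p_value = cmp$p_value,
      stars = cmp$stars
    )
  })
}

#' Two-group comparison of expression values
#'
#' Unpaired two-tailed Student's t-test (equal variances by default; Welch
#' via `var_equal = FALSE`) on log-scale expression values, with the usual
#' significance stars at thresholds 0.05, 0.01 and 0.001. Degenerate input
#' with zero variance in both groups gives `t = 0, p = 1` when the means are
#' equal and `p = 0` otherwise.
#'
#' @param control,treated Numeric vectors (log-scale expression), at least 2
#'   values each.
#' @param var_equal Pool the variance (classic Student) or not (Welch).
#' @return A one-row tibble: `estimate` (treated - control mean difference),
#'   `statistic`, `df`, `p_value`, `stars`.
#' @export
#' @examples
#' compare_groups(c(1, 1.1, 0.9), c(2, 2.2, 1.9))
compare_groups <- function(control, treated, var_equal = TRUE) {
  if (length(control) < 2 || length(treated) < 2) {
    abort("Both groups need at least 2 values for a t-test.")
  }
  est <- mean(treated) - mean(control)
  if (sd(control) == 0 && sd(treated) == 0) {
    p <- if (est == 0) 1 else 0
    return(tibble(
      estimate = est, statistic = if (est == 0) 0 else Inf,
      df = length(control) + length(treated) - 2,
      p_value = p, stars = star_labels(p)
    ))
  }
  tt <- stats::t.test(treated, control,
    var.equal = var_equal, alternative = "two.sided"
  )
  tibble(
    estimate = est,
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    stars = star_labels(tt$p.value)
  )
}

#' Read a qPCR plate table
#'
#' Reads the comma-separated plate dialect written by [simulate_qpcr()] /
#' [write_experiment()]: one row per well with sample, condition, gene,
#' dilution, replicate and Ct columns.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_qpcr <- function(path) {
  ct <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("sample_id", "condition", "gene_id", "Ct")
  if (!all(needed %in% names(ct))) {
    abort(sprintf("qPCR table must have columns: %s.", paste(needed, collapse = ", ")))
  }
  ct
}
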