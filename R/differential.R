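#' Treated-versus-control fold changes on the RPKM scale
#'
#' Computes per-feature fold changes between one control and one treated
#' library. Features with a zero count on either side get a pseudocount
#' (default 0.5) added to the raw counts of *both* libraries before RPKM
#' conversion, so folds are always finite. Folds are reported symmetrically:
#' `fold_change = max(r_t, r_c) / min(r_t, r_c) >= 1` with an explicit
#' `direction` (`up`, `down`, `unchanged`).
#'
#' @param counts Count tibble (`feature_id`, `length_nt`, library columns).
#' @param library_totals Named totals per library.
#' @param control,treated Names of the control and treated library columns.
#' @param pseudocount Count added to zero-containing pairs (default 0.5).
#' @return A tibble: `feature_id`, `rpkm_control`, `rpkm_treated`,
#'   `fold_change`, `direction`.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   feature_id = c("a", "b"), length_nt = 22,
#'   L1 = c(100L, 0L), L2 = c(800L, 10L)
#' )
#' fold_changes(counts, c(L1 = 1e6, L2 = 1e6), "L1", "L2")
fold_changes <- function(counts, library_totals, control, treated, pseudocount = 0.5) {
  for (l in c(control, treated)) {
    if (!l %in% names(counts)) abort(sprintf("Library `%s` not found in `counts`.", l))
    if (!l %in% names(library_totals)) {
      abort(sprintf("Library `%s` has no entry in `library_totals`.", l))
    }
  }
  x_c <- counts[[control]]
  x_t <- counts[[treated]]
  zero_pair <- x_c == 0 | x_t == 0
  x_c <- x_c + pseudocount * zero_pair
  x_t <- x_t + pseudocount * zero_pair
  len_kb <- counts$length_nt / 1000
  r_c <- x_c / (len_kb * (library_totals[[control]] / 1e6))
  r_t <- x_t / (len_kb * (library_totals[[treated]] / 1e6))
  tibble(
    feature_id = counts$feature_id,
    rpkm_control = r_c,
    rpkm_treated = r_t,
    fold_change = pmax(r_t, r_c) / pmin(r_t, r_c),
    direction = dplyr::case_when(
      r_t > r_c ~ "up",
      r_t < r_c ~ "down",
      TRUE ~ "unchanged"
    )
  )
}

# Two-sided conditional exact test of equal relative abundance.
# Conditions on both library depths and the feature total (the 2x2 table
# count-vs-remainder), i.e. the observed count in the control library is
# hypergeometric under the null. The two-sided p-value sums all outcomes no
# more probable than the observed one (the fisher.test convention, relative
# tolerance 1e-7), computed with O(log n) tail searches exploiting
# unimodality of the hypergeometric pmf, so it stays fast for counts in the
# millions.
exact_count_test <- function(x1, x2, d1, d2) {
  k <- x1 + x2
  if (k == 0) return(1)
  lo <- max(0, k - d2)
  hi <- min(k, d1)
  if (lo == hi) return(1)
  log_f <- function(y) dhyper(y, d1, d2, k, log = TRUE)
  lf_obs <- log_f(x1) + 1e-7
  mode <- floor((k + 1) * (d1 + 1) / (d1 + d2 + 2))
  mode <- min(max(mode, lo), hi)

  # smallest y in [from..to] (pmf non-increasing there) with log_f(y) <= lf_obs
  search_down <- function(from, to) {
    if (log_f(from) <= lf_obs) return(from)
    if (log_f(to) > lf_obs) return(to + 1)
    while (to - from > 1) {
      mid <- floor((from + to) / 2)
      if (log_f(mid) <= lf_obs) to <- mid else from <- mid
    }
    to
  }
  # largest y in [from..to] (pmf non-decreasing there) with log_f(y) <= lf_obs
  search_up <- function(from, to) {
    if (log_f(to) <= lf_obs) return(to)
    if (log_f(from) > lf_obs) return(from - 1)
    while (to - from > 1) {
      mid <- ceiling((from + to) / 2)
      if (log_f(mid) <= lf_obs) from <- mid else to <- mid
    }
    from
  }

  if (x1 <= mode) {
    left <- phyper(x1, d1, d2, k)
    y <- search_down(mode, hi)
    right <- if (y > hi) 0 else phyper(y - 1, d1, d2, k, lower.tail = FALSE)
  } else {
    right <- phyper(x1 - 1, d1, d2, k, lower.tail = FALSE)
    y <- search_up(lo, mode)
    left <- if (y < lo) 0 else phyper(y, d1, d2, k)
  }
  min(1, left + right)
}

#' Per-feature significance of a two-library abundance shift
#'
#' Tests, for every feature, whether its relative abundance differs between
#' the control and treated libraries, conditioning on the two library depths:
#' a two-sided exact test on the 2x2 table (feature count vs library
#' remainder), i.e. Fisher's exact test, with Benjamini-Hochberg q-values.
#' This replaces replicate-based differential testing, which a pooled
#' one-library-per-condition design cannot support.
#'
#' @inheritParams fold_changes
#' @param alpha Significance level on the q-value scale (default 0.05).
#' @return A tibble: `feature_id`, `p_value`, `q_value`, `significant`.
#' @export
significance_test <- function(counts, library_totals, control, treated, alpha = 0.05) {
  for (l in c(control, treated)) {
    if (!l %in% names(counts)) abort(sprintf("Library `%s` not found in `counts`.", l))
  }
  d1 <- library_totals[[control]]
  d2 <- library_totals[[treated]]
  if (is.null(d1) || is.null(d2) || d1 <= 0 || d2 <= 0) {
    abort("Both libraries need a positive depth in `library_totals`.")
  }
  x1 <- as.numeric(counts[[control]])
  x2 <- as.numeric(counts[[treated]])
  if (any(x1 != round(x1)) || any(x2 != round(x2))) {
    abort("`significance_test()` needs integer read counts, not RPKM.")
  }
  p <- vapply(seq_along(x1), function(i) exact_count_test(x1[i], x2[i], d1, d2),
    numeric(1))
  tibble(
    feature_id = counts$feature_id,
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    significant = p.adjust(p, method = "BH") <= alpha
  )
}

#' Full differential table for one compartment
#'
#' Combines [fold_changes()] and [significance_test()] into the per-feature
#' differential record: RPKM in both libraries, symmetric fold with
#' direction, p/q values, significance, the affected call
#' (`significant & fold_change >= min_fold`, emulating "reliable change"
#' lists) and a low-evidence flag for features whose raw counts are below
#' `low_count` in both libraries.
#'
#' @inheritParams significance_test
#' @param compartment Label stored in the output (e.g. `"tumour"`).
#' @param min_fold Minimum symmetric fold for the affected call (default 1.5).
#' @param pseudocount Passed to [fold_changes()].
#' @param low_count Raw-count threshold for the low-evidence flag (default 10).
#' @return A tibble with one row per feature.
#' @export
#' @examples
#' cfg <- sim_config(seed = 3, library_depths = c(L1 = 2e6, L2 = 2e6, L3 = 2e6, L4 = 2e6))
#' expt <- simulate_counts(generate_catalog(cfg), cfg)
#' diff_t <- differential_table(expt$counts, expt$library_totals, "L1", "L2", "tumour")
#' dplyr::count(diff_t, affected, direction)
differential_table <- function(counts, library_totals, control, treated,
                               compartment = NA_character_, alpha = 0.05,
                               min_fold = 1.5, pseudocount = 0.5,
                               low_count = 10) {
  fc <- fold_changes(counts, library_totals, control, treated, pseudocount)
  sig <- significance_test(counts, library_totals, control, treated, alpha)
  out <- dplyr::left_join(fc, sig, by = "feature_id")
  dplyr::mutate(out,
    compartment = compartment,
    affected = .data$significant & .data$fold_change >= min_fold,
    low_evidence = counts[[control]] < low_count & counts[[treated]] < low_count
  )
}

#' Partition affected features into common and compartment-specific sets
#'
#' @param tumour_significant,serum_significant Character vectors of affected
#'   feature ids per compartment.
#' @return A tibble `feature_id`, `partition` with levels `common`,
#'   `tumour_only`, `serum_only`. The three sets are disjoint;
#'   `common + tumour_only` recovers the tumour set and `common + serum_only`
#'   the serum set.
#' @export
#' @examples
#' overlap_partition(c("a", "b", "c"), c("b", "c", "d")) |> dplyr::count(partition)
overlap_partition <- function(tumour_significant, serum_significant) {
  tumour_significant <- unique(as.character(tumour_significant))
  serum_significant <- unique(as.character(serum_significant))
  common <- intersect(tumour_significant, serum_significant)
  tibble(
    feature_id = c(
      common,
      setdiff(tumour_significant, common),
      setdiff(serum_significant, common)
    ),
    partition = rep(
      c("common", "tumour_only", "serum_only"),
      c(
        length(common),
        length(tumour_significant) - length(common),
        length(serum_significant) - length(common)
      )
    )
  )
}
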