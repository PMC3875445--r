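#' Rank qPCR validation candidates by the TS/TF statistic
#'
#' Implements the candidate-prioritization algorithm for a four-library
#' tumour/serum design, step by step:
#' 1. sort features by tumour-control abundance (`L1` RPKM) descending and
#'    superpose the treated tumour library;
#' 2. likewise for serum (`L3` sorted, `L4` superposed);
#' 3. compute the tumour (`L2/L1`) and serum (`L3/L4`) fold changes;
#' 4. keep the `top_n` most abundant tumour features (by `L1`; or the union
#'    of the `L1` and `L2` top lists with `top_by = "union"`), sorted by
#'    tumour fold descending;
#' 5. reject features not present (zero RPKM) in any of the four libraries;
#' 6. compute the total score `TS = L1 + L3`, the total fold
#'    `TF = L2/L1 + L3/L4` and their ratio `TS/TF`;
#' 7. sort by `TS/TF` ascending (ties: `TF` descending, then feature id);
#' 8. mark as selected the features with `0 < TS/TF <= ts_tf_max` and
#'    `TF >= min_tf` ("high TF");
#' 9. annotate from a curated oncomir/suppressor list.
#'
#' Low TS/TF favours the most abundant-for-their-fold candidates; the serum
#' fold is oriented control/treated (`L3/L4`), so circulating drops count
#' towards `TF` just like tumour boosts.
#'
#' @param rpkm RPKM tibble with `feature_id` and the four library columns.
#' @param annotations Curated tibble `feature_id`, `class`
#'   (`oncomir`/`suppressor`); defaults to [default_annotations()]. Features
#'   not listed get class `unknown`.
#' @param tumour_control,tumour_treated,serum_control,serum_treated Library
#'   column names (defaults `L1`, `L2`, `L3`, `L4`).
#' @param top_n Size of the abundance short-list (default 100).
#' @param ts_tf_max Upper bound of the TS/TF selection window (default 20).
#' @param min_tf Minimum total fold for selection (default 4: two compartment
#'   folds of at least 2 each).
#' @param top_by Whether the short-list is the top `top_n` by tumour-control
#'   abundance (`"L1"`, default) or the union of the `L1` and `L2` top lists.
#' @return A ranked tibble of surviving candidates: `feature_id`,
#'   `score_L1`, `score_L3`, `fold_tumour`, `fold_serum`, `TS`, `TF`,
#'   `ts_over_tf`, `selected`, `annotation`. Empty (with a warning) if no
#'   feature survives the presence filter.
#' @export
#' @examples
#' rpkm <- tibble::tibble(
#'   feature_id = c("a", "b", "c"),
#'   L1 = c(100, 50, 10), L2 = c(800, 300, 40),
#'   L3 = c(60, 30, 5), L4 = c(10, 15, 2.5)
#' )
#' prioritize_candidates(rpkm, top_n = 3)
prioritize_candidates <- function(rpkm,
                                  annotations = default_annotations(),
                                  tumour_control = "L1", tumour_treated = "L2",
                                  serum_control = "L3", serum_treated = "L4",
                                  top_n = 100, ts_tf_max = 20, min_tf = 4,
                                  top_by = c("L1", "union")) {
  top_by <- match.arg(top_by)
  libs <- c(tumour_control, tumour_treated, serum_control, serum_treated)
  missing <- setdiff(libs, names(rpkm))
  if (length(missing) > 0) {
    abort(sprintf("RPKM table lacks library column(s): %s.",
      paste(missing, collapse = ", ")))
  }

  work <- tibble(
    feature_id = rpkm$feature_id,
    score_L1 = rpkm[[tumour_control]],
    score_L2 = rpkm[[tumour_treated]],
    score_L3 = rpkm[[serum_control]],
    score_L4 = rpkm[[serum_treated]]
  )

  # steps 1-3: abundance-sorted views with the treated libraries superposed,
  # then compartment folds (finite only where the denominator is nonzero)
  work <- dplyr::arrange(work, dplyr::desc(.data$score_L1), .data$feature_id)
  work <- dplyr::mutate(work,
    fold_tumour = ifelse(.data$score_L1 > 0, .data$score_L2 / .data$score_L1, NA_real_),
    fold_serum = ifelse(.data$score_L4 > 0, .data$score_L3 / .data$score_L4, NA_real_)
  )

  # step 4: abundance short-list
  shortlist <- if (top_by == "L1") {
    head(work, top_n)
  } else {
    top1 <- head(work$feature_id, top_n)
    by_l2 <- dplyr::arrange(work, dplyr::desc(.data$score_L2), .data$feature_id)
    dplyr::filter(work, .data$feature_id %in% union(top1, head(by_l2$feature_id, top_n)))
  }
  shortlist <- dplyr::arrange(shortlist, dplyr::desc(.data$fold_tumour), .data$feature_id)

  # step 5: presence in all four libraries
  survivors <- dplyr::filter(
    shortlist,
    .data$score_L1 > 0, .data$score_L2 > 0, .data$score_L3 > 0, .data$score_L4 > 0
  )
  if (nrow(survivors) == 0) {
    warn("No candidate is present in all four libraries; returning an empty table.")
    return(tibble(
      feature_id = character(), score_L1 = numeric(), score_L3 = numeric(),
      fold_tumour = numeric(), fold_serum = numeric(), TS = numeric(),
      TF = numeric(), ts_over_tf = numeric(), selected = logical(),
      annotation = character()
    ))
  }

  # steps 6-8: TS, TF, TS/TF, ranking and the selection window
  survivors <- dplyr::mutate(survivors,
    TS = .data$score_L1 + .data$score_L3,
    TF = .data$fold_tumour + .data$fold_serum,
    ts_over_tf = .data$TS / .data$TF
  )
  survivors <- dplyr::arrange(survivors,
    .data$ts_over_tf, dplyr::desc(.data$TF), .data$feature_id)
  survivors <- dplyr::mutate(survivors,
    selected = .data$ts_over_tf > 0 & .data$ts_over_tf <= ts_tf_max & .data$TF >= min_tf
  )

  # step 9: curated annotation
  out <- dplyr::left_join(
    survivors,
    dplyr::select(annotations, "feature_id", annotation = "class"),
    by = "feature_id"
  )
  out <- dplyr::mutate(out,
    annotation = dplyr::coalesce(.data$annotation, "unknown")
  )
  dplyr::select(
    out, "feature_id", "score_L1", "score_L3", "fold_tumour", "fold_serum",
    "TS", "TF", "ts_over_tf", "selected", "annotation"
  )
}

#' Curated oncomir / tumour-suppressor annotation list
#'
#' The annotation list shipped with the package: the nine qPCR-validated
#' miRNAs of the murine LLC study plus the let-7 family, with their
#' literature role.
#'
#' @return A tibble `feature_id`, `class`, `citation`.
#' @export
default_annotations <- function() {
  path <- system.file("extdata", "oncomir_annotations.tsv", package = "mirshift")
  readr::read_tsv(path, show_col_types = FALSE)
}
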