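#' Compute RPKM abundances from a count matrix
#'
#' RPKM (the abundance unit Q) is defined per feature and library as
#' `count / ((length_nt / 1000) * (library_total_reads / 1e6))` — reads per
#' kilobase of mature miRNA per million total reads in the library.
#'
#' @param counts Tibble with `feature_id`, `length_nt` and one non-negative
#'   integer column per library.
#' @param library_totals Named numeric vector of total reads per library;
#'   names must cover the count columns.
#' @param length_col Column holding feature lengths in nt. The default is the
#'   mature length; supply a hairpin-length column instead to normalize by
#'   precursor size.
#' @return A tibble of the same shape with count columns replaced by RPKM.
#'   Zero counts map to zero RPKM.
#' @export
#' @examples
#' counts <- tibble::tibble(feature_id = "mir-a", length_nt = 22, L1 = 5000)
#' compute_rpkm(counts, c(L1 = 1e7))$L1 # 5000 / (0.022 * 10)
compute_rpkm <- function(counts, library_totals, length_col = "length_nt") {
  if (!length_col %in% names(counts)) {
    abort(sprintf("Length column `%s` not found in `counts`.", length_col))
  }
  libs <- intersect(library_columns(counts, exclude = c("feature_id", length_col)),
    names(library_totals))
  if (length(libs) == 0L) {
    abort("No count column matches a name in `library_totals`.")
  }
  lengths_nt <- counts[[length_col]]
  if (any(!is.finite(lengths_nt) | lengths_nt <= 0)) {
    bad <- counts$feature_id[!is.finite(lengths_nt) | lengths_nt <= 0]
    abort(sprintf("Non-positive length for feature(s): %s.",
      paste(head(bad, 5), collapse = ", ")))
  }
  if (any(library_totals[libs] <= 0)) {
    abort(sprintf("Non-positive total reads for library(ies): %s.",
      paste(libs[library_totals[libs] <= 0], collapse = ", ")))
  }
  for (l in libs) {
    if (any(counts[[l]] < 0)) abort(sprintf("Negative counts in library %s.", l))
    if (sum(counts[[l]]) > library_totals[[l]]) {
      abort(sprintf("Feature counts in %s exceed the library total.", l))
    }
    counts[[l]] <- counts[[l]] / ((lengths_nt / 1000) * (library_totals[[l]] / 1e6))
  }
  counts
}

#' Summarise per-library read-class composition
#'
#' Computes, per library, the mapped total (sum of the miRNA, mRNA, rRNA and
#' filter classes) and each class's percentage of total library reads,
#' rounded half-up to one decimal — the convention of published
#' read-classification tables. Note that published tables occasionally differ
#' from this arithmetic in single cells (e.g. a 1.35% cell printed as 1.4%).
#'
#' @param class_counts Tibble with columns `library`, `miRNA`, `mRNA`,
#'   `rRNA`, `filter`, `total_reads` (wide, one row per library) or a long
#'   tibble (`library`, `class`, `count`) including a `total` class or
#'   accompanied by `total_reads`.
#' @return A long tibble: `library`, `class` (the four classes plus
#'   `mapped`), `count`, `percent`.
#' @export
#' @examples
#' comp <- tibble::tibble(
#'   library = "L2", miRNA = 1399612, mRNA = 21972560,
#'   rRNA = 5783418, filter = 4986000, total_reads = 51371107
#' )
#' summarize_composition(comp)
summarize_composition <- function(class_counts) {
  classes <- c("miRNA", "mRNA", "rRNA", "filter")
  if (all(c("library", "class", "count") %in% names(class_counts))) {
    class_counts <- tidyr::pivot_wider(
      dplyr::filter(class_counts, .data$class %in% c(classes, "total", "unmapped")),
      names_from = "class", values_from = "count"
    )
    if ("total" %in% names(class_counts)) {
      class_counts <- dplyr::rename(class_counts, total_reads = "total")
    } else if ("unmapped" %in% names(class_counts)) {
      class_counts <- dplyr::mutate(class_counts,
        total_reads = .data$miRNA + .data$mRNA + .data$rRNA +
          .data$filter + .data$unmapped
      )
    }
  }
  needed <- c("library", classes, "total_reads")
  if (!all(needed %in% names(class_counts))) {
    abort(sprintf("`class_counts` must provide columns: %s.",
      paste(needed, collapse = ", ")))
  }
  if (any(class_counts$total_reads <= 0)) abort("Library totals must be positive.")
  mapped <- rowSums(as.matrix(class_counts[classes]))
  if (any(mapped > class_counts$total_reads)) {
    abort("Class counts exceed the library total in at least one library.")
  }
  out <- dplyr::bind_cols(class_counts[c("library", classes, "total_reads")],
    mapped = mapped)
  out <- tidyr::pivot_longer(out, cols = dplyr::all_of(c(classes, "mapped")),
    names_to = "class", values_to = "count")
  dplyr::mutate(out,
    percent = round_half_up(100 * .data$count / .data$total_reads, 1)
  )[c("library", "class", "count", "total_reads", "percent")]
}

#' Read miRNA feature lengths from a GFF3 annotation
#'
#' Extracts mature-miRNA (or hairpin) feature names and lengths from a
#' miRBase-style GFF3 file. Requires the `rtracklayer` package.
#'
#' @param path Path to a GFF3 file.
#' @param type Feature type to keep: `"miRNA"` (mature, default) or
#'   `"miRNA_primary_transcript"` (hairpin).
#' @return A tibble `feature_id`, `length_nt`.
#' @export
read_mirna_gff <- function(path, type = c("miRNA", "miRNA_primary_transcript")) {
  type <- match.arg(type)
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading GFF3 requires the `rtracklayer` package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == type]
  name <- if (!is.null(gr$Name)) gr$Name else gr$ID
  tibble(feature_id = as.character(name), length_nt = BiocGenerics::width(gr))
}
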