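#' Simulation configuration for a synthetic four-library experiment
#'
#' Builds the configuration object consumed by [generate_catalog()] and
#' [simulate_counts()]. The defaults emulate the pooled study design the
#' package targets: four libraries (tumour control `L1`, tumour treated `L2`,
#' serum control `L3`, serum treated `L4`) with realistic read-class
#' composition, 615 tumour-detectable and 617 serum-detectable miRNAs, and a
#' treated-versus-control effect structure of 116 up + 7 down miRNAs in the
#' tumour and 137 down + 2 up in serum, of which 81 affected miRNAs are shared
#' between compartments. Tumour boosts are drawn uniformly from 2-10x and
#' serum drops from 2-6x.
#'
#' @param seed Integer master seed. Stage streams are derived from it
#'   (catalog, counts and qPCR use `seed`, `seed + 1`, `seed + 2`).
#' @param library_depths Named positive integers, total reads per library
#'   `L1..L4`. The depth is the RPKM denominator, so a feature with base
#'   abundance `a` has expected count `a * length_kb * depth / 1e6`.
#' @param dispersion Negative-binomial overdispersion of feature counts
#'   (variance `mu + dispersion * mu^2`); `0` gives the Poisson limit.
#' @param n_tumour_detectable,n_serum_detectable,n_shared_detectable Number of
#'   miRNAs detectable in the tumour, in serum, and in both compartments.
#' @param n_tumour_up,n_tumour_down Designed affected counts in the tumour.
#' @param n_serum_down,n_serum_up Designed affected counts in serum.
#' @param n_common_affected Number of affected miRNAs shared by both
#'   compartments (the remaining affected features are compartment-specific).
#' @param tumour_up_range,tumour_down_range,serum_down_range,serum_up_range
#'   Two-element fold ranges; effect multipliers are drawn uniformly from them
#'   (down effects use the reciprocal).
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of base
#'   abundance on the RPKM scale.
#' @param affected_weight_power Affected features are sampled with probability
#'   proportional to `base_abundance^affected_weight_power`. The default 1
#'   (size-biased sampling) reflects that reliable change calls in a pooled
#'   two-library design concentrate in well-measured miRNAs.
#' @param composition_fractions 4 x 5 matrix of per-library fractions over
#'   read classes `miRNA`, `mRNA`, `rRNA`, `filter`, `unmapped`; rows must sum
#'   to 1.
#' @param replicates Libraries per condition (the pooled design has 1).
#'
#' @return A list of class `sim_config`.
#' @seealso [generate_catalog()], [simulate_counts()], [simulate_qpcr()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, library_depths = c(L1 = 1e6, L2 = 1e6, L3 = 1e6, L4 = 1e6))
#' cfg$n_tumour_up
sim_config <- function(seed = 1L,
                       library_depths = c(
                         L1 = 71675921, L2 = 51371107,
                         L3 = 42561316, L4 = 56516886
                       ),
                       dispersion = 0.1,
                       n_tumour_detectable = 615L,
                       n_serum_detectable = 617L,
                       n_shared_detectable = 550L,
                       n_tumour_up = 116L,
                       n_tumour_down = 7L,
                       n_serum_down = 137L,
                       n_serum_up = 2L,
                       n_common_affected = 81L,
                       tumour_up_range = c(2, 10),
                       tumour_down_range = c(2, 10),
                       serum_down_range = c(2, 6),
                       serum_up_range = c(2, 6),
                       abundance_meanlog = 3,
                       abundance_sdlog = 2,
                       affected_weight_power = 2,
                       composition_fractions = default_composition_fractions(),
                       replicates = 1L) {
  assert_number(seed, "seed")
  if (length(library_depths) != 4L || is.null(names(library_depths))) {
    abort("`library_depths` must be a named vector of four library depths.")
  }
  if (any(library_depths <= 0)) {
    abort("`library_depths` must all be positive.")
  }
  assert_number(dispersion, "dispersion")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  counts <- c(
    n_tumour_detectable, n_serum_detectable, n_shared_detectable,
    n_tumour_up, n_tumour_down, n_serum_down, n_serum_up, n_common_affected
  )
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Feature-count parameters must be non-negative integers.")
  }
  n_tumour_affected <- n_tumour_up + n_tumour_down
  n_serum_affected <- n_serum_down + n_serum_up
  if (n_tumour_affected > n_tumour_detectable) {
    abort("Tumour effect counts exceed the tumour-detectable total.")
  }
  if (n_serum_affected > n_serum_detectable) {
    abort("Serum effect counts exceed the serum-detectable total.")
  }
  if (n_common_affected > min(n_tumour_affected, n_serum_affected)) {
    abort("`n_common_affected` cannot exceed either compartment's affected total.")
  }
  if (n_shared_detectable > min(n_tumour_detectable, n_serum_detectable)) {
    abort("`n_shared_detectable` cannot exceed either detectable total.")
  }
  for (r in list(tumour_up_range, tumour_down_range, serum_down_range, serum_up_range)) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      abort("Effect ranges must be positive two-element intervals (lo <= hi).")
    }
  }
  composition_fractions <- as.matrix(composition_fractions)
  if (!identical(dim(composition_fractions), c(4L, 5L)) ||
    !identical(colnames(composition_fractions), read_classes())) {
    abort(sprintf(
      "`composition_fractions` must be a 4 x 5 matrix with columns %s.",
      paste(read_classes(), collapse = ", ")
    ))
  }
  if (any(abs(rowSums(composition_fractions) - 1) > 1e-9)) {
    abort("Each row of `composition_fractions` must sum to 1 (tolerance 1e-9).")
  }
  if (any(composition_fractions < 0)) {
    abort("Composition fractions must be non-negative.")
  }

  structure(
    list(
      seed = as.integer(seed),
      library_depths = library_depths,
      dispersion = dispersion,
      n_tumour_detectable = as.integer(n_tumour_detectable),
      n_serum_detectable = as.integer(n_serum_detectable),
      n_shared_detectable = as.integer(n_shared_detectable),
      n_tumour_up = as.integer(n_tumour_up),
      n_tumour_down = as.integer(n_tumour_down),
      n_serum_down = as.integer(n_serum_down),
      n_serum_up = as.integer(n_serum_up),
      n_common_affected = as.integer(n_common_affected),
      tumour_up_range = tumour_up_range,
      tumour_down_range = tumour_down_range,
      serum_down_range = serum_down_range,
      serum_up_range = serum_up_range,
      abundance_meanlog = abundance_meanlog,
      abundance_sdlog = abundance_sdlog,
      affected_weight_power = affected_weight_power,
      composition_fractions = composition_fractions,
      replicates = as.integer(replicates)
    ),
    class = "sim_config"
  )
}

read_classes <- function() c("miRNA", "mRNA", "rRNA", "filter", "unmapped")

#' Default per-library read-class fractions
#'
#' Fractions of total reads falling into each mapping class, per library,
#' derived from the read-classification totals of the four pooled LLC
#' libraries shipped in `inst/extdata/llc_library_composition.tsv`
#' (miRNA, mRNA, rRNA and filtering RNAs; the remainder is unmapped).
#'
#' @return A 4 x 5 numeric matrix (libraries x classes), rows summing to 1.
#' @export
default_composition_fractions <- function() {
  counts <- rbind(
    L1 = c(miRNA = 965017, mRNA = 31407252, rRNA = 9348471, filter = 6511041, total = 71675921),
    L2 = c(miRNA = 1399612, mRNA = 21972560, rRNA = 5783418, filter = 4986000, total = 51371107),
    L3 = c(miRNA = 835664, mRNA = 20476883, rRNA = 2623843, filter = 8200681, total = 42561316),
    L4 = c(miRNA = 560568, mRNA = 27024143, rRNA = 3195154, filter = 8876496, total = 56516886)
  )
  fr <- counts[, c("miRNA", "mRNA", "rRNA", "filter")] / counts[, "total"]
  cbind(fr, unmapped = 1 - rowSums(fr))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat(
    "  libraries:",
    paste(sprintf("%s=%.3g", names(x$library_depths), x$library_depths), collapse = " "),
    "\n"
  )
  cat(
    "  detectable: tumour", x$n_tumour_detectable,
    "serum", x$n_serum_detectable,
    "shared", x$n_shared_detectable, "\n"
  )
  cat(
    "  affected: tumour", x$n_tumour_up, "up /", x$n_tumour_down, "down;",
    "serum", x$n_serum_down, "down /", x$n_serum_up, "up;",
    "common", x$n_common_affected, "\n"
  )
  cat("  dispersion:", x$dispersion, "\n")
  invisible(x)
}
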