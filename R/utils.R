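# Internal helpers shared across modules.

# Round half away from zero, the convention used for printed percentages.
# base::round() rounds half to even, which disagrees on e.g. 2.75 -> 2.8.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Child seed for a named stage stream, derived from one master seed so that
# stages are individually reproducible.  Stream order is part of the contract:
# catalog = 0, counts = 1, qpcr = 2.
stage_seed <- function(seed, stage = c("catalog", "counts", "qpcr")) {
  stage <- match.arg(stage)
  offset <- c(catalog = 0L, counts = 1L, qpcr = 2L)[[stage]]
  (as.integer(seed) + offset) %% .Machine$integer.max
}

assert_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# Columns of `df` that hold per-library values (everything numeric except
# annotation columns).
library_columns <- function(df, exclude = c("feature_id", "length_nt")) {
  setdiff(names(df)[vapply(df, is.numeric, logical(1))], exclude)
}

star_labels <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
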