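# Independent oracles and fixture builders used across the suite.

# Exhaustive average-linkage oracle: at every step recompute the mean
# pairwise Euclidean distance between all member pairs of every cluster pair
# directly from the raw points (no running update).
upgma_oracle <- function(m) {
  D <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1) {
    best <- NULL
    bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- mean(D[clusters[[i]], clusters[[j]]])
          if (d < bestd - 1e-12) {
            bestd <- d
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, bestd)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    members <- c(members, list(merged))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, members = members)
}

# Member sets of every merge of an hclust-style tree, as sorted leaf indices.
merge_members <- function(h) {
  out <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    grab <- function(code) if (code < 0) -code else out[[code]]
    out[[k]] <- sort(c(grab(h$merge[k, 1]), grab(h$merge[k, 2])))
  }
  out
}

# Brute-force geNorm M: for every gene, loop over all other genes and take
# the sd across samples of the log2 ratio, then average.
m_value_oracle <- function(logq) {
  genes <- colnames(logq)
  vapply(genes, function(g) {
    others <- setdiff(genes, g)
    mean(vapply(others, function(o) sd(logq[, g] - logq[, o]), numeric(1)))
  }, numeric(1))
}

# Pooled-variance two-sample t, from the textbook formula.
student_t_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Small equal-depth simulation config used where full study depths are
# unnecessary.
small_sim_config <- function(seed, depth = 2e6, ...) {
  sim_config(
    seed = seed,
    library_depths = c(L1 = depth, L2 = depth, L3 = depth, L4 = depth),
    ...
  )
}

# Five-feature worked micro-table: control scores 100/50/10/5/1 in both
# compartments, compartment folds 8/6/4/2/1.5. Hand-computed expectations:
#   A: TS 200, TF 16, TS/TF 12.5      B: TS 100, TF 12, TS/TF 8.333
#   C: TS  20, TF  8, TS/TF 2.5       D: TS  10, TF  4, TS/TF 2.5
#   E: TS   2, TF  3, TS/TF 0.667
# Ranking ascending in TS/TF (C before D by TF at the tie): E, C, D, B, A.
micro_rpkm <- function() {
  scores <- c(A = 100, B = 50, C = 10, D = 5, E = 1)
  folds <- c(A = 8, B = 6, C = 4, D = 2, E = 1.5)
  tibble::tibble(
    feature_id = names(scores),
    L1 = unname(scores), L2 = unname(scores * folds),
    L3 = unname(scores), L4 = unname(scores / folds)
  )
}

# Noise-free qPCR spec for closed-form checks.
noiseless_qpcr_spec <- function(...) {
  qpcr_sim_spec(ct_sd = 0, loading_sd = 0, stable_ref_sd = 0, unstable_ref_sd = 0, ...)
}
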