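#' Z-score scaling of an abundance matrix
#'
#' Standardizes each row (feature) or column (library) of an RPKM table to
#' mean 0 and standard deviation 1, the transform underlying clustered
#' heat-map displays. The sample standard deviation (denominator `n - 1`) is
#' used. Constant vectors map to all zeros with a warning.
#'
#' @param x A tibble with `feature_id` and numeric library columns, or a
#'   numeric matrix with rownames.
#' @param axis `"rows"` to scale each feature profile, `"columns"` to scale
#'   each library.
#' @return An object of the input's kind with values replaced by Z-scores and
#'   attribute `scaling_axis` set.
#' @export
#' @examples
#' m <- tibble::tibble(feature_id = "a", L1 = 1, L2 = 2, L3 = 3)
#' zscore_matrix(m, "rows")
zscore_matrix <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  is_df <- is.data.frame(x)
  m <- if (is_df) {
    libs <- library_columns(x)
    mm <- as.matrix(x[libs])
    rownames(mm) <- x$feature_id
    mm
  } else {
    as.matrix(x)
  }
  if (!is.numeric(m)) abort("`x` must be numeric.")
  n_along <- if (axis == "rows") ncol(m) else nrow(m)
  if (n_along < 2) abort("Cannot Z-score along an axis of length 1.")

  scale_vec <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      warn("Constant vector mapped to zeros during Z-scoring.")
      rep(0, length(v))
    } else {
      (v - mean(v)) / s
    }
  }
  z <- if (axis == "rows") t(apply(m, 1, scale_vec)) else apply(m, 2, scale_vec)
  dimnames(z) <- dimnames(m)

  if (is_df) {
    out <- x
    out[library_columns(x)] <- as_tibble(z)
    attr(out, "scaling_axis") <- axis
    out
  } else {
    attr(z, "scaling_axis") <- axis
    z
  }
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Agglomerates items by unweighted pair-group average linkage on Euclidean
#' distances, the dendrogram computation of clustered heat maps. Fully
#' deterministic: ties in the minimum inter-cluster distance are broken by
#' the smallest pair of cluster ids (a cluster's id is the smallest input
#' position among its members), and the leaf order puts the smaller-id
#' subtree first at every merge.
#'
#' @param x A tibble (`feature_id` + numeric columns, e.g. from
#'   [zscore_matrix()]) or numeric matrix; items are rows or columns per `on`.
#' @param on Cluster `"rows"` (features) or `"columns"` (libraries).
#' @return An object of class `c("upgma", "hclust")` with the usual `merge`,
#'   `height`, `order`, `labels` components, so `stats` and `ape` dendrogram
#'   tooling applies.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
#' upgma(m)$height # first merge at height 1
upgma <- function(x, on = c("rows", "columns")) {
  on <- match.arg(on)
  m <- if (is.data.frame(x)) {
    mm <- as.matrix(x[library_columns(x)])
    rownames(mm) <- x$feature_id
    mm
  } else {
    as.matrix(x)
  }
  if (on == "columns") m <- t(m)
  if (nrow(m) < 2) abort("Need at least two items to cluster.")
  if (any(!is.finite(m))) abort("Non-finite values in the clustering input.")

  n <- nrow(m)
  labels <- rownames(m) %||% as.character(seq_len(n))
  d <- as.matrix(dist(m))
  diag(d) <- NA
  active <- rep(TRUE, n)
  rep_id <- seq_len(n) # smallest member position, the cluster id
  size <- rep(1L, n)
  code <- -seq_len(n) # hclust merge encoding
  leaves <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    dmin <- min(d[active, active], na.rm = TRUE)
    # ties are detected up to relative rounding error so that exactly
    # equidistant geometries resolve by id, not by float noise
    tol <- dmin * 1e-12 + 1e-15
    cand <- which(d <= dmin + tol & outer(active, active, `&`), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_ids <- cbind(
      pmin(rep_id[cand[, 1]], rep_id[cand[, 2]]),
      pmax(rep_id[cand[, 1]], rep_id[cand[, 2]])
    )
    best <- order(pair_ids[, 1], pair_ids[, 2])[1]
    i <- cand[best, 1]
    j <- cand[best, 2]
    if (rep_id[j] < rep_id[i]) { tmp <- i; i <- j; j <- tmp }

    merge[step, ] <- c(code[i], code[j])
    height[step] <- dmin
    leaves[[i]] <- c(leaves[[i]], leaves[[j]])

    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
      (size[i] + size[j])
    d[others, i] <- d[i, others]
    active[j] <- FALSE
    d[j, ] <- NA
    d[, j] <- NA
    size[i] <- size[i] + size[j]
    rep_id[i] <- min(rep_id[i], rep_id[j])
    code[i] <- step
  }

  structure(
    list(
      merge = merge,
      height = height,
      order = leaves[[which(active)]],
      labels = labels,
      method = "average",
      dist.method = "euclidean",
      call = match.call()
    ),
    class = c("upgma", "hclust")
  )
}

#' Write a dendrogram as a Newick tree
#'
#' Exports a clustering from [upgma()] (or any `hclust` object) to Newick
#' format, with branch lengths derived from the merge heights (ultrametric
#' tree; leaf-to-root depth equals half the final merge height, the `ape`
#' convention for `hclust` trees).
#'
#' @param clustering An `hclust`/`upgma` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(stats::as.hclust(clustering))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Z-score and cluster an RPKM table for heat-map display
#'
#' Convenience wrapper reproducing the numeric content of a clustered
#' abundance heat map: features are clustered on row-scaled Z-scores and
#' libraries on column-scaled Z-scores, independently, each by [upgma()] on
#' Euclidean distances.
#'
#' @param rpkm RPKM tibble (`feature_id` + library columns).
#' @return A list of class `heatmap_clustering`: `scaled_rows`,
#'   `scaled_columns` (Z-scored tibbles), `feature_dendrogram`,
#'   `library_dendrogram`.
#' @export
cluster_profiles <- function(rpkm) {
  scaled_rows <- zscore_matrix(rpkm, "rows")
  scaled_cols <- zscore_matrix(rpkm, "columns")
  structure(
    list(
      scaled_rows = scaled_rows,
      scaled_columns = scaled_cols,
      feature_dendrogram = upgma(scaled_rows, on = "rows"),
      library_dendrogram = upgma(scaled_cols, on = "columns")
    ),
    class = "heatmap_clustering"
  )
}
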