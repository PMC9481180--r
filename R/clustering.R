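#' Cells-by-features table for phenotypic clustering
#'
#' A light wrapper around a numeric matrix (rows = cells, columns =
#' features) with cell ids as rownames. Missing values are allowed and
#' tracked; rows with missing retained features are excluded before
#' distance computation (see [euclidean_distances()]).
#'
#' @param x Numeric matrix or data.frame of feature values; rownames (or a
#'   `cell_id` column) identify cells.
#' @param feature_names Optional character vector to subset/reorder the
#'   columns.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(x, feature_names = NULL) {
  if (is.data.frame(x)) {
    if ("cell_id" %in% names(x)) {
      ids <- as.character(x$cell_id)
      x <- x[, setdiff(names(x), "cell_id"), drop = FALSE]
      x <- as.matrix(x)
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("feature_table requires a numeric matrix")
  if (is.null(rownames(x))) rownames(x) <- sprintf("cell%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, colnames(x))
    if (length(missing)) {
      stop("feature(s) not in table: ", paste(missing, collapse = ", "))
    }
    x <- x[, feature_names, drop = FALSE]
  }
  structure(list(matrix = x, cell_ids = rownames(x),
                 feature_names = colnames(x)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x$matrix), "cells x", ncol(x$matrix),
      "features;", sum(is.na(x$matrix)), "missing values\n")
  invisible(x)
}

#' Read/write feature tables as CSV
#'
#' One row per cell; first column `cell_id`, remaining columns features.
#' @param path CSV path.
#' @param t A [feature_table()].
#' @return `read_feature_table`: a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character"))
  if (!"cell_id" %in% names(df)) stop("feature CSV ", path, " lacks a cell_id column")
  feature_table(df)
}

#' @rdname read_feature_table
#' @param format `"csv"` (default) or `"json"` (array of per-cell objects).
#' @export
write_feature_table <- function(t, path, format = c("csv", "json")) {
  stopifnot(inherits(t, "feature_table"))
  format <- match.arg(format)
  df <- data.frame(cell_id = t$cell_ids, t$matrix, check.names = FALSE,
                   row.names = NULL)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Z-score scaling of a feature table
#'
#' Each retained feature column is centred to mean 0 and scaled to sample
#' standard deviation 1 (n-1 denominator), computing the moments over
#' observed values only; missing values stay missing. Columns that are
#' constant, or have fewer than 2 observed values, are dropped with a
#' warning (their z-score is undefined).
#'
#' @param t A [feature_table()].
#' @return A scaled [feature_table()].
#' @export
zscore_scale <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  x <- t$matrix
  keep <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    obs <- x[!is.na(x[, j]), j]
    if (length(obs) < 2 || stats::sd(obs) == 0) {
      keep[j] <- FALSE
    } else {
      keep[j] <- TRUE
      x[, j] <- (x[, j] - mean(obs)) / stats::sd(obs)
    }
  }
  if (any(!keep)) {
    warning("dropping feature(s) with undefined z-score: ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("no feature column admits a z-score")
  feature_table(x[, keep, drop = FALSE])
}

#' Euclidean distances between cells
#'
#' @param t A [feature_table()] with no missing values among its columns;
#'   rows with missing features must be excluded first (their ids are the
#'   analyst's record of exclusion).
#' @return A `dist` object (symmetric, zero diagonal).
#' @export
euclidean_distances <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (anyNA(t$matrix)) {
    bad <- t$cell_ids[rowSums(is.na(t$matrix)) > 0]
    stop("missing feature values for cell(s): ", paste(bad, collapse = ", "),
         "; exclude incomplete rows (complete_rows()) before computing distances")
  }
  stats::dist(t$matrix, method = "euclidean")
}

#' Drop rows with missing feature values
#'
#' @param t A [feature_table()].
#' @return A list: `table` (complete rows only) and `excluded` (cell ids
#'   that had missing values).
#' @export
complete_rows <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  bad <- rowSums(is.na(t$matrix)) > 0
  list(table = feature_table(t$matrix[!bad, , drop = FALSE]),
       excluded = t$cell_ids[bad])
}

#' Ward agglomeration of a Euclidean distance matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion
#' (Lance-Williams updates on the squared dissimilarities, as in
#' `hclust(method = "ward.D2")`). With Euclidean input every merge height
#' equals `sqrt(2 * dESS)`, where `dESS` is the increase in within-cluster
#' sum of squared deviations caused by that merge; heights are
#' nondecreasing, which is asserted.
#'
#' @param d A `dist` object from [euclidean_distances()].
#' @return An object of class `ward_dendrogram` wrapping the `hclust`
#'   result: `merge`, `height`, `order`, `labels`, `n`.
#' @export
ward_linkage <- function(d) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < 2) stop("need at least 2 observations to cluster")
  hc <- stats::hclust(d, method = "ward.D2")
  if (any(diff(hc$height) < -1e-9)) {
    stop("Ward merge heights decreased; input is not a valid Euclidean distance matrix")
  }
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, n = n, hclust = hc),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat("<ward_dendrogram>", x$n, "leaves;", length(x$height), "merges; top height",
      signif(max(x$height), 6), "\n")
  invisible(x)
}

#' Merge heights recomputed from within-cluster sums of squares
#'
#' Independent validation of a Ward dendrogram against the raw data: for
#' each merge step the increase in within-cluster sum of squared deviations
#' (dESS) is computed directly from the coordinates of the two clusters
#' being merged, and returned as `sqrt(2 * dESS)`. Useful for checking
#' `ward_linkage()` output on small problems.
#'
#' @param dend A [ward_linkage()] result.
#' @param x The numeric matrix the distances were computed from (rows in
#'   the same order).
#' @return Numeric vector of per-merge heights.
#' @export
ess_merge_heights <- function(dend, x) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  x <- as.matrix(x)
  ess <- function(rows) {
    if (length(rows) < 2) return(0)
    xm <- x[rows, , drop = FALSE]
    sum(base::sweep(xm, 2, colMeans(xm))^2)
  }
  members <- vector("list", nrow(dend$merge))
  heights <- numeric(nrow(dend$merge))
  for (s in seq_len(nrow(dend$merge))) {
    get_members <- function(idx) {
      if (idx < 0) -idx else members[[idx]]
    }
    a <- get_members(dend$merge[s, 1])
    b <- get_members(dend$merge[s, 2])
    members[[s]] <- c(a, b)
    d_ess <- ess(members[[s]]) - ess(a) - ess(b)
    heights[s] <- sqrt(2 * d_ess)
  }
  heights
}

#' Cut a Ward dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges; labels are renumbered `1..k` by
#' first appearance in the dendrogram's leaf order, so the labelling is a
#' deterministic function of the tree.
#'
#' @param dend A [ward_linkage()] result.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer label vector in input-row order.
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  if (k < 1 || k > dend$n) stop("k must be in 1..", dend$n)
  raw <- stats::cutree(dend$hclust, k = k)
  first_seen <- raw[dend$order]
  mapping <- stats::setNames(seq_along(unique(first_seen)), unique(first_seen))
  out <- as.integer(mapping[as.character(raw)])
  names(out) <- names(raw)
  out
}

#' Silhouette coefficients for a clustering
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance
#' of point `i` to its own cluster (excluding itself) and `b(i)` the
#' smallest mean distance to another cluster; singleton clusters get
#' `s(i) = 0`.
#'
#' @param labels Integer cluster labels (>= 2 distinct, all clusters
#'   non-empty).
#' @param d A `dist` object over the same points.
#' @return List with `mean` and `per_point`.
#' @export
silhouette_score <- function(labels, d) {
  stopifnot(inherits(d, "dist"))
  if (length(unique(labels)) < 2) {
    stop("silhouette requires at least 2 clusters")
  }
  sil <- cluster::silhouette(as.integer(labels), d)
  list(mean = mean(sil[, "sil_width"]), per_point = as.numeric(sil[, "sil_width"]))
}

#' Silhouette-guided choice of the number of clusters
#'
#' Cuts the Ward dendrogram at each k in `k_range`, computes the mean
#' silhouette on the supplied distances, and picks the k with the largest
#' mean (smallest k on ties). When even the best mean silhouette is below
#' `structure_floor` the result is flagged as showing no substantial
#' cluster structure.
#'
#' @param d A `dist` object (typically over the z-scored features).
#' @param k_range Candidate cluster numbers (default `2:min(10, n - 1)`).
#' @param structure_floor Mean-silhouette floor below which `no_structure`
#'   is flagged (default 0.25).
#' @return An object of class `clustering_result`: `dendrogram`,
#'   `labels_by_k`, `silhouette_by_k`, `best_k`, `best_labels`,
#'   `no_structure`.
#' @export
select_k <- function(d, k_range = NULL, structure_floor = 0.25) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < 3) stop("need at least 3 observations to select k")
  if (is.null(k_range)) k_range <- 2:min(10, n - 1)
  if (any(k_range < 2 | k_range > n)) stop("k_range must lie in 2..n")
  dend <- ward_linkage(d)
  labels_by_k <- list()
  sil_by_k <- stats::setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    lab <- cut_dendrogram(dend, k)
    labels_by_k[[as.character(k)]] <- lab
    sil_by_k[i] <- silhouette_score(lab, d)$mean
  }
  best_k <- k_range[which.max(sil_by_k)]  # which.max takes the first (smallest k) on ties
  structure(
    list(dendrogram = dend,
         labels_by_k = labels_by_k,
         silhouette_by_k = sil_by_k,
         best_k = best_k,
         best_labels = labels_by_k[[as.character(best_k)]],
         no_structure = max(sil_by_k) < structure_floor),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("<clustering_result>", x$dendrogram$n, "cells; best k =", x$best_k,
      "(mean silhouette", signif(x$silhouette_by_k[as.character(x$best_k)], 3),
      ")\n")
  if (x$no_structure) cat("  flagged: no substantial cluster structure\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same points;
#' 1 means identical partitions (up to label names), 0 is the chance level.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / denom
}

#' Export a dendrogram's merge table
#'
#' One row per merge: step, the two merged cluster indices in `hclust`
#' convention (negative = leaf), the merge height, and the size of the
#' resulting cluster.
#'
#' @param dend A [ward_linkage()] result.
#' @return A data.frame.
#' @export
merge_table <- function(dend) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  sizes <- integer(nrow(dend$merge))
  size_of <- function(idx) if (idx < 0) 1L else sizes[idx]
  for (s in seq_len(nrow(dend$merge))) {
    sizes[s] <- size_of(dend$merge[s, 1]) + size_of(dend$merge[s, 2])
  }
  data.frame(step = seq_len(nrow(dend$merge)),
             i = dend$merge[, 1], j = dend$merge[, 2],
             height = dend$height, size = sizes)
}

#' Newick-style text rendering of a dendrogram
#'
#' Nested-parenthesis text with merge heights as branch annotations;
#' intended for reports and diffs, not phylogenetics.
#'
#' @param dend A [ward_linkage()] result.
#' @return A single string.
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  labs <- if (is.null(dend$labels)) as.character(seq_len(dend$n)) else dend$labels
  render <- function(idx) {
    if (idx < 0) return(labs[-idx])
    paste0("(", render(dend$merge[idx, 1]), ",", render(dend$merge[idx, 2]),
           "):", signif(dend$height[idx], 8))
  }
  paste0(render(nrow(dend$merge)), ";")
}
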