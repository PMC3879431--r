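#' Euclidean distances along one axis of a binary matrix
#'
#' Pairwise Euclidean distances between the rows (`axis = "rows"`) or
#' columns (`axis = "cols"`) of a matrix. For 0/1 annotation matrices
#' this equals the square root of the Hamming distance.
#'
#' @param m Numeric matrix (>= 2 items along the chosen axis).
#' @param axis `"rows"` or `"cols"`.
#' @return A symmetric `matrix` of distances with zero diagonal and the
#'   axis names as dimnames.
#' @export
euclidean_distances <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") m <- t(m)
  if (nrow(m) < 2L)
    stop("need >= 2 items along axis '", axis, "'")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' UPGMA (unweighted average linkage) hierarchical clustering
#'
#' Agglomerative clustering by the unweighted pair-group method with
#' arithmetic mean: at each step the pair of clusters with the smallest
#' average inter-cluster distance is merged at that distance, and the
#' merged cluster's distance to any other cluster C is the size-weighted
#' mean `(|A| d(A,C) + |B| d(B,C)) / (|A| + |B|)` — equivalently the
#' unweighted mean over all original member pairs. Merge heights are
#' monotone nondecreasing (the UPGMA tree is ultrametric).
#'
#' Ties on the minimal distance are broken deterministically: the pair
#' whose (sorted) minimal original member indices are lexicographically
#' smallest is merged first. The leaf order places the subtree
#' containing the smaller original index first.
#'
#' @param d A `dist` object or a symmetric nonnegative matrix with zero
#'   diagonal.
#' @return An object of classes `upgma` and `hclust` (fields `merge`,
#'   `height`, `order`, `labels`, `method = "average"`), so standard
#'   dendrogram tools apply.
#' @export
#' @examples
#' m <- rbind(a = c(1, 0, 0), b = c(1, 1, 0), c = c(0, 1, 1))
#' upgma(euclidean_distances(m))
upgma <- function(d) {
  dm <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  n <- nrow(dm)
  if (n < 2L) stop("need >= 2 items to cluster")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)) ||
      any(diag(dm) != 0) || any(dm < 0))
    stop("distance input must be symmetric, nonnegative, zero-diagonal")
  labels <- rownames(dm)

  # active clusters: id (merge-matrix convention: -leaf or +step),
  # size, minimal original member (tie-break key)
  active <- data.frame(id = -seq_len(n), size = 1L, minmem = seq_len(n))
  cur <- dm                       # current inter-cluster distances
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- nrow(active)
    # minimal distance, ties broken by smallest (minmem_i, minmem_j)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        key <- sort(c(active$minmem[i], active$minmem[j]))
        cand <- list(i = i, j = j, d = cur[i, j], key = key)
        if (is.null(best) || cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L]))))
          best <- cand
      }
    }
    i <- best$i; j <- best$j
    height[step] <- best$d
    # hclust merge convention orders the pair (negatives first, then
    # ascending); we keep the smaller-minmem cluster first
    pair <- c(active$id[i], active$id[j])
    if (active$minmem[j] < active$minmem[i]) pair <- rev(pair)
    merge[step, ] <- pair

    si <- active$size[i]; sj <- active$size[j]
    newrow <- (si * cur[i, ] + sj * cur[j, ]) / (si + sj)
    keep <- setdiff(seq_len(k), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newrow[keep]),
                 c(newrow[keep], 0))
    active <- rbind(active[keep, , drop = FALSE],
                    data.frame(id = step, size = si + sj,
                               minmem = min(active$minmem[c(i, j)])))
  }

  structure(list(merge = merge, height = height,
                 order = leaf_order(merge),
                 labels = labels, method = "average",
                 dist.method = "euclidean",
                 call = match.call()),
            class = c("upgma", "hclust"))
}

# recursive leaf order; at every merge the subtree whose minimal
# original leaf index is smaller comes first
leaf_order <- function(merge) {
  minleaf <- function(node) {
    if (node < 0L) -node else min(minleaf(merge[node, 1L]),
                                  minleaf(merge[node, 2L]))
  }
  walk <- function(node) {
    if (node < 0L) return(-node)
    a <- merge[node, 1L]; b <- merge[node, 2L]
    if (minleaf(a) > minleaf(b)) { tmp <- a; a <- b; b <- tmp }
    c(walk(a), walk(b))
  }
  walk(nrow(merge))
}

#' Merge table of a dendrogram
#'
#' Flat description of the merge sequence: one row per merge with the
#' comma-separated original member labels of each side and the merge
#' height.
#'
#' @param dend An `upgma`/`hclust` object.
#' @return A data.frame: `step`, `members_a`, `members_b`, `height`,
#'   `size`.
#' @export
merge_table <- function(dend) {
  labels <- dend$labels
  if (is.null(labels)) labels <- as.character(seq_along(dend$order))
  members <- function(node) {
    if (node < 0L) return(labels[-node])
    c(members(dend$merge[node, 1L]), members(dend$merge[node, 2L]))
  }
  n_merge <- nrow(dend$merge)
  data.frame(
    step = seq_len(n_merge),
    members_a = vapply(dend$merge[, 1L], function(x)
      paste(members(x), collapse = ","), ""),
    members_b = vapply(dend$merge[, 2L], function(x)
      paste(members(x), collapse = ","), ""),
    height = dend$height,
    size = vapply(seq_len(n_merge), function(s)
      length(members(s)), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Bidirectional UPGMA clustering of a binary annotation matrix
#'
#' Clusters the rows (genes) and columns (annotations) of a 0/1
#' presence/absence matrix independently by UPGMA on Euclidean
#' distances, and returns the matrix reordered by both leaf orders.
#' Reordering is a pure permutation: the multiset of values is
#' unchanged.
#'
#' @param m Binary matrix with >= 2 rows and >= 2 columns.
#' @return A list of class `biclustering`: `row_dendrogram`,
#'   `col_dendrogram` (both `upgma` objects), `reordered` (the permuted
#'   matrix).
#' @export
cluster_bidirectional <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L) stop("degenerate axis: need >= 2 rows")
  if (ncol(m) < 2L) stop("degenerate axis: need >= 2 columns")
  row_dend <- upgma(euclidean_distances(m, "rows"))
  col_dend <- upgma(euclidean_distances(m, "cols"))
  structure(list(row_dendrogram = row_dend,
                 col_dendrogram = col_dend,
                 reordered = m[row_dend$order, col_dend$order,
                               drop = FALSE]),
            class = "biclustering")
}

#' @export
print.biclustering <- function(x, ...) {
  cat(sprintf("Bidirectional UPGMA clustering: %d rows x %d columns\n",
              nrow(x$reordered), ncol(x$reordered)))
  cat("Row leaf order:", paste(rownames(x$reordered), collapse = " "), "\n")
  cat("Column leaf order:", paste(colnames(x$reordered), collapse = " "), "\n")
  invisible(x)
}
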