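# Hierarchical clustering of brain regions by cell-type composition:
# correlation distance between max-normalised regional profiles, Ward
# linkage on those dissimilarities, and flat cuts. Ward's update rule on
# non-Euclidean correlation dissimilarities is formally improper (Ward
# assumes squared Euclidean distances) but is applied verbatim here as the
# method of record; the caveat is documented in the vignette.

#' Correlation distance between regional composition profiles
#'
#' d(r, s) = 1 - Pearson correlation of the cell-type profiles of regions r
#' and s (rows of the matrix). Symmetric, zero diagonal, range [0, 2].
#' Regions with a constant profile (zero variance across cell types) have no
#' defined correlation and are rejected by name.
#'
#' @param m regions x cell-types matrix (typically the max-normalised density
#'   matrix); needs >= 2 columns.
#' @return A dist-like symmetric matrix with regions as dimnames.
#' @export
correlation_distance <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2)
    stop("need at least 2 cell types per region profile", call. = FALSE)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(m)[v == 0] %||% which(v == 0)
    stop("constant profile (correlation undefined) for region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(t(m))
  d[abs(d) < .Machine$double.eps^0.75] <- 0
  diag(d) <- 0
  d
}

#' Agglomerative clustering with Ward's update rule
#'
#' Classic Lance-Williams agglomeration on the given dissimilarity matrix
#' using Ward's coefficients: after merging clusters i and j,
#' d(ij, l) = ((n_i + n_l) d(il) + (n_j + n_l) d(jl) - n_l d(ij)) /
#' (n_i + n_j + n_l). At every step the pair at minimal dissimilarity is
#' merged; exact ties are broken by the lexicographically smallest
#' (min index, max index) pair of current cluster ids, making the tree
#' reproducible across platforms. Heights are the merge dissimilarities, as
#' in `hclust(method = "ward.D")`.
#'
#' @param d symmetric non-negative dissimilarity matrix (e.g. from
#'   [correlation_distance()]).
#' @param method only `"ward"` is implemented.
#' @return A `cluster_tree`: list with `merge` (n-1 x 2, hclust convention:
#'   negative = leaf), `height`, `size` (cluster size after each merge),
#'   `labels`, `order` (leaf order for display). Convertible with
#'   [as.hclust.cluster_tree()].
#' @export
hierarchical_cluster <- function(d, method = "ward") {
  method <- match.arg(method, "ward")
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two leaves", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d))) || any(d < 0))
    stop("dissimilarity matrix must be symmetric and non-negative", call. = FALSE)
  labels <- rownames(d) %||% as.character(seq_len(n))
  size <- rep(1L, n)           # current cluster sizes
  id <- -seq_len(n)            # hclust id of each active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  msize <- integer(n - 1)
  work <- d
  diag(work) <- Inf
  work[lower.tri(work)] <- Inf   # use upper triangle only: (i < j)
  for (step in seq_len(n - 1)) {
    # smallest dissimilarity; ties -> lexicographically smallest (i, j)
    mval <- min(work)
    cand <- which(work == mval, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    merge[step, ] <- sort_merge_pair(id[i], id[j])
    height[step] <- mval
    ni <- size[i]; nj <- size[j]
    msize[step] <- ni + nj
    # Lance-Williams Ward update against every other active cluster
    others <- which(active); others <- others[others != i & others != j]
    for (l in others) {
      dil <- work[min(i, l), max(i, l)]
      djl <- work[min(j, l), max(j, l)]
      nl <- size[l]
      newd <- ((ni + nl) * dil + (nj + nl) * djl - nl * mval) / (ni + nj + nl)
      work[min(i, l), max(i, l)] <- newd
    }
    # cluster j is absorbed into slot i
    active[j] <- FALSE
    size[i] <- ni + nj
    id[i] <- step
    work[j, ] <- Inf; work[, j] <- Inf
  }
  structure(list(merge = merge, height = height, size = msize,
                 labels = labels, order = tree_leaf_order(merge, n)),
            class = "cluster_tree")
}

# hclust convention orders each merge row: singletons (negative) before
# clusters, then increasing
sort_merge_pair <- function(a, b) {
  if (a < 0 && b < 0) c(min(a, b), max(a, b))
  else if (a < 0) c(a, b)
  else if (b < 0) c(b, a)
  else c(min(a, b), max(a, b))
}

# leaf display order: concatenate subtrees recursively from the final merge
tree_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d leaves, %d merges (Ward on given dissimilarities)\n",
              length(x$labels), nrow(x$merge)))
  invisible(x)
}

#' Convert a cluster_tree to an hclust object
#'
#' @param x a `cluster_tree`.
#' @param ... unused.
#' @return An object of class `hclust` (usable with plot, cutree, dendrogram
#'   machinery).
#' @export
as.hclust.cluster_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "ward",
                 call = match.call(), dist.method = "correlation"),
            class = "hclust")
}

#' Cut a cluster tree into k flat clusters
#'
#' Undoes the last k - 1 merges: labels are the connected components after
#' the first n - k merges, numbered 1..k in order of first leaf appearance.
#' The partition at k is always a refinement of the partition at k - 1.
#'
#' @param tree a `cluster_tree`.
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return Integer vector of labels named by leaf.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k))
    stop(sprintf("k must be an integer in [1, %d]", n), call. = FALSE)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  cluster_leaf <- integer(n - 1)   # a representative leaf of each merged node
  steps <- if (n - k >= 1) seq_len(n - k) else integer(0)
  for (s in seq_len(n - 1)) {
    la <- if (tree$merge[s, 1] < 0) -tree$merge[s, 1] else cluster_leaf[tree$merge[s, 1]]
    lb <- if (tree$merge[s, 2] < 0) -tree$merge[s, 2] else cluster_leaf[tree$merge[s, 2]]
    cluster_leaf[s] <- la
    if (s %in% steps) parent[find(lb)] <- find(la)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labs <- match(roots, unique(roots))
  stats::setNames(labs, tree$labels)
}

#' Write a linkage and flat labels as CSV
#'
#' @param tree a `cluster_tree`.
#' @param linkage_path CSV (step, node_a, node_b, height, size).
#' @param labels_path optional CSV of flat labels (needs `k`).
#' @param k cut level for `labels_path`.
#' @export
write_cluster_tree <- function(tree, linkage_path, labels_path = NULL, k = NULL) {
  utils::write.csv(data.frame(step = seq_along(tree$height),
                              node_a = tree$merge[, 1], node_b = tree$merge[, 2],
                              height = tree$height, size = tree$size),
                   linkage_path, row.names = FALSE)
  if (!is.null(labels_path)) {
    stopifnot(!is.null(k))
    labs <- cut_tree(tree, k)
    utils::write.csv(data.frame(leaf = names(labs), cluster = as.integer(labs)),
                     labels_path, row.names = FALSE)
  }
  invisible(linkage_path)
}
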