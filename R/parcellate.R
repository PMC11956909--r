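# Percentile-thresholded DBSCAN parcellation -- the core procedure. For each
# cell in a cloud the number of neighbours within a fixed radius epsilon
# (150 um by default) is counted; per-cell-type percentiles of these counts
# (10th..90th) become MinPoints thresholds; DBSCAN is run once per threshold,
# so low percentiles delineate broad territories and high percentiles only
# the densest foci. Neighbor counts convert to cells/mm^3 through the volume
# of the epsilon-ball.

#' Volume of the epsilon-ball in mm^3
#'
#' @param epsilon_um neighbourhood radius in um.
#' @return (4/3) * pi * (epsilon/1000)^3, in mm^3 (~0.01414 mm^3 at 150 um).
#' @export
eps_ball_volume_mm3 <- function(epsilon_um) {
  stopifnot_scalar_num(epsilon_um, "epsilon_um", positive = TRUE)
  (4 / 3) * pi * (epsilon_um / 1000)^3
}

#' Per-point neighbour counts within a radius
#'
#' For each point p, the number of other points q with ||p - q|| <= epsilon
#' (Euclidean, boundary inclusive, the point itself excluded). Computed with
#' a uniform-grid spatial index but contractually identical to the all-pairs
#' definition.
#'
#' @param points a cell point table, or an n x 3 coordinate matrix in um.
#' @param epsilon_um neighbourhood radius in um.
#' @param subset optional integer indices: counts are computed (and returned)
#'   only for these points, against the full cloud -- used e.g. to restrict
#'   density estimation to interior points.
#' @return Integer vector of counts (length n, or length(subset)).
#' @export
neighbor_counts <- function(points, epsilon_um = 150, subset = NULL) {
  xyz <- as_coords(points)
  n <- nrow(xyz)
  if (n == 0) return(integer(0))
  counts <- integer(n)
  e2 <- epsilon_um^2
  env <- environment()
  grid_sweep(xyz, epsilon_um, subset = subset, FUN = function(qi, cand, d2) {
    env$counts[qi] <- env$counts[qi] + as.integer(rowSums(d2 <= e2)) - 1L
  })
  if (is.null(subset)) counts else counts[subset]
}

as_coords <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    points
  } else point_matrix(points)
}

#' All point pairs within a radius
#'
#' Every unordered pair (i, j), i < j, with ||p_i - p_j|| <= epsilon.
#' Grid-indexed but contractually identical to the all-pairs double loop.
#' This is the shared primitive behind [neighbor_counts()] and [dbscan()]:
#' a sweep over nine MinPoints levels computes it once.
#'
#' @inheritParams neighbor_counts
#' @return Two-column integer matrix of row indices (i < j).
#' @export
neighbor_pairs <- function(points, epsilon_um = 150) {
  xyz <- as_coords(points)
  if (nrow(xyz) == 0) return(matrix(integer(0), 0, 2))
  e2 <- epsilon_um^2
  acc <- new.env(parent = emptyenv())
  acc$chunks <- vector("list", 64); acc$k <- 0L
  grid_sweep(xyz, epsilon_um, FUN = function(qi, cand, d2) {
    hit <- which(d2 <= e2, arr.ind = TRUE, useNames = FALSE)
    i <- qi[hit[, 1]]; j <- cand[hit[, 2]]
    keep <- i < j                       # dedupe + drop self
    if (any(keep)) {
      acc$k <- acc$k + 1L
      acc$chunks[[acc$k]] <- cbind(i[keep], j[keep])
    }
  })
  if (acc$k == 0L) return(matrix(integer(0), 0, 2))
  do.call(rbind, acc$chunks[seq_len(acc$k)])
}

#' Estimate a cloud's density from neighbour counts
#'
#' Mean neighbour count of interior points divided by the epsilon-ball
#' volume. Only points at least epsilon away from the given domain bounds are
#' used, because the epsilon-ball of a boundary point leaves the sampled
#' domain and would bias the estimate downwards (an edge correction).
#'
#' @param points point table or coordinate matrix (um).
#' @param epsilon_um radius in um.
#' @param bounds 2 x 3 matrix (rows = lo, hi of the sampled box in um);
#'   default: the cloud's bounding box.
#' @return Estimated density in cells/mm^3.
#' @export
neighborhood_density <- function(points, epsilon_um = 150, bounds = NULL) {
  xyz <- as_coords(points)
  if (is.null(bounds)) bounds <- rbind(apply(xyz, 2, min), apply(xyz, 2, max))
  interior <- xyz[, 1] >= bounds[1, 1] + epsilon_um & xyz[, 1] <= bounds[2, 1] - epsilon_um &
    xyz[, 2] >= bounds[1, 2] + epsilon_um & xyz[, 2] <= bounds[2, 2] - epsilon_um &
    xyz[, 3] >= bounds[1, 3] + epsilon_um & xyz[, 3] <= bounds[2, 3] - epsilon_um
  if (!any(interior))
    stop("no interior points: domain smaller than 2 * epsilon on some axis",
         call. = FALSE)
  k <- neighbor_counts(xyz, epsilon_um, subset = which(interior))
  mean(k) / eps_ball_volume_mm3(epsilon_um)
}

#' Percentile MinPoints thresholds per cell type
#'
#' For one cell type observed in several subjects: each subject's per-cell
#' neighbour counts are reduced to the requested percentiles (linear
#' interpolation between order statistics); percentiles are averaged over
#' subjects and multiplied by the number of subjects to give the pooled
#' MinPoints (rounded to nearest integer, .5 up) used when clustering the
#' pooled cloud. The per-brain density equivalent of each level is the mean
#' percentile divided by the epsilon-ball volume.
#'
#' @param points cell point table for a single cell type (column `subject_id`
#'   splits subjects). Subjects with no points are dropped with a warning;
#'   if all are empty the call fails.
#' @param epsilon_um radius in um (default 150).
#' @param levels percentile levels in (0, 100); default 10, 20, ..., 90.
#' @return A `threshold_table` data.frame: level, per_subject_percentile_mean,
#'   minpoints_pooled, density_cells_per_mm3, with attributes `epsilon_um`,
#'   `n_subjects`, `cell_type`.
#' @export
percentile_thresholds <- function(points, epsilon_um = 150,
                                  levels = seq(10, 90, by = 10)) {
  if (any(levels <= 0 | levels >= 100))
    stop("percentile levels must lie strictly between 0 and 100", call. = FALSE)
  ct <- unique(points$cell_type)
  if (length(ct) > 1)
    stop("percentile_thresholds expects a single cell type; got: ",
         paste(ct, collapse = ", "), call. = FALSE)
  subj <- split(seq_len(nrow(points)), points$subject_id)
  empty <- lengths(subj) == 0
  if (any(empty)) {
    warning("subject(s) with no points excluded: ",
            paste(names(subj)[empty], collapse = ", "), call. = FALSE)
    subj <- subj[!empty]
  }
  if (!length(subj)) stop("all subjects are empty", call. = FALSE)
  per_subj <- vapply(subj, function(idx) {
    k <- neighbor_counts(point_matrix(points)[idx, , drop = FALSE], epsilon_um)
    stats::quantile(k, levels / 100, names = FALSE, type = 7)
  }, numeric(length(levels)))
  per_subj <- matrix(per_subj, nrow = length(levels))
  n_subjects <- length(subj)
  pmean <- rowMeans(per_subj)
  out <- data.frame(
    level = levels,
    per_subject_percentile_mean = pmean,
    minpoints_pooled = as.integer(round_half_up(pmean * n_subjects)),
    density_cells_per_mm3 = pmean / eps_ball_volume_mm3(epsilon_um))
  structure(out, epsilon_um = epsilon_um, n_subjects = n_subjects,
            cell_type = ct %||% NA_character_,
            class = c("threshold_table", "data.frame"))
}

#' Convert between MinPoints and per-brain density
#'
#' A pooled MinPoints of k over n subjects corresponds to a per-brain density
#' of (k / n) / V_eps cells/mm^3, with V_eps the epsilon-ball volume;
#' `density_to_minpoints` inverts this, rounding to the nearest integer.
#'
#' @param k MinPoints (neighbour count), >= 0.
#' @param epsilon_um radius in um.
#' @param n_subjects number of pooled subjects (>= 1).
#' @return Density in cells/mm^3 (or MinPoints for the inverse).
#' @export
minpoints_to_density <- function(k, epsilon_um = 150, n_subjects = 1) {
  stopifnot(all(k >= 0), n_subjects >= 1)
  (k / n_subjects) / eps_ball_volume_mm3(epsilon_um)
}

#' @param density_cells_per_mm3 per-brain density to invert.
#' @rdname minpoints_to_density
#' @export
density_to_minpoints <- function(density_cells_per_mm3, epsilon_um = 150,
                                 n_subjects = 1) {
  stopifnot(all(density_cells_per_mm3 >= 0), n_subjects >= 1)
  as.integer(round_half_up(density_cells_per_mm3 * n_subjects *
                             eps_ball_volume_mm3(epsilon_um)))
}

#' DBSCAN spatial clustering of a point cloud
#'
#' Standard DBSCAN with this package's conventions: a point is CORE iff its
#' neighbour count (self excluded, boundary inclusive) is >= `minpoints`;
#' clusters are the epsilon-connected components of core points; a non-core
#' point within epsilon of a core point joins the cluster of its lowest-index
#' core neighbour (border point); everything else is noise (cluster -1).
#' Deterministic given the input row order: clusters are numbered 1, 2, ...
#' by their lowest-index core point.
#'
#' @param points cell point table or n x 3 coordinate matrix (um).
#' @param epsilon_um neighbourhood radius in um.
#' @param minpoints core threshold (neighbour count, self excluded).
#' @param pairs optional precomputed [neighbor_pairs()] for these points at
#'   this epsilon (a sweep computes them once and reuses them per level).
#' @return A `parcellation`: list with `cluster` (integer per point, -1 =
#'   noise), `is_core` (logical), `epsilon_um`, `minpoints` and a `clusters`
#'   summary data.frame (id, size, n_core, centroid, bounding box).
#' @export
dbscan <- function(points, epsilon_um = 150, minpoints = 10, pairs = NULL) {
  xyz <- as_coords(points)
  n <- nrow(xyz)
  stopifnot_scalar_num(epsilon_um, "epsilon_um", positive = TRUE)
  stopifnot(minpoints >= 0)
  if (n == 0)
    return(new_parcellation(integer(0), logical(0), epsilon_um, minpoints, xyz))
  if (is.null(pairs)) pairs <- neighbor_pairs(xyz, epsilon_um)
  counts <- tabulate(pairs, nbins = n)
  is_core <- counts >= minpoints
  cluster <- rep(-1L, n)
  if (any(is_core)) {
    core_idx <- which(is_core)
    # clusters = connected components of core points under epsilon-adjacency
    cc <- is_core[pairs[, 1]] & is_core[pairs[, 2]]
    v <- integer(n); v[core_idx] <- seq_along(core_idx)   # compress ids
    g <- igraph::make_graph(
      edges = as.numeric(rbind(v[pairs[cc, 1]], v[pairs[cc, 2]])),
      n = length(core_idx), directed = FALSE)
    comp <- igraph::components(g)$membership
    # number clusters 1..K by their lowest-index core point
    first <- tapply(core_idx, comp, min)
    memb <- as.integer(rank(first))[comp]
    cluster[core_idx] <- memb
    # border points join the cluster of their lowest-index core neighbour
    one_core <- xor(is_core[pairs[, 1]], is_core[pairs[, 2]])
    if (any(one_core)) {
      p1 <- pairs[one_core, 1]; p2 <- pairs[one_core, 2]
      swap <- is_core[p1]                 # put the non-core point first
      b <- ifelse(swap, p2, p1)
      c_ <- ifelse(swap, p1, p2)
      o <- order(b, c_)
      firstb <- !duplicated(b[o])
      cluster[b[o][firstb]] <- cluster[c_[o][firstb]]
    }
  }
  new_parcellation(cluster, is_core, epsilon_um, minpoints, xyz)
}

new_parcellation <- function(cluster, is_core, epsilon_um, minpoints, xyz) {
  ids <- sort(unique(cluster[cluster > 0]))
  summaries <- lapply(ids, function(cid) {
    sel <- cluster == cid
    data.frame(cluster_id = cid, size = sum(sel), n_core = sum(sel & is_core),
               x_um = mean(xyz[sel, 1]), y_um = mean(xyz[sel, 2]),
               z_um = mean(xyz[sel, 3]),
               x_min = min(xyz[sel, 1]), x_max = max(xyz[sel, 1]),
               y_min = min(xyz[sel, 2]), y_max = max(xyz[sel, 2]),
               z_min = min(xyz[sel, 3]), z_max = max(xyz[sel, 3]))
  })
  structure(list(cluster = cluster, is_core = is_core,
                 epsilon_um = epsilon_um, minpoints = minpoints,
                 clusters = if (length(summaries)) do.call(rbind, summaries)
                            else data.frame()),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: eps %.0f um, MinPoints %d -> %d clusters, %d/%d noise\n",
              x$epsilon_um, x$minpoints, nrow(x$clusters),
              sum(x$cluster == -1L), length(x$cluster)))
  invisible(x)
}

#' Run DBSCAN at every percentile threshold
#'
#' One [dbscan()] run per row of the threshold table, all at the table's
#' epsilon, on the same (pooled) cloud; results are returned in level order.
#' Because MinPoints is non-decreasing in the level, the core-point set at a
#' higher level is always a subset of the core-point set at a lower one.
#'
#' @param points the pooled cell point table (all subjects of one cell type).
#' @param thresholds a `threshold_table` from [percentile_thresholds()].
#' @return A named list (`p10`, `p20`, ...) of `parcellation` objects.
#' @export
percentile_sweep <- function(points, thresholds) {
  stopifnot(inherits(thresholds, "threshold_table"))
  eps <- attr(thresholds, "epsilon_um")
  pairs <- neighbor_pairs(points, eps)
  res <- lapply(seq_len(nrow(thresholds)), function(i)
    dbscan(points, eps, thresholds$minpoints_pooled[i], pairs = pairs))
  names(res) <- paste0("p", thresholds$level)
  res
}

#' Overlap between spatial clusters and atlas regions
#'
#' Scores every (cluster, region) pair by Dice and Jaccard overlap of their
#' point sets, plus the fraction of the cluster's points inside the region.
#'
#' @param parcellation a `parcellation`.
#' @param points the same points with a `region_id` column (see
#'   [assign_regions()]).
#' @return Data.frame: cluster_id, region_id, n_overlap, dice, jaccard,
#'   cluster_in_region.
#' @export
cluster_region_overlap <- function(parcellation, points) {
  if (is.null(points$region_id))
    stop("points must carry region_id; run assign_regions() first", call. = FALSE)
  cl <- parcellation$cluster
  stopifnot(length(cl) == nrow(points))
  ids <- sort(unique(cl[cl > 0]))
  regs <- sort(unique(points$region_id[points$region_id > 0]))
  out <- list()
  for (cid in ids) {
    a <- cl == cid
    na <- sum(a)
    for (rid in regs) {
      b <- points$region_id == rid
      nb <- sum(b)
      ov <- sum(a & b)
      out[[length(out) + 1]] <- data.frame(
        cluster_id = cid, region_id = rid, n_overlap = ov,
        dice = if (na + nb > 0) 2 * ov / (na + nb) else 0,
        jaccard = if (na + nb - ov > 0) ov / (na + nb - ov) else 0,
        cluster_in_region = if (na > 0) ov / na else 0)
    }
  }
  if (!length(out))
    return(data.frame(cluster_id = integer(0), region_id = integer(0),
                      n_overlap = integer(0), dice = numeric(0),
                      jaccard = numeric(0), cluster_in_region = numeric(0)))
  do.call(rbind, out)
}

#' Write a percentile sweep as per-point CSV and JSON summary
#'
#' @param sweep named list of `parcellation`s from [percentile_sweep()].
#' @param csv_path per-point CSV (point_index, level, cluster_id, is_core).
#' @param json_path cluster summaries (per level) as JSON.
#' @export
write_sweep <- function(sweep, csv_path, json_path = NULL) {
  per_point <- do.call(rbind, lapply(names(sweep), function(nm) {
    p <- sweep[[nm]]
    data.frame(point_index = seq_along(p$cluster),
               level = as.integer(sub("^p", "", nm)),
               cluster_id = p$cluster, is_core = p$is_core)
  }))
  utils::write.csv(per_point, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- lapply(sweep, function(p)
      list(epsilon_um = p$epsilon_um, minpoints = p$minpoints,
           n_clusters = nrow(p$clusters), n_noise = sum(p$cluster == -1L),
           clusters = p$clusters))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
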