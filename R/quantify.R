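# Region assignment and the region x cell-type density matrix (cells/mm^3)
# with its max-normalised variant -- the composition profiles that feed the
# hierarchical clustering and the two-group comparison.

#' Assign atlas region ids to points
#'
#' Each point is mapped to the voxel containing it (floor of coordinate /
#' spacing, half-open convention: a point exactly on a shared voxel face
#' belongs to the higher-index voxel) and receives that voxel's label.
#' Points outside the volume get region 0 (background); their count is
#' reported via a message and an attribute.
#'
#' @param points a cell point table.
#' @param atlas a `label_volume`.
#' @return `points` with a `region_id` column added and attribute
#'   `n_out_of_bounds`.
#' @export
assign_regions <- function(points, atlas) {
  stopifnot(inherits(atlas, "label_volume"))
  xyz <- point_matrix(points)
  if (nrow(xyz) && any(!is.finite(xyz)))
    stop("point coordinates must be finite", call. = FALSE)
  d <- dim(atlas$labels)
  vox <- cbind(floor(xyz[, 1] / atlas$spacing[1]),
               floor(xyz[, 2] / atlas$spacing[2]),
               floor(xyz[, 3] / atlas$spacing[3]))
  inside <- rep(TRUE, nrow(xyz))
  for (a in 1:3) inside <- inside & vox[, a] >= 0 & vox[, a] < d[a]
  region <- integer(nrow(xyz))
  if (any(inside)) {
    lin <- vox[inside, 1] + d[1] * (vox[inside, 2] + d[2] * vox[inside, 3]) + 1
    region[inside] <- atlas$labels[lin]
  }
  n_oob <- sum(!inside)
  if (n_oob > 0)
    message(sprintf("%d of %d points fall outside the atlas volume (assigned background)",
                    n_oob, nrow(xyz)))
  points$region_id <- region
  attr(points, "n_out_of_bounds") <- n_oob
  points
}

#' Region x cell-type density matrix
#'
#' Counts points per (region, cell type, subject), converts to densities by
#' dividing by the region volume in mm^3, and aggregates across subjects as
#' the unweighted mean density. Background (region 0) points are excluded
#' from the matrix but reported per type so counts are conserved.
#'
#' @param points a cell point table carrying `region_id` (see
#'   [assign_regions()]).
#' @param atlas a `label_volume`; all its regions appear as rows, with zero
#'   counts where no points fall.
#' @return A `region_density_matrix`: list with `counts` and `density`
#'   (3D arrays region x type x subject), `density_mean` (matrix, mean over
#'   subjects), `region_volume_mm3`, `out_of_atlas` (per-type count of
#'   background/out-of-bounds points) and dimension names.
#' @export
region_density_matrix <- function(points, atlas) {
  if (is.null(points$region_id))
    stop("points must carry region_id; run assign_regions() first", call. = FALSE)
  regs <- atlas$regions
  if (any(regs$volume_mm3 <= 0))
    stop("zero-volume region(s): ",
         paste(regs$id[regs$volume_mm3 <= 0], collapse = ", "), call. = FALSE)
  types <- sort(unique(points$cell_type))
  subjects <- unique(points$subject_id)
  rr <- factor(points$region_id, levels = regs$id)
  tt <- factor(points$cell_type, levels = types)
  ss <- factor(points$subject_id, levels = subjects)
  counts <- table(region = rr, cell_type = tt, subject = ss, useNA = "no")
  counts <- array(as.integer(counts), dim = dim(counts), dimnames = dimnames(counts))
  density <- counts / array(regs$volume_mm3,
                            dim = dim(counts))  # recycles along rows (regions)
  density_mean <- apply(density, c(1, 2), mean)
  in_atlas <- !is.na(rr)
  out_of_atlas <- table(factor(points$cell_type[!in_atlas], levels = types))
  groups <- unique(points[c("subject_id", "group")])
  structure(list(counts = counts, density = density,
                 density_mean = density_mean,
                 region_volume_mm3 = stats::setNames(regs$volume_mm3, regs$id),
                 out_of_atlas = stats::setNames(as.integer(out_of_atlas), types),
                 regions = regs, cell_types = types,
                 subjects = stats::setNames(as.character(groups$group),
                                            groups$subject_id)),
            class = "region_density_matrix")
}

#' @export
print.region_density_matrix <- function(x, ...) {
  cat(sprintf("region_density_matrix: %d regions x %d cell types x %d subjects\n",
              nrow(x$density_mean), ncol(x$density_mean), dim(x$counts)[3]))
  cat("mean density (cells/mm3):\n")
  print(round(x$density_mean, 1))
  invisible(x)
}

#' Max-normalise a density matrix
#'
#' Divides each cell-type column by its maximum over regions, mapping every
#' type's regional profile into [0, 1] with its peak region at exactly 1.
#' All-zero columns are left at zero with a warning. The normalisation is
#' invariant to rescaling any column by a positive constant.
#'
#' @param x a `region_density_matrix` (its subject-mean densities are
#'   normalised) or a plain regions x types matrix.
#' @return A matrix of the same shape in [0, 1].
#' @export
max_normalize <- function(x) {
  m <- if (inherits(x, "region_density_matrix")) x$density_mean else as.matrix(x)
  cm <- apply(m, 2, max)
  zero <- cm == 0
  if (any(zero)) {
    warning("all-zero cell-type column(s) left unnormalised: ",
            paste(colnames(m)[zero] %||% which(zero), collapse = ", "),
            call. = FALSE)
    cm[zero] <- 1
  }
  sweep(m, 2, cm, "/")
}

#' Write a density matrix as tidy and wide CSVs
#'
#' @param rdm a `region_density_matrix`.
#' @param tidy_path long CSV (region_id, cell_type, subject_id, count,
#'   density_cells_per_mm3).
#' @param wide_path wide CSV of the max-normalised subject-mean matrix.
#' @export
write_density_matrix <- function(rdm, tidy_path, wide_path = NULL) {
  dn <- dimnames(rdm$counts)
  tidy <- expand.grid(region_id = dn$region, cell_type = dn$cell_type,
                      subject_id = dn$subject, stringsAsFactors = FALSE)
  tidy$count <- as.integer(rdm$counts)
  tidy$density_cells_per_mm3 <- as.numeric(rdm$density)
  utils::write.csv(tidy, tidy_path, row.names = FALSE)
  if (!is.null(wide_path)) {
    norm <- suppressWarnings(max_normalize(rdm))
    utils::write.csv(data.frame(region_id = rownames(norm), norm,
                                check.names = FALSE),
                     wide_path, row.names = FALSE)
  }
  invisible(tidy_path)
}
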