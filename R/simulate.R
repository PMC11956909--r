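# Synthetic cohorts: region-wise homogeneous Poisson point clouds with known
# intensities (cells/mm^3), optional multiplicative group effects, and
# rendered nuclear-image stacks with ground-truth centroids. These emulate
# the point clouds produced by whole-brain two-photon imaging of nuclear
# reporter lines, at the density scale such data show (~2e4-5e5 cells/mm^3).

#' Region-by-cell-type intensity table
#'
#' Declares the generating intensity lambda (cells/mm^3) for each
#' (region, cell type) pair, plus optional multiplicative group effects
#' (e.g. a sex effect on one cell type).
#'
#' @param region_id integer vector of region ids (must exist in the atlas the
#'   table is used with).
#' @param cell_type character vector of cell-type names.
#' @param lambda non-negative intensities, cells/mm^3, recycled against the
#'   longer of `region_id`/`cell_type`.
#' @param group_effects optional data.frame with columns `cell_type`, `group`,
#'   `multiplier` (> 0); intensities of that cell type are multiplied by
#'   `multiplier` for subjects of that group.
#' @return An `intensity_table` data.frame with attribute `group_effects`.
#' @export
intensity_table <- function(region_id, cell_type, lambda, group_effects = NULL) {
  tab <- data.frame(region_id = as.integer(region_id),
                    cell_type = as.character(cell_type),
                    lambda = as.numeric(lambda),
                    stringsAsFactors = FALSE)
  if (any(tab$lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  if (anyDuplicated(tab[c("region_id", "cell_type")]))
    stop("each (region_id, cell_type) pair may appear at most once", call. = FALSE)
  if (!is.null(group_effects)) {
    stopifnot(all(c("cell_type", "group", "multiplier") %in% names(group_effects)))
    if (any(group_effects$multiplier <= 0))
      stop("group multipliers must be > 0", call. = FALSE)
  }
  structure(tab, group_effects = group_effects, class = c("intensity_table", "data.frame"))
}

#' Default demonstration intensities
#'
#' Four cell types across the eight regions of [default_toy_atlas()], with
#' lambdas spanning (at `scale = 1`) the density range regional nuclear
#' densities cover in whole-brain data (~2e4 to 5e5 cells/mm^3), arranged in
#' four blocks of two regions so composition clustering has a planted
#' structure to find. The default `scale = 0.005` keeps a six-subject
#' demonstration cohort near 1e5 points; the block structure and dynamic
#' range are scale-invariant, so clustering and parcellation behave the same
#' at any scale.
#'
#' @param scale multiplier applied to every lambda.
#' @param group_effects passed through to [intensity_table()].
#' @return An `intensity_table`.
#' @export
default_intensity_table <- function(scale = 0.005, group_effects = NULL) {
  types <- c("typeA", "typeB", "typeC", "typeD")
  # rows = regions 1..8 (blocks {1,2}, {3,4}, {5,6}, {7,8}), cols = types
  lam <- matrix(c(
    # typeA   typeB    typeC    typeD
    500000,   50000,   20000,   60000,   # 1 CTX-a
    450000,   60000,   25000,   55000,   # 2 CTX-b
    60000,   400000,   30000,   20000,   # 3 TH
    50000,   350000,   40000,   30000,   # 4 STR
    30000,    40000,  300000,   80000,   # 5 HY
    20000,    50000,  250000,   90000,   # 6 MB
    80000,    20000,   60000,  400000,   # 7 HPF-sph
    90000,    30000,   50000,  450000),  # 8 FC-sph
    nrow = 8, byrow = TRUE, dimnames = list(NULL, types))
  intensity_table(region_id = rep(1:8, times = 4),
                  cell_type = rep(types, each = 8),
                  lambda = as.numeric(lam) * scale,
                  group_effects = group_effects)
}

#' Sample one subject's point cloud from an atlas
#'
#' Within every labelled voxel of each region, the number of cells of each
#' type is Poisson with mean lambda x voxel volume (lambda multiplied by the
#' subject group's effect, if any), and cells are placed uniformly inside the
#' voxel. This is an exact draw of a region-wise homogeneous Poisson process
#' restricted to the labelled voxels.
#'
#' @param atlas a `label_volume`.
#' @param intensities an [intensity_table()].
#' @param subject_id subject identifier stored in the output.
#' @param group group label (matched against the table's group effects).
#' @param seed integer seed; identical seeds give byte-identical tables.
#' @return A cell point table: data.frame `x_um, y_um, z_um, cell_type,
#'   subject_id, group`.
#' @export
sample_point_cloud <- function(atlas, intensities, subject_id = "s1",
                               group = "none", seed = 1L) {
  stopifnot(inherits(atlas, "label_volume"))
  unknown <- setdiff(unique(intensities$region_id), atlas$regions$id)
  if (length(unknown))
    stop("intensity table references unknown region ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ge <- attr(intensities, "group_effects")
  sp <- atlas$spacing
  voxel_mm3 <- prod(sp) / 1e9
  dim_vox <- dim(atlas$labels)
  lab_vec <- as.integer(atlas$labels)
  out <- vector("list", nrow(intensities))
  set.seed(as.integer(seed %% 2147483647))
  # fixed row order: iterate the table sorted by (cell_type, region_id) so the
  # draw sequence does not depend on the table's row order
  ord <- order(intensities$cell_type, intensities$region_id)
  for (i in ord) {
    lam <- intensities$lambda[i]
    ct <- intensities$cell_type[i]
    if (!is.null(ge)) {
      hit <- ge$cell_type == ct & ge$group == group
      if (any(hit)) lam <- lam * prod(ge$multiplier[hit])
    }
    if (lam <= 0) next
    vox <- which(lab_vec == intensities$region_id[i])
    if (!length(vox)) next
    counts <- stats::rpois(length(vox), lam * voxel_mm3)
    tot <- sum(counts)
    if (tot == 0L) next
    vrep <- rep(vox, counts) - 1L
    k <- vrep %/% (dim_vox[1] * dim_vox[2])
    j <- (vrep %% (dim_vox[1] * dim_vox[2])) %/% dim_vox[1]
    ii <- vrep %% dim_vox[1]
    out[[i]] <- data.frame(
      x_um = (ii + stats::runif(tot)) * sp[1],
      y_um = (j + stats::runif(tot)) * sp[2],
      z_um = (k + stats::runif(tot)) * sp[3],
      cell_type = ct, stringsAsFactors = FALSE)
  }
  pts <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pts))
    pts <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      cell_type = character(0), stringsAsFactors = FALSE)
  pts$subject_id <- rep(as.character(subject_id), nrow(pts))
  pts$group <- rep(as.character(group), nrow(pts))
  rownames(pts) <- NULL
  pts
}

#' Sample a multi-subject cohort
#'
#' Each subject's point cloud is drawn with a seed derived deterministically
#' from the root seed and the subject's position (see Details), so a cohort is
#' reproducible as a whole and each subject individually.
#'
#' @details Subject `i` uses seed `(root * 48271 + i * 391) mod (2^31 - 1)`;
#'   the constants are fixed and documented so an external caller can
#'   regenerate any single subject.
#'
#' @param atlas,intensities as in [sample_point_cloud()].
#' @param subjects data.frame with columns `subject_id` and `group`.
#' @param seed root seed.
#' @return A single cell point table with all subjects stacked.
#' @export
sample_cohort <- function(atlas, intensities, subjects, seed = 1L) {
  stopifnot(all(c("subject_id", "group") %in% names(subjects)))
  tabs <- lapply(seq_len(nrow(subjects)), function(i) {
    sample_point_cloud(atlas, intensities,
                       subject_id = subjects$subject_id[i],
                       group = subjects$group[i],
                       seed = derive_seed(seed, i))
  })
  do.call(rbind, tabs)
}

#' Image-stack specification for the nuclei renderer
#'
#' @param shape stack dimensions in voxels (x, y, z).
#' @param spacing voxel spacing in um; the default 1 x 1 x 50 matches
#'   micrometre-resolution serial section imaging with 50 um section spacing.
#' @param nucleus_radius_um Gaussian blob sigma in um (~nuclear radius).
#' @param peak_amplitude blob peak intensity above background.
#' @param background constant background level.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @return An `image_spec`.
#' @export
image_spec <- function(shape = c(256, 256, 8), spacing = c(1, 1, 50),
                       nucleus_radius_um = 3, peak_amplitude = 100,
                       background = 10, noise_sd = 10) {
  stopifnot(length(shape) == 3, length(spacing) == 3)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (nucleus_radius_um <= 0) stop("nucleus_radius_um must be > 0", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 nucleus_radius_um = nucleus_radius_um,
                 peak_amplitude = peak_amplitude, background = background,
                 noise_sd = noise_sd),
            class = "image_spec")
}

#' Render a nuclear-image stack from a point cloud
#'
#' Each point becomes an anisotropy-aware Gaussian blob (sigma =
#' `nucleus_radius_um`, converted to voxels per axis) of the stated amplitude
#' on a constant background, plus independent Gaussian noise. The returned
#' ground-truth centroids are the input points, so detector accuracy can be
#' scored exactly.
#'
#' @param points a cell point table (or any data.frame with `x_um,y_um,z_um`);
#'   all points must lie inside the stack's physical extent.
#' @param spec an [image_spec()].
#' @param seed seed for the noise draw.
#' @return list with `stack` (3D numeric array), `truth` (data.frame of
#'   centroids in um) and `spec`.
#' @export
render_nuclei_stack <- function(points, spec, seed = 1L) {
  stopifnot(inherits(spec, "image_spec"))
  extent <- spec$shape * spec$spacing
  xyz <- point_matrix(points)
  if (nrow(xyz)) {
    bad <- which(xyz[, 1] < 0 | xyz[, 1] >= extent[1] |
                 xyz[, 2] < 0 | xyz[, 2] >= extent[2] |
                 xyz[, 3] < 0 | xyz[, 3] >= extent[3])
    if (length(bad))
      stop("points outside the stack extent at rows: ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  stack <- array(spec$background, dim = spec$shape)
  sig_vox <- spec$nucleus_radius_um / spec$spacing
  half <- pmax(1L, ceiling(3 * sig_vox))
  for (p in seq_len(nrow(xyz))) {
    cv <- xyz[p, ] / spec$spacing + 0.5   # voxel-centre coordinates (1-based)
    ir <- lapply(1:3, function(a) {
      lo <- max(1L, floor(cv[a] - half[a])); hi <- min(spec$shape[a], ceiling(cv[a] + half[a]))
      if (lo > hi) integer(0) else lo:hi
    })
    if (!all(lengths(ir) > 0)) next
    gx <- exp(-(ir[[1]] - cv[1])^2 / (2 * sig_vox[1]^2))
    gy <- exp(-(ir[[2]] - cv[2])^2 / (2 * sig_vox[2]^2))
    gz <- exp(-(ir[[3]] - cv[3])^2 / (2 * sig_vox[3]^2))
    blob <- spec$peak_amplitude * (gx %o% gy %o% gz)
    stack[ir[[1]], ir[[2]], ir[[3]]] <- stack[ir[[1]], ir[[2]], ir[[3]]] + blob
  }
  if (spec$noise_sd > 0) {
    set.seed(as.integer(seed %% 2147483647))
    stack <- stack + array(stats::rnorm(prod(spec$shape), 0, spec$noise_sd),
                           dim = spec$shape)
  }
  truth <- data.frame(x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3])
  list(stack = stack, truth = truth, spec = spec)
}

#' Read or write an image stack as multi-page TIFF
#'
#' Stacks are written one z-slice per page as 32-bit float. Values are scaled
#' by `scale` into [0, 1] on write and unscaled on read, because the TIFF
#' writer stores floats in that range.
#'
#' @param stack 3D numeric array.
#' @param path TIFF path.
#' @param scale divisor applied before writing (default: stack max).
#' @export
write_stack_tiff <- function(stack, path, scale = max(stack, 1e-12)) {
  slices <- lapply(seq_len(dim(stack)[3]), function(k)
    pmin(pmax(t(stack[, , k]) / scale, 0), 1))
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  attr(path, "scale") <- scale
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale = 1) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  arr <- array(0, dim = c(ncol(slices[[1]]), nrow(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- t(slices[[k]])
  arr * scale
}
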