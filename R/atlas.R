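# Toy label-volume atlases: axis-aligned boxes and spheres rasterised onto a
# voxel grid, standing in for a real anatomical reference volume. World
# coordinates are in micrometres, corner-anchored: voxel (i, j, k) (0-based)
# spans the half-open box [i*sx, (i+1)*sx) x [j*sy, (j+1)*sy) x [k*sz, (k+1)*sz),
# and a point belongs to the voxel floor(coord / spacing).

#' Define a toy atlas
#'
#' An atlas specification lists the physical extent and voxel spacing of the
#' volume plus a set of pairwise-disjoint regions, each an axis-aligned box or
#' a sphere in world (micrometre) coordinates. Region id 0 is reserved for
#' background.
#'
#' @param volume_extent numeric length-3, physical size of the volume in um.
#' @param voxel_spacing numeric length-3, voxel size in um (e.g. c(50, 50, 50)).
#' @param regions list of regions created by [box_region()] or
#'   [sphere_region()].
#' @return An object of class `atlas_spec`.
#' @seealso [build_toy_atlas()] which rasterises the specification.
#' @export
atlas_spec <- function(volume_extent, voxel_spacing, regions = list()) {
  stopifnot(length(volume_extent) == 3, length(voxel_spacing) == 3)
  if (any(volume_extent <= 0) || any(voxel_spacing <= 0))
    stop("volume_extent and voxel_spacing must be positive", call. = FALSE)
  ids <- vapply(regions, `[[`, numeric(1), "id")
  if (anyDuplicated(ids)) stop("region ids must be unique", call. = FALSE)
  if (any(ids <= 0)) stop("region ids must be > 0 (0 is background)", call. = FALSE)
  for (r in regions) {
    bb <- region_bbox(r)
    if (any(bb$lo < 0) || any(bb$hi > volume_extent))
      stop(sprintf("region %d ('%s') extends outside the volume extent",
                   r$id, r$name), call. = FALSE)
  }
  structure(list(volume_extent = as.numeric(volume_extent),
                 voxel_spacing = as.numeric(voxel_spacing),
                 regions = regions),
            class = "atlas_spec")
}

#' @param id positive integer region id (unique within the atlas).
#' @param name region name.
#' @param lo,hi opposite corners of the box in um.
#' @rdname atlas_spec
#' @export
box_region <- function(id, name, lo, hi) {
  stopifnot(length(lo) == 3, length(hi) == 3)
  if (any(hi <= lo)) stop("box region must have hi > lo on every axis", call. = FALSE)
  list(id = as.integer(id), name = name, type = "box",
       lo = as.numeric(lo), hi = as.numeric(hi))
}

#' @param center sphere centre in um.
#' @param radius sphere radius in um.
#' @rdname atlas_spec
#' @export
sphere_region <- function(id, name, center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  list(id = as.integer(id), name = name, type = "sphere",
       center = as.numeric(center), radius = as.numeric(radius))
}

region_bbox <- function(r) {
  if (r$type == "box") list(lo = r$lo, hi = r$hi)
  else list(lo = r$center - r$radius, hi = r$center + r$radius)
}

# TRUE for the points (n x 3, um) inside region r's geometry (half-open boxes,
# closed spheres).
region_contains <- function(r, xyz) {
  if (r$type == "box") {
    xyz[, 1] >= r$lo[1] & xyz[, 1] < r$hi[1] &
      xyz[, 2] >= r$lo[2] & xyz[, 2] < r$hi[2] &
      xyz[, 3] >= r$lo[3] & xyz[, 3] < r$hi[3]
  } else {
    (xyz[, 1] - r$center[1])^2 + (xyz[, 2] - r$center[2])^2 +
      (xyz[, 3] - r$center[3])^2 <= r$radius^2
  }
}

#' Rasterise a toy atlas specification into a label volume
#'
#' Each voxel is labelled with the id of the region whose geometry contains
#' the voxel centre (0 = background). Overlapping regions -- two regions
#' claiming the same voxel centre -- are rejected. Reported region volumes are
#' voxel counts times the voxel volume, so they agree exactly with any
#' voxel-centre counting oracle.
#'
#' @param spec an [atlas_spec()].
#' @return A `label_volume`: list with `labels` (3D integer array), `spacing`
#'   (um), `extent` (um) and `regions` (data.frame id, name, n_voxels,
#'   volume_mm3).
#' @export
build_toy_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  dim_vox <- as.integer(round(spec$volume_extent / spec$voxel_spacing))
  labels <- array(0L, dim = dim_vox)
  sp <- spec$voxel_spacing
  # voxel centre coordinates along each axis
  cx <- (seq_len(dim_vox[1]) - 0.5) * sp[1]
  cy <- (seq_len(dim_vox[2]) - 0.5) * sp[2]
  cz <- (seq_len(dim_vox[3]) - 0.5) * sp[3]
  for (r in spec$regions) {
    bb <- region_bbox(r)
    # restrict the test to the voxels whose centres can fall in the bbox
    ix <- which(cx >= bb$lo[1] & cx <= bb$hi[1])
    iy <- which(cy >= bb$lo[2] & cy <= bb$hi[2])
    iz <- which(cz >= bb$lo[3] & cz <= bb$hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- as.matrix(expand.grid(x = cx[ix], y = cy[iy], z = cz[iz]))
    inside <- region_contains(r, g)
    if (!any(inside)) next
    gi <- as.matrix(expand.grid(i = ix, j = iy, k = iz))[inside, , drop = FALSE]
    lin <- gi[, 1] + dim_vox[1] * (gi[, 2] - 1L + dim_vox[2] * (gi[, 3] - 1L))
    clash <- labels[lin] != 0L
    if (any(clash)) {
      other <- labels[lin][which(clash)[1]]
      stop(sprintf("regions %d and %d overlap (share at least one voxel centre)",
                   other, r$id), call. = FALSE)
    }
    labels[lin] <- r$id
  }
  voxel_mm3 <- prod(sp) / 1e9
  counts <- vapply(spec$regions, function(r) sum(labels == r$id), numeric(1))
  regions <- data.frame(
    id = vapply(spec$regions, `[[`, integer(1), "id"),
    name = vapply(spec$regions, `[[`, character(1), "name"),
    n_voxels = as.integer(counts),
    volume_mm3 = counts * voxel_mm3,
    stringsAsFactors = FALSE)
  structure(list(labels = labels, spacing = sp,
                 extent = spec$volume_extent, regions = regions,
                 spec = spec),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s voxels at %s um spacing (%.2f x %.2f x %.2f mm)\n",
              paste(dim(x$labels), collapse = " x "),
              paste(x$spacing, collapse = " x "),
              x$extent[1] / 1e3, x$extent[2] / 1e3, x$extent[3] / 1e3))
  cat(sprintf("%d regions, %.3f mm3 labelled\n",
              nrow(x$regions), sum(x$regions$volume_mm3)))
  invisible(x)
}

#' Default demonstration atlas
#'
#' A 4 x 4 x 2.4 mm toy volume at 50 um isotropic voxels containing eight
#' disjoint regions (six boxes, two spheres) of varied sizes (0.06--1.5 mm3),
#' enough to exercise quantification, clustering and parcellation without any
#' configuration. Geometry is fixed, not random.
#'
#' @return A `label_volume`.
#' @export
default_toy_atlas <- function() {
  spec <- atlas_spec(
    volume_extent = c(4000, 4000, 2400),
    voxel_spacing = c(50, 50, 50),
    regions = list(
      box_region(1L, "CTX-a", lo = c(200, 200, 200),  hi = c(1400, 1400, 1200)),
      box_region(2L, "CTX-b", lo = c(1600, 200, 200), hi = c(2800, 1400, 1200)),
      box_region(3L, "TH",    lo = c(3000, 200, 200), hi = c(3800, 1200, 1000)),
      box_region(4L, "STR",   lo = c(200, 1600, 200), hi = c(1200, 2600, 1000)),
      box_region(5L, "HY",    lo = c(1400, 1600, 200), hi = c(2200, 2400, 900)),
      box_region(6L, "MB",    lo = c(2400, 1600, 200), hi = c(3400, 2500, 1100)),
      sphere_region(7L, "HPF-sph", center = c(1000, 3200, 1600), radius = 500),
      sphere_region(8L, "FC-sph",  center = c(2600, 3200, 1600), radius = 280)
    ))
  build_toy_atlas(spec)
}

#' Read or write a label volume as NIfTI plus a region-table CSV
#'
#' The integer label array is stored as NIfTI-1 with the voxel spacing in the
#' pixdim header field; the region table travels in a sidecar CSV
#' (`id,name,n_voxels,volume_mm3`).
#'
#' @param atlas a `label_volume`.
#' @param nifti_path path to the `.nii`/`.nii.gz` file.
#' @param regions_path path to the region-table CSV; defaults to the NIfTI
#'   path with extension `.regions.csv`.
#' @return `write_label_volume` returns the NIfTI path invisibly;
#'   `read_label_volume` returns a `label_volume` (without the generating
#'   `spec`, which is not serialised).
#' @export
write_label_volume <- function(atlas, nifti_path,
                               regions_path = default_regions_path(nifti_path)) {
  stopifnot(inherits(atlas, "label_volume"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- atlas$spacing / 1000   # stored in mm
  RNifti::pixunits(img) <- "mm"
  RNifti::writeNifti(img, nifti_path)
  utils::write.csv(atlas$regions, regions_path, row.names = FALSE)
  invisible(nifti_path)
}

default_regions_path <- function(nifti_path)
  paste0(sub("\\.nii(\\.gz)?$", "", nifti_path), ".regions.csv")

#' @rdname write_label_volume
#' @export
read_label_volume <- function(nifti_path,
                              regions_path = default_regions_path(nifti_path)) {
  img <- RNifti::readNifti(nifti_path)
  spacing <- RNifti::pixdim(img) * 1000   # stored in mm
  labels <- array(as.integer(img), dim = dim(img))
  regions <- utils::read.csv(regions_path, stringsAsFactors = FALSE)
  structure(list(labels = labels, spacing = spacing,
                 extent = dim(labels) * spacing, regions = regions,
                 spec = NULL),
            class = "label_volume")
}

#' Read or write a cell point table as CSV
#'
#' The point-cloud exchange format used by every stage: one row per cell with
#' columns `x_um`, `y_um`, `z_um`, `cell_type`, `subject_id`, `group` (plus
#' `region_id` once assigned).
#'
#' @param points a `cell point table` data.frame.
#' @param path CSV path.
#' @export
write_point_table <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_point_table
#' @export
read_point_table <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "z_um", "cell_type", "subject_id", "group")
  miss <- setdiff(need, names(pts))
  if (length(miss))
    stop("point table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pts
}

# n x 3 coordinate matrix from a point table
point_matrix <- function(points)
  cbind(points$x_um, points$y_um, points$z_um)
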