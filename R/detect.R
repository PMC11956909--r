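# Unsupervised nuclei detection on 3D stacks: curvature-tensor blobness at a
# nuclear scale, a percentile threshold on the response, 26-connected
# components and a size filter. Also the gamma-compression + Sobel operator
# used to enhance anatomical features before registration, and a matcher that
# scores detections against ground truth.

# --- small array helpers --------------------------------------------------

# shift a 3D array by (dx,dy,dz) voxels with replicate (clamped) boundaries
shift3 <- function(arr, dx, dy, dz) {
  d <- dim(arr)
  ix <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
  arr[ix, iy, iz, drop = FALSE]
}

# separable 1D Gaussian convolution along one axis (replicate boundaries);
# sigma in voxels. Below 0.3 voxels the kernel is a delta and the axis is
# skipped (relevant for 50 um z-spacing, where sigma_z << 1 voxel).
gauss_smooth_axis <- function(arr, sigma, axis) {
  if (sigma < 0.3) return(arr)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  out <- array(0, dim = dim(arr))
  for (t in -r:r) {
    sh <- c(0L, 0L, 0L); sh[axis] <- t
    out <- out + k[t + r + 1] * shift3(arr, sh[1], sh[2], sh[3])
  }
  out
}

gauss_smooth <- function(arr, sigma_vox) {
  for (axis in 1:3) arr <- gauss_smooth_axis(arr, sigma_vox[axis], axis)
  arr
}

# central first difference along an axis, physical units (per um)
diff1 <- function(arr, axis, h_um) {
  sh <- function(t) { s <- c(0L, 0L, 0L); s[axis] <- t; shift3(arr, s[1], s[2], s[3]) }
  (sh(1L) - sh(-1L)) / (2 * h_um)
}

# second difference along an axis, physical units (per um^2)
diff2 <- function(arr, axis, h_um) {
  sh <- function(t) { s <- c(0L, 0L, 0L); s[axis] <- t; shift3(arr, s[1], s[2], s[3]) }
  (sh(1L) - 2 * arr + sh(-1L)) / (h_um^2)
}

# eigenvalues of a field of symmetric 3x3 matrices, analytic (vectorised).
# Inputs are vectors of the six independent entries; returns a 3-column
# matrix of eigenvalues in decreasing order.
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  e1 <- e2 <- e3 <- q
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    e3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2[nz] <- 3 * q[nz] - e1[nz] - e3[nz]
  }
  cbind(e1, e2, e3)
}

# --- feature enhancement --------------------------------------------------

#' Gamma compression followed by a per-slice Sobel operator
#'
#' Rescales the stack to [0, 1] (global min-max), applies intensity^gamma,
#' then computes the 2D Sobel gradient magnitude slice by slice. Because of
#' the rescale step the output is invariant to affine intensity rescaling of
#' the input. A constant stack maps to all zeros.
#'
#' @param stack 3D numeric array.
#' @param gamma positive compression exponent (< 1 compresses bright values).
#' @return Array of the same shape with the edge-enhanced response.
#' @export
enhance_features <- function(stack, gamma = 0.5) {
  stopifnot_scalar_num(gamma, "gamma", positive = TRUE)
  if (length(stack) == 0) stop("stack is empty", call. = FALSE)
  rng <- range(stack)
  x <- if (rng[2] > rng[1]) (stack - rng[1]) / (rng[2] - rng[1])
       else array(0, dim = dim(stack))
  x <- x^gamma
  sob <- function(m) {
    # replicate-padded 3x3 Sobel pair on a 2D slice
    p <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    p <- cbind(p[, 1, drop = FALSE], p, p[, ncol(p), drop = FALSE])
    i <- 2:(nrow(p) - 1); j <- 2:(ncol(p) - 1)
    gx <- (p[i + 1, j - 1] + 2 * p[i + 1, j] + p[i + 1, j + 1]) -
          (p[i - 1, j - 1] + 2 * p[i - 1, j] + p[i - 1, j + 1])
    gy <- (p[i - 1, j + 1] + 2 * p[i, j + 1] + p[i + 1, j + 1]) -
          (p[i - 1, j - 1] + 2 * p[i, j - 1] + p[i + 1, j - 1])
    sqrt(gx^2 + gy^2)
  }
  out <- array(0, dim = dim(x))
  for (k in seq_len(dim(x)[3])) out[, , k] <- sob(x[, , k])
  out
}

# --- nuclei detection -----------------------------------------------------

#' Unsupervised nuclei detection by curvature-tensor blobness
#'
#' The stack is smoothed with an anisotropy-aware Gaussian (sigma in um,
#' converted to voxels per axis), the Gaussian-regularised second-derivative
#' (curvature) tensor is evaluated at every voxel, and a bright-blob score is
#' formed as the product of the clamped negative eigenvalues
#' `prod(max(0, -lambda_i))` -- positive only where the intensity surface
#' curves downwards along all three principal directions. Voxels scoring
#' above the stated percentile of the score distribution are grouped into
#' 26-connected components, filtered by voxel count, and summarised by their
#' score-weighted centroids in um.
#'
#' @param stack 3D numeric array.
#' @param spacing voxel spacing in um (length 3); required so sigma is
#'   interpretable in physical units.
#' @param tensor_sigma_um smoothing scale in um; default 3 (~nuclear radius).
#' @param response_percentile percentile (0-100, exclusive) of the blobness
#'   score above which voxels are kept.
#' @param min_size_vox,max_size_vox component size limits in voxels; the
#'   default floor of 8 exceeds the size of noise speckle, whose spatial
#'   correlation length after Gaussian regularisation at sigma ~3 voxels
#'   produces spurious components of up to ~7 voxels, while in-focus nuclei
#'   span tens of voxels at micrometre sampling.
#' @return A `detection_result`: list with `centroids` (data.frame x_um, y_um,
#'   z_um, component_id, size_voxels), `label` (integer component array) and
#'   the parameters used.
#' @export
detect_nuclei <- function(stack, spacing, tensor_sigma_um = 3,
                          response_percentile = 99,
                          min_size_vox = 8, max_size_vox = Inf) {
  if (missing(spacing) || is.null(spacing) || length(spacing) != 3 ||
      any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel `spacing` (um, length 3) is required so sigma is interpretable in um",
         call. = FALSE)
  stopifnot_scalar_num(tensor_sigma_um, "tensor_sigma_um", positive = TRUE)
  if (response_percentile <= 0 || response_percentile >= 100)
    stop("response_percentile must be strictly between 0 and 100", call. = FALSE)
  sig_vox <- tensor_sigma_um / spacing
  sm <- gauss_smooth(stack, sig_vox)
  h11 <- diff2(sm, 1, spacing[1]); h22 <- diff2(sm, 2, spacing[2])
  h33 <- diff2(sm, 3, spacing[3])
  h12 <- diff1(diff1(sm, 1, spacing[1]), 2, spacing[2])
  h13 <- diff1(diff1(sm, 1, spacing[1]), 3, spacing[3])
  h23 <- diff1(diff1(sm, 2, spacing[2]), 3, spacing[3])
  ev <- sym3_eigenvalues(as.numeric(h11), as.numeric(h22), as.numeric(h33),
                         as.numeric(h12), as.numeric(h13), as.numeric(h23))
  score <- pmax(0, -ev[, 1]) * pmax(0, -ev[, 2]) * pmax(0, -ev[, 3])
  thr <- stats::quantile(score, response_percentile / 100, names = FALSE, type = 7)
  mask <- array(score > thr, dim = dim(stack))
  lab <- label_components_26(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size_vox & sizes <= max_size_vox)
  # relabel surviving components 1..K in order of first appearance
  remap <- integer(length(sizes)); remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  cent <- component_centroids(lab, array(score, dim = dim(stack)), spacing)
  structure(list(centroids = cent, label = lab,
                 params = list(spacing = spacing,
                               tensor_sigma_um = tensor_sigma_um,
                               response_percentile = response_percentile,
                               min_size_vox = min_size_vox,
                               max_size_vox = max_size_vox,
                               score_threshold = thr)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result: %d components (sigma %.1f um, pct %.1f)\n",
              nrow(x$centroids), x$params$tensor_sigma_um,
              x$params$response_percentile))
  invisible(x)
}

# 26-connected components of a logical 3D mask via an edge list over the 13
# half-neighborhood offsets and igraph's component search.
label_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dim = d)
  if (!length(idx)) return(lab)
  pos <- arrayInd(idx, d)
  key <- (pos[, 1] - 1) + d[1] * ((pos[, 2] - 1) + d[2] * (pos[, 3] - 1))
  vid <- integer(prod(d)); vid[key + 1] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[1:13, , drop = FALSE]   # half neighborhood (lexicographically first 13)
  efrom <- integer(0); eto <- integer(0)
  for (o in seq_len(nrow(offs))) {
    np <- cbind(pos[, 1] + offs[o, 1], pos[, 2] + offs[o, 2], pos[, 3] + offs[o, 3])
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(ok)) next
    nkey <- (np[ok, 1] - 1) + d[1] * ((np[ok, 2] - 1) + d[2] * (np[ok, 3] - 1))
    nv <- vid[nkey + 1]
    hit <- nv > 0L
    efrom <- c(efrom, which(ok)[hit])
    eto <- c(eto, nv[hit])
  }
  g <- igraph::make_graph(edges = as.numeric(rbind(efrom, eto)),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber by first voxel occurrence so ids are deterministic
  first <- tapply(seq_along(idx), comp, min)
  ord <- rank(first)
  lab[idx] <- as.integer(ord[comp])
  lab
}

component_centroids <- function(lab, weight, spacing) {
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      component_id = integer(0), size_voxels = integer(0)))
  comp <- lab[idx]
  pos <- arrayInd(idx, dim(lab))
  w <- weight[idx]
  wsum <- tapply(w, comp, sum)
  cx <- tapply(w * (pos[, 1] - 0.5) * spacing[1], comp, sum) / wsum
  cy <- tapply(w * (pos[, 2] - 0.5) * spacing[2], comp, sum) / wsum
  cz <- tapply(w * (pos[, 3] - 0.5) * spacing[3], comp, sum) / wsum
  size <- as.integer(table(comp))
  data.frame(x_um = as.numeric(cx), y_um = as.numeric(cy), z_um = as.numeric(cz),
             component_id = as.integer(names(wsum)), size_voxels = size)
}

# --- detection scoring ----------------------------------------------------

#' Score detections against ground truth
#'
#' Builds the bipartite graph linking each detection to every truth point
#' within `radius_um` and finds a maximum-cardinality one-to-one matching
#' (augmenting paths; the TP/FP/FN counts depend only on the maximum
#' cardinality, which is unique). Mean centroid error is averaged over the
#' matched pairs; when several maximum matchings exist their mean distances
#' can differ slightly.
#'
#' @param detected,truth data.frames with `x_um`, `y_um`, `z_um` (either may
#'   be empty).
#' @param radius_um maximum centre distance for a detection to count as a hit.
#' @return A `detection_metrics` list: tp, fp, fn, precision, recall, f1,
#'   mean_centroid_error_um, and the matched index pairs.
#' @export
match_detections <- function(detected, truth, radius_um = 5) {
  stopifnot_scalar_num(radius_um, "radius_um", positive = TRUE)
  nd <- nrow(detected); nt <- nrow(truth)
  adj <- vector("list", nd)
  if (nd > 0 && nt > 0) {
    dm <- sqrt(cross_dist2(point_matrix_xyz(detected), point_matrix_xyz(truth)))
    for (i in seq_len(nd)) {
      cand <- which(dm[i, ] <= radius_um)
      adj[[i]] <- cand[order(dm[i, cand])]   # try nearest truth first
    }
  }
  match_t <- rep(NA_integer_, nt)   # truth -> detection
  seen <- rep(FALSE, nt)
  try_augment <- function(i) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <<- TRUE
      if (is.na(match_t[j]) || try_augment(match_t[j])) {
        match_t[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(nd)) {
    seen <- rep(FALSE, nt)
    try_augment(i)
  }
  tp <- sum(!is.na(match_t))
  fp <- nd - tp; fn <- nt - tp
  err <- if (tp > 0) {
    j <- which(!is.na(match_t))
    mean(sqrt(rowSums((point_matrix_xyz(truth)[j, , drop = FALSE] -
                       point_matrix_xyz(detected)[match_t[j], , drop = FALSE])^2)))
  } else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, mean_centroid_error_um = err,
                 matches = data.frame(detected = match_t[!is.na(match_t)],
                                      truth = which(!is.na(match_t)))),
            class = "detection_metrics")
}

point_matrix_xyz <- function(df) cbind(df$x_um, df$y_um, df$z_um)

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("detection_metrics: TP %d FP %d FN %d  precision %.3f recall %.3f F1 %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  if (!is.na(x$mean_centroid_error_um))
    cat(sprintf("mean centroid error %.2f um\n", x$mean_centroid_error_um))
  invisible(x)
}
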