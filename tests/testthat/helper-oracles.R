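# Independent reference implementations (deliberately naive) and fixture
# builders shared across the test files. The oracles never call the package
# code paths they check.

# O(n^2) neighbour counts: all-pairs double definition, boundary inclusive
brute_neighbor_counts <- function(xyz, eps) {
  D <- as.matrix(stats::dist(xyz))
  as.integer(rowSums(D <= eps) - 1L)
}

# Reference DBSCAN: all-pairs distance matrix + breadth-first search over
# core points; border points take the cluster of their lowest-index core
# neighbour (the same tie rule the package documents).
ref_dbscan <- function(xyz, eps, minpts) {
  D <- as.matrix(stats::dist(xyz))
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) setdiff(which(D[i, ] <= eps), i))
  core <- lengths(nb) >= minpts
  cl <- rep(-1L, n)
  cur <- 0L
  for (i in which(core)) {
    if (cl[i] > 0) next
    cur <- cur + 1L
    queue <- i
    cl[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if (core[w] && cl[w] < 0) { cl[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) cl[i] <- cl[min(cn)]
  }
  cl
}

# two labelings describe the same partition (noise label -1 must map to -1)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1, b == -1)) return(FALSE)
  keep <- a != -1
  if (!any(keep)) return(TRUE)
  tab <- table(a[keep], b[keep])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# point cloud with three well-separated Gaussian blobs + uniform outliers
blob_cloud <- function(n_blob = 100, n_noise = 30, sd = 30, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(250, 250, 250), c(750, 250, 250), c(500, 750, 600))
  pts <- do.call(rbind, lapply(1:3, function(b)
    cbind(rnorm(n_blob, centers[b, 1], sd), rnorm(n_blob, centers[b, 2], sd),
          rnorm(n_blob, centers[b, 3], sd))))
  rbind(pts, cbind(runif(n_noise, 0, 1000), runif(n_noise, 0, 1000),
                   runif(n_noise, 0, 800)))
}

# small two-box atlas for quantification tests (1.6 x 1.6 x 0.8 mm, 50 um)
tiny_atlas <- function() {
  build_toy_atlas(atlas_spec(
    volume_extent = c(1600, 1600, 800),
    voxel_spacing = c(50, 50, 50),
    regions = list(
      box_region(1L, "left",  lo = c(100, 100, 100), hi = c(700, 1500, 700)),
      box_region(2L, "right", lo = c(900, 100, 100), hi = c(1500, 1500, 700)))))
}

# dart-throwing placement: n points in a stack's extent, same-slice pairs at
# least min_sep_um apart in-plane, at slice centres in z
separated_nuclei <- function(n, shape, spacing, min_sep_um = 12,
                             margin_um = 5, seed = 1) {
  set.seed(seed)
  ext <- shape * spacing
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    cand <- c(runif(1, margin_um, ext[1] - margin_um),
              runif(1, margin_um, ext[2] - margin_um),
              (sample(shape[3], 1) - 0.5) * spacing[3])
    same <- pts[pts[, 3] == cand[3], , drop = FALSE]
    if (nrow(same) == 0 ||
        min(sqrt((same[, 1] - cand[1])^2 + (same[, 2] - cand[2])^2)) >= min_sep_um)
      pts <- rbind(pts, cand)
  }
  data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3])
}

# the standard detection fixture: 200 nuclei, peak/noise = 10
detection_fixture <- function(seed, n = 200) {
  sp <- image_spec(shape = c(400, 400, 8), spacing = c(1, 1, 50),
                   nucleus_radius_um = 3, peak_amplitude = 100,
                   background = 10, noise_sd = 10)
  pts <- separated_nuclei(n, sp$shape, sp$spacing, min_sep_um = 14, seed = seed)
  render_nuclei_stack(pts, sp, seed = seed + 1000)
}

detect_standard <- function(stack, spacing = c(1, 1, 50)) {
  detect_nuclei(stack, spacing = spacing, tensor_sigma_um = 3,
                response_percentile = 99.5, min_size_vox = 8)
}

# homogeneous Poisson cloud of intensity lambda (cells/mm^3) in a box (um)
poisson_box <- function(lambda, box_um, seed) {
  set.seed(seed)
  vol_mm3 <- prod(box_um) / 1e9
  n <- rpois(1, lambda * vol_mm3)
  cbind(runif(n, 0, box_um[1]), runif(n, 0, box_um[2]), runif(n, 0, box_um[3]))
}

# spherical insert of intensity lambda_in inside a background box, returning
# coordinates plus the ground-truth membership flag
planted_insert_cloud <- function(lambda_bg, lambda_in, box_um, center_um,
                                 radius_um, seed) {
  set.seed(seed)
  vol_mm3 <- prod(box_um) / 1e9
  nbg <- rpois(1, lambda_bg * vol_mm3)
  bg <- cbind(runif(nbg, 0, box_um[1]), runif(nbg, 0, box_um[2]),
              runif(nbg, 0, box_um[3]))
  inside <- sqrt((bg[, 1] - center_um[1])^2 + (bg[, 2] - center_um[2])^2 +
                   (bg[, 3] - center_um[3])^2) <= radius_um
  bg <- bg[!inside, , drop = FALSE]   # carve the sphere out of the background
  sph_mm3 <- (4 / 3) * pi * (radius_um / 1000)^3
  nin <- rpois(1, lambda_in * sph_mm3)
  acc <- matrix(NA_real_, 0, 3)
  while (nrow(acc) < nin) {
    m <- 2 * (nin - nrow(acc)) + 20
    cand <- cbind(runif(m, -radius_um, radius_um), runif(m, -radius_um, radius_um),
                  runif(m, -radius_um, radius_um))
    cand <- cand[rowSums(cand^2) <= radius_um^2, , drop = FALSE]
    acc <- rbind(acc, cand)
  }
  ins <- sweep(acc[seq_len(nin), , drop = FALSE], 2, center_um, "+")
  list(xyz = rbind(bg, ins),
       is_insert = c(rep(FALSE, nrow(bg)), rep(TRUE, nin)))
}

# planted 4-block composition matrix: 8 regions x 4 types, block-distinct
# profiles with multiplicative lognormal noise of the given CV
planted_block_matrix <- function(noise_cv, seed) {
  set.seed(seed)
  base <- matrix(20000, 8, 4, dimnames = list(paste0("r", 1:8),
                                              paste0("t", 1:4)))
  for (b in 1:4) base[c(2 * b - 1, 2 * b), b] <- 400000
  base * matrix(exp(rnorm(32, 0, noise_cv)), 8, 4)
}

# per-subject long density table for the group-comparison simulations.
# Between-subject noise is Gaussian with sd = cv * mean -- the large-count
# Poisson limit of regional densities -- so the calibration checks probe the
# Welch stage under its own distributional assumptions.
simulated_density_long <- function(n_per_group, n_regions, n_types, cv,
                                   effect_type = NULL, effect = 1, seed = 1) {
  set.seed(seed)
  subjects <- sprintf("s%02d", seq_len(2 * n_per_group))
  groups <- rep(c("g1", "g2"), each = n_per_group)
  grid <- expand.grid(region_id = seq_len(n_regions),
                      cell_type = paste0("t", seq_len(n_types)),
                      subject_id = subjects, stringsAsFactors = FALSE)
  grid$group <- groups[match(grid$subject_id, subjects)]
  mu <- 1e5
  grid$density <- mu * (1 + stats::rnorm(nrow(grid), 0, cv))
  if (!is.null(effect_type)) {
    hit <- grid$cell_type == effect_type & grid$group == "g1"
    grid$density[hit] <- grid$density[hit] * effect
  }
  grid
}
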