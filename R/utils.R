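# Internal helpers shared across modules: half-up rounding, deterministic
# per-subject seed streams, and the uniform-grid spatial index used by the
# neighbor-count and DBSCAN code.

# round-half-up; base round() is banker's rounding (round(4.5) == 4)
round_half_up <- function(x) floor(x + 0.5)

# Deterministic per-subject seed stream: subject i under root seed s draws
# seed (s * 48271 + i * 391) mod (2^31 - 1). 48271 is the MINSTD multiplier;
# the derivation only needs to be fixed and collision-sparse within a cohort,
# not cryptographic. Result always fits a 32-bit R integer.
derive_seed <- function(root_seed, index) {
  m <- 2147483647
  ((root_seed %% m) * 48271 + (index %% m) * 391) %% m
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# --- uniform grid spatial index ------------------------------------------

# Bin points (n x 3 matrix, um) into cubic cells of side `cell`; returns the
# cell id per point plus an ordering so points of one cell are contiguous.
grid_index <- function(xyz, cell) {
  ix <- floor(xyz[, 1] / cell)
  iy <- floor(xyz[, 2] / cell)
  iz <- floor(xyz[, 3] / cell)
  ix <- ix - min(ix); iy <- iy - min(iy); iz <- iz - min(iz)
  nx <- max(ix) + 1; ny <- max(iy) + 1; nz <- max(iz) + 1
  id <- ix + nx * (iy + ny * iz)
  ord <- order(id)
  list(id = id, ord = ord, nx = nx, ny = ny, nz = nz,
       starts = c(0L, cumsum(tabulate(id[ord] + 1L, nbins = nx * ny * nz))))
}

# For each distinct nonempty cell, the point indices in it and in its 26
# neighbors. Returns a function(cid) -> list(self = idx, nbhd = idx).
grid_neighborhood_lookup <- function(gi) {
  nx <- gi$nx; ny <- gi$ny; nz <- gi$nz
  pts_sorted <- gi$ord
  starts <- gi$starts
  cell_points <- function(cid) {
    # cid is 0-based
    a <- starts[cid + 1L] + 1L
    b <- starts[cid + 2L]
    if (b < a) integer(0) else pts_sorted[a:b]
  }
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  function(cid) {
    cz <- cid %/% (nx * ny)
    rem <- cid %% (nx * ny)
    cy <- rem %/% nx
    cx <- rem %% nx
    nbx <- cx + offsets[, 1]; nby <- cy + offsets[, 2]; nbz <- cz + offsets[, 3]
    ok <- nbx >= 0 & nbx < nx & nby >= 0 & nby < ny & nbz >= 0 & nbz < nz
    ncells <- nbx[ok] + nx * (nby[ok] + ny * nbz[ok])
    list(self = cell_points(cid),
         nbhd = unlist(lapply(ncells, cell_points), use.names = FALSE))
  }
}

# Squared Euclidean cross-distances between rows of a (m x 3) and b (k x 3).
cross_dist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 +
    outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2
}

# Apply FUN(query_idx, cand_idx, d2) for every nonempty grid cell (or only
# cells containing `subset` points), chunking queries so the distance block
# stays under ~2.5e6 doubles. FUN sees squared distances to all candidate
# points in the 27-cell neighborhood (self included in candidates).
grid_sweep <- function(xyz, epsilon, subset = NULL, FUN) {
  n <- nrow(xyz)
  gi <- grid_index(xyz, epsilon)
  lookup <- grid_neighborhood_lookup(gi)
  cells <- if (is.null(subset)) unique(gi$id) else unique(gi$id[subset])
  keep <- if (is.null(subset)) NULL else rep(FALSE, n)
  if (!is.null(subset)) keep[subset] <- TRUE
  for (cid in cells) {
    pts <- lookup(cid)
    q <- pts$self
    if (!is.null(keep)) q <- q[keep[q]]
    if (length(q) == 0L) next
    cand <- pts$nbhd
    block <- max(1L, floor(2.5e6 / max(1L, length(cand))))
    for (s in seq(1L, length(q), by = block)) {
      qi <- q[s:min(length(q), s + block - 1L)]
      d2 <- cross_dist2(xyz[qi, , drop = FALSE], xyz[cand, , drop = FALSE])
      FUN(qi, cand, d2)
    }
  }
  invisible(NULL)
}
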