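# Synthetic-brain generator: atlas rasterisation, Poisson point clouds,
# image rendering.

test_that("toy atlas rasterisation matches voxel-centre counting", {
  # 1 mm cube inside a 2 mm volume at 50 um voxels: (1000/50)^3 voxels
  at <- build_toy_atlas(atlas_spec(
    volume_extent = c(2000, 2000, 2000), voxel_spacing = c(50, 50, 50),
    regions = list(box_region(1L, "cube", lo = c(500, 500, 500),
                              hi = c(1500, 1500, 1500)))))
  expect_equal(at$regions$n_voxels, 8000L)
  expect_equal(at$regions$volume_mm3, 1.0)
  expect_equal(sum(at$labels != 0L), 8000L)

  # empty region list -> all-background volume, empty region table
  empty <- build_toy_atlas(atlas_spec(c(1000, 1000, 1000), c(100, 100, 100)))
  expect_true(all(empty$labels == 0L))
  expect_equal(nrow(empty$regions), 0L)

  # boxes sharing a face: half-open voxels -> accepted, volumes additive,
  # and each label equals a brute-force point-in-box test of voxel centres
  spec <- atlas_spec(
    volume_extent = c(1200, 800, 800), voxel_spacing = c(50, 50, 50),
    regions = list(
      box_region(1L, "a", lo = c(100, 100, 100), hi = c(600, 700, 700)),
      box_region(2L, "b", lo = c(600, 100, 100), hi = c(1100, 700, 700))))
  at2 <- build_toy_atlas(spec)
  expect_equal(sum(at2$regions$volume_mm3), sum(at2$labels != 0) * 0.05^3)
  centres <- as.matrix(expand.grid(
    x = (seq_len(dim(at2$labels)[1]) - 0.5) * 50,
    y = (seq_len(dim(at2$labels)[2]) - 0.5) * 50,
    z = (seq_len(dim(at2$labels)[3]) - 0.5) * 50))
  want <- integer(nrow(centres))
  for (r in spec$regions) {
    inside <- centres[, 1] >= r$lo[1] & centres[, 1] < r$hi[1] &
      centres[, 2] >= r$lo[2] & centres[, 2] < r$hi[2] &
      centres[, 3] >= r$lo[3] & centres[, 3] < r$hi[3]
    want[inside] <- r$id
  }
  expect_identical(as.integer(at2$labels), want)
})

test_that("atlas geometry errors are caught by name", {
  expect_error(build_toy_atlas(atlas_spec(
    volume_extent = c(1000, 1000, 1000), voxel_spacing = c(50, 50, 50),
    regions = list(
      box_region(1L, "a", lo = c(100, 100, 100), hi = c(600, 600, 600)),
      box_region(2L, "b", lo = c(400, 400, 400), hi = c(900, 900, 900))))),
    "1 and 2 overlap")
  expect_error(atlas_spec(
    volume_extent = c(1000, 1000, 1000), voxel_spacing = c(50, 50, 50),
    regions = list(box_region(1L, "big", lo = c(0, 0, 0),
                              hi = c(2000, 500, 500)))),
    "outside the volume extent")
  expect_error(atlas_spec(c(1000, 1000, 1000), c(50, 50, 50),
    regions = list(box_region(1L, "a", c(0, 0, 0), c(500, 500, 500)),
                   box_region(1L, "b", c(600, 600, 600), c(900, 900, 900)))),
    "unique")
})

test_that("sphere volumes agree with brute-force voxel-centre counts", {
  at <- build_toy_atlas(atlas_spec(
    volume_extent = c(1500, 1500, 1500), voxel_spacing = c(30, 30, 30),
    regions = list(sphere_region(3L, "ball", center = c(700, 800, 600),
                                 radius = 400))))
  centres <- as.matrix(expand.grid(
    x = (seq_len(50) - 0.5) * 30, y = (seq_len(50) - 0.5) * 30,
    z = (seq_len(50) - 0.5) * 30))
  n_inside <- sum((centres[, 1] - 700)^2 + (centres[, 2] - 800)^2 +
                    (centres[, 3] - 600)^2 <= 400^2)
  expect_equal(at$regions$n_voxels, n_inside)
  expect_equal(at$regions$volume_mm3, n_inside * 0.03^3)
})

test_that("point clouds are Poisson at the requested intensity", {
  at <- tiny_atlas()   # two 0.216 mm3 ... boxes; volumes from the table
  vol <- at$regions$volume_mm3[1]
  lam <- 50000
  it <- intensity_table(1L, "t", lam)
  counts <- vapply(1:60, function(s)
    nrow(sample_point_cloud(at, it, seed = s)), numeric(1))
  expected <- lam * vol
  se <- sqrt(expected / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # all-zero intensities -> empty table with the full column set
  none <- sample_point_cloud(at, intensity_table(1:2, "t", 0), seed = 1)
  expect_equal(nrow(none), 0L)
  expect_named(none, c("x_um", "y_um", "z_um", "cell_type", "subject_id", "group"))
})

test_that("sampling is deterministic and validated", {
  at <- tiny_atlas()
  it <- intensity_table(c(1L, 2L), c("a", "b"), c(20000, 30000))
  p1 <- sample_point_cloud(at, it, subject_id = "sX", group = "m", seed = 99)
  p2 <- sample_point_cloud(at, it, subject_id = "sX", group = "m", seed = 99)
  expect_identical(p1, p2)
  expect_error(sample_point_cloud(at, intensity_table(7L, "a", 1000), seed = 1),
               "unknown region")
  # all points land inside voxels labelled with their region
  p1r <- assign_regions(p1, at)
  expect_true(all(p1r$region_id[p1r$cell_type == "a"] == 1L))
  expect_true(all(p1r$region_id[p1r$cell_type == "b"] == 2L))
})

test_that("group multipliers scale intensities multiplicatively", {
  at <- tiny_atlas()
  ge <- data.frame(cell_type = "a", group = "m", multiplier = 2)
  it <- intensity_table(1L, "a", 30000, group_effects = ge)
  n_f <- mean(vapply(1:30, function(s)
    nrow(sample_point_cloud(at, it, group = "f", seed = s)), numeric(1)))
  n_m <- mean(vapply(1:30, function(s)
    nrow(sample_point_cloud(at, it, group = "m", seed = 1000 + s)), numeric(1)))
  expect_gt(n_m / n_f, 1.8)
  expect_lt(n_m / n_f, 2.2)
})

test_that("per-subject cohort streams are deterministic and distinct", {
  at <- tiny_atlas()
  it <- intensity_table(1L, "a", 20000)
  subjects <- data.frame(subject_id = c("s1", "s2"), group = c("g1", "g2"))
  c1 <- sample_cohort(at, it, subjects, seed = 5)
  c2 <- sample_cohort(at, it, subjects, seed = 5)
  expect_identical(c1, c2)
  s1 <- c1[c1$subject_id == "s1", c("x_um", "y_um", "z_um")]
  s2 <- c1[c1$subject_id == "s2", c("x_um", "y_um", "z_um")]
  expect_false(isTRUE(all.equal(s1[seq_len(min(nrow(s1), nrow(s2))), ],
                                s2[seq_len(min(nrow(s1), nrow(s2))), ])))
})

test_that("rendered stacks honour background, peaks and noise level", {
  sp <- image_spec(shape = c(40, 40, 4), noise_sd = 0)
  blank <- render_nuclei_stack(data.frame(x_um = numeric(0), y_um = numeric(0),
                                          z_um = numeric(0)), sp)
  expect_true(all(blank$stack == sp$background))

  # one point at a voxel centre -> global maximum at that voxel
  one <- render_nuclei_stack(data.frame(x_um = 20.5, y_um = 10.5, z_um = 75),
                             sp)
  expect_equal(which.max(one$stack),
               21L + 40L * (11L - 1L) + 40L * 40L * (2L - 1L))
  expect_equal(max(one$stack), sp$background + sp$peak_amplitude)

  # noise sd recovered from a blob-free corner
  spn <- image_spec(shape = c(64, 64, 4), peak_amplitude = 100, noise_sd = 10)
  r <- render_nuclei_stack(data.frame(x_um = 50, y_um = 50, z_um = 75), spn,
                           seed = 3)
  corner <- r$stack[40:64, 40:64, 3:4]
  expect_lt(abs(stats::sd(corner) - 10) / 10, 0.05)

  expect_error(render_nuclei_stack(data.frame(x_um = -5, y_um = 1, z_um = 1),
                                   sp), "outside the stack extent")
})
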