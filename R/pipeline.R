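# End-to-end orchestration: generate a synthetic cohort, quantify regional
# densities, cluster region composition, run the percentile-DBSCAN sweep on
# one focal cell type, and compare the two groups. One YAML-serialisable
# config, one root seed, a manifest with content hashes of every output.

#' Pipeline configuration
#'
#' Validated container for every knob of [run_pipeline()]. All randomness
#' derives from `seed`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed root integer seed.
#' @param epsilon_um DBSCAN radius in um (default 150).
#' @param levels percentile levels for the MinPoints sweep.
#' @param k flat cut level for the composition clustering.
#' @param alpha FDR level for the group comparison.
#' @param n_per_group subjects per group in the generated cohort.
#' @param intensity_scale scale factor for [default_intensity_table()].
#' @param focal_cell_type cell type used for the parcellation sweep.
#' @param group_effect optional multiplier applied to `focal_cell_type` in
#'   group "g1" (1 = no effect).
#' @param stages character subset of
#'   c("generate","quantify","cluster","parcellate","compare").
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, epsilon_um = 150,
                            levels = seq(10, 90, by = 10), k = 4,
                            alpha = 0.05, n_per_group = 3,
                            intensity_scale = 0.005,
                            focal_cell_type = "typeA",
                            group_effect = 1,
                            stages = c("generate", "quantify", "cluster",
                                       "parcellate", "compare")) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              epsilon_um = epsilon_um, levels = levels, k = k, alpha = alpha,
              n_per_group = n_per_group, intensity_scale = intensity_scale,
              focal_cell_type = focal_cell_type, group_effect = group_effect,
              stages = stages)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!is.character(cfg$out_dir) || length(cfg$out_dir) != 1)
    stop("config field `out_dir` must be a single path", call. = FALSE)
  if (!is.numeric(cfg$epsilon_um) || cfg$epsilon_um <= 0)
    stop("config field `epsilon_um` must be > 0", call. = FALSE)
  if (any(cfg$levels <= 0 | cfg$levels >= 100))
    stop("config field `levels` must lie strictly in (0, 100)", call. = FALSE)
  if (cfg$k < 1) stop("config field `k` must be >= 1", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config field `alpha` must lie in (0, 1)", call. = FALSE)
  if (cfg$n_per_group < 1)
    stop("config field `n_per_group` must be >= 1", call. = FALSE)
  if (cfg$group_effect <= 0)
    stop("config field `group_effect` must be > 0", call. = FALSE)
  bad <- setdiff(cfg$stages, c("generate", "quantify", "cluster",
                               "parcellate", "compare"))
  if (length(bad))
    stop("config field `stages` has unknown stage(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' Read / write a pipeline config as YAML
#' @param path YAML path.
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full demonstration pipeline
#'
#' Stages (each optional via `cfg$stages`, later stages require earlier
#' ones): generate a cohort on [default_toy_atlas()]; quantify the region x
#' cell-type density matrix; cluster the max-normalised composition; run the
#' percentile-DBSCAN sweep on the focal cell type's pooled cloud; compare
#' the two groups. Every file written is listed in `manifest.json` with its
#' md5 hash; identical config + seed give identical hashes. On a stage
#' failure, outputs written so far are kept and a `FAILED` marker names the
#' stage and cause.
#'
#' @param cfg a `pipeline_config`.
#' @return The manifest, invisibly: list of stage outputs with md5 hashes.
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) paths[length(paths) + 1] <<- p
  stage <- "configure"
  result <- tryCatch({
    write_pipeline_config(cfg, file.path(cfg$out_dir, "config.yaml"))
    add(file.path(cfg$out_dir, "config.yaml"))
    atlas <- default_toy_atlas()
    ge <- if (cfg$group_effect != 1)
      data.frame(cell_type = cfg$focal_cell_type, group = "g1",
                 multiplier = cfg$group_effect)
    intens <- default_intensity_table(scale = cfg$intensity_scale,
                                      group_effects = ge)
    points <- NULL
    if ("generate" %in% cfg$stages) {
      stage <- "generate"
      subjects <- data.frame(
        subject_id = sprintf("s%02d", seq_len(2 * cfg$n_per_group)),
        group = rep(c("g1", "g2"), each = cfg$n_per_group))
      points <- sample_cohort(atlas, intens, subjects, seed = cfg$seed)
      # uncompressed NIfTI so the manifest hash is a pure function of content
      # (gzip headers can embed timestamps)
      write_label_volume(atlas, file.path(cfg$out_dir, "atlas.nii"))
      add(file.path(cfg$out_dir, "atlas.nii"))
      add(file.path(cfg$out_dir, "atlas.regions.csv"))
      write_point_table(points, file.path(cfg$out_dir, "points.csv"))
      add(file.path(cfg$out_dir, "points.csv"))
    }
    rdm <- NULL
    if ("quantify" %in% cfg$stages) {
      stage <- "quantify"
      points <- assign_regions(points, atlas)
      rdm <- region_density_matrix(points, atlas)
      write_density_matrix(rdm, file.path(cfg$out_dir, "densities.csv"),
                           file.path(cfg$out_dir, "densities_normalized.csv"))
      add(file.path(cfg$out_dir, "densities.csv"))
      add(file.path(cfg$out_dir, "densities_normalized.csv"))
    }
    if ("cluster" %in% cfg$stages) {
      stage <- "cluster"
      norm <- max_normalize(rdm)
      tree <- hierarchical_cluster(correlation_distance(norm))
      write_cluster_tree(tree, file.path(cfg$out_dir, "linkage.csv"),
                         file.path(cfg$out_dir, "cluster_labels.csv"),
                         k = min(cfg$k, nrow(norm)))
      add(file.path(cfg$out_dir, "linkage.csv"))
      add(file.path(cfg$out_dir, "cluster_labels.csv"))
    }
    if ("parcellate" %in% cfg$stages) {
      stage <- "parcellate"
      focal <- points[points$cell_type == cfg$focal_cell_type, ]
      thr <- percentile_thresholds(focal, cfg$epsilon_um, cfg$levels)
      utils::write.csv(
        cbind(cell_type = cfg$focal_cell_type, as.data.frame(thr)),
        file.path(cfg$out_dir, "thresholds.csv"), row.names = FALSE)
      add(file.path(cfg$out_dir, "thresholds.csv"))
      sweep_res <- percentile_sweep(focal, thr)
      write_sweep(sweep_res, file.path(cfg$out_dir, "parcellation.csv"),
                  file.path(cfg$out_dir, "parcellation_summary.json"))
      add(file.path(cfg$out_dir, "parcellation.csv"))
      add(file.path(cfg$out_dir, "parcellation_summary.json"))
      ov <- cluster_region_overlap(sweep_res[[length(sweep_res)]], focal)
      utils::write.csv(ov, file.path(cfg$out_dir, "overlap.csv"),
                       row.names = FALSE)
      add(file.path(cfg$out_dir, "overlap.csv"))
    }
    if ("compare" %in% cfg$stages) {
      stage <- "compare"
      cmp <- compare_groups(rdm, alpha = cfg$alpha)
      utils::write.csv(as.data.frame(cmp),
                       file.path(cfg$out_dir, "comparison.csv"),
                       row.names = FALSE)
      add(file.path(cfg$out_dir, "comparison.csv"))
    }
    TRUE
  }, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest <- list(
    seed = cfg$seed,
    version = as.character(utils::packageVersion("densityatlas")),
    settings = list(epsilon_um = cfg$epsilon_um, levels = cfg$levels,
                    k = cfg$k, alpha = cfg$alpha,
                    minpoints_rounding = "nearest, .5 up",
                    neighbor_convention = "self excluded, boundary inclusive",
                    border_ties = "lowest-index core neighbour"),
    files = lapply(stats::setNames(paths, basename(paths)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
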