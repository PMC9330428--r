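# Run configuration: named profiles, schema validation, YAML/JSON loading.
#
# "paper" holds the at-scale defaults (full geometry, 200 epochs, batch 8);
# "desk" is the CPU/CI-sized stated world the test suite trains in.  Tests
# never mutate paper defaults.

#' Pipeline geometry block
#'
#' @param preprocess_cfg a [preprocess_config()].
#' @param spec1,spec2 stage [patch_spec()]s.
#' @param min_volume_mm3 minimum connected-component volume kept by
#'   [find_kidney_rois()].
#' @return list used by [train_stage()] and [segment_case_two_stage()].
#' @export
pipeline_geometry <- function(preprocess_cfg = preprocess_config(),
                              spec1 = default_patch_spec(1),
                              spec2 = default_patch_spec(2),
                              min_volume_mm3 = 2000) {
  list(preprocess_cfg = preprocess_cfg, spec1 = spec1, spec2 = spec2,
       min_volume_mm3 = min_volume_mm3)
}

#' Default run configuration
#'
#' @param profile `"paper"` (at-scale values) or `"desk"` (CPU-sized).
#' @param seed run seed.
#' @return nested configuration list (classed `run_config`).
#' @export
default_config <- function(profile = c("desk", "paper"), seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    cfg <- list(
      profile = "paper", seed = as.integer(seed),
      preprocess = list(hu_low = -135, hu_high = 215, target_z_spacing = 1.25,
                        stage1_xy = c(256L, 256L)),
      stage1 = list(crop_xy = c(192L, 192L), cube_len = 96L, stride = 48L),
      stage2 = list(roi_xy = c(160L, 160L), cube_len = 64L, stride = 32L,
                    min_volume_mm3 = 2000),
      augment = list(affine_angle_deg = 10, flip_axis = "x", on_the_fly = TRUE),
      backbone = list(name = "unet3d", depth = 3L, base_channels = 8L),
      train = list(epochs = 200L, batch_size = 8L, lr = 1e-3,
                   weight_decay = 1e-3, folds = 5L, test_fraction = 0.3,
                   plateau_factor = 0.1, plateau_patience = 10L, min_lr = 1e-5),
      phantom = list(n_cases = 20L, stone_count_range = c(1L, 3L),
                     diameter_range_mm = c(3, 9), stone_free_fraction = NULL),
      eval = list(success_threshold = 0.5))
  } else {
    cfg <- list(
      profile = "desk", seed = as.integer(seed),
      preprocess = list(hu_low = -135, hu_high = 215, target_z_spacing = 1.25,
                        stage1_xy = c(96L, 96L)),
      stage1 = list(crop_xy = c(64L, 64L), cube_len = 32L, stride = 16L),
      stage2 = list(roi_xy = c(64L, 64L), cube_len = 32L, stride = 16L,
                    min_volume_mm3 = 2000),
      augment = list(affine_angle_deg = 10, flip_axis = "x", on_the_fly = TRUE),
      backbone = list(name = "unet3d", depth = 2L, base_channels = 8L),
      train = list(epochs = 20L, batch_size = 2L, lr = 1e-3,
                   weight_decay = 1e-3, folds = 5L, test_fraction = 0.3,
                   plateau_factor = 0.1, plateau_patience = 10L, min_lr = 1e-5),
      phantom = list(n_cases = 20L, stone_count_range = c(1L, 3L),
                     diameter_range_mm = c(3, 9), stone_free_fraction = NULL),
      eval = list(success_threshold = 0.5))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Validate a configuration against the schema
#'
#' Unknown keys (at top level or inside a block) fail with a message naming
#' the offending key.
#'
#' @param cfg configuration list.
#' @return the validated config, invisibly.
#' @export
validate_config <- function(cfg) {
  ref <- unclass(default_config("desk"))
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad)) stop("unknown config key: ", bad[1])
  for (blk in names(cfg)) {
    if (is.list(ref[[blk]]) && is.list(cfg[[blk]])) {
      badk <- setdiff(names(cfg[[blk]]), names(ref[[blk]]))
      if (length(badk)) stop("unknown config key: ", blk, ".", badk[1])
    }
  }
  invisible(cfg)
}

#' Load a configuration file (YAML or JSON) over profile defaults
#'
#' @param path file path; extension decides the parser.
#' @param profile base profile the file overrides.
#' @return merged, validated `run_config`.
#' @export
load_config <- function(path, profile = "desk") {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config(profile)
  if (!is.null(raw$profile)) base <- default_config(raw$profile)
  cfg <- utils::modifyList(unclass(base), raw)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

# Materialize the typed objects a run needs from the flat config.
config_objects <- function(cfg) {
  pre <- preprocess_config(cfg$preprocess$hu_low, cfg$preprocess$hu_high,
                           cfg$preprocess$target_z_spacing,
                           cfg$preprocess$stage1_xy)
  list(
    preprocess_cfg = pre,
    pipe = pipeline_geometry(
      pre,
      patch_spec(cfg$stage1$crop_xy, cfg$stage1$cube_len, cfg$stage1$stride),
      patch_spec(cfg$stage2$roi_xy, cfg$stage2$cube_len, cfg$stage2$stride),
      cfg$stage2$min_volume_mm3),
    augment = augment_policy(cfg$augment$affine_angle_deg, cfg$augment$flip_axis,
                             cfg$augment$on_the_fly, seed = cfg$seed),
    backbone_cfg = backbone_config(cfg$backbone$name, cfg$backbone$depth,
                                   cfg$backbone$base_channels),
    tcfg = train_config(cfg$train$epochs, cfg$train$batch_size, cfg$train$lr,
                        cfg$train$weight_decay, cfg$train$folds,
                        cfg$train$test_fraction, cfg$train$plateau_factor,
                        cfg$train$plateau_patience, cfg$train$min_lr,
                        seed = cfg$seed))
}
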