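# YAML run configuration: schema, validation, and the simulate stage driver
# used by the command-line interface.

run_config_schema <- function() {
  list(
    seed = "integer",
    out_dir = "character",
    geometry = list(source_to_isocenter = "numeric",
                    source_to_detector = "numeric",
                    detector_cols = "integer", detector_rows = "integer",
                    pixel_size = "numeric", angle_step = "numeric"),
    phantom = list(grid_dims = "integer", spacing = "numeric",
                   bone_hu = "numeric", brain_hu = "numeric",
                   noise_sd = "numeric", n_phantoms = "integer"),
    scan = list(couch_angle = "numeric", range_start = "numeric",
                range_end = "numeric"),
    simulation = list(couch_angles = "numeric", repeats = "integer",
                      trans_max = "numeric", rot_max = "numeric",
                      trans_grid = "numeric", rot_grid = "numeric"),
    loss = list(lambda1 = "numeric", lambda2 = "numeric",
                bone_threshold = "numeric", scale = "numeric",
                moment_order_k = "integer", normalize = "logical"),
    network = list(volume_shape = "integer", projection_shape = "integer",
                   base_channels = "integer", latent_width = "integer",
                   conv_stride = "integer",
                   patch_size = "integer", patches_per_volume = "integer"),
    training = list(lr0 = "numeric", lr_decay = "numeric",
                    plateau_tol = "numeric", plateau_epochs = "integer",
                    max_epochs = "integer", couch_angle = "numeric",
                    monitor = "character"),
    evaluation = list(sphere_radius = "numeric", sphere_sep = "numeric"))
}

validate_section <- function(cfg, schema, path = character()) {
  for (key in names(cfg)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(schema))
      stop("unknown config key: ", here, call. = FALSE)
    if (is.list(schema[[key]])) {
      if (!is.list(cfg[[key]]))
        stop("config key ", here, " must be a section", call. = FALSE)
      validate_section(cfg[[key]], schema[[key]], c(path, key))
    }
  }
  invisible(TRUE)
}

#' Read and validate a YAML run configuration
#'
#' Nested sections `geometry`, `phantom`, `scan`, `simulation`, `loss`,
#' `network`, `training`, `evaluation` plus a root `seed` and `out_dir`.
#' Unknown keys are rejected with the path of the offending key; sections
#' may be omitted (defaults apply).
#'
#' @param path YAML file path.
#' @param required sections that must be present.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path, required = character()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_section(cfg, run_config_schema())
  for (r in required)
    if (is.null(cfg[[r]]))
      stop("missing required config section: ", r, call. = FALSE)
  structure(cfg, class = "run_config")
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  if (is.null(g)) return(cone_beam_geometry())
  do.call(cone_beam_geometry, g)
}

config_loss <- function(cfg) {
  if (is.null(cfg$loss)) return(loss_config())
  do.call(loss_config, cfg$loss)
}

# provenance block written next to every CLI output
provenance <- function(cfg, seed) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  codes <- utf8ToInt(txt)
  hash <- sprintf("%08x", sum(codes * (seq_along(codes) %% 97 + 1)) %% 2^31)
  list(config_hash = hash,
       config = unclass(cfg), seed = seed,
       package_version = as.character(utils::packageVersion("noncopcbct")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulation stage of a configuration
#'
#' Generates the configured phantoms, builds the (phantom x couch angle x
#' repeat) dataset manifest, writes each coplanar prior and ground truth as
#' NIfTI, each projection stack as TIFF+JSON, and the manifest as JSON
#' lines plus a provenance block. Idempotent for a fixed seed.
#'
#' @param cfg a `run_config` (see [read_run_config()]).
#' @param out_dir output directory (created if missing); overrides
#'   `cfg$out_dir`.
#' @return The manifest data.frame, invisibly.
#' @export
run_simulate <- function(cfg, out_dir = cfg$out_dir) {
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 0L
  ph_cfg <- cfg$phantom %||% list()
  n_ph <- ph_cfg$n_phantoms %||% 2L
  sim <- cfg$simulation %||% list()
  couch_angles <- sim$couch_angles %||% c(45, -45, 90, -90)
  repeats <- sim$repeats %||% 3L
  ranges <- error_ranges(sim$trans_max %||% 10, sim$rot_max %||% 3,
                         sim$trans_grid %||% 0.1, sim$rot_grid %||% 0.1)
  geometry <- config_geometry(cfg)
  specs <- lapply(seq_len(n_ph), function(i)
    phantom_spec(grid_dims = ph_cfg$grid_dims %||% c(32L, 32L, 32L),
                 spacing = ph_cfg$spacing %||% c(4, 4, 4),
                 bone_hu = ph_cfg$bone_hu %||% 1200,
                 brain_hu = ph_cfg$brain_hu %||% 40,
                 noise_sd = ph_cfg$noise_sd %||% 20,
                 seed = seed + i))
  phantoms <- lapply(specs, make_phantom)
  samples <- build_dataset(phantoms, couch_angles, repeats,
                           geometry = geometry, ranges = ranges, seed = seed)
  plan <- plan_dataset(n_ph, couch_angles, repeats, ranges, seed)
  plan$ccbct_path <- file.path(out_dir, sprintf("phantom%02d_ccbct.nii.gz",
                                                plan$phantom))
  plan$gcbct_path <- file.path(out_dir, sprintf("sample%04d_gcbct.nii.gz",
                                                seq_len(nrow(plan))))
  plan$proj_path <- file.path(out_dir, sprintf("sample%04d_proj.tif",
                                               seq_len(nrow(plan))))
  for (i in seq_len(n_ph))
    write_volume(phantoms[[i]], plan$ccbct_path[match(i, plan$phantom)])
  for (i in seq_along(samples)) {
    write_volume(samples[[i]]$ground_truth, plan$gcbct_path[i])
    write_projections(samples[[i]]$projections, plan$proj_path[i])
  }
  write_manifest(plan, file.path(out_dir, "manifest.jsonl"))
  jsonlite::write_json(provenance(cfg, seed),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(plan)
}
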