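#' Pipeline configuration
#'
#' Bundles the per-stage parameter objects, the mask source (ground truth
#' or a trained U-Net) and one master seed that is propagated to every
#' stage.
#'
#' @param synth a [synth_params()]
#' @param watershed a [watershed_params()]
#' @param scan a [scan_params()]
#' @param unet a [unet_config()], used when `use_trained_model` is TRUE
#' @param n_planes number of independent planes to simulate and analyse
#' @param n_train training planes simulated when `use_trained_model`
#' @param use_trained_model if TRUE, semantic masks come from a U-Net
#'   trained on separately simulated planes; if FALSE, from ground truth
#' @param seed master seed; stage seeds are derived from it
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(synth = synth_params(),
                            watershed = watershed_params(),
                            scan = scan_params(),
                            unet = unet_config(),
                            n_planes = 3, n_train = 8,
                            use_trained_model = FALSE, seed = 1L) {
  structure(list(synth = synth, watershed = watershed, scan = scan,
                 unet = unet, n_planes = as.integer(n_planes),
                 n_train = as.integer(n_train),
                 use_trained_model = isTRUE(use_trained_model),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `synth`, `watershed`, `scan`, `unet`, `n_planes`,
#' `n_train`, `use_trained_model`, `seed`; each stage key holds arguments
#' for the corresponding constructor. Missing keys keep their defaults.
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synth)) args$synth <- do.call(synth_params, y$synth)
  if (!is.null(y$watershed))
    args$watershed <- do.call(watershed_params, y$watershed)
  if (!is.null(y$scan)) args$scan <- do.call(scan_params, y$scan)
  if (!is.null(y$unet)) args$unet <- do.call(unet_config, y$unet)
  for (k in c("n_planes", "n_train", "use_trained_model", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' simulate -> (train + predict | ground-truth masks) -> instance
#' segmentation -> size filter -> face detection and line scans -> paired
#' statistics. Every intermediate is written under `out_dir` (channel PNGs,
#' label maps, the records CSV, the JSON report, a stacked mask volume) and
#' a manifest records the seed and per-stage counts. Two runs with the same
#' configuration produce byte-identical CSV records.
#'
#' @param cfg a [pipeline_config()]
#' @param out_dir output directory
#' @param force overwrite an existing non-empty output directory
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(cfg, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # stage 1: simulate
  planes <- lapply(seq_len(cfg$n_planes), function(p) {
    sp <- cfg$synth
    sp$seed <- cfg$seed * 1000L + p
    simulate_islet(sp)
  })
  for (p in seq_along(planes))
    write_islet(planes[[p]], file.path(out_dir, "planes"),
                sprintf("plane%02d", p))
  # stage 2: semantic masks
  if (cfg$use_trained_model) {
    train_planes <- lapply(seq_len(cfg$n_train), function(p) {
      sp <- cfg$synth
      sp$image_size <- cfg$unet$input_size
      sp$n_cells <- max(1L, as.integer(round(
        cfg$synth$n_cells * (cfg$unet$input_size / cfg$synth$image_size)^2)))
      sp$seed <- cfg$seed * 1000L + 500L + p
      simulate_islet(sp)
    })
    pairs <- lapply(train_planes, function(is)
      list(x = unet_input(is$channels), y = as_binary_mask(is$truth_instances > 0)))
    n_val <- max(1L, length(pairs) %/% 4L)
    fit <- train_unet(build_unet(cfg$unet), pairs[seq_len(length(pairs) - n_val)],
                      pairs[(length(pairs) - n_val + 1L):length(pairs)])
    masks <- lapply(planes, function(is) {
      if (cfg$synth$image_size != cfg$unet$input_size)
        stop("unet input_size must equal synth image_size in trained mode")
      predict_mask(fit$model, unet_input(is$channels))
    })
  } else {
    masks <- lapply(planes, function(is) as_binary_mask(is$truth_instances > 0))
  }
  # stage 3: instances + size filter
  lms <- lapply(masks, function(m)
    filter_instances(instance_segment(m, cfg$watershed),
                     cfg$watershed$min_area_px))
  for (p in seq_along(lms))
    png::writePNG(lms[[p]] / 65535,
                  file.path(out_dir, sprintf("instances_plane%02d.png", p)))
  # stage 4: polarity records
  channels <- lapply(planes, function(is) is$channels)
  records <- analyse_islet(channels, lms, cfg$scan, islet_id = "synthetic",
                           csv = file.path(out_dir, "records.csv"))
  # stage 5: statistics
  report <- summarize_faces(records, json = file.path(out_dir, "report.json"))
  # stacked mask volume
  vol <- stack_masks(masks, voxel_geometry(cfg$synth$pixel_size_um,
                                           cfg$synth$pixel_size_um * 3.727))
  export_volume(vol, file.path(out_dir, "masks.tif"))
  manifest <- list(seed = cfg$seed, n_planes = cfg$n_planes,
                   use_trained_model = cfg$use_trained_model,
                   instances_per_plane = vapply(lms, max, integer(1)),
                   n_records = nrow(records),
                   n_complete = report$n_complete,
                   n_skipped = sum(vapply(lms, max, integer(1))) - nrow(records),
                   package_version = as.character(utils::packageVersion("isletpol")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
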