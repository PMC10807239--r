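#' Construct a 3-channel image stack
#'
#' The canonical container for one case: a non-negative intensity array
#' indexed `(z, y, x, channel)` with exactly three named channels — nuclei
#' (SYTO-16-like counterstain), membrane (DiD-like counterstain) and marker
#' (PD-L1 signal) — plus physical calibration.
#'
#' @param voxels 4D numeric array `(n_z, height, width, 3)`.
#' @param channel_names channel labels, fixed order.
#' @param z_spacing_um,pixel_size_um physical calibration, both > 0.
#' @return a `channel_stack` object.
#' @export
channel_stack <- function(voxels,
                          channel_names = c("nuclei", "membrane", "marker"),
                          z_spacing_um = 1.4, pixel_size_um = 0.621) {
  d <- dim(voxels)
  if (length(d) != 4 || d[4] != 3)
    stopf("voxels must be a (z, y, x, channel) array with 3 channels")
  if (length(channel_names) != 3) stopf("exactly 3 channel names required")
  if (z_spacing_um <= 0 || pixel_size_um <= 0)
    stopf("physical spacings must be > 0")
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stopf("intensities must be finite and >= 0")
  structure(list(voxels = voxels, channel_names = channel_names,
                 z_spacing_um = z_spacing_um, pixel_size_um = pixel_size_um),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("channel_stack: %d layers of %dx%d px, channels [%s]\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  z spacing %.3g um, pixel size %.3g um\n",
              x$z_spacing_um, x$pixel_size_um))
  invisible(x)
}

# one layer as (y, x, channel) array
stack_layer <- function(stack, z_index) {
  stack$voxels[z_index + 1, , , , drop = TRUE]
}

#' Write a channel stack as multi-page TIFF
#'
#' Pages are ordered z-major, channel-minor (z0/c0, z0/c1, z0/c2, z1/c0, ...)
#' with a JSON ImageDescription on the first page recording axes, channel
#' names and physical calibration, so the file round-trips self-describing.
#' Samples are 32-bit float.
#'
#' @param stack a `channel_stack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * 3)
  for (z in seq_len(d[1])) for (c in 1:3)
    pages[[(z - 1) * 3 + c]] <- stack$voxels[z, , , c]
  meta <- jsonlite::toJSON(list(
    axes = "ZCYX", channels = stack$channel_names,
    z_spacing_um = stack$z_spacing_um, pixel_size_um = stack$pixel_size_um,
    shape = d[1:3]), auto_unbox = TRUE, digits = NA)
  write_tiff(path, pages, sample_format = "float32",
             description = as.character(meta))
}

#' Read a channel stack from multi-page TIFF
#'
#' Calibration and channel layout are taken from the JSON ImageDescription
#' when present; otherwise they must be supplied (`channel_map` naming the
#' within-layer page index of each channel, plus the physical spacings).
#'
#' @param path TIFF file.
#' @param channel_map named integer vector (1-based within-z page index) for
#'   `nuclei`, `membrane`, `marker`; default taken from metadata or 1:3.
#' @param z_spacing_um,pixel_size_um fallback calibration when the file
#'   carries none; an error is raised if neither source provides it.
#' @return a `channel_stack`.
#' @export
read_stack <- function(path, channel_map = NULL,
                       z_spacing_um = NULL, pixel_size_um = NULL) {
  tf <- read_tiff(path)
  meta <- NULL
  if (!is.null(tf$description)) {
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
  }
  n_ch <- if (!is.null(channel_map)) max(unlist(channel_map))
          else if (!is.null(meta$channels)) length(meta$channels) else 3L
  n_pages <- length(tf$pages)
  if (n_pages %% n_ch != 0 || n_pages < n_ch)
    stopf("missing channel: %d pages cannot hold %d channels per layer",
          n_pages, n_ch)
  if (is.null(channel_map)) {
    nm <- meta$channels %||% c("nuclei", "membrane", "marker")
    channel_map <- setNames(seq_along(nm), nm)
  }
  need <- c("nuclei", "membrane", "marker")
  if (!all(need %in% names(channel_map)))
    stopf("missing channel: channel_map must name %s",
          paste(setdiff(need, names(channel_map)), collapse = ", "))
  zs <- z_spacing_um %||% meta$z_spacing_um
  px <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(zs) || is.null(px))
    stopf("missing calibration: file has no metadata and no fallback given")
  n_z <- n_pages %/% n_ch
  h <- dim(tf$pages[[1]])[1]; w <- dim(tf$pages[[1]])[2]
  voxels <- array(0, c(n_z, h, w, 3))
  for (z in seq_len(n_z)) for (k in seq_along(need)) {
    voxels[z, , , k] <- tf$pages[[(z - 1) * n_ch + channel_map[[need[k]]]]]
  }
  channel_stack(voxels, need, z_spacing_um = zs, pixel_size_um = px)
}

#' Write binary mask stacks as multi-page TIFF
#'
#' One 8-bit page per layer, 0/255 encoding; lossless round-trip via
#' [read_masks()].
#'
#' @param masks logical `(z, y, x)` array (or a list of 2D masks).
#' @param path output path.
#' @param reference optional array/stack the masks must be congruent with.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path, reference = NULL) {
  if (is.list(masks)) {
    masks <- array(unlist(lapply(masks, as_mask)),
                   c(dim(masks[[1]]), length(masks)))
    masks <- aperm(masks, c(3, 1, 2))
  }
  if (length(dim(masks)) != 3) stopf("masks must be a (z, y, x) array")
  check_binary_mask(masks)
  if (!is.null(reference)) {
    rd <- if (inherits(reference, "channel_stack")) dim(reference$voxels)[1:3]
          else dim(reference)[1:3]
    if (any(dim(masks) != rd))
      stopf("shape mismatch: masks (%s) not congruent with reference (%s)",
            paste(dim(masks), collapse = ","), paste(rd, collapse = ","))
  }
  pages <- lapply(seq_len(dim(masks)[1]), function(z) {
    m <- matrix(0, dim(masks)[2], dim(masks)[3])
    m[masks[z, , ]] <- 255
    m
  })
  write_tiff(path, pages, sample_format = "uint8",
             description = '{"axes":"ZYX","encoding":"0/255 binary"}')
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  tf <- read_tiff(path)
  n_z <- length(tf$pages)
  d <- dim(tf$pages[[1]])
  out <- array(FALSE, c(n_z, d[1], d[2]))
  for (z in seq_len(n_z)) out[z, , ] <- tf$pages[[z]] > 0
  out
}

#' Run the full per-case scoring pipeline
#'
#' Selects the analysis layers, obtains per-layer tumor/immune/PD-L1 masks —
#' either by running the two segmentation models or, in oracle mode, by
#' taking supplied ground-truth masks — scores each layer, and assembles the
#' depth profile with its 3D summary. Oracle mode is fully deterministic.
#'
#' @param stack a `channel_stack`.
#' @param segmenters list with `tumor` and `immune` segmenters (model mode).
#' @param truth a `ground_truth` (oracle mode); its label stacks are used
#'   directly as the working masks (the stored tumor region is already the
#'   merged area, so no morphological consolidation is re-applied).
#' @param config list of options: `case_id`, `analysis_interval_um` (default
#'   7), `closing_radius_px` (default 20), `max_hole_px` (default 5000),
#'   `marker_threshold` (`"otsu"` or numeric), `exclude_dcis` (default
#'   FALSE), `reference_2d` (optional list `score`/`category` from a paired
#'   2D reading; in oracle mode defaults to the phantom's superficial-layer
#'   reference).
#' @return a `case_report`: `case_id`, per-layer data frame `layers`, and
#'   `summary` (the profile fields).
#' @export
run_case <- function(stack, segmenters = NULL, truth = NULL, config = list()) {
  if (is.null(segmenters) && is.null(truth))
    stopf("either segmenters or ground truth must be provided")
  cfg <- utils::modifyList(list(
    case_id = "case", analysis_interval_um = 7,
    closing_radius_px = 20, max_hole_px = 5000,
    marker_threshold = "otsu", exclude_dcis = FALSE,
    reference_2d = NULL), config)
  d <- dim(stack$voxels)
  zs <- select_layers(d[1], stack$z_spacing_um, cfg$analysis_interval_um)
  log_info("case %s: %d/%d layers analysed", cfg$case_id, length(zs), d[1])
  scores <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    z <- zs[i]
    if (!is.null(truth)) {
      masks <- list(
        tumor_area_mask = truth$tumor_mask[z + 1, , ],
        immune_mask = truth$immune_mask[z + 1, , ],
        immune_in_tumor_mask = truth$immune_mask[z + 1, , ] &
          truth$tumor_mask[z + 1, , ],
        pdl1_pos_ic_mask = truth$pdl1_pos_mask[z + 1, , ])
      dcis <- truth$dcis_mask[z + 1, , ]
    } else {
      layer <- stack_layer(stack, z)
      tumor_cells <- predict_mask(segmenters$tumor, layer)
      tumor_area <- merge_tumor_area(tumor_cells, cfg$closing_radius_px,
                                     cfg$max_hole_px)
      immune <- predict_mask(segmenters$immune, layer)
      sp <- split_immune(immune, tumor_area)
      pdl1 <- pdl1_positive_ic(layer[, , 3], sp$immune_in_tumor,
                               threshold = cfg$marker_threshold)
      masks <- list(tumor_area_mask = tumor_area, immune_mask = immune,
                    immune_in_tumor_mask = sp$immune_in_tumor,
                    pdl1_pos_ic_mask = pdl1)
      dcis <- NULL
    }
    scores[[i]] <- layer_ic_score(masks, z_index = z,
                                  z_spacing_um = stack$z_spacing_um,
                                  dcis_mask = dcis,
                                  exclude_dcis = cfg$exclude_dcis)
  }
  ref <- cfg$reference_2d
  if (is.null(ref) && !is.null(truth)) ref <- render_reference_2d(truth)
  profile <- build_profile(cfg$case_id, scores, reference_2d = ref)
  layers <- do.call(rbind, lapply(scores, function(s)
    data.frame(z_index = s$z_index, depth_um = s$depth_um,
               tumor_area_px = s$tumor_area_px,
               immune_area_px = s$immune_area_px,
               immune_in_tumor_px = s$immune_in_tumor_px,
               pdl1_ic_area_px = s$pdl1_ic_area_px,
               ic_score_pct = s$ic_score_pct,
               category = s$category, no_tumor = s$no_tumor)))
  structure(list(case_id = cfg$case_id, layers = layers,
                 summary = profile, config = cfg), class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("case %s: %d layers analysed (%d scored)\n", x$case_id,
              nrow(x$layers), sum(!x$layers$no_tumor)))
  cat(sprintf("  3D average IC score %.2f%% (%s); range %.2f-%.2f%%\n",
              s$average_score_pct, s$average_category,
              s$min_score, s$max_score))
  cat(sprintf("  crosses 1%% threshold: %s; pattern: %s\n",
              s$crossing_1pct, s$pattern))
  if (!is.null(s$reference_2d))
    cat(sprintf("  2D reference %.2f%% (%s) -> %s\n", s$reference_2d$score,
                s$reference_2d$category, s$discordance))
  invisible(x)
}

#' Write a case report to disk
#'
#' The per-layer table goes to `<case_id>_layers.csv` and the summary to
#' `<case_id>_summary.json` — both diff-able plain text.
#'
#' @param report a `case_report`.
#' @param dir output directory (created if needed).
#' @return the two paths, invisibly.
#' @export
write_case_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(report$case_id, "_layers.csv"))
  js <- file.path(dir, paste0(report$case_id, "_summary.json"))
  write.csv(report$layers, csv, row.names = FALSE)
  s <- unclass(report$summary)
  s$layers <- NULL
  jsonlite::write_json(s, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv, js))
}
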