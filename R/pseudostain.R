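# Virtual bright-field rendering of fluorescence channels for pathologist-
# familiar visual QC. A Beer-Lambert absorption model: each channel's
# intensity acts as the concentration of a virtual dye with a fixed optical-
# density color vector, and transmitted light through a white background is
# RGB = 255 * exp(-sum_c gain_c * I_c * OD_c). Zero signal is exactly white;
# contributions are additive in optical density, so channels never interact.

#' Stain recipe for pseudo-bright-field rendering
#'
#' @param od named list of non-negative RGB absorbance vectors, one per
#'   channel to render (names must match channel names).
#' @param gains named numeric gains per channel (default 1).
#' @return a `stain_recipe`.
#' @export
stain_recipe <- function(od, gains = NULL) {
  if (!length(od) || is.null(names(od))) stopf("od must be a named list")
  for (v in od) {
    if (length(v) != 3 || any(v < 0)) stopf("absorbance vectors are RGB >= 0")
  }
  gains <- gains %||% rep(1, length(od))
  if (is.null(names(gains)) && length(gains) == length(od))
    names(gains) <- names(od)
  structure(list(od = od, gains = gains), class = "stain_recipe")
}

#' Pseudo-H&E recipe
#'
#' Hematoxylin (standard optical-density vector 0.65/0.70/0.29) renders the
#' nuclei counterstain; eosin (0.07/0.99/0.11) renders the membrane
#' counterstain.
#'
#' @return a `stain_recipe`.
#' @export
he_recipe <- function() {
  stain_recipe(list(nuclei = c(0.65, 0.70, 0.29),
                    membrane = c(0.07, 0.99, 0.11)),
               gains = c(nuclei = 1.2, membrane = 0.8))
}

#' Pseudo-IHC recipe
#'
#' Hematoxylin counterstains the nuclei channel and DAB brown
#' (0.27/0.57/0.78) renders the marker channel, mimicking a chromogenic
#' PD-L1 stain.
#'
#' @return a `stain_recipe`.
#' @export
ihc_recipe <- function() {
  stain_recipe(list(nuclei = c(0.65, 0.70, 0.29),
                    marker = c(0.27, 0.57, 0.78)),
               gains = c(nuclei = 0.8, marker = 1.5))
}

#' Render a pseudo-stained RGB image from fluorescence channels
#'
#' @param channels named list of congruent non-negative intensity matrices
#'   normalised to about \[0, 1\] (a `(h, w, 3)` layer array with standard
#'   channel order is also accepted).
#' @param recipe a `stain_recipe`; channels absent from the recipe are
#'   ignored.
#' @return `(h, w, 3)` numeric array of RGB values in \[0, 255\].
#' @export
render_pseudo <- function(channels, recipe) {
  if (is.array(channels) && length(dim(channels)) == 3) {
    channels <- list(nuclei = channels[, , 1], membrane = channels[, , 2],
                     marker = channels[, , 3])
  }
  if (!inherits(recipe, "stain_recipe")) stopf("recipe must be a stain_recipe")
  used <- intersect(names(recipe$od), names(channels))
  if (!length(used)) stopf("recipe names none of the supplied channels")
  d <- dim(channels[[used[1]]])
  od_total <- array(0, c(d[1], d[2], 3))
  for (ch in used) {
    img <- channels[[ch]]
    check_congruent(img, channels[[used[1]]], "channels")
    if (any(img < 0)) stopf("negative intensities in channel '%s'", ch)
    g <- if (ch %in% names(recipe$gains)) unname(recipe$gains[[ch]]) else 1
    for (k in 1:3) od_total[, , k] <- od_total[, , k] + g * img * recipe$od[[ch]][k]
  }
  255 * exp(-od_total)
}

#' Write an RGB rendering (or mask overlay) as 8-bit RGB TIFF
#'
#' @param rgb `(h, w, 3)` array with values in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_tiff <- function(rgb, path) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) stopf("rgb must be (h, w, 3)")
  write_tiff(path, list(rgb), sample_format = "uint8")
}

#' Per-layer QC overlay of the working masks
#'
#' Renders the mask set of one layer with the conventional colors: white
#' merged tumor area, cyan tumor cells, yellow immune cells, magenta PD-L1+
#' intratumoral immune cells, over a dark background.
#'
#' @param masks list with any of `tumor_area_mask`, `tumor_cell_mask`,
#'   `immune_mask`, `pdl1_pos_ic_mask`.
#' @return `(h, w, 3)` RGB array in \[0, 255\].
#' @export
mask_overlay <- function(masks) {
  base <- masks$tumor_area_mask %||% masks$tumor_cell_mask %||%
    masks$immune_mask %||% masks$pdl1_pos_ic_mask
  if (is.null(base)) stopf("no masks supplied")
  d <- dim(base)
  rgb <- array(15, c(d[1], d[2], 3))
  paint <- function(rgb, m, col) {
    if (is.null(m)) return(rgb)
    m <- as_mask(m)
    for (k in 1:3) {
      ch <- rgb[, , k]; ch[m] <- col[k]; rgb[, , k] <- ch
    }
    rgb
  }
  rgb <- paint(rgb, masks$tumor_area_mask, c(200, 200, 200))
  rgb <- paint(rgb, masks$tumor_cell_mask, c(0, 255, 255))
  rgb <- paint(rgb, masks$immune_mask, c(255, 255, 0))
  rgb <- paint(rgb, masks$pdl1_pos_ic_mask, c(255, 0, 255))
  rgb
}
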