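#' Consolidate a tumor-cell mask into the merged tumor-area mask
#'
#' The immune-cell score denominator is the tumor *area* in the SP142 sense:
#' tumor cells plus the intratumoral stroma enclosed between them. The
#' per-layer tumor-cell mask is consolidated by a morphological closing with
#' a disc of `closing_radius_px`, followed by filling of enclosed background
#' holes of at most `max_hole_px` pixels. The operation is extensive
#' (input is a subset of output) and idempotent on already-merged masks.
#'
#' @param tumor_cell_mask logical matrix from the tumor segmenter.
#' @param closing_radius_px disc radius for the closing (default 20 px);
#'   bridges inter-nuclear stroma without connecting separate nests.
#' @param max_hole_px largest enclosed hole that is filled (default 5000 px).
#' @return logical merged tumor-area matrix.
#' @export
merge_tumor_area <- function(tumor_cell_mask, closing_radius_px = 20,
                             max_hole_px = 5000) {
  if (closing_radius_px < 0) stopf("closing radius must be >= 0")
  m <- as_mask(tumor_cell_mask)
  fill_holes(close_disc(m, closing_radius_px), max_hole_px)
}

#' Split an immune mask into intratumoral and peritumoral parts
#'
#' Immune cells inside the merged tumor area are the tumor-infiltrating
#' immune cells entering the score; those outside are peritumoral. Exact set
#' intersection/difference: the two outputs are disjoint and their union is
#' the input immune mask.
#'
#' @param immune_mask,tumor_area_mask congruent logical matrices.
#' @return list with `immune_in_tumor` and `immune_peritumoral`.
#' @export
split_immune <- function(immune_mask, tumor_area_mask) {
  check_congruent(immune_mask, tumor_area_mask)
  im <- as_mask(immune_mask); tu <- as_mask(tumor_area_mask)
  list(immune_in_tumor = im & tu, immune_peritumoral = im & !tu)
}

#' PD-L1-positive tumor-infiltrating immune cell mask
#'
#' Positivity is binary and independent of staining intensity: a pixel of the
#' intratumoral immune mask is positive when its marker-channel intensity
#' reaches the threshold. With `mode = "component"` (default) positivity is
#' decided per immune cell: every 8-connected component of the intratumoral
#' immune mask whose positive pixel fraction reaches `min_pos_frac` is
#' returned whole, matching cell-level scoring of a membrane-localised stain
#' while staying robust to isolated noise pixels crossing the threshold.
#' `mode = "pixel"` returns the thresholded pixels themselves.
#'
#' @param marker_channel numeric matrix (marker intensities).
#' @param immune_in_tumor_mask logical matrix, congruent.
#' @param threshold numeric cut, or `"otsu"` to derive it from the marker
#'   histogram restricted to the immune mask. Because Otsu degenerates on
#'   unimodal (marker-free) data, the derived cut is floored at the
#'   background level `mean + 4 sd` of the marker outside the immune mask.
#'   The resolved value is logged.
#' @param mode `"component"` or `"pixel"`.
#' @param min_pos_frac minimum fraction of a component's pixels that must
#'   cross the threshold for the cell to count as positive (component mode;
#'   default 0.05 — a membrane ring covers far more of a cell footprint).
#' @return logical mask, a subset of `immune_in_tumor_mask`.
#' @export
pdl1_positive_ic <- function(marker_channel, immune_in_tumor_mask,
                             threshold = "otsu", mode = c("component", "pixel"),
                             min_pos_frac = 0.05) {
  check_congruent(marker_channel, immune_in_tumor_mask, "marker and mask")
  mode <- match.arg(mode)
  im <- as_mask(immune_in_tumor_mask)
  if (!any(im)) return(im)
  if (identical(threshold, "otsu")) {
    bg <- marker_channel[!im]
    floor_ <- if (length(bg) > 1) mean(bg) + 4 * stats::sd(bg) else 0
    threshold <- max(otsu_threshold(marker_channel[im]), floor_)
  }
  if (!is.numeric(threshold) || !is.finite(threshold))
    stopf("marker threshold must be finite")
  log_info("marker positivity threshold = %.4f", threshold)
  pos <- im & (marker_channel >= threshold)
  if (mode == "pixel" || !any(pos)) return(pos)
  lab <- label_components(im, 8)
  sizes <- tabulate(lab[lab > 0])
  pos_counts <- tabulate(lab[pos], nbins = length(sizes))
  keep <- which(pos_counts / sizes >= min_pos_frac)
  array(lab %in% keep, dim = dim(im))
}

#' Assign the clinical PD-L1 category for an immune-cell score
#'
#' The SP142 convention at the 1% clinical cutoff: a score of at least 1%
#' is positive, a score strictly between 0 and 1% is borderline, and exactly
#' 0% is negative.
#'
#' @param ic_score_pct score(s) in percent, within \[0, 100\].
#' @return character vector in `{"negative","borderline","positive"}`.
#' @export
categorize <- function(ic_score_pct) {
  if (any(!is.finite(ic_score_pct)) ||
      any(ic_score_pct < 0) || any(ic_score_pct > 100))
    stopf("ic_score_pct must lie in [0, 100]")
  ifelse(ic_score_pct >= 1, "positive",
         ifelse(ic_score_pct > 0, "borderline", "negative"))
}

#' Score one layer: PD-L1 immune-cell score and category
#'
#' The immune-cell (IC) score of a layer is the area of PD-L1-expressing
#' tumor-infiltrating immune cells divided by the total tumor area, in
#' percent. Areas are raw pixel counts (the ratio is calibration-invariant).
#' With `exclude_dcis = TRUE`, in-situ (DCIS) pixels are removed from the
#' denominator and from the numerator-eligible region, implementing the
#' assay-guide rule that only invasive carcinoma is scored; leaving DCIS in
#' the denominator dilutes (underestimates) the score.
#'
#' A layer whose tumor area is zero has no defined score (the denominator is
#' the tumor area): it is returned flagged `no_tumor` with an `NA` score, not
#' scored 0.
#'
#' @param masks list with `tumor_area_mask` and `pdl1_pos_ic_mask` (and
#'   optionally `immune_mask`, `immune_in_tumor_mask`) — congruent logical
#'   matrices for one layer.
#' @param z_index 0-based layer index.
#' @param z_spacing_um physical z step, for the reported depth.
#' @param dcis_mask optional logical matrix of in-situ regions.
#' @param exclude_dcis logical; default `FALSE` (in-situ area left in the
#'   denominator, matching the uncorrected two-model pipeline).
#' @return a `layer_score` list: `z_index`, `depth_um`, `tumor_area_px`,
#'   `immune_area_px`, `immune_in_tumor_px`, `pdl1_ic_area_px`,
#'   `ic_score_pct`, `category`, `no_tumor`.
#' @export
layer_ic_score <- function(masks, z_index = 0, z_spacing_um = 1.4,
                           dcis_mask = NULL, exclude_dcis = FALSE) {
  tu <- as_mask(masks$tumor_area_mask)
  ic <- as_mask(masks$pdl1_pos_ic_mask)
  check_congruent(tu, ic, "tumor area and PD-L1+ IC masks")
  if (exclude_dcis && !is.null(dcis_mask)) {
    dc <- as_mask(dcis_mask)
    check_congruent(tu, dc, "tumor area and DCIS masks")
    tu <- tu & !dc
    ic <- ic & !dc
  }
  a_tumor <- sum(tu)
  a_ic <- sum(ic & tu)
  imm <- if (!is.null(masks$immune_mask)) sum(as_mask(masks$immune_mask)) else NA_integer_
  imm_in <- if (!is.null(masks$immune_in_tumor_mask))
    sum(as_mask(masks$immune_in_tumor_mask) & tu) else NA_integer_
  if (a_tumor == 0) {
    return(structure(list(
      z_index = z_index, depth_um = z_index * z_spacing_um,
      tumor_area_px = 0L, immune_area_px = imm, immune_in_tumor_px = imm_in,
      pdl1_ic_area_px = a_ic, ic_score_pct = NA_real_,
      category = NA_character_, no_tumor = TRUE), class = "layer_score"))
  }
  score <- 100 * a_ic / a_tumor
  structure(list(
    z_index = z_index, depth_um = z_index * z_spacing_um,
    tumor_area_px = as.integer(a_tumor), immune_area_px = imm,
    immune_in_tumor_px = imm_in, pdl1_ic_area_px = as.integer(a_ic),
    ic_score_pct = score, category = categorize(score), no_tumor = FALSE),
    class = "layer_score")
}
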