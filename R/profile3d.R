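#' Select analysis layers from an acquired z-stack
#'
#' Stacks are acquired at a fine z step (1.4 µm here) but scored at a coarser
#' analysis interval (7 µm), i.e. every `round(interval / spacing)`-th
#' optical section starting at the surface.
#'
#' @param n_z number of acquired layers.
#' @param z_spacing_um acquisition z step (> 0).
#' @param analysis_interval_um analysis interval (>= spacing).
#' @return 0-based z indices `0, stride, 2*stride, ... < n_z`.
#' @export
select_layers <- function(n_z, z_spacing_um, analysis_interval_um = 7) {
  if (z_spacing_um <= 0 || analysis_interval_um <= 0)
    stopf("spacing and interval must be > 0")
  if (analysis_interval_um < z_spacing_um)
    stopf("analysis interval (%g) must be >= z spacing (%g)",
          analysis_interval_um, z_spacing_um)
  stride <- max(1L, as.integer(round(analysis_interval_um / z_spacing_um)))
  seq.int(0L, n_z - 1L, by = stride)
}

#' Classify the depth pattern of per-layer PD-L1 categories
#'
#' A case is `uniform_negative` when every layer is negative,
#' `uniform_expressed` when every layer shows expression (borderline or
#' positive), and `heterogeneous_presence` when expressing and negative
#' layers coexist. Independently, `crossing` flags cases whose layers span
#' both sides of the 1% clinical cutoff (some below — negative or borderline
#' — and some at/above it).
#'
#' @param categories character vector of per-layer categories.
#' @return list with `pattern` and logical `crossing`.
#' @export
pattern_label <- function(categories) {
  categories <- categories[!is.na(categories)]
  if (!length(categories)) stopf("at least one category required")
  if (!all(categories %in% IC_CATEGORIES))
    stopf("unknown category: %s",
          paste(setdiff(categories, IC_CATEGORIES), collapse = ", "))
  expressed <- categories %in% c("borderline", "positive")
  crossing <- any(categories == "positive") && any(categories != "positive")
  pattern <- if (!any(expressed)) "uniform_negative"
    else if (all(expressed)) "uniform_expressed"
    else "heterogeneous_presence"
  list(pattern = pattern, crossing = crossing)
}

#' Relative depth variation of immune-cell area
#'
#' `(max - min) / max` of the per-layer immune areas — the fractional swing
#' of infiltrate across the imaged depth (can exceed 10% in real cases).
#'
#' @param immune_areas numeric vector of per-layer immune areas (max > 0).
#' @return fraction in \[0, 1\].
#' @export
immune_area_variation <- function(immune_areas) {
  immune_areas <- immune_areas[!is.na(immune_areas)]
  if (!length(immune_areas)) stopf("at least one layer required")
  mx <- max(immune_areas)
  if (mx <= 0) stopf("all immune areas are zero; variation undefined")
  (mx - min(immune_areas)) / mx
}

#' Direction of 2D-vs-3D category disagreement
#'
#' Compares the category of the 3D average score against the 2D reference
#' category, on the ordinal scale negative < borderline < positive.
#'
#' @param average_score 3D average IC score (percent).
#' @param reference_2d list with `score` and/or `category`.
#' @return `"concordant"`, `"3d_higher"` or `"3d_lower"`.
#' @export
discordance_2d_3d <- function(average_score, reference_2d) {
  cat3d <- categorize(average_score)
  cat2d <- reference_2d$category %||% categorize(reference_2d$score)
  o <- match(c(cat3d, cat2d), IC_CATEGORIES)
  if (any(is.na(o))) stopf("unknown category")
  if (o[1] == o[2]) "concordant" else if (o[1] > o[2]) "3d_higher" else "3d_lower"
}

#' Assemble per-layer scores into a case depth profile
#'
#' Computes the 3D summary: unweighted average score over layers with a
#' defined score, min/max/range, the 1%-crossing flag
#' (`min < 1 <= max`), the depth pattern, the immune-area variation, and —
#' when a 2D reference is given — the discordance direction. Layers flagged
#' `no_tumor` carry no score and are excluded from all summaries.
#'
#' @param case_id identifier.
#' @param layer_scores list of `layer_score` objects (from
#'   [layer_ic_score()]), in depth order.
#' @param reference_2d optional list with `score` and/or `category`.
#' @return a `case_profile` list.
#' @export
build_profile <- function(case_id, layer_scores, reference_2d = NULL) {
  if (!length(layer_scores)) stopf("at least one layer required")
  sc <- vapply(layer_scores, function(s) s$ic_score_pct %||% NA_real_, numeric(1))
  cats <- vapply(layer_scores, function(s) s$category %||% NA_character_, character(1))
  imm <- vapply(layer_scores, function(s)
    as.numeric(s$immune_area_px %||% NA_real_), numeric(1))
  ok <- !is.na(sc)
  if (!any(ok)) stopf("all layers are no-tumor; profile undefined")
  scores <- sc[ok]
  avg <- mean(scores)
  mn <- min(scores); mx <- max(scores)
  pat <- pattern_label(cats[ok])
  iav <- if (any(!is.na(imm)) && max(imm, na.rm = TRUE) > 0)
    immune_area_variation(imm) else NA_real_
  out <- list(
    case_id = case_id,
    n_layers = length(layer_scores), n_scored = sum(ok),
    average_score_pct = avg,
    average_category = categorize(min(avg, 100)),
    min_score = mn, max_score = mx, range = mx - mn,
    crossing_1pct = (mn < 1) && (mx >= 1),
    pattern = pat$pattern,
    category_crossing = pat$crossing,
    immune_area_range_frac = iav,
    reference_2d = reference_2d,
    discordance = if (!is.null(reference_2d))
      discordance_2d_3d(avg, reference_2d) else NULL,
    score_delta_2d = if (!is.null(reference_2d) && !is.null(reference_2d$score))
      avg - reference_2d$score else NULL)
  structure(out, class = "case_profile")
}

#' Cohort agreement table between reference and predicted categories
#'
#' Confusion counts over the three score categories plus the overall percent
#' agreement (matches / n x 100) — the concordance statistic used for
#' method-vs-IHC and inter-observer comparisons.
#'
#' @param reference,predicted equal-length category vectors.
#' @return an `agreement_table`: `confusion` (reference x predicted),
#'   `overall_percent_agreement`, `n_cases`.
#' @export
agreement_table <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stopf("category vectors differ in length (%d vs %d)",
          length(reference), length(predicted))
  bad <- setdiff(unique(c(reference, predicted)), IC_CATEGORIES)
  if (length(bad)) stopf("unknown category: %s", paste(bad, collapse = ", "))
  rf <- factor(reference, levels = IC_CATEGORIES)
  pf <- factor(predicted, levels = IC_CATEGORIES)
  confusion <- table(reference = rf, predicted = pf)
  n <- length(reference)
  structure(list(confusion = confusion,
                 overall_percent_agreement = 100 * sum(diag(confusion)) / n,
                 n_cases = n), class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("agreement over %d cases: %.1f%%\n", x$n_cases,
              x$overall_percent_agreement))
  print(x$confusion)
  invisible(x)
}

#' Cohort-level profile table
#'
#' One row per case with the 3D summary and the 2D comparison — the
#' machine-readable cohort table.
#'
#' @param profiles list of `case_profile` (or `case_report`) objects.
#' @return data frame.
#' @export
cohort_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (inherits(p, "case_report")) p <- p$summary
    data.frame(
      case_id = p$case_id, average_score_pct = p$average_score_pct,
      average_category = p$average_category,
      min_score = p$min_score, max_score = p$max_score, range = p$range,
      crossing_1pct = p$crossing_1pct, pattern = p$pattern,
      immune_area_range_frac = p$immune_area_range_frac,
      reference_score = p$reference_2d$score %||% NA_real_,
      reference_category = p$reference_2d$category %||% NA_character_,
      discordance = p$discordance %||% NA_character_)
  })
  do.call(rbind, rows)
}
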