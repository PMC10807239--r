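#' Binary morphology with a disc structuring element
#'
#' Dilation, erosion and closing of 2D binary masks by a Euclidean disc of
#' the given pixel radius, computed through an exact squared distance
#' transform (a pixel is within the dilation iff its distance to the nearest
#' foreground pixel is at most `radius`). Erosion is dilation of the
#' complement; closing is dilation followed by erosion, so enclosed gaps
#' narrower than the disc are bridged.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels; `0` returns the input unchanged.
#' @return logical matrix of the same dimensions.
#' @export
dilate_disc <- function(mask, radius) {
  if (radius < 0) stopf("radius must be >= 0")
  mask <- as_mask(mask)
  if (radius == 0 || !any(mask)) return(mask)
  d2 <- .edt_sq(mask)
  d2 <= radius * radius + 1e-9
}

#' @rdname dilate_disc
#' @export
erode_disc <- function(mask, radius) {
  if (radius < 0) stopf("radius must be >= 0")
  mask <- as_mask(mask)
  if (radius == 0) return(mask)
  !dilate_disc(!mask, radius)
}

#' @rdname dilate_disc
#' @export
close_disc <- function(mask, radius) {
  erode_disc(dilate_disc(mask, radius), radius)
}

#' Fill enclosed holes in a binary mask
#'
#' Background components (4-connected) that do not touch the image border and
#' are at most `max_px` pixels in size are converted to foreground.
#'
#' @param mask logical matrix.
#' @param max_px largest hole size (pixels) that is filled; `Inf` fills all
#'   enclosed holes.
#' @return logical matrix.
#' @export
fill_holes <- function(mask, max_px = Inf) {
  mask <- as_mask(mask)
  bg <- !mask
  if (!any(bg)) return(mask)
  lab <- .label_cc(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  sizes <- tabulate(lab[lab > 0])
  holes <- setdiff(which(sizes <= max_px), border)
  if (length(holes)) mask[lab %in% holes] <- TRUE
  mask
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix; background 0, components numbered from 1 in scan
#'   order.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  .label_cc(as_mask(mask), as.integer(connectivity))
}

#' Gaussian blur of a 2D image
#'
#' Separable Gaussian filtering with replicate border padding; the kernel is
#' truncated at 3 sigma and renormalised.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return numeric matrix.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  .conv_sep(img, k)
}

#' Otsu threshold of an intensity sample
#'
#' Maximises between-class variance over a 256-bin histogram of the supplied
#' intensities; returns the bin-centre cut. Used to derive a per-stack marker
#' positivity threshold when no fixed value is configured.
#'
#' @param x numeric vector of intensities.
#' @param n_bins histogram resolution.
#' @return numeric scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (!length(x)) stopf("no finite intensities for Otsu threshold")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  tot <- w[n_bins]; mu_t <- mu[n_bins]
  w1 <- w[-n_bins]; m1 <- mu[-n_bins]
  between <- (mu_t * w1 - m1 * tot)^2 / (w1 * (tot - w1) * tot^2)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}
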