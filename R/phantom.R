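# Synthetic cleared-tissue phantom: 3-channel z-stacks (nuclei, membrane,
# marker) with exact voxel-level ground truth and designed per-layer IC
# fractions. Geometry is a stand-in for breast-carcinoma morphology: tumor
# nests as discs densely filled with large overlapping elliptical nuclei,
# immune cells as small isolated round nuclei in and around the nests, the
# marker as a membrane ring on a chosen subset of intratumoral immune cells,
# and optional duct-like in-situ (DCIS) regions bounded by an unbroken
# bright membrane ring.

#' Phantom generator parameters
#'
#' Defaults follow the acquisition geometry of cleared 200-µm-thick
#' specimens imaged confocally: z step 1.4 µm (so 143 optical sections span
#' the slice) and lateral calibration 0.621 µm/px.
#'
#' @param image_shape integer vector `(n_z, height, width)` in voxels.
#' @param z_spacing_um physical z step (default 1.4).
#' @param pixel_size_um lateral calibration (default 0.621).
#' @param tumor_nest_count number of tumor-cell nests (disc-shaped, constant
#'   through depth — tumor area is near-uniform across layers).
#' @param tumor_nest_radius_px nominal nest radius; per-nest radii are
#'   jittered +/-10%.
#' @param immune_density_profile per-layer immune-cell counts; a scalar is
#'   broadcast to all layers. Depth gradients model infiltration changes.
#' @param pdl1_fraction_profile per-layer designed IC fractions in \[0, 1\]
#'   (target score / 100); scalar broadcast.
#' @param dcis_count number of duct-like in-situ regions (default 0).
#' @param noise_sigma additive Gaussian noise sd on unit-scale intensities
#'   (default 0.05), clipped to non-negative.
#' @param intensity_decay_per_um multiplicative depth attenuation
#'   `exp(-decay * depth_um)` (default 0: exported stacks are assumed
#'   depth-normalised).
#' @param seed integer RNG seed; all randomness flows from it.
#' @return validated `phantom_params` list.
#' @export
phantom_params <- function(image_shape = c(143, 192, 192),
                           z_spacing_um = 1.4,
                           pixel_size_um = 0.621,
                           tumor_nest_count = 3,
                           tumor_nest_radius_px = 34,
                           immune_density_profile = 40,
                           pdl1_fraction_profile = 0.01,
                           dcis_count = 0,
                           noise_sigma = 0.05,
                           intensity_decay_per_um = 0,
                           seed = 1) {
  if (length(image_shape) != 3 || any(image_shape < 1))
    stopf("image_shape must be positive (n_z, height, width)")
  if (z_spacing_um <= 0 || pixel_size_um <= 0)
    stopf("physical spacings must be > 0")
  n_z <- as.integer(image_shape[1])
  expand <- function(p, name) {
    if (length(p) == 1) p <- rep(p, n_z)
    if (length(p) != n_z)
      stopf("%s has length %d; expected 1 or n_z = %d", name, length(p), n_z)
    p
  }
  immune_density_profile <- expand(immune_density_profile, "immune_density_profile")
  pdl1_fraction_profile <- expand(pdl1_fraction_profile, "pdl1_fraction_profile")
  if (any(pdl1_fraction_profile < 0 | pdl1_fraction_profile > 1))
    stopf("pdl1_fraction_profile entries must lie in [0, 1]")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  structure(list(
    image_shape = as.integer(image_shape), z_spacing_um = z_spacing_um,
    pixel_size_um = pixel_size_um, tumor_nest_count = tumor_nest_count,
    tumor_nest_radius_px = tumor_nest_radius_px,
    immune_density_profile = immune_density_profile,
    pdl1_fraction_profile = pdl1_fraction_profile,
    dcis_count = dcis_count, noise_sigma = noise_sigma,
    intensity_decay_per_um = intensity_decay_per_um,
    seed = as.integer(seed)), class = "phantom_params")
}

# pixel indices of an annulus r_inner < d <= r_outer around (cy, cx)
disc_idx <- function(h, w, cy, cx, r_outer, r_inner = -1) {
  y0 <- max(1L, floor(cy - r_outer)); y1 <- min(h, ceiling(cy + r_outer))
  x0 <- max(1L, floor(cx - r_outer)); x1 <- min(w, ceiling(cx + r_outer))
  if (y0 > y1 || x0 > x1) return(integer(0))
  ys <- y0:y1; xs <- x0:x1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  rin2 <- if (r_inner < 0) -1 else r_inner^2
  sel <- d2 <= r_outer^2 & d2 > rin2
  iy <- row(sel)[sel] + y0 - 1L
  ix <- col(sel)[sel] + x0 - 1L
  (ix - 1L) * h + iy
}

# pixel indices of an ellipse shell q_inner < q <= 1 in normalised radius
ellipse_idx <- function(h, w, cy, cx, a, b, theta, q_inner = -1) {
  r <- max(a, b)
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(integer(0))
  ys <- (y0:y1) - cy; xs <- (x0:x1) - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(ys * st, xs * ct, "+")   # rotated coords
  v <- outer(ys * ct, -xs * st, "+")
  q <- (u / a)^2 + (v / b)^2
  sel <- q <= 1 & q > q_inner
  iy <- row(sel)[sel] + y0 - 1L
  ix <- col(sel)[sel] + x0 - 1L
  (ix - 1L) * h + iy
}

# rejection-sample k centers inside `region_idx` (linear indices of allowed
# centers) keeping pairwise distance >= min_dist; returns matrix (y, x)
sample_centers <- function(h, region_idx, k, min_dist, existing = NULL) {
  if (k <= 0) return(cbind(y = numeric(0), x = numeric(0)))
  pts <- existing
  out <- NULL
  tries <- 0L
  while ((is.null(out) || nrow(out) < k) && tries < 4000L) {
    tries <- tries + 1L
    idx <- region_idx[sample.int(length(region_idx), 1)]
    y <- ((idx - 1L) %% h) + 1L
    x <- ((idx - 1L) %/% h) + 1L
    ok <- TRUE
    if (!is.null(pts) && nrow(pts)) {
      d2 <- (pts[, 1] - y)^2 + (pts[, 2] - x)^2
      ok <- all(d2 >= min_dist^2)
    }
    if (ok) {
      pts <- rbind(pts, c(y, x))
      out <- rbind(out, c(y = y, x = x))
    }
  }
  out %||% cbind(y = numeric(0), x = numeric(0))
}

#' Generate a synthetic phantom case
#'
#' Renders a 3-channel z-stack plus congruent ground-truth label stacks and
#' an exact per-layer truth table. For each layer, the designed IC fraction
#' is realised by greedily marking whole intratumoral immune cells PD-L1+
#' until their footprint area best matches `fraction x tumor area`; the
#' residual is bounded by half an immune-cell footprint, so realised scores
#' track the design within voxel discretisation. Deterministic for a fixed
#' seed.
#'
#' @param params a [phantom_params()] object.
#' @return list with `stack` (a `channel_stack`) and `truth` (a
#'   `ground_truth`: `tumor_mask`, `immune_mask`, `pdl1_pos_mask`,
#'   `dcis_mask` logical `(z, y, x)` arrays plus `per_layer_truth` data
#'   frame).
#' @export
generate_case <- function(params) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  n_z <- params$image_shape[1]
  h <- params$image_shape[2]
  w <- params$image_shape[3]
  with_seed(params$seed, {
    nuclei <- array(0, c(n_z, h, w))
    membrane <- array(0, c(n_z, h, w))
    marker <- array(0, c(n_z, h, w))
    tumor_mask <- array(FALSE, c(n_z, h, w))
    immune_mask <- array(FALSE, c(n_z, h, w))
    pdl1_mask <- array(FALSE, c(n_z, h, w))
    dcis_mask <- array(FALSE, c(n_z, h, w))

    # --- fixed-through-depth geometry: nest and DCIS discs ---
    r_nest <- params$tumor_nest_radius_px * runif(params$tumor_nest_count, 0.9, 1.1)
    r_dcis <- rep(0.8 * params$tumor_nest_radius_px, params$dcis_count)
    radii <- c(r_nest, r_dcis)
    n_disc <- length(radii)
    if (2 * (max(radii) + 2) >= min(h, w))
      stopf("tumor_nest_radius_px %g too large for a %dx%d field",
            params$tumor_nest_radius_px, h, w)
    sep_scale <- 1
    centers <- NULL
    repeat {
      centers <- NULL
      ok <- TRUE
      for (i in seq_len(n_disc)) {
        m <- ceiling(radii[i]) + 2
        cand <- NULL
        for (t in seq_len(400)) {
          y <- runif(1, m, h - m); x <- runif(1, m, w - m)
          if (is.null(centers) ||
              all((centers[, 1] - y)^2 + (centers[, 2] - x)^2 >=
                  (sep_scale * (radii[i] + centers[, 3] + 26))^2)) {
            cand <- c(y, x, radii[i]); break
          }
        }
        if (is.null(cand)) { ok <- FALSE; break }
        centers <- rbind(centers, cand)
      }
      if (ok) break
      sep_scale <- sep_scale * 0.9   # relax separation if field is crowded
    }
    tumor2d <- matrix(FALSE, h, w)       # tumor region (incl. DCIS)
    dcis2d <- matrix(FALSE, h, w)
    for (i in seq_len(n_disc)) {
      idx <- disc_idx(h, w, centers[i, 1], centers[i, 2], radii[i])
      tumor2d[idx] <- TRUE
      if (i > length(r_nest)) dcis2d[idx] <- TRUE
    }
    idc2d <- tumor2d & !dcis2d
    a_tumor <- sum(tumor2d)

    # interior region where an immune cell of radius r fits fully inside IDC
    interior_cache <- list()
    interior_idx <- function(r) {
      key <- as.character(r)
      if (is.null(interior_cache[[key]])) {
        er <- erode_disc(idc2d, r + 2)
        interior_cache[[key]] <<- which(er)
      }
      interior_cache[[key]]
    }
    outside_idx <- which(!dilate_disc(tumor2d, 18))

    for (z in seq_len(n_z)) {
      frac <- params$pdl1_fraction_profile[z]
      n_imm <- max(0L, round(params$immune_density_profile[z]))
      target_px <- round(frac * a_tumor)
      need_pos <- if (target_px > 0) ceiling(target_px / 28) + 1L else 0L
      n_in <- min(max(round(0.45 * n_imm), need_pos), 3L * max(n_imm, need_pos))
      n_out <- max(n_imm - n_in, 0L)

      nuc <- matrix(0, h, w); mem <- matrix(0, h, w); mar <- matrix(0, h, w)
      imm2d <- matrix(FALSE, h, w); pos2d <- matrix(FALSE, h, w)

      # immune cells: radius 3-5 px, round, isolated
      r_in <- if (n_in > 0) sample(3:5, n_in, replace = TRUE) else integer(0)
      cen_in <- sample_centers(h, interior_idx(5), n_in, 14)
      n_in <- nrow(cen_in)
      r_in <- r_in[seq_len(n_in)]
      r_out_v <- if (n_out > 0) sample(3:5, n_out, replace = TRUE) else integer(0)
      cen_out <- sample_centers(h, outside_idx, n_out, 14, existing = cen_in)
      n_out <- nrow(cen_out)
      r_out_v <- r_out_v[seq_len(n_out)]

      # tumor nuclei: overlapping ellipses confined to their disc
      for (i in seq_len(n_disc)) {
        n_nuc <- round(pi * radii[i]^2 / 65)
        disc_i <- disc_idx(h, w, centers[i, 1], centers[i, 2], radii[i])
        in_disc <- matrix(FALSE, h, w); in_disc[disc_i] <- TRUE
        for (k in seq_len(n_nuc)) {
          ci <- disc_i[sample.int(length(disc_i), 1)]
          cy <- ((ci - 1L) %% h) + 1L; cx <- ((ci - 1L) %/% h) + 1L
          a <- runif(1, 8, 12); b <- 0.6 * a; th <- runif(1, 0, pi)
          idx <- ellipse_idx(h, w, cy, cx, a, b, th)
          idx <- idx[in_disc[idx]]
          nuc[idx] <- pmax(nuc[idx], runif(1, 0.7, 1.0))
          shell <- ellipse_idx(h, w, cy, cx, a, b, th, q_inner = 0.72)
          shell <- shell[in_disc[shell]]
          mem[shell] <- pmax(mem[shell], runif(1, 0.5, 0.8))
        }
      }

      # carve a dark moat around each immune cell, then stamp it
      all_cen <- rbind(cen_in, cen_out)
      all_r <- c(r_in, r_out_v)
      for (k in seq_len(nrow(all_cen))) {
        moat <- disc_idx(h, w, all_cen[k, 1], all_cen[k, 2], all_r[k] + 2)
        nuc[moat] <- 0
        mem[moat] <- 0
      }
      for (k in seq_len(nrow(all_cen))) {
        cy <- all_cen[k, 1]; cx <- all_cen[k, 2]; r <- all_r[k]
        body <- disc_idx(h, w, cy, cx, r)
        nuc[body] <- runif(1, 0.8, 1.0)
        ring <- disc_idx(h, w, cy, cx, r, r - 1.6)
        mem[ring] <- pmax(mem[ring], runif(1, 0.6, 0.9))
        imm2d[body] <- TRUE
      }

      # designed-fraction PD-L1 positives among intratumoral immune cells
      if (target_px > 0 && n_in > 0) {
        ord <- sample.int(n_in)
        cum <- 0L
        for (k in ord) {
          body <- disc_idx(h, w, cen_in[k, 1], cen_in[k, 2], r_in[k])
          a_cell <- length(body)
          if (abs(cum + a_cell - target_px) <= abs(cum - target_px)) {
            cum <- cum + a_cell
            pos2d[body] <- TRUE
            ring <- disc_idx(h, w, cen_in[k, 1], cen_in[k, 2], r_in[k], r_in[k] - 1.8)
            mar[ring] <- 1.0
          }
          if (cum >= target_px) break
        }
      }

      # DCIS duct boundary: unbroken bright membrane ring
      if (params$dcis_count > 0) {
        for (i in (length(r_nest) + 1):n_disc) {
          ring <- disc_idx(h, w, centers[i, 1], centers[i, 2],
                           radii[i], radii[i] - 3)
          mem[ring] <- 1.0
        }
      }

      att <- exp(-params$intensity_decay_per_um * (z - 1) * params$z_spacing_um)
      sd_ <- params$noise_sigma
      noisy <- function(m) {
        m <- m * att
        if (sd_ > 0) m <- m + matrix(rnorm(h * w, 0, sd_), h, w)
        pmax(m, 0)
      }
      nuclei[z, , ] <- noisy(nuc)
      membrane[z, , ] <- noisy(mem)
      marker[z, , ] <- noisy(mar)
      tumor_mask[z, , ] <- tumor2d
      dcis_mask[z, , ] <- dcis2d
      immune_mask[z, , ] <- imm2d
      pdl1_mask[z, , ] <- pos2d
    }

    voxels <- array(0, c(n_z, h, w, 3))
    voxels[, , , 1] <- nuclei
    voxels[, , , 2] <- membrane
    voxels[, , , 3] <- marker
    stack <- channel_stack(voxels, z_spacing_um = params$z_spacing_um,
                           pixel_size_um = params$pixel_size_um)

    plt <- data.frame(
      z_index = seq_len(n_z) - 1L,
      depth_um = (seq_len(n_z) - 1L) * params$z_spacing_um,
      tumor_px = apply(tumor_mask, 1, sum),
      dcis_px = apply(dcis_mask, 1, sum),
      immune_px = apply(immune_mask, 1, sum),
      immune_in_tumor_px = vapply(seq_len(n_z), function(z)
        sum(immune_mask[z, , ] & tumor_mask[z, , ]), integer(1)),
      pdl1_ic_px = apply(pdl1_mask, 1, sum))
    plt$ic_score_pct <- ifelse(plt$tumor_px > 0,
                               100 * plt$pdl1_ic_px / plt$tumor_px, NA_real_)
    plt$category <- ifelse(is.na(plt$ic_score_pct), NA_character_,
                           categorize(pmin(plt$ic_score_pct, 100)))
    truth <- structure(list(
      tumor_mask = tumor_mask, immune_mask = immune_mask,
      pdl1_pos_mask = pdl1_mask, dcis_mask = dcis_mask,
      per_layer_truth = plt), class = "ground_truth")
    log_info("phantom case: %d layers, tumor area %d px/layer", n_z, a_tumor)
    list(stack = stack, truth = truth, params = params)
  })
}

#' Linear depth gradient of designed IC fractions
#'
#' Models expression appearing (or vanishing) with depth, e.g. no expression
#' superficially changing to positive deeper in the slice.
#'
#' @param start_fraction,end_fraction fractions in \[0, 1\].
#' @param n_z number of layers (>= 1).
#' @return numeric vector of length `n_z`, linear between the endpoints.
#' @export
gradient_profile <- function(start_fraction, end_fraction, n_z) {
  if (start_fraction < 0 || start_fraction > 1 ||
      end_fraction < 0 || end_fraction > 1)
    stopf("fractions must lie in [0, 1]")
  if (n_z < 1) stopf("n_z must be >= 1")
  if (n_z == 1) return(start_fraction)
  seq(start_fraction, end_fraction, length.out = n_z)
}

#' Simulated 2D reference reading of a phantom
#'
#' The most superficial layer (z = 0), adjacent to where the paired
#' histology sections would be cut, serves as the simulated IHC reference:
#' its exact ground-truth IC score and category.
#'
#' @param truth a `ground_truth` object.
#' @return list with `score` (percent) and `category`.
#' @export
render_reference_2d <- function(truth) {
  if (!inherits(truth, "ground_truth")) stopf("truth must be a ground_truth")
  plt <- truth$per_layer_truth
  if (!nrow(plt)) stopf("empty ground truth")
  s <- plt$ic_score_pct[1]
  if (is.na(s)) stopf("layer 0 has no tumor; reference undefined")
  list(score = s, category = categorize(s))
}
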