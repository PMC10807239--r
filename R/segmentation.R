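# Two-stage semantic segmentation: a tumor-cell model and an immune-cell
# model, each a per-pixel classifier on the two counterstain channels
# (nuclei, membrane). Two model families are provided: a trainable
# multiscale-feature logistic classifier (the default "small model"), and a
# deterministic threshold + morphology + size-filter baseline that serves as
# an independent oracle route for the rest of the pipeline.

FEATURE_SIGMAS <- c(2, 4, 8)

# multiscale convolutional features of one (h, w, >=2) layer
pixel_features <- function(layer) {
  if (length(dim(layer)) != 3 || dim(layer)[3] < 2)
    stopf("channel mismatch: layer must have nuclei and membrane channels")
  nuc <- layer[, , 1]; mem <- layer[, , 2]
  g2 <- gaussian_blur(nuc, FEATURE_SIGMAS[1])
  g4 <- gaussian_blur(nuc, FEATURE_SIGMAS[2])
  g8 <- gaussian_blur(nuc, FEATURE_SIGMAS[3])
  gm <- gaussian_blur(mem, FEATURE_SIGMAS[1])
  # local standard deviation at sigma 4: separates dense nuclear texture
  # (tumor nests) from flat background at the same mean brightness
  tex <- sqrt(pmax(gaussian_blur(nuc^2, FEATURE_SIGMAS[2]) - g4^2, 0))
  list(nuc = nuc, mem = mem, g2 = g2, g4 = g4, g8 = g8, gm = gm, tex = tex)
}

features_matrix <- function(feats, idx = NULL) {
  cols <- lapply(feats, function(f) if (is.null(idx)) as.vector(f) else f[idx])
  do.call(cbind, cols)
}

#' Crop annotated images into a seeded train/validation/test patch set
#'
#' Each layer image is zero-padded to a multiple of `patch_size`, cut into a
#' grid of square patches with congruent binary labels, and every patch is
#' randomly assigned to one of the three splits in the configured ratio
#' (default 8:1:1). Assignment is a seeded permutation: deterministic for a
#' fixed seed and disjoint across splits.
#'
#' @param images list of `(h, w, channel)` arrays (>= 2 channels; only the
#'   two counterstains are used downstream), or a single `channel_stack`
#'   whose layers are all used.
#' @param label_stacks list of logary masks congruent with `images` (or a
#'   `(z, y, x)` array when `images` is a stack).
#' @param patch_size square patch edge, default 256.
#' @param ratio three split weights, default `c(8, 1, 1)`.
#' @param seed RNG seed for the assignment.
#' @return a `patchset`: lists `patches` and `labels`, character `split`,
#'   plus `patch_size`.
#' @export
make_patchset <- function(images, label_stacks, patch_size = 256,
                          ratio = c(8, 1, 1), seed = 1) {
  if (inherits(images, "channel_stack")) {
    n_z <- dim(images$voxels)[1]
    lab <- label_stacks
    images <- lapply(seq_len(n_z) - 1L, stack_layer, stack = images)
    label_stacks <- lapply(seq_len(n_z), function(z) lab[z, , ])
  }
  if (!length(images) || length(images) != length(label_stacks))
    stopf("images and label_stacks must be non-empty and congruent")
  if (length(ratio) != 3 || any(ratio < 0) || sum(ratio) <= 0)
    stopf("ratio must be three non-negative weights")
  patches <- list(); labels <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]; lab <- as_mask(label_stacks[[i]])
    d <- dim(img)
    if (length(d) != 3) stopf("each image must be (h, w, channel)")
    check_congruent(lab, img[, , 1], "label and image")
    if (patch_size > max(d[1], d[2]))
      stopf("patch_size %d larger than image (%dx%d)", patch_size, d[1], d[2])
    nh <- ceiling(d[1] / patch_size); nw <- ceiling(d[2] / patch_size)
    pad_img <- array(0, c(nh * patch_size, nw * patch_size, d[3]))
    pad_img[seq_len(d[1]), seq_len(d[2]), ] <- img
    pad_lab <- matrix(FALSE, nh * patch_size, nw * patch_size)
    pad_lab[seq_len(d[1]), seq_len(d[2])] <- lab
    for (r in seq_len(nh)) for (c in seq_len(nw)) {
      ys <- (r - 1) * patch_size + seq_len(patch_size)
      xs <- (c - 1) * patch_size + seq_len(patch_size)
      patches[[length(patches) + 1]] <- pad_img[ys, xs, , drop = FALSE]
      labels[[length(labels) + 1]] <- pad_lab[ys, xs]
    }
  }
  n <- length(patches)
  n_val <- round(n * ratio[2] / sum(ratio))
  n_test <- round(n * ratio[3] / sum(ratio))
  split <- rep("train", n)
  ord <- with_seed(seed, sample.int(n))
  if (n_val > 0) split[ord[seq_len(n_val)]] <- "validation"
  if (n_test > 0) split[ord[n_val + seq_len(n_test)]] <- "test"
  structure(list(patches = patches, labels = labels, split = split,
                 patch_size = patch_size, seed = seed), class = "patchset")
}

#' Train a segmentation model on a patch set
#'
#' The default small model is a per-pixel weighted logistic regression on
#' multiscale counterstain features (raw intensities, Gaussian means at
#' sigma 2/4/8 px and a difference-of-Gaussians band-pass). Class imbalance
#' is handled by a foreground weight equal to the background/foreground
#' pixel ratio, capped at 20. Training is seeded (pixel subsampling) and the
#' validation pixel accuracy is computed and stored.
#'
#' @param patchset a `patchset` from [make_patchset()].
#' @param target `"tumor"` or `"immune"`.
#' @param model_config list: `pixels_per_patch` (default 500 sampled
#'   training pixels per patch), `threshold` (probability cut, default 0.5),
#'   `seed` (default 7), `weight_cap` (default 20).
#' @return a `segmenter` with the fitted coefficients, threshold, target and
#'   `validation_accuracy`.
#' @export
train_segmenter <- function(patchset, target = c("tumor", "immune"),
                            model_config = list()) {
  target <- match.arg(target)
  cfg <- utils::modifyList(list(pixels_per_patch = 500, threshold = 0.5,
                                seed = 7, weight_cap = 20), model_config)
  tr <- which(patchset$split == "train")
  if (!length(tr)) stopf("empty train split")
  X <- list(); y <- list()
  with_seed(cfg$seed, {
    for (i in tr) {
      feats <- pixel_features(patchset$patches[[i]])
      lab <- patchset$labels[[i]]
      n_px <- length(lab)
      take <- sample.int(n_px, min(cfg$pixels_per_patch, n_px))
      X[[length(X) + 1]] <- features_matrix(feats, take)
      y[[length(y) + 1]] <- as.numeric(lab[take])
    }
  })
  X <- do.call(rbind, X); y <- unlist(y)
  if (length(unique(y)) < 2)
    stopf("single-class labels: training split has no %s",
          if (all(y == 0)) "foreground" else "background")
  w_fg <- min(sum(y == 0) / sum(y == 1), cfg$weight_cap)
  w <- ifelse(y == 1, w_fg, 1)
  fit <- suppressWarnings(
    glm.fit(cbind(1, X), y, weights = w, family = binomial()))
  if (!fit$converged)
    warning("segmenter training did not converge; coefficients reported as-is")
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0   # aliased (constant/collinear) features drop out
  seg <- structure(list(
    target = target, type = "logistic",
    coef = coefs, threshold = cfg$threshold,
    patch_size = patchset$patch_size, feature_names = colnames(X),
    converged = fit$converged, validation_accuracy = NA_real_),
    class = "segmenter")
  val <- which(patchset$split == "validation")
  if (length(val)) {
    conf <- Reduce(add_confusion, lapply(val, function(i)
      evaluate_pixelwise(predict_mask(seg, patchset$patches[[i]]),
                         patchset$labels[[i]])))
    seg$validation_accuracy <- conf$accuracy
    log_info("%s model validation accuracy %.3f", target, conf$accuracy)
  }
  seg
}

#' Deterministic threshold + morphology segmenter
#'
#' The classical baseline standing in for a trained model: threshold the
#' nuclei counterstain, clean with a binary opening, and keep connected
#' components in a size range — small round objects for the immune class,
#' large/clustered objects for the tumor class. Fully deterministic; used as
#' the oracle route in end-to-end tests.
#'
#' @param target `"tumor"` or `"immune"`.
#' @param params list: `threshold` (intensity cut on the nuclei channel,
#'   default 0.4), `min_px`/`max_px` (component size range; defaults 150/Inf
#'   for tumor, 12/120 for immune), `open_radius` (default 1).
#' @return a `segmenter` of type `"classical"`.
#' @export
classical_segmenter <- function(target = c("tumor", "immune"), params = list()) {
  target <- match.arg(target)
  defaults <- if (target == "tumor")
    list(threshold = 0.35, min_px = 150, max_px = Inf, open_radius = 0)
  else
    list(threshold = 0.3, min_px = 12, max_px = 120, open_radius = 0)
  p <- utils::modifyList(defaults, params)
  if (is.null(p$threshold) || !is.finite(p$threshold) ||
      is.null(p$min_px) || is.null(p$max_px) || p$min_px > p$max_px)
    stopf("empty or inconsistent classical segmenter parameterization")
  structure(list(target = target, type = "classical", params = p,
                 threshold = 0.5), class = "segmenter")
}

#' @export
print.segmenter <- function(x, ...) {
  cat(sprintf("%s segmenter (%s)\n", x$target, x$type))
  if (x$type == "logistic")
    cat(sprintf("  %d coefficients; validation accuracy %s\n",
                length(x$coef),
                if (is.na(x$validation_accuracy)) "n/a"
                else sprintf("%.3f", x$validation_accuracy)))
  invisible(x)
}

predict_prob_logistic <- function(seg, layer) {
  feats <- pixel_features(layer)
  eta <- cbind(1, features_matrix(feats)) %*% seg$coef
  matrix(stats::plogis(eta), dim(layer)[1], dim(layer)[2])
}

predict_classical <- function(seg, layer) {
  p <- seg$params
  nuc <- layer[, , 1]
  m <- nuc >= p$threshold
  if (p$open_radius > 0) m <- dilate_disc(erode_disc(m, p$open_radius), p$open_radius)
  if (!any(m)) return(m)
  lab <- label_components(m, 8)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= p$min_px & sizes <= p$max_px)
  out <- matrix(FALSE, nrow(m), ncol(m))
  if (length(keep)) out[lab %in% keep] <- TRUE
  out
}

#' Predict a binary mask for one full layer
#'
#' Logistic models are applied tile-wise at the training patch size with 50%
#' overlap; overlapping probabilities are averaged before one global
#' threshold, so tile seams introduce no mask artifacts. The classical
#' segmenter runs on the full layer directly. Inference is deterministic.
#'
#' @param segmenter a `segmenter`.
#' @param layer `(h, w, channel)` array with the counterstain channels
#'   first.
#' @return logical mask `(h, w)`.
#' @export
predict_mask <- function(segmenter, layer) {
  if (length(dim(layer)) != 3 || dim(layer)[3] < 2)
    stopf("channel mismatch: layer must carry at least 2 channels")
  if (segmenter$type == "classical") return(predict_classical(segmenter, layer))
  h <- dim(layer)[1]; w <- dim(layer)[2]
  ps <- segmenter$patch_size %||% 256
  if (h <= ps && w <= ps) {
    prob <- predict_prob_logistic(segmenter, layer)
    return(prob >= segmenter$threshold)
  }
  stride <- max(1L, ps %/% 2L)
  acc <- matrix(0, h, w); wt <- matrix(0, h, w)
  ys <- unique(c(seq(1, max(1, h - ps + 1), by = stride), max(1, h - ps + 1)))
  xs <- unique(c(seq(1, max(1, w - ps + 1), by = stride), max(1, w - ps + 1)))
  for (y0 in ys) for (x0 in xs) {
    yy <- y0:min(h, y0 + ps - 1); xx <- x0:min(w, x0 + ps - 1)
    p <- predict_prob_logistic(segmenter, layer[yy, xx, , drop = FALSE])
    acc[yy, xx] <- acc[yy, xx] + p
    wt[yy, xx] <- wt[yy, xx] + 1
  }
  (acc / wt) >= segmenter$threshold
}

#' Exact pixelwise confusion counts and derived metrics
#'
#' Integer TP/FP/FN/TN over congruent binary masks, with pixel accuracy,
#' precision, recall and IoU. Empty-target conventions: IoU (and
#' precision/recall) are defined as 1 when their denominator is empty, so an
#' empty prediction on an empty target is a perfect score rather than 0/0.
#'
#' @param pred_mask,truth_mask congruent binary masks.
#' @return a `pixel_confusion` list: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `precision`, `recall`, `iou`.
#' @export
evaluate_pixelwise <- function(pred_mask, truth_mask) {
  check_congruent(pred_mask, truth_mask)
  p <- as_mask(pred_mask); t <- as_mask(truth_mask)
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  mk <- function(num, den) if (den == 0) 1 else num / den
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 accuracy = (tp + tn) / (tp + fp + fn + tn),
                 precision = mk(tp, tp + fp),
                 recall = mk(tp, tp + fn),
                 iou = mk(tp, tp + fp + fn)),
            class = "pixel_confusion")
}

# pool two confusion objects (summing counts, recomputing metrics)
add_confusion <- function(a, b) {
  tp <- a$tp + b$tp; fp <- a$fp + b$fp; fn <- a$fn + b$fn; tn <- a$tn + b$tn
  mk <- function(num, den) if (den == 0) 1 else num / den
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / (tp + fp + fn + tn),
                 precision = mk(tp, tp + fp), recall = mk(tp, tp + fn),
                 iou = mk(tp, tp + fp + fn)), class = "pixel_confusion")
}

#' Evaluate a segmenter on one split of a patch set
#'
#' Pools pixel confusion counts over all patches of the split.
#'
#' @param segmenter a `segmenter`.
#' @param patchset a `patchset`.
#' @param split `"test"` (default), `"validation"` or `"train"`.
#' @return a `pixel_confusion`.
#' @export
evaluate_split <- function(segmenter, patchset, split = "test") {
  idx <- which(patchset$split == split)
  if (!length(idx)) stopf("no patches in split '%s'", split)
  Reduce(add_confusion, lapply(idx, function(i)
    evaluate_pixelwise(predict_mask(segmenter, patchset$patches[[i]]),
                       patchset$labels[[i]])))
}

#' Serialize / restore a segmenter as JSON
#'
#' @param segmenter a `segmenter`.
#' @param path JSON file.
#' @return `path` / the restored `segmenter`.
#' @export
write_segmenter <- function(segmenter, path) {
  jsonlite::write_json(unclass(segmenter), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_segmenter
#' @export
read_segmenter <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!is.null(obj$params)) {
    obj$params <- lapply(as.list(obj$params), function(v)
      if (is.character(v) && v %in% c("Inf", "-Inf")) as.numeric(v) else v)
  }
  structure(obj, class = "segmenter")
}
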