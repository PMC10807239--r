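test_that("make_patchset splits 8:1:1 deterministically and disjointly", {
  img <- array(runif(64 * 64 * 2), c(64, 64, 2))
  lab <- matrix(FALSE, 64, 64); lab[10:20, 10:20] <- TRUE
  imgs <- replicate(20, img, simplify = FALSE)   # 20 x 4 patches of 32 = 80
  labs <- replicate(20, lab, simplify = FALSE)
  ps <- make_patchset(imgs, labs, patch_size = 32, seed = 5)
  expect_equal(as.integer(table(ps$split)[c("train", "validation", "test")]),
               c(64L, 8L, 8L))
  ps2 <- make_patchset(imgs, labs, patch_size = 32, seed = 5)
  expect_identical(ps$split, ps2$split)
  ps3 <- make_patchset(imgs, labs, patch_size = 32, seed = 6)
  expect_false(identical(ps$split, ps3$split))
  expect_equal(table(ps3$split), table(ps$split))  # proportions unchanged

  # 10 patches -> 8/1/1
  ps10 <- make_patchset(imgs[1:10], labs[1:10], patch_size = 64, seed = 1)
  expect_equal(sort(as.integer(table(ps10$split))), c(1L, 1L, 8L))

  expect_error(make_patchset(imgs[1:2], labs[1:2], patch_size = 128), "larger")
  expect_error(make_patchset(list(), list()), "non-empty")
})

test_that("evaluate_pixelwise counts match the enumerated 4-pixel example", {
  pred <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  truth <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  pc <- evaluate_pixelwise(pred, truth)
  expect_equal(unlist(pc[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_equal(pc$accuracy, 0.5)
  # identity and anti-identity
  expect_equal(evaluate_pixelwise(truth, truth)$accuracy, 1)
  expect_equal(evaluate_pixelwise(truth, truth)$iou, 1)
  expect_equal(evaluate_pixelwise(!truth, truth)$accuracy, 0)
  # empty-target convention
  none <- matrix(FALSE, 2, 2)
  expect_equal(evaluate_pixelwise(none, none)$iou, 1)
  expect_error(evaluate_pixelwise(pred, matrix(TRUE, 3, 3)), "shape mismatch")
})

test_that("pixel confusion equals a brute-force loop on 100 random mask pairs", {
  set.seed(20)
  for (k in 1:100) {
    pred <- matrix(runif(256) < runif(1), 16, 16)
    truth <- matrix(runif(256) < runif(1), 16, 16)
    pc <- evaluate_pixelwise(pred, truth)
    bf <- brute_confusion(pred, truth)
    expect_identical(unlist(pc[c("tp", "fp", "fn", "tn")]), bf)
    expect_equal(pc$accuracy, (bf["tp"] + bf["tn"]) / 256, ignore_attr = TRUE)
    denom <- bf["tp"] + bf["fp"] + bf["fn"]
    expect_equal(pc$iou, if (denom == 0) 1 else bf[["tp"]] / denom,
                 ignore_attr = TRUE)
  }
})

test_that("classical segmenters recover phantom structures deterministically", {
  case <- small_phantom(n_z = 1, fraction = 0.02, seed = 31)
  layer <- layer_of(case)
  segs <- classical_segs()
  imm <- predict_mask(segs$immune, layer)
  tri <- case$truth$immune_mask[1, , ]
  expect_gte(sum(imm & tri) / sum(tri), 0.9)   # voxel recall
  tum <- predict_mask(segs$tumor, layer)
  merged <- merge_tumor_area(tum, 10, 2000)
  expect_gte(evaluate_pixelwise(merged, case$truth$tumor_mask[1, , ])$iou, 0.7)
  # determinism
  expect_identical(imm, predict_mask(segs$immune, layer))
  # blank layer -> empty masks
  blank <- array(0, dim(layer))
  expect_false(any(predict_mask(segs$immune, blank)))
  expect_false(any(predict_mask(segs$tumor, blank)))
  # size filter excluding everything -> empty
  strict <- classical_segmenter("immune", list(min_px = 1e6, max_px = Inf))
  expect_error(classical_segmenter("immune", list(min_px = 10, max_px = 1)),
               "parameterization")
  expect_false(any(predict_mask(strict, layer)))
})

test_that("channel mismatch is rejected at prediction time", {
  seg <- classical_segmenter("tumor")
  expect_error(predict_mask(seg, array(0, c(16, 16, 1))), "channel mismatch")
  expect_error(predict_mask(seg, matrix(0, 16, 16)), "channel mismatch")
})

test_that("trained segmenter separates trivially separable patches", {
  # foreground and background occupy disjoint intensity ranges
  set.seed(7)
  mk_patch <- function() {
    lab <- matrix(FALSE, 48, 48)
    lab[sample(38, 1) + 0:8, sample(38, 1) + 0:8] <- TRUE
    img <- array(0, c(48, 48, 2))
    bg <- matrix(runif(48 * 48, 0, 0.1), 48, 48)
    bg[lab] <- runif(sum(lab), 0.8, 1)
    img[, , 1] <- bg
    img[, , 2] <- 0.05
    list(img = img, lab = lab)
  }
  ps <- local({
    pl <- replicate(30, mk_patch(), simplify = FALSE)
    make_patchset(lapply(pl, `[[`, "img"), lapply(pl, `[[`, "lab"),
                  patch_size = 48, seed = 2)
  })
  # perfectly separable data: glm reaches the separation boundary of its
  # iteration budget, which it reports as non-convergence
  seg <- suppressWarnings(train_segmenter(ps, "tumor", model_config = list(seed = 3)))
  conf <- evaluate_split(seg, ps, "test")
  expect_gte(conf$accuracy, 0.95)
  # against a fixed-threshold oracle classifier on the same patches
  idx <- which(ps$split == "test")
  oracle <- Reduce(icscore3d:::add_confusion,
                   lapply(idx, function(i)
                     evaluate_pixelwise(ps$patches[[i]][, , 1] >= 0.5,
                                        ps$labels[[i]])))
  expect_gte(oracle$accuracy, 0.99)  # the task really is separable
  expect_gte(conf$accuracy, oracle$accuracy - 0.05)
})

test_that("single-class training labels are rejected", {
  img <- array(runif(32 * 32 * 2), c(32, 32, 2))
  labs <- replicate(10, matrix(FALSE, 32, 32), simplify = FALSE)
  ps <- make_patchset(replicate(10, img, simplify = FALSE), labs,
                      patch_size = 32, seed = 1)
  expect_error(train_segmenter(ps, "immune"), "single-class")
})

test_that("tiled prediction is consistent with single-patch prediction", {
  case <- small_phantom(n_z = 1, fraction = 0.02, seed = 31)
  layer <- layer_of(case)
  ps <- make_patchset(list(layer), list(case$truth$tumor_mask[1, , ]),
                      patch_size = 96, ratio = c(1, 0, 0), seed = 1)
  seg <- train_segmenter(ps, "tumor", model_config = list(seed = 5))
  # replicate one training patch in a 2x2 tile
  patch <- ps$patches[[1]]
  tile <- array(0, c(192, 192, dim(patch)[3]))
  for (dy in c(0, 96)) for (dx in c(0, 96))
    tile[dy + 1:96, dx + 1:96, ] <- patch
  single <- predict_mask(seg, patch)
  tiled <- predict_mask(seg, tile)
  # away from seams (central half of each tile) predictions agree
  core <- 24:72
  expect_gte(mean(tiled[core, core] == single[core, core]), 0.98)
})

test_that("segmenters serialize and round-trip through JSON", {
  case <- small_phantom(n_z = 1, fraction = 0.02, seed = 31)
  layer <- layer_of(case)
  path <- withr::local_tempfile(fileext = ".json")
  seg <- classical_segmenter("immune")
  write_segmenter(seg, path)
  back <- read_segmenter(path)
  expect_identical(predict_mask(back, layer), predict_mask(seg, layer))
})
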