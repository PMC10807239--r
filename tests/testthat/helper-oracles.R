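# Brute-force reference implementations, independent of the package's
# distance-transform / Rcpp code paths. Slow but transparent; used on small
# masks only.

brute_dilate <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  fg <- which(mask, arr.ind = TRUE)
  if (!nrow(fg)) return(out)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    d2 <- (fg[, 1] - i)^2 + (fg[, 2] - j)^2
    if (min(d2) <= r * r + 1e-9) out[i, j] <- TRUE
  }
  out
}

brute_erode <- function(mask, r) !brute_dilate(!mask, r)

brute_fill_holes <- function(mask, max_px = Inf) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (sj in seq_len(w)) for (si in seq_len(h)) {
    if (mask[si, sj] || lab[si, sj]) next
    nxt <- nxt + 1L
    queue <- list(c(si, sj)); lab[si, sj] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- p[1] + d[1]; jj <- p[2] + d[2]
        if (ii < 1 || jj < 1 || ii > h || jj > w) next
        if (!mask[ii, jj] && !lab[ii, jj]) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  out <- mask
  for (k in seq_len(nxt)) {
    if (k %in% border) next
    if (sum(lab == k) <= max_px) out[lab == k] <- TRUE
  }
  out
}

brute_confusion <- function(pred, truth) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (k in seq_along(pred)) {
    if (pred[k] && truth[k]) tp <- tp + 1L
    else if (pred[k] && !truth[k]) fp <- fp + 1L
    else if (!pred[k] && truth[k]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

random_blob_mask <- function(h, w, n_seeds = 4, r_range = c(3, 9)) {
  m <- matrix(FALSE, h, w)
  for (k in seq_len(n_seeds)) {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    r <- runif(1, r_range[1], r_range[2])
    for (i in seq_len(h)) for (j in seq_len(w))
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
  }
  m
}
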