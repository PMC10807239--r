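`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a local RNG seed, restoring the caller's RNG state after.
# All stochastic entry points route through this so no global state leaks.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_binary_mask <- function(m, name = "mask") {
  if (!is.logical(m) && !all(m %in% c(0, 1, TRUE, FALSE)))
    stopf("%s must be binary (logical or 0/1)", name)
  invisible(TRUE)
}

as_mask <- function(m) {
  if (is.logical(m)) m else array(m != 0, dim = dim(m) %||% length(m))
}

check_congruent <- function(a, b, what = "masks") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (length(da) != length(db) || any(da != db))
    stopf("shape mismatch: %s have dims (%s) vs (%s)", what,
          paste(da, collapse = ","), paste(db, collapse = ","))
  invisible(TRUE)
}

log_info <- function(fmt, ...) {
  if (isTRUE(getOption("icscore3d.verbose", FALSE)))
    message(sprintf("[icscore3d] %s", sprintf(fmt, ...)))
  invisible(NULL)
}
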