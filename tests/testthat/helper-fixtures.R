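# Shared small phantom fixtures, generated once per test run.
fixture_env <- new.env()

small_phantom <- function(n_z = 3, fraction = 0.02, seed = 42, ...) {
  key <- paste("p", n_z, paste(fraction, collapse = "_"), seed,
               paste(unlist(list(...)), collapse = "_"), sep = "-")
  if (is.null(fixture_env[[key]])) {
    p <- phantom_params(image_shape = c(n_z, 192, 192),
                        pdl1_fraction_profile = fraction, seed = seed, ...)
    fixture_env[[key]] <- generate_case(p)
  }
  fixture_env[[key]]
}

layer_of <- function(case, z = 0) {
  l <- case$stack$voxels[z + 1, , , , drop = TRUE]
  dim(l) <- dim(case$stack$voxels)[c(2, 3, 4)]
  l
}

classical_segs <- function() {
  list(tumor = classical_segmenter("tumor"),
       immune = classical_segmenter("immune"))
}
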