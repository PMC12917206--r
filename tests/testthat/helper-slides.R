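# Small slides shared across test files, built once per test run.

small_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_slide(n_rows = 6, n_cols = 6, n_genes = 3, seed = 7)
    cache
  }
})

small_tiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sl <- small_slide()
      cache <<- extract_tiles(sl$image, sl$spots, tile_px = sl$tile_px)
    }
    cache
  }
})

small_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- extract_features(small_tiles())
    cache
  }
})

# strong-signal slide for classification checks: wide expression spread
# (slope 2) and mild overdispersion so the High/Low signal is learnable
classification_slide <- function(seed = 11, n_rows = 20, n_cols = 20,
                                 n_genes = 4) {
  generate_slide(
    n_rows = n_rows, n_cols = n_cols, n_genes = n_genes, seed = seed,
    link_coeffs = data.frame(gene = sprintf("gene_%02d", seq_len(n_genes)),
                             a = rep(2, n_genes), b = rep(2, n_genes)),
    dispersion_range = c(30, 50))
}
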