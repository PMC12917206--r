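## Tile -> embedding extraction behind one surface. Three kinds:
##   handcrafted — deterministic morphometrics, used throughout the tests
##   imported    — adapter for externally computed embeddings
##   builtin_cnn — a small seeded random-filter convolutional bank with
##                 global average pooling (frozen weights; the trainable
##                 part of the model lives in the NB head / adapter)

#' Describe a feature extractor
#'
#' @param kind `"handcrafted"`, `"imported"` or `"builtin_cnn"`.
#' @param output_dim embedding dimension F (`builtin_cnn` only; the
#'   handcrafted extractor has a fixed F = 9, imported inherits F from
#'   the embedding table).
#' @param embeddings for `"imported"`: a spots x F matrix with spot-id
#'   rownames (e.g. from [read_embeddings]).
#' @param seed for `"builtin_cnn"`: seed that freezes the filter weights.
#' @param downsample_px side length tiles are averaged down to before
#'   convolution (`builtin_cnn` only).
#' @return list of class `extractor_spec`.
#' @export
extractor_spec <- function(kind = c("handcrafted", "imported", "builtin_cnn"),
                           output_dim = 64L, embeddings = NULL, seed = 0L,
                           downsample_px = 32L) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, pooling = "global_average")
  if (kind == "imported") {
    if (is.null(embeddings))
      stop_spotnb("imported extractor needs an embeddings matrix",
                  "spotnb_parameter_error")
    spec$embeddings <- embeddings
    spec$output_dim <- ncol(embeddings)
  } else if (kind == "builtin_cnn") {
    if (output_dim < 1)
      stop_spotnb("output_dim must be >= 1", "spotnb_parameter_error")
    spec$output_dim <- as.integer(output_dim)
    spec$seed <- as.integer(seed)
    spec$downsample_px <- as.integer(downsample_px)
    spec$kernel_px <- 5L
    spec$weights <- with_seed(seed, {
      k <- spec$kernel_px
      matrix(rnorm(k * k * 3 * output_dim, sd = 1 / sqrt(k * k * 3)),
             nrow = k * k * 3, ncol = output_dim)
    })
  } else {
    spec$output_dim <- 9L
  }
  structure(spec, class = "extractor_spec")
}

handcrafted_feature_names <- c(
  "fg_frac", "mean_r", "mean_g", "mean_b", "var_r", "var_g", "var_b",
  "n_blobs", "mean_blob_area")

# Morphometrics of one tile: foreground fraction, per-channel mean and
# variance, blob count (connected components of the foreground mask with
# area >= min_area) and mean blob area. All are invariant to flips and
# 90-degree rotations.
handcrafted_tile_features <- function(tile, min_area = 5L) {
  mask <- tissue_mask(tile)
  feats <- c(
    mean(mask),
    mean(tile[, , 1]), mean(tile[, , 2]), mean(tile[, , 3]),
    stats::var(as.vector(tile[, , 1])), stats::var(as.vector(tile[, , 2])),
    stats::var(as.vector(tile[, , 3]))
  )
  if (any(mask)) {
    lab <- EBImage::bwlabel(mask)
    areas <- tabulate(lab[lab > 0])
    areas <- areas[areas >= min_area]
    feats <- c(feats, length(areas), if (length(areas)) mean(areas) else 0)
  } else {
    feats <- c(feats, 0, 0)
  }
  setNames(feats, handcrafted_feature_names)
}

# block-average a channel matrix down to out_px x out_px
block_downsample <- function(m, out_px) {
  n <- nrow(m)
  idx <- pmin(floor((seq_len(n) - 1) * out_px / n) + 1L, out_px)
  rowsum_m <- rowsum(m, idx)
  t(rowsum(t(rowsum_m), idx)) / tcrossprod(tabulate(idx, out_px))
}

# im2col: all k x k patches (valid) of a 2-D matrix as rows
im2col <- function(m, k) {
  n_out <- nrow(m) - k + 1L
  cols <- matrix(0, n_out * n_out, k * k)
  ci <- 1L
  for (dx in seq_len(k)) for (dy in seq_len(k)) {
    cols[, ci] <- as.vector(m[dy:(dy + n_out - 1L), dx:(dx + n_out - 1L)])
    ci <- ci + 1L
  }
  cols
}

builtin_cnn_tile_features <- function(tile, spec) {
  d <- spec$downsample_px
  small <- lapply(1:3, function(ch) block_downsample(tile[, , ch], d) / 255)
  patches <- do.call(cbind, lapply(small, im2col, k = spec$kernel_px))
  act <- pmax(patches %*% spec$weights, 0)     # ReLU
  colMeans(act)                                # global average pooling
}

#' Extract per-spot feature embeddings from tiles
#'
#' Applies the configured extractor to every tile and returns the
#' spots x F embedding matrix (rows sorted by spot id). All extractors
#' are pure functions of the tile given fixed weights, so identical tiles
#' map to identical embeddings.
#'
#' @param tiles a [tile_set].
#' @param spec an [extractor_spec] (default: handcrafted morphometrics).
#' @return spots x F matrix of class `latent_features`.
#' @export
extract_features <- function(tiles, spec = extractor_spec("handcrafted")) {
  ids <- tiles$spot_id
  if (spec$kind == "imported") {
    missing <- setdiff(ids, rownames(spec$embeddings))
    if (length(missing))
      stop_spotnb(sprintf("no embedding row for spot(s): %s",
                          paste(missing, collapse = ", ")),
                  "spotnb_alignment_error")
    m <- spec$embeddings[ids, , drop = FALSE]
  } else {
    f <- switch(spec$kind,
                handcrafted = function(t) handcrafted_tile_features(t),
                builtin_cnn = function(t) builtin_cnn_tile_features(t, spec))
    rows <- lapply(tiles$tiles, f)
    m <- do.call(rbind, rows)
    rownames(m) <- ids
    if (spec$kind == "builtin_cnn")
      colnames(m) <- paste0("cnn_", seq_len(ncol(m)))
  }
  latent_features(m, extractor = spec$kind)
}
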