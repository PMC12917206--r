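## Spot-centred tiling, tissue-coverage QC, stain normalisation and
## augmentation. Geometry convention: a tile of side T around a spot
## centre c (0-based pixel coordinates) spans [c - floor(T/2),
## c - floor(T/2) + T) on each axis.

#' Construct a tile set
#' @param tiles named list (by spot id) of T x T x 3 arrays in \[0, 255\].
#' @param tile_px tile side length in pixels.
#' @param coverage optional named numeric tissue-coverage per tile.
#' @param provenance optional character tag per tile (e.g. augmentation op).
#' @return list of class `tile_set`.
#' @export
tile_set <- function(tiles, tile_px, coverage = NULL, provenance = NULL) {
  ids <- names(tiles)
  if (is.null(ids) || anyDuplicated(ids))
    stop_spotnb("tiles must be uniquely named by spot id", "spotnb_validation_error")
  for (t in tiles)
    if (!all(dim(t)[1:2] == tile_px))
      stop_spotnb("all tiles must share the same tile_px", "spotnb_validation_error")
  structure(list(
    tiles = tiles,
    spot_id = ids,
    tile_px = as.integer(tile_px),
    coverage = coverage %||% setNames(rep(NA_real_, length(ids)), ids),
    provenance = provenance %||% setNames(rep("original", length(ids)), ids)
  ), class = "tile_set")
}

#' @export
length.tile_set <- function(x) length(x$tiles)

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> %d tiles of %dx%d px (%d with coverage computed)\n",
              length(x), x$tile_px, x$tile_px, sum(!is.na(x$coverage))))
  invisible(x)
}

#' Extract spot-centred tiles from a slide image
#'
#' Crops one square tile per in-tissue spot, centred on the spot's pixel
#' coordinates. For tile side T the window is
#' `[c - floor(T/2), c - floor(T/2) + T)` per axis, so the spot centre is
#' the exact centre pixel for odd T (within one pixel for even T).
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param spots a [spot_table]; only `in_tissue` spots are tiled.
#' @param tile_px tile side in pixels (default 299).
#' @param edge_policy `"drop"` omits spots whose window leaves the image
#'   (with a message); `"pad_reflect"` mirror-pads the image instead.
#' @return A [tile_set] keyed by spot id.
#' @export
extract_tiles <- function(image, spots, tile_px = 299L,
                          edge_policy = c("drop", "pad_reflect")) {
  edge_policy <- match.arg(edge_policy)
  tile_px <- as.integer(tile_px)
  if (tile_px <= 0)
    stop_spotnb("tile_px must be positive", "spotnb_parameter_error")
  spots <- spots[spots$in_tissue, , drop = FALSE]
  if (nrow(spots) == 0)
    stop_spotnb("no in-tissue spots to tile", "spotnb_empty_error")
  H <- dim(image)[1]; W <- dim(image)[2]
  half <- tile_px %/% 2L
  tiles <- list(); dropped <- character()
  for (i in seq_len(nrow(spots))) {
    # 0-based window start per axis
    x0 <- spots$pixel_x[i] - half
    y0 <- spots$pixel_y[i] - half
    if (x0 < 0 || y0 < 0 || x0 + tile_px > W || y0 + tile_px > H) {
      if (edge_policy == "drop") {
        dropped <- c(dropped, spots$spot_id[i])
        next
      }
      rows <- reflect_index(y0 + seq_len(tile_px), H)
      cols <- reflect_index(x0 + seq_len(tile_px), W)
      tiles[[spots$spot_id[i]]] <- image[rows, cols, , drop = FALSE]
    } else {
      tiles[[spots$spot_id[i]]] <-
        image[y0 + seq_len(tile_px), x0 + seq_len(tile_px), , drop = FALSE]
    }
  }
  if (length(dropped))
    message(sprintf("extract_tiles: dropped %d spot(s) at the image edge: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (!length(tiles))
    stop_spotnb("all spots fell outside the image", "spotnb_empty_error")
  tile_set(tiles, tile_px)
}

# mirror (reflect) 1-based indices into [1, n]
reflect_index <- function(idx, n) {
  idx <- abs(idx - 1L)
  period <- 2L * (n - 1L)
  idx <- idx %% period
  ifelse(idx >= n, period - idx, idx) + 1L
}

# Otsu threshold on values in [0, 1]; returns NA when the histogram is
# effectively single-binned (degenerate input).
otsu_threshold <- function(x, levels = 256L) {
  h <- tabulate(pmin(pmax(floor(x * levels) + 1L, 1L), levels), levels)
  if (sum(h > 0) < 2) return(NA_real_)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 0.5) / levels
}

# Logical tissue-foreground mask of an RGB tile: pixels whose HSV
# saturation exceeds an Otsu threshold on the saturation channel, with a
# fixed 0.05 fallback when the saturation histogram is degenerate.
tissue_mask <- function(tile) {
  if (length(dim(tile)) != 3 || dim(tile)[3] < 3)
    stop_spotnb("tissue mask requires an RGB tile", "spotnb_format_error")
  hsv <- grDevices::rgb2hsv(as.vector(tile[, , 1]), as.vector(tile[, , 2]),
                            as.vector(tile[, , 3]), maxColorValue = 255)
  sat <- hsv[2, ]
  thr <- otsu_threshold(sat)
  if (is.na(thr) || thr <= 0 || thr >= 1) thr <- 0.05
  matrix(sat > thr, nrow = dim(tile)[1])
}

#' Tissue coverage of a tile
#'
#' Fraction of pixels classified as tissue foreground. Foreground is
#' defined on the HSV saturation channel: pixels above an Otsu threshold
#' computed on that channel (fixed threshold 0.05 when Otsu degenerates,
#' e.g. on a blank tile). Deterministic for a fixed tile.
#'
#' @param tile T x T x 3 array in \[0, 255\].
#' @return real in \[0, 1\].
#' @export
tissue_coverage <- function(tile) {
  mean(tissue_mask(tile))
}

compute_coverage <- function(tiles) {
  tiles$coverage <- setNames(
    vapply(tiles$tiles, tissue_coverage, numeric(1)), tiles$spot_id)
  tiles
}

#' Filter tiles by tissue coverage
#'
#' Keeps exactly the tiles whose tissue coverage is at least
#' `min_coverage` (default 0.70: tiles covering less than 70% tissue are
#' removed). Coverage is computed on demand; tile order is preserved.
#'
#' @param tiles a [tile_set].
#' @param min_coverage threshold in \[0, 1\].
#' @return The filtered [tile_set] with coverage filled in.
#' @export
qc_filter <- function(tiles, min_coverage = 0.70) {
  if (!is.numeric(min_coverage) || min_coverage < 0 || min_coverage > 1)
    stop_spotnb("min_coverage must lie in [0, 1]", "spotnb_parameter_error")
  if (anyNA(tiles$coverage)) tiles <- compute_coverage(tiles)
  keep <- tiles$coverage >= min_coverage
  tile_set(tiles$tiles[keep], tiles$tile_px,
           coverage = tiles$coverage[keep],
           provenance = tiles$provenance[keep])
}

## ---- stain normalisation ----------------------------------------------

# Optical density of 8-bit intensities; +1 guards log(0).
rgb_to_od <- function(I) -log((I + 1) / 256)
od_to_rgb <- function(D) pmin(pmax(exp(-D) * 256 - 1, 0), 255)

# 3 x n matrix of foreground OD pixels (subsampled deterministically).
od_pixels <- function(img, max_px = 10000L) {
  mask <- tissue_mask(img)
  if (!any(mask))
    stop_spotnb("no tissue pixels found in the stain reference",
                "spotnb_degenerate_error")
  V <- rbind(rgb_to_od(img[, , 1])[mask],
             rgb_to_od(img[, , 2])[mask],
             rgb_to_od(img[, , 3])[mask])
  if (ncol(V) > max_px)
    V <- V[, round(seq(1, ncol(V), length.out = max_px)), drop = FALSE]
  V
}

# Macenko-style two-stain basis: SVD plane of the OD cloud, extreme
# angle percentiles (1/99). Returns a 2 x 3 matrix (rows = stains,
# unit-norm), haematoxylin-like stain (larger red OD) first.
macenko_basis <- function(V) {
  e <- eigen(stats::cov(t(V)), symmetric = TRUE)
  plane <- e$vectors[, 1:2, drop = FALSE]
  # orient so projections are mostly positive
  for (j in 1:2) if (sum(crossprod(plane[, j], V)) < 0) plane[, j] <- -plane[, j]
  proj <- crossprod(plane, V)                      # 2 x n
  phi <- atan2(proj[2, ], proj[1, ])
  q <- stats::quantile(phi, c(0.01, 0.99), names = FALSE)
  v1 <- plane %*% c(cos(q[1]), sin(q[1]))
  v2 <- plane %*% c(cos(q[2]), sin(q[2]))
  W <- cbind(as.vector(v1), as.vector(v2))
  W <- pmax(W, 0)
  norms <- sqrt(colSums(W^2))
  if (any(norms < 1e-8))
    stop_spotnb("degenerate stain basis", "spotnb_degenerate_error")
  W <- sweep(W, 2, norms, "/")
  if (W[1, 1] < W[1, 2]) W <- W[, 2:1]            # H-like stain first
  t(W)
}

# Sparse two-stain dictionary refinement (multiplicative-update NMF with
# an L1 penalty on concentrations), initialised from the Macenko basis.
vahadane_basis <- function(V, sparsity = 0.1, n_iter = 50L) {
  W <- t(macenko_basis(V))                         # 3 x 2
  H <- stain_concentrations(t(W), V)               # 2 x n
  eps <- 1e-8
  for (it in seq_len(n_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + sparsity + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    W <- sweep(W, 2, pmax(sqrt(colSums(W^2)), eps), "/")
  }
  if (any(!is.finite(W)))
    stop_spotnb("stain dictionary learning failed", "spotnb_degenerate_error")
  if (W[1, 1] < W[1, 2]) W <- W[, 2:1]
  t(W)
}

# Non-negative concentrations of a 2 x 3 basis (rows = stains) on OD
# pixels V (3 x n): least squares clamped at zero.
stain_concentrations <- function(basis, V) {
  W <- t(basis)                                    # 3 x 2
  C <- solve(crossprod(W), crossprod(W, V))
  pmax(C, 0)
}

#' Fit a stain template from a reference image or tile set
#'
#' Captures the reference's two-stain colour basis (unit-norm rows), the
#' 99th percentile of each stain's pixel concentration, and the mean
#' R, G, B intensities — the statistics [normalise_stain] maps other
#' tiles onto.
#'
#' @param reference an RGB array in \[0, 255\] or a [tile_set] (tiles are
#'   pooled).
#' @param method `"vahadane"` (sparse dictionary learning, default) or
#'   `"macenko"` (SVD-plane angle percentiles).
#' @return list of class `stain_template` with `basis` (2 x 3),
#'   `conc_p99` (length 2) and `channel_means` (length 3).
#' @export
fit_stain_template <- function(reference, method = c("vahadane", "macenko")) {
  method <- match.arg(method)
  img <- if (inherits(reference, "tile_set")) pool_tiles(reference) else reference
  V <- od_pixels(img)
  basis <- if (method == "vahadane") vahadane_basis(V) else macenko_basis(V)
  conc <- stain_concentrations(basis, V)
  structure(list(
    basis = basis,
    conc_p99 = apply(conc, 1, stats::quantile, probs = 0.99, names = FALSE),
    channel_means = apply(img, 3, mean),
    method = method
  ), class = "stain_template")
}

# stack a tile set's pixels into one tall pseudo-image
pool_tiles <- function(tiles) {
  arrs <- tiles$tiles
  out <- array(0, dim = c(tiles$tile_px * length(arrs), tiles$tile_px, 3))
  for (i in seq_along(arrs))
    out[(i - 1) * tiles$tile_px + seq_len(tiles$tile_px), , ] <- arrs[[i]]
  out
}

#' Normalise a tile's stain appearance onto a template
#'
#' `"vahadane"` (default) and `"macenko"` separate the tile into two
#' stain concentration maps in optical-density space, rescale each
#' stain's concentrations to the template's 99th percentiles, and
#' reconstruct with the template basis; a final per-channel gain aligns
#' the mean R, G, B intensities with the template's (the channel-mean
#' contract), preserving the within-channel rank order of pixel optical
#' densities. `"channel_mean"` applies only the gain step. If stain
#' separation fails numerically the function warns and falls back to
#' `"channel_mean"`; an all-background tile is returned unchanged with a
#' warning.
#'
#' @param tile T x T x 3 array in \[0, 255\].
#' @param template a [fit_stain_template] result.
#' @param method `"vahadane"`, `"macenko"` or `"channel_mean"`.
#' @return The normalised tile (same shape, \[0, 255\]).
#' @export
normalise_stain <- function(tile, template,
                            method = c("vahadane", "macenko", "channel_mean")) {
  method <- match.arg(method)
  if (!any(tissue_mask(tile))) {
    warning("all-background tile; returned unchanged")
    return(tile)
  }
  if (method != "channel_mean") {
    out <- tryCatch({
      V <- od_pixels(tile, max_px = 5000L)
      basis <- if (method == "vahadane") vahadane_basis(V) else macenko_basis(V)
      Dfull <- rbind(as.vector(rgb_to_od(tile[, , 1])),
                     as.vector(rgb_to_od(tile[, , 2])),
                     as.vector(rgb_to_od(tile[, , 3])))
      C <- stain_concentrations(basis, Dfull)
      p99 <- apply(stain_concentrations(basis, V), 1, stats::quantile,
                   probs = 0.99, names = FALSE)
      scale <- ifelse(p99 > 1e-8, template$conc_p99 / p99, 1)
      C <- C * scale
      Dnew <- t(template$basis) %*% C
      recon <- array(0, dim = dim(tile))
      for (ch in 1:3)
        recon[, , ch] <- matrix(od_to_rgb(Dnew[ch, ]), nrow = dim(tile)[1])
      recon
    }, error = function(e) {
      warning(sprintf("stain separation failed (%s); falling back to channel_mean",
                      conditionMessage(e)))
      NULL
    })
    tile <- out %||% tile
  }
  match_channel_means(tile, template$channel_means)
}

# multiplicative per-channel gain toward target means (rank-preserving);
# iterated because clipping to [0, 255] biases the achieved mean
match_channel_means <- function(tile, target, max_iter = 25L) {
  for (ch in 1:3) {
    for (it in seq_len(max_iter)) {
      m <- mean(tile[, , ch])
      if (m < 1e-6 || abs(m - target[ch]) < 0.05) break
      tile[, , ch] <- pmin(pmax(tile[, , ch] * (target[ch] / m), 0), 255)
    }
  }
  tile
}

## ---- augmentation ------------------------------------------------------

flip_tile_h <- function(t) t[, rev(seq_len(dim(t)[2])), , drop = FALSE]
flip_tile_v <- function(t) t[rev(seq_len(dim(t)[1])), , , drop = FALSE]
rot90_tile <- function(t) {
  # 90 degrees counter-clockwise
  out <- array(0, dim = c(dim(t)[2], dim(t)[1], dim(t)[3]))
  for (ch in seq_len(dim(t)[3]))
    out[, , ch] <- t(t[, , ch])[rev(seq_len(dim(t)[2])), , drop = FALSE]
  out
}

#' Append augmented copies of every tile
#'
#' Applies each requested dihedral operation to each tile and appends the
#' copies with provenance tags (`<spot_id>__<op>`). The output is fully
#' determined by the input and `ops`; `seed` is accepted for interface
#' stability with stochastic augmentations.
#'
#' @param tiles a [tile_set].
#' @param ops subset of `c("flip_h", "flip_v", "rot90")`.
#' @param seed integer (unused by the deterministic ops).
#' @return The enlarged [tile_set].
#' @export
augment_tiles <- function(tiles, ops = c("flip_h", "flip_v", "rot90"),
                          seed = 0L) {
  bad <- setdiff(ops, c("flip_h", "flip_v", "rot90"))
  if (length(bad))
    stop_spotnb(sprintf("unknown augmentation op(s): %s", paste(bad, collapse = ", ")),
                "spotnb_parameter_error")
  if (!length(ops))
    stop_spotnb("ops must be non-empty", "spotnb_parameter_error")
  new_tiles <- tiles$tiles
  prov <- tiles$provenance
  for (op in ops) {
    f <- switch(op, flip_h = flip_tile_h, flip_v = flip_tile_v, rot90 = rot90_tile)
    for (id in tiles$spot_id) {
      nid <- paste0(id, "__", op)
      new_tiles[[nid]] <- f(tiles$tiles[[id]])
      prov[nid] <- op
    }
  }
  tile_set(new_tiles, tiles$tile_px, provenance = prov[names(new_tiles)])
}
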