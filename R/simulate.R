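## Synthetic-slide generator: an H&E-like image of elliptical "nucleus"
## blobs on a pale pink background, a square spot grid, and NB counts
## tied to the rendered morphology through a known log-linear link
##   mu*_g(spot) = exp(a_g + b_g * m~)       (m~ = standardised blob count)
## with counts ~ NB(mean mu*, dispersion r_g). The stored truth gives
## every downstream module a ground-truth target. The generator bridges
## the (mean, dispersion) parameterisation to the head's (r, p) via
## p = r / (r + mu), under which mean = r (1 - p) / p holds exactly.

SIM_BG <- c(248, 237, 242)        # pale pink background (low saturation)
SIM_NUCLEUS <- c(96, 60, 150)     # haematoxylin-like purple

#' Generate a synthetic slide with known ground truth
#'
#' Renders one tile region per spot on a shared slide image. Per spot, a
#' latent morphology (number of non-touching elliptical blobs and their
#' total area) is drawn; per gene, the true NB mean follows the
#' log-linear link on the standardised blob count. Fully deterministic
#' under `seed`.
#'
#' @param n_rows,n_cols spot grid size.
#' @param spacing_px centre-to-centre spot spacing in pixels (default
#'   `tile_px + 5` so tiles do not overlap and blob counts per tile stay
#'   exact).
#' @param tile_px tile side in pixels (default 45; use 299 for
#'   production-geometry slides).
#' @param n_genes number of genes.
#' @param blob_density_range integer range for the per-spot blob count.
#' @param blob_radius_range ellipse semi-axis range in pixels.
#' @param link_coeffs optional data.frame (gene, a, b) overriding the
#'   auto-drawn intercepts `a_g ~ U(0.5, 2)` and slopes `b_g ~ U(0.6, 1.2)`.
#' @param dispersion_range range for the per-gene NB dispersion r_g.
#' @param stain_shift optional length-3 multiplicative per-channel gain
#'   applied to the final image (exercises stain normalisation).
#' @param noise_sd luminance noise added equally to all channels.
#' @param spatial_pattern how blob density varies over the grid:
#'   `"iid"` (default) draws each spot's blob count independently;
#'   `"gradient"` ramps the density along the columns; `"halves"` puts
#'   low density on the left half and high on the right, emulating two
#'   tissue regions with distinct morphology (gives expression fields
#'   with genuine spatial autocorrelation).
#' @param seed RNG seed.
#' @return list of class `synthetic_slide`: `image`, `spots`
#'   ([spot_table]), `counts` ([expression_matrix]), `truth` (gene table
#'   with a, b, r; per-spot `mu` matrix; `morphology` table), `seed`.
#' @export
generate_slide <- function(n_rows = 6L, n_cols = 6L, spacing_px = NULL,
                           tile_px = 45L, n_genes = 4L,
                           blob_density_range = c(2L, 12L),
                           blob_radius_range = c(1.8, 3.0),
                           link_coeffs = NULL,
                           dispersion_range = c(2, 10),
                           stain_shift = NULL, noise_sd = 1.5,
                           spatial_pattern = c("iid", "gradient", "halves"),
                           seed = 1L) {
  spatial_pattern <- match.arg(spatial_pattern)
  spacing_px <- as.integer(spacing_px %||% (tile_px + 5L))
  if (n_genes < 1) stop_spotnb("n_genes must be >= 1", "spotnb_parameter_error")
  half <- tile_px %/% 2L
  max_r <- max(blob_radius_range)
  if (half - ceiling(max_r) - 3 < 2)
    stop_spotnb("tile_px too small for the blob radius range",
                "spotnb_parameter_error")
  if (spacing_px < tile_px)
    stop_spotnb("spacing_px below tile_px would overlap tiles",
                "spotnb_parameter_error")
  W <- (n_cols - 1L) * spacing_px + tile_px
  H <- (n_rows - 1L) * spacing_px + tile_px

  with_seed(seed, {
    n <- n_rows * n_cols
    ids <- sprintf("spot_%04d", seq_len(n))
    grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
    grid <- grid[order(grid$row, grid$col), ]
    px <- half + (grid$col - 1L) * spacing_px       # 0-based centres
    py <- half + (grid$row - 1L) * spacing_px

    chans <- lapply(SIM_BG, function(v) matrix(v, H, W))
    n_blobs <- integer(n); tot_area <- numeric(n)
    place_r <- half - ceiling(max_r) - 2
    lo <- blob_density_range[1]; hi <- blob_density_range[2]
    for (i in seq_len(n)) {
      target <- switch(spatial_pattern,
        iid = sample(lo:hi, 1),
        gradient = {
          mid <- lo + (hi - lo) * (grid$col[i] - 1) / max(n_cols - 1, 1)
          max(lo, min(hi, round(mid) + sample(-1:1, 1)))
        },
        halves = {
          third <- max(1, round((hi - lo) / 3))
          if (grid$col[i] <= n_cols / 2) sample(lo:(lo + third), 1)
          else sample((hi - third):hi, 1)
        })
      centres <- matrix(numeric(0), 0, 2); radii <- numeric(0)
      # local tile block; blob centres relative to the tile origin
      block <- lapply(SIM_BG, function(v) matrix(v, tile_px, tile_px))
      ox <- px[i] - half; oy <- py[i] - half     # 0-based tile origin
      tries <- 0L
      while (nrow(centres) < target && tries < 400L) {
        tries <- tries + 1L
        cx <- px[i] + runif(1, -place_r, place_r)
        cy <- py[i] + runif(1, -place_r, place_r)
        rx <- runif(1, blob_radius_range[1], blob_radius_range[2])
        ry <- runif(1, blob_radius_range[1], blob_radius_range[2])
        rr <- max(rx, ry)
        if (nrow(centres) > 0) {
          d <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
          if (any(d < radii + rr + 2.5)) next   # keep blobs non-touching
        }
        centres <- rbind(centres, c(cx, cy)); radii <- c(radii, rr)
        block <- render_ellipse(block, cx - ox, cy - oy, rx, ry, SIM_NUCLEUS)
        n_blobs[i] <- n_blobs[i] + 1L
        tot_area[i] <- tot_area[i] + pi * rx * ry
      }
      rows <- oy + seq_len(tile_px); cols <- ox + seq_len(tile_px)
      for (ch in 1:3) chans[[ch]][rows, cols] <- block[[ch]]
    }

    if (noise_sd > 0) {
      lum <- matrix(rnorm(H * W, sd = noise_sd), H, W)
      chans <- lapply(chans, function(m) m + lum)
    }
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- chans[[ch]]
    if (!is.null(stain_shift))
      for (ch in 1:3) img[, , ch] <- img[, , ch] * stain_shift[ch]
    img <- round(pmin(pmax(img, 0), 255))

    genes <- sprintf("gene_%02d", seq_len(n_genes))
    if (is.null(link_coeffs)) {
      link_coeffs <- data.frame(gene = genes,
                                a = runif(n_genes, 0.5, 2),
                                b = runif(n_genes, 0.6, 1.2))
    }
    r_g <- runif(n_genes, dispersion_range[1], dispersion_range[2])
    m_std <- if (stats::sd(n_blobs) > 0)
      (n_blobs - mean(n_blobs)) / stats::sd(n_blobs) else rep(0, n)
    mu <- exp(outer(m_std, link_coeffs$b) +
                matrix(link_coeffs$a, n, n_genes, byrow = TRUE))
    counts <- matrix(rnbinom(n * n_genes, mu = mu,
                             size = matrix(r_g, n, n_genes, byrow = TRUE)),
                     n, n_genes, dimnames = list(ids, genes))
    dimnames(mu) <- list(ids, genes)

    spots <- spot_table(ids, grid$row, grid$col, px, py,
                        in_tissue = TRUE, spot_diameter_um = 55)
    structure(list(
      image = img,
      spots = spots,
      counts = expression_matrix(counts),
      truth = list(
        genes = data.frame(gene = genes, a = link_coeffs$a,
                           b = link_coeffs$b, r = r_g,
                           morphology_feature = "n_blobs"),
        mu = mu[order(ids), , drop = FALSE],
        morphology = data.frame(spot_id = ids, n_blobs = n_blobs,
                                total_blob_area = tot_area)[order(ids), ]
      ),
      tile_px = as.integer(tile_px),
      spatial_pattern = spatial_pattern,
      seed = as.integer(seed)
    ), class = "synthetic_slide")
  })
}

# draw an anti-aliased filled ellipse into the channel list
render_ellipse <- function(chans, cx, cy, rx, ry, colour) {
  H <- nrow(chans[[1]]); W <- ncol(chans[[1]])
  # 0-based pixel coords -> 1-based matrix indices
  x0 <- max(floor(cx - rx - 2) + 1, 1); x1 <- min(ceiling(cx + rx + 2) + 1, W)
  y0 <- max(floor(cy - ry - 2) + 1, 1); y1 <- min(ceiling(cy + ry + 2) + 1, H)
  xs <- x0:x1; ys <- y0:y1
  ex <- ((xs - 1) - cx) / rx
  ey <- ((ys - 1) - cy) / ry
  e <- sqrt(outer(ey^2, ex^2, "+"))
  alpha <- pmin(pmax((1 - e) * min(rx, ry) + 0.5, 0), 1)
  for (ch in 1:3) {
    block <- chans[[ch]][ys, xs, drop = FALSE]
    chans[[ch]][ys, xs] <- block * (1 - alpha) + colour[ch] * alpha
  }
  chans
}

#' Report the stored generator truth
#'
#' Returns the exact stored ground truth without recomputation.
#'
#' @param slide a [generate_slide] result.
#' @return list with `genes` (gene, a, b, r, morphology_feature), `mu`
#'   (spots x genes true means) and `morphology`.
#' @export
truth_report <- function(slide) {
  slide$truth
}

#' Write a synthetic slide to a directory
#'
#' Writes `image.png`, `positions.csv`, the MatrixMarket count triplets
#' with label lists, and `truth.csv` (per-gene link coefficients).
#'
#' @param slide a [generate_slide] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_slide <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(slide$image, file.path(dir, "image.png"))
  write_spot_table(slide$spots, file.path(dir, "positions.csv"))
  write_counts(slide$counts, dir)
  data.table::fwrite(slide$truth$genes, file.path(dir, "truth.csv"))
  invisible(dir)
}
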