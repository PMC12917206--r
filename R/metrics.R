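## Evaluation metrics: per-gene Pearson correlation, Moran's I over a
## spot-neighbourhood graph, ROC AUC, and the geometric spatial-pattern
## IoU (z-score -> binarise -> rasterise -> Gaussian smooth -> binarise
## -> intersection-over-union).

#' Pearson correlation between predicted and measured expression
#' @param pred,truth per-spot numeric vectors.
#' @return correlation in \[-1, 1\].
#' @export
gene_pcc <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2)
    stop_spotnb("need two aligned vectors of >= 2 spots", "spotnb_validation_error")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0)
    stop_spotnb("correlation undefined for a constant vector",
                "spotnb_undefined_error")
  stats::cor(pred, truth)
}

# Spot-neighbourhood weight matrix. grid_rook: unit weights between
# spots one step apart along array rows or columns; knn: k nearest
# neighbours by pixel distance (symmetrised).
spot_weights <- function(spots, type = c("grid_rook", "knn"), k = 6L,
                         row_standardise = TRUE) {
  type <- match.arg(type)
  n <- nrow(spots)
  W <- matrix(0, n, n)
  if (type == "grid_rook") {
    dr <- abs(outer(spots$array_row, spots$array_row, "-"))
    dc <- abs(outer(spots$array_col, spots$array_col, "-"))
    W[(dr == 1 & dc == 0) | (dr == 0 & dc == 1)] <- 1
  } else {
    d <- as.matrix(stats::dist(cbind(spots$pixel_x, spots$pixel_y)))
    diag(d) <- Inf
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[seq_len(min(k, n - 1))]
      W[i, nb] <- 1
    }
    W <- pmax(W, t(W))                        # symmetrise
  }
  diag(W) <- 0
  if (all(W == 0))
    stop_spotnb("no neighbour pairs in the spot graph", "spotnb_degenerate_error")
  if (row_standardise) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  W
}

#' Moran's I spatial autocorrelation
#'
#' `I = n / sum(W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` over a spot-neighbourhood graph: rook adjacency on the array
#' grid (default, row-standardised) or k-nearest-neighbour weights for
#' hexagonal layouts.
#'
#' @param values per-spot numeric vector aligned to `spots`.
#' @param spots a [spot_table].
#' @param weights `"grid_rook"` or `"knn"`.
#' @param row_standardise divide each row of the weight matrix by its sum.
#' @param k neighbours for `"knn"`.
#' @return Moran's I.
#' @export
morans_i <- function(values, spots, weights = c("grid_rook", "knn"),
                     row_standardise = TRUE, k = 6L) {
  if (length(values) != nrow(spots))
    stop_spotnb("values and spots differ in length", "spotnb_alignment_error")
  if (length(values) < 2 || stats::sd(values) == 0)
    stop_spotnb("Moran's I undefined for a constant field",
                "spotnb_undefined_error")
  W <- spot_weights(spots, match.arg(weights), k = k,
                    row_standardise = row_standardise)
  xc <- values - mean(values)
  n <- length(values)
  (n / sum(W)) * as.numeric(t(xc) %*% W %*% xc) / sum(xc^2)
}

#' Rasterise per-spot values onto the array grid
#'
#' @param values per-spot numeric vector aligned to `spots`.
#' @param spots a [spot_table].
#' @param fill value for unoccupied grid cells (default 0).
#' @return list of class `spot_raster` with `values` (matrix over the
#'   occupied row/col range) and logical `mask` of occupied cells.
#' @export
spot_raster <- function(values, spots, fill = 0) {
  r <- spots$array_row - min(spots$array_row) + 1L
  c_ <- spots$array_col - min(spots$array_col) + 1L
  m <- matrix(fill, max(r), max(c_))
  mask <- matrix(FALSE, max(r), max(c_))
  m[cbind(r, c_)] <- values
  mask[cbind(r, c_)] <- TRUE
  structure(list(values = m, mask = mask), class = "spot_raster")
}

# Separable 2-D Gaussian smoothing on a matrix; sigma in grid units,
# kernel truncated at 4 sigma, zero (constant) padding at the boundary.
gaussian_smooth <- function(m, sigma = 1, truncate = 4) {
  radius <- ceiling(truncate * sigma)
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    padded <- c(rep(0, radius), v, rep(0, radius))
    vapply(seq_along(v), function(i) sum(padded[i:(i + 2 * radius)] * k),
           numeric(1))
  }
  m <- apply(m, 2, conv1)                     # smooth columns (over rows)
  t(apply(m, 1, conv1))                       # smooth rows (over columns)
}

#' Geometric spatial-pattern IoU
#'
#' Compares the spatial pattern of two per-spot fields: (1) z-score each
#' field across spots; (2) binarise at zero (z > 0 -> 1); (3) rasterise
#' onto the array grid, unoccupied cells filled 0; (4) smooth each
#' binary raster with a separable 2-D Gaussian (sigma in grid units,
#' truncation 4 sigma, zero boundary padding); (5) re-binarise the
#' smoothed rasters at 0.5; (6) return intersection-over-union over the
#' occupied (tissue-mask) cells. If both patterns are empty on the mask
#' the score is 1 by convention. The score is symmetric, lies in
#' \[0, 1\], and is invariant to positive affine transforms of either
#' field.
#'
#' @param pred,truth per-spot numeric vectors aligned to `spots`.
#' @param spots a [spot_table].
#' @param sigma Gaussian width in grid units (default 1).
#' @return IoU in \[0, 1\].
#' @export
spatial_pattern_iou <- function(pred, truth, spots, sigma = 1) {
  binar <- function(x) {
    if (stats::sd(x) == 0)
      stop_spotnb("spatial IoU undefined for a constant field",
                  "spotnb_undefined_error")
    as.numeric((x - mean(x)) / stats::sd(x) > 0)
  }
  ras_p <- spot_raster(binar(pred), spots)
  ras_t <- spot_raster(binar(truth), spots)
  A <- gaussian_smooth(ras_p$values, sigma) > 0.5
  B <- gaussian_smooth(ras_t$values, sigma) > 0.5
  mask <- ras_p$mask
  union <- sum((A | B) & mask)
  if (union == 0) return(1)
  sum(A & B & mask) / union
}

#' ROC AUC for High/Low classification
#'
#' Area under the ROC curve of the predicted High-probabilities against
#' the binary labels (rank statistic, midrank tie handling). Perfectly
#' ranked probabilities give 1, anti-ranked 0.
#'
#' @param prob per-spot predicted probability of High.
#' @param labels per-spot labels: "High"/"Low", logical, or 0/1.
#' @return AUC in \[0, 1\].
#' @export
classification_auc <- function(prob, labels) {
  y <- if (is.character(labels)) as.integer(labels == "High")
       else as.integer(labels)
  if (length(unique(y)) < 2)
    stop_spotnb("AUC undefined with a single class", "spotnb_undefined_error")
  as.numeric(pROC::auc(pROC::roc(y, prob, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}
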