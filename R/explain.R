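## LIME attribution over nucleus segments. A trained model f is probed
## on perturbed copies of one tile in which random subsets of segments
## are blanked out; a locally weighted sparse linear model over the
## segment-inclusion indicators approximates f near the tile, and its
## coefficients score each segment's contribution.

# Colour deconvolution to Haematoxylin-Eosin-DAB optical densities.
# Stain OD vectors after Ruifrok & Johnston's calibration.
hed_matrix <- function() {
  M <- rbind(h = c(0.65, 0.70, 0.29),
             e = c(0.07, 0.99, 0.11),
             d = c(0.27, 0.57, 0.78))
  M / sqrt(rowSums(M^2))
}

#' RGB tile to HED optical-density channels
#' @param tile T x T x 3 array in \[0, 255\].
#' @return T x T x 3 array of haematoxylin, eosin, DAB densities.
#' @export
rgb_to_hed <- function(tile) {
  V <- cbind(as.vector(rgb_to_od(tile[, , 1])),
             as.vector(rgb_to_od(tile[, , 2])),
             as.vector(rgb_to_od(tile[, , 3])))
  hed <- V %*% solve(hed_matrix())
  array(hed, dim = dim(tile))
}

relabel_mask <- function(lab, min_area) {
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Segment nuclei in a tile
#'
#' `"hed_threshold"`: colour-deconvolve to HED, Otsu-threshold the
#' haematoxylin density channel, label connected components and drop
#' those below `min_area` pixels. `"imported"`: validate and relabel a
#' user-supplied labelled mask (e.g. from an external nucleus
#' segmenter). Labels are contiguous 1..K with 0 = background.
#'
#' @param tile T x T x 3 array in \[0, 255\].
#' @param method `"hed_threshold"` or `"imported"`.
#' @param min_area minimum nucleus area in pixels.
#' @param mask for `"imported"`: integer-labelled matrix matching the tile.
#' @return integer matrix of class `segmentation_mask` with attribute
#'   `areas` (pixel count per segment).
#' @export
segment_tile <- function(tile, method = c("hed_threshold", "imported"),
                         min_area = 10L, mask = NULL) {
  method <- match.arg(method)
  if (method == "imported") {
    if (is.null(mask) || !identical(dim(mask)[1:2], dim(tile)[1:2]))
      stop_spotnb("imported mask must match the tile dimensions",
                  "spotnb_alignment_error")
    lab <- relabel_mask(matrix(as.integer(mask), nrow(mask)), min_area)
  } else {
    hed <- rgb_to_hed(tile)
    h <- hed[, , 1]
    rng <- range(h)
    if (diff(rng) < 1e-8)
      stop_spotnb("no nuclei found (flat haematoxylin channel)",
                  "spotnb_empty_error")
    hn <- (h - rng[1]) / diff(rng)
    thr <- otsu_threshold(as.vector(hn))
    if (is.na(thr)) thr <- 0.5
    lab <- relabel_mask(EBImage::bwlabel(hn > thr), min_area)
  }
  if (max(lab) == 0)
    stop_spotnb("no segments found", "spotnb_empty_error")
  structure(lab, class = c("segmentation_mask", class(lab)),
            areas = tabulate(lab[lab > 0]))
}

#' Write / read a labelled mask as 16-bit single-channel TIFF
#' @param mask integer-labelled matrix.
#' @param path TIFF path.
#' @return `path` (write) / integer matrix (read).
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask) / 65535, nrow(mask)),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m))
}

# render a perturbed tile: segments with indicator 0 are replaced
perturb_tile <- function(tile, mask, z, replacement) {
  out <- tile
  fill <- switch(replacement,
                 mean_color = apply(tile, 3, mean),
                 grey = c(128, 128, 128))
  off <- which(z == 0)
  if (length(off)) {
    sel <- mask %in% off
    for (ch in 1:3) {
      m <- out[, , ch]; m[sel] <- fill[ch]; out[, , ch] <- m
    }
  }
  out
}

#' LIME attribution of a model prediction over tile segments
#'
#' Draws binary segment-inclusion vectors, renders the corresponding
#' perturbed tiles (excluded segments replaced by the tile's mean colour
#' or mid-grey), evaluates the model on each, and fits a locally
#' weighted sparse linear model of the predictions on the inclusion
#' indicators. Proximity weights are `exp(-D^2 / kernel_width^2)` with D
#' the fraction of segments removed. Sparsity is enforced by keeping the
#' first `top_k` segments entering a weighted L1 path, then refitting by
#' weighted least squares. The first sample is always the full-inclusion
#' vector, whose prediction reproduces `f(x)` in the design.
#'
#' @param model_fn function(tile) -> numeric prediction (or named vector;
#'   `gene` selects the element).
#' @param tile T x T x 3 array in \[0, 255\].
#' @param mask a [segment_tile] result.
#' @param gene optional name selecting one element of the model output.
#' @param n_samples perturbation samples (default 1000); must be at
#'   least the number of segments + 2. With `enumerate = TRUE` and
#'   K <= 12 segments, all 2^K inclusion vectors are used instead.
#' @param kernel_width proximity kernel width (default 0.25).
#' @param replacement `"mean_color"` (default) or `"grey"`.
#' @param top_k segments kept by the sparsity step (default min(10, K)).
#' @param seed RNG seed; the result is deterministic given config + seed.
#' @param enumerate use the full enumeration instead of sampling.
#' @return list of class `attribution_map`: per-segment `weights`,
#'   `intercept`, `kernel_width`, `n_samples`, `seed`, `selected`.
#' @export
lime_explain <- function(model_fn, tile, mask, gene = NULL,
                         n_samples = 1000L, kernel_width = 0.25,
                         replacement = c("mean_color", "grey"),
                         top_k = NULL, seed = 0L, enumerate = FALSE) {
  replacement <- match.arg(replacement)
  K <- max(mask)
  if (K < 1) stop_spotnb("mask has no segments", "spotnb_empty_error")
  top_k <- top_k %||% min(10L, K)
  eval_f <- function(t) {
    out <- model_fn(t)
    val <- if (!is.null(gene)) out[[gene]] else out[[1]]
    as.numeric(val)
  }
  if (enumerate) {
    if (K > 12)
      stop_spotnb("enumeration limited to 12 segments", "spotnb_parameter_error")
    Z <- as.matrix(expand.grid(rep(list(c(1, 0)), K)))[, K:1, drop = FALSE]
    colnames(Z) <- NULL
  } else {
    if (n_samples < K + 2)
      stop_spotnb("n_samples must be at least the segment count + 2",
                  "spotnb_parameter_error")
    Z <- with_seed(seed, {
      z <- matrix(rbinom((n_samples - 1) * K, 1, 0.5), n_samples - 1, K)
      rbind(rep(1, K), z)                     # sanity row: full inclusion
    })
  }
  f <- apply(Z, 1, function(z) eval_f(perturb_tile(tile, mask, z, replacement)))
  D <- 1 - rowMeans(Z)                        # fraction of segments removed
  w <- exp(-D^2 / kernel_width^2)

  selected <- seq_len(K)
  if (top_k < K) {
    path <- glmnet::glmnet(Z, f, weights = w, alpha = 1, standardize = FALSE,
                           nlambda = 100)
    entry <- apply(path$beta != 0, 1, function(nz) {
      j <- which(nz)[1]; if (is.na(j)) Inf else j
    })
    selected <- order(entry)[seq_len(top_k)]
  }
  Xs <- Z[, selected, drop = FALSE]
  fit <- tryCatch(
    stats::lm.wfit(cbind(1, Xs), f, w = w),
    error = function(e) NULL)
  coefs <- if (!is.null(fit) && !anyNA(fit$coefficients)) {
    fit$coefficients
  } else {
    warning("singular LIME design; using ridge fallback (lambda = 1e-6)")
    A <- cbind(1, Xs)
    as.vector(solve(crossprod(A * sqrt(w)) + diag(1e-6, ncol(A)),
                    crossprod(A * sqrt(w), f * sqrt(w))))
  }
  weights <- setNames(rep(0, K), as.character(seq_len(K)))
  weights[selected] <- unname(coefs[-1])
  structure(list(weights = weights, intercept = unname(coefs[1]),
                 kernel_width = kernel_width,
                 n_samples = nrow(Z), seed = seed, selected = selected,
                 gene = gene),
            class = "attribution_map")
}

#' Aggregate LIME weights per nucleus
#'
#' @param attr an [lime_explain] result.
#' @param mask the [segment_tile] mask the attribution was computed on.
#' @return list with `table` (data.frame nucleus, weight, area_px) and
#'   `overlay` (matrix assigning each nucleus pixel its weight, NA
#'   background).
#' @export
aggregate_nucleus_scores <- function(attr, mask) {
  K <- max(mask)
  if (K != length(attr$weights))
    stop_spotnb("attribution and mask disagree on the segment count",
                "spotnb_alignment_error")
  areas <- base::attr(mask, "areas") %||% tabulate(mask[mask > 0], K)
  tbl <- data.frame(nucleus = seq_len(K),
                    weight = as.numeric(attr$weights),
                    area_px = areas)
  overlay <- matrix(NA_real_, nrow(mask), ncol(mask))
  nz <- mask > 0
  overlay[nz] <- tbl$weight[mask[nz]]
  list(table = tbl, overlay = overlay)
}

#' Select the tiles with highest predicted expression for a gene
#'
#' Presentation utility: sort spots by predicted mean for one gene and
#' return the top `n` spot ids.
#'
#' @param pred_table a [predict_expression] `table`.
#' @param gene gene name.
#' @param n how many tiles.
#' @return character vector of spot ids.
#' @export
top_expression_tiles <- function(pred_table, gene, n = 5L) {
  sub <- pred_table[pred_table$gene == gene, , drop = FALSE]
  head(sub$spot_id[order(-sub$mean)], n)
}
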