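# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths.

# -log NB pmf via R's dnbinom (independent of the package's log-gamma form)
oracle_nb_nll <- function(x, r, p) {
  -dnbinom(x, size = r, prob = p, log = TRUE)
}

# Pearson correlation from the raw definition
oracle_pcc <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Moran's I by explicit double loop over a weight matrix
oracle_morans_i <- function(x, W) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * xc[i] * xc[j]
  (n / sum(W)) * num / sum(xc^2)
}

# AUC by enumeration of positive-negative pairs (ties count 1/2)
oracle_auc <- function(prob, y) {
  pos <- prob[y == 1]; neg <- prob[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Brute-force spatial-pattern IoU: independently coded six-step pipeline
# (explicit 2-D kernel accumulation rather than separable convolution).
oracle_spatial_iou <- function(pred, truth, spots, sigma = 1) {
  zbin <- function(v) as.numeric((v - mean(v)) / sd(v) > 0)
  rasterize <- function(v) {
    r <- spots$array_row - min(spots$array_row) + 1
    c_ <- spots$array_col - min(spots$array_col) + 1
    m <- matrix(0, max(r), max(c_))
    m[cbind(r, c_)] <- v
    m
  }
  maskm <- {
    r <- spots$array_row - min(spots$array_row) + 1
    c_ <- spots$array_col - min(spots$array_col) + 1
    m <- matrix(FALSE, max(r), max(c_))
    m[cbind(r, c_)] <- TRUE
    m
  }
  smooth2d <- function(m, sigma) {
    rad <- ceiling(4 * sigma)
    k1 <- exp(-((-rad):rad)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
    k2 <- outer(k1, k1)                     # separable => outer product
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      acc <- 0
      for (di in (-rad):rad) for (dj in (-rad):rad) {
        ii <- i + di; jj <- j + dj
        v <- if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m))
          m[ii, jj] else 0                  # constant (zero) padding
        acc <- acc + v * k2[di + rad + 1, dj + rad + 1]
      }
      out[i, j] <- acc
    }
    out
  }
  A <- smooth2d(rasterize(zbin(pred)), sigma) > 0.5
  B <- smooth2d(rasterize(zbin(truth)), sigma) > 0.5
  u <- sum((A | B) & maskm)
  if (u == 0) return(1)
  sum(A & B & maskm) / u
}

# Weighted least squares on the full design, for the LIME enumeration check
oracle_wls <- function(Z, f, w) {
  A <- cbind(1, Z)
  as.vector(solve(crossprod(A * sqrt(w)), crossprod(A * sqrt(w), f * sqrt(w))))
}
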