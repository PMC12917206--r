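make_tile <- function(col, T = 21) {
  array(rep(col, each = T * T), dim = c(T, T, 3))
}

test_that("tile windows follow the stated geometry", {
  img <- array(0, dim = c(1000, 1000, 3))
  img[, , 1] <- matrix(seq_len(1000), 1000, 1000)          # row index in R
  img[, , 2] <- matrix(seq_len(1000), 1000, 1000, byrow = TRUE)  # col index
  st <- spot_table("a", 1, 1, 500, 500)
  tl <- extract_tiles(img, st, tile_px = 299)$tiles[["a"]]
  # 0-based window [351, 650) per axis -> 1-based rows/cols 352..650
  expect_equal(tl[1, 1, 1], 352)
  expect_equal(tl[299, 1, 1], 650)
  expect_equal(tl[1, 1, 2], 352)
  expect_equal(tl[1, 299, 2], 650)
  # centre pixel of an odd tile is the spot centre
  expect_equal(tl[150, 150, 1], 501)  # 0-based row 500
  expect_equal(tl[150, 150, 2], 501)
})

test_that("tile centre pixels equal the slide colour at each spot centre", {
  sl <- small_slide()
  tiles <- small_tiles()
  expect_equal(length(tiles), nrow(sl$spots))
  half <- sl$tile_px %/% 2
  for (id in sl$spots$spot_id[c(1, 10, 36)]) {
    i <- which(sl$spots$spot_id == id)
    centre <- sl$image[sl$spots$pixel_y[i] + 1, sl$spots$pixel_x[i] + 1, ]
    expect_equal(as.numeric(tiles$tiles[[id]][half + 1, half + 1, ]),
                 as.numeric(centre))
  }
})

test_that("edge spots are dropped or reflected per edge_policy", {
  img <- array(128, dim = c(400, 400, 3))
  st <- spot_table(c("mid", "edge"), c(1, 2), c(1, 1), c(200, 10), c(200, 200))
  expect_message(ts_drop <- extract_tiles(img, st, tile_px = 299), "dropped")
  expect_equal(length(ts_drop), 1)
  ts_pad <- extract_tiles(img, st, tile_px = 299, edge_policy = "pad_reflect")
  expect_equal(length(ts_pad), 2)
  expect_error(extract_tiles(img, st, tile_px = 0),
               class = "spotnb_parameter_error")
  st_out <- spot_table("x", 1, 1, 200, 200, in_tissue = FALSE)
  expect_error(extract_tiles(img, st_out, tile_px = 99),
               class = "spotnb_empty_error")
})

test_that("tissue coverage is 0 on white, 1 on saturated pink, 0.5 on half/half", {
  white <- make_tile(c(255, 255, 255))
  pink <- make_tile(c(228, 60, 160))
  expect_equal(tissue_coverage(white), 0)
  expect_equal(tissue_coverage(pink), 1)
  half <- white
  half[, 1:10, ] <- pink[, 1:10, ]
  expect_equal(tissue_coverage(half), 10 / 21, tolerance = 0.02)
  expect_error(tissue_coverage(matrix(1, 3, 3)), class = "spotnb_format_error")
})

test_that("qc_filter keeps exactly the tiles at or above the threshold", {
  white <- make_tile(c(255, 255, 255))
  pink <- make_tile(c(228, 60, 160))
  half <- white; half[, 1:10, ] <- pink[, 1:10, ]
  ts <- tile_set(list(a = pink, b = half, c = white), 21)
  kept <- qc_filter(ts, 0.7)
  expect_identical(kept$spot_id, "a")
  expect_equal(length(qc_filter(ts, 0)), 3)
  expect_error(qc_filter(ts, 1.5), class = "spotnb_parameter_error")
})

test_that("qc_filter is monotone in the threshold", {
  set.seed(42)
  tiles <- lapply(1:12, function(i) {
    t <- make_tile(c(255, 255, 255))
    k <- sample(0:21, 1)
    if (k > 0) t[, seq_len(k), ] <- make_tile(c(228, 60, 160))[, seq_len(k), ]
    t
  })
  names(tiles) <- sprintf("t%02d", 1:12)
  ts <- tile_set(tiles, 21)
  for (pair in list(c(0.2, 0.5), c(0.5, 0.8), c(0.3, 0.9))) {
    lo <- qc_filter(ts, pair[1])$spot_id
    hi <- qc_filter(ts, pair[2])$spot_id
    expect_true(all(hi %in% lo))
  }
})

test_that("stain templates capture channel means and reject blank input", {
  sl <- small_slide()
  tmpl <- fit_stain_template(sl$image)
  expect_equal(tmpl$channel_means, apply(sl$image, 3, mean))
  expect_equal(sqrt(rowSums(tmpl$basis^2)), c(1, 1), tolerance = 1e-8)
  white <- make_tile(c(255, 255, 255), T = 31)
  expect_error(fit_stain_template(white), class = "spotnb_degenerate_error")
})

test_that("a two-stain image's basis is recovered within 5 degrees", {
  # synthesise from a known basis: H-like and E-like OD vectors
  basis <- rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  basis <- basis / sqrt(rowSums(basis^2))
  set.seed(3)
  n <- 60
  # mixed pixels plus near-pure regions of each stain, as in real tissue
  npx <- n * n
  kind <- sample(1:3, npx, replace = TRUE, prob = c(0.25, 0.25, 0.5))
  conc <- cbind(runif(npx, 0, 1.2) * (kind != 2),
                runif(npx, 0, 0.8) * (kind != 1))
  od <- conc %*% basis
  img <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pmin(pmax(exp(-od[, ch]) * 256 - 1, 0), 255), n)
  img <- round(img)
  for (method in c("vahadane", "macenko")) {
    tmpl <- fit_stain_template(img, method = method)
    for (s in 1:2) {
      ang <- acos(pmin(sum(tmpl$basis[s, ] * basis[s, ]), 1)) * 180 / pi
      expect_lt(ang, 5)
    }
  }
})

test_that("stain normalisation restores channel means of shifted tiles", {
  sl <- small_slide()
  tmpl <- fit_stain_template(sl$image)
  tiles <- small_tiles()
  tl <- tiles$tiles[[1]]
  # fixed point: normalising against a template fitted on itself
  self_tmpl <- fit_stain_template(tl)
  out_self <- normalise_stain(tl, self_tmpl, "vahadane")
  expect_lt(max(abs(apply(out_self, 3, mean) - apply(tl, 3, mean))), 1)
  # darkened copy restored within 3 grey levels
  dark <- round(tl * 0.8)
  for (method in c("vahadane", "macenko", "channel_mean")) {
    out <- normalise_stain(dark, tmpl, method)
    expect_lt(max(abs(apply(out, 3, mean) - tmpl$channel_means)), 3)
  }
  # idempotence: renormalising moves channel means by < 3 grey levels
  out1 <- normalise_stain(dark, tmpl, "vahadane")
  out2 <- normalise_stain(out1, tmpl, "vahadane")
  expect_lt(max(abs(apply(out2, 3, mean) - apply(out1, 3, mean))), 3)
  # all-background tile returned unchanged with a warning
  white <- make_tile(c(255, 255, 255))
  expect_warning(out_w <- normalise_stain(white, tmpl, "vahadane"), "background")
  expect_identical(out_w, white)
})

test_that("augmentation ops are involutive and leave coverage unchanged", {
  tiles <- small_tiles()
  tl <- tiles$tiles[[1]]
  aug <- augment_tiles(tiles, ops = c("flip_h", "flip_v", "rot90"))
  expect_equal(length(aug), 4 * length(tiles))
  id <- tiles$spot_id[1]
  fh <- aug$tiles[[paste0(id, "__flip_h")]]
  expect_identical(fh[, rev(seq_len(dim(fh)[2])), , drop = FALSE], tl)
  # rot90 four times is the identity
  r <- tl
  for (k in 1:4) r <- augment_tiles(tile_set(list(x = r), tiles$tile_px),
                                    ops = "rot90")$tiles[["x__rot90"]]
  expect_identical(r, tl)
  for (op in c("flip_h", "flip_v", "rot90"))
    expect_equal(tissue_coverage(aug$tiles[[paste0(id, "__", op)]]),
                 tissue_coverage(tl))
  expect_error(augment_tiles(tiles, ops = "swirl"), class = "spotnb_parameter_error")
  # deterministic: identical output across runs
  aug2 <- augment_tiles(tiles, ops = c("flip_h", "flip_v", "rot90"))
  expect_identical(aug$tiles, aug2$tiles)
})
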