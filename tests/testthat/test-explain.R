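# a tile with planted dark-purple nuclei at known positions
planted_tile <- function(centres, radius = 3, T = 41) {
  tile <- array(0, dim = c(T, T, 3))
  tile[, , 1] <- 248; tile[, , 2] <- 237; tile[, , 3] <- 242
  for (k in seq_len(nrow(centres))) {
    for (i in seq_len(T)) for (j in seq_len(T)) {
      if ((i - centres[k, 1])^2 + (j - centres[k, 2])^2 <= radius^2) {
        tile[i, j, ] <- c(96, 60, 150)
      }
    }
  }
  tile
}

five_centres <- rbind(c(8, 8), c(8, 30), c(20, 20), c(33, 10), c(33, 32))

test_that("HED thresholding finds the planted nuclei", {
  tile <- planted_tile(five_centres)
  mask <- segment_tile(tile, "hed_threshold", min_area = 5)
  expect_equal(max(mask), 5)
  white <- array(255, dim = c(21, 21, 3))
  expect_error(segment_tile(white, "hed_threshold"), class = "spotnb_empty_error")
})

test_that("imported masks round-trip unchanged through 16-bit TIFF", {
  tile <- planted_tile(five_centres)
  mask <- segment_tile(tile, "hed_threshold", min_area = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask(unclass(mask), path)
  back <- read_mask(path)
  expect_identical(back, matrix(as.integer(mask), nrow(mask)))
  mask2 <- segment_tile(tile, "imported", min_area = 5, mask = back)
  expect_identical(as.integer(mask2), as.integer(mask))
  expect_error(segment_tile(tile, "imported", mask = back[1:10, ]),
               class = "spotnb_alignment_error")
})

test_that("LIME recovers a planted per-segment linear signal", {
  tile <- planted_tile(five_centres[1:3, ])
  mask <- segment_tile(tile, "hed_threshold", min_area = 5)
  expect_equal(max(mask), 3)
  # model reads the mean red intensity over segment 1's original pixels
  seg1 <- mask == 1
  fn <- function(t) mean(t[, , 1][seg1])
  attr_map <- lime_explain(fn, tile, mask, n_samples = 400, seed = 5)
  w <- abs(attr_map$weights)
  expect_gt(w[1], 10 * max(w[2], w[3]))
  # the planted segment ranks first across seeded reruns
  firsts <- vapply(1:20, function(s) {
    a <- lime_explain(fn, tile, mask, n_samples = 400, seed = s)
    which.max(abs(a$weights))
  }, integer(1))
  expect_gte(mean(firsts == 1), 0.95)
})

test_that("a constant model yields near-zero weights", {
  tile <- planted_tile(five_centres[1:3, ])
  mask <- segment_tile(tile, "hed_threshold", min_area = 5)
  attr_map <- lime_explain(function(t) 1.5, tile, mask, n_samples = 200, seed = 1)
  expect_true(all(abs(attr_map$weights) < 1e-3))
  expect_equal(attr_map$intercept, 1.5, tolerance = 1e-3)
})

test_that("full enumeration reproduces the weighted least-squares oracle", {
  tile <- planted_tile(five_centres)
  mask <- segment_tile(tile, "hed_threshold", min_area = 5)
  K <- max(mask)
  effects <- c(2, -1, 0.5, 0, 3)
  fn <- function(t) {
    z <- vapply(seq_len(K), function(k)
      as.numeric(mean(t[, , 3][mask == k]) > 200), numeric(1))
    # z == 1 iff the segment was blanked by the mean-colour fill
    sum(effects * (1 - z)) + 0.25
  }
  # constant kernel: huge width makes all weights equal
  attr_map <- lime_explain(fn, tile, mask, kernel_width = 1e6, seed = 1,
                           enumerate = TRUE, top_k = K)
  Z <- as.matrix(expand.grid(rep(list(c(1, 0)), K)))[, K:1]
  f <- apply(Z, 1, function(z) sum(effects * z) + 0.25)
  beta <- oracle_wls(Z, f, rep(1, nrow(Z)))
  expect_equal(unname(attr_map$weights), beta[-1], tolerance = 1e-8)
  expect_equal(attr_map$intercept, beta[1], tolerance = 1e-8)
})

test_that("the full-inclusion sanity row reproduces f(x)", {
  tile <- planted_tile(five_centres[1:2, ])
  mask <- segment_tile(tile, "hed_threshold", min_area = 5)
  seen <- new.env(); seen$first <- NULL
  fn <- function(t) {
    v <- mean(t)
    if (is.null(seen$first)) seen$first <- list(tile = t, value = v)
    v
  }
  lime_explain(fn, tile, mask, n_samples = 50, seed = 3)
  expect_identical(seen$first$tile, tile)
  expect_equal(seen$first$value, mean(tile))
})

test_that("LIME is deterministic given config and seed", {
  tile <- planted_tile(five_centres[1:3, ])
  mask <- segment_tile(tile, "hed_threshold", min_area = 5)
  fn <- function(t) mean(t[, , 1])
  a1 <- lime_explain(fn, tile, mask, n_samples = 200, seed = 7)
  a2 <- lime_explain(fn, tile, mask, n_samples = 200, seed = 7)
  expect_identical(a1$weights, a2$weights)
  expect_error(lime_explain(fn, tile, mask, n_samples = 3),
               class = "spotnb_parameter_error")
})

test_that("nucleus scores aggregate with areas and overlay correctly", {
  tile <- planted_tile(five_centres[1:2, ])
  mask <- segment_tile(tile, "hed_threshold", min_area = 5)
  attr_map <- structure(list(weights = c(`1` = 0.5, `2` = -0.2), intercept = 0,
                             kernel_width = 0.25, n_samples = 0, seed = 0,
                             selected = 1:2), class = "attribution_map")
  agg <- aggregate_nucleus_scores(attr_map, mask)
  expect_equal(agg$table$weight, c(0.5, -0.2))
  expect_equal(agg$table$area_px, as.vector(base::attr(mask, "areas")))
  expect_true(all(is.na(agg$overlay[mask == 0])))
  expect_true(all(agg$overlay[mask == 1] == 0.5))
  expect_true(all(agg$overlay[mask == 2] == -0.2))
  bad <- structure(list(weights = c(`1` = 0.5)), class = "attribution_map")
  expect_error(aggregate_nucleus_scores(bad, mask), class = "spotnb_alignment_error")
})

test_that("positive- vs negative-score nucleus areas are recoverable", {
  tile <- planted_tile(five_centres, radius = 3)
  big <- planted_tile(five_centres[1:2, ], radius = 6)
  # combine: two large nuclei and three small ones
  comb <- tile
  sel <- big[, , 1] < 200
  for (ch in 1:3) { m <- comb[, , ch]; m[sel] <- big[, , ch][sel]; comb[, , ch] <- m }
  mask <- segment_tile(comb, "hed_threshold", min_area = 5)
  areas <- base::attr(mask, "areas")
  w <- ifelse(areas > stats::median(areas), 0.8, -0.3)
  attr_map <- structure(list(weights = setNames(w, seq_along(w))),
                        class = "attribution_map")
  agg <- aggregate_nucleus_scores(attr_map, mask)
  pos_area <- mean(agg$table$area_px[agg$table$weight > 0])
  neg_area <- mean(agg$table$area_px[agg$table$weight < 0])
  expect_gt(pos_area, neg_area)
})

test_that("weights follow a segment label permutation", {
  tile <- planted_tile(five_centres[1:3, ])
  mask <- segment_tile(tile, "hed_threshold", min_area = 5)
  seg_means <- lapply(1:3, function(k) mask == k)
  fn_for <- function(target) function(t) mean(t[, , 1][seg_means[[target]]])
  a1 <- lime_explain(fn_for(1), tile, mask, n_samples = 300, seed = 4)
  a2 <- lime_explain(fn_for(2), tile, mask, n_samples = 300, seed = 4)
  expect_equal(which.max(abs(a1$weights)), c(`1` = 1L))
  expect_equal(which.max(abs(a2$weights)), c(`2` = 2L))
})

test_that("top_expression_tiles sorts by predicted mean", {
  tbl <- data.frame(spot_id = c("a", "b", "c"), gene = "g",
                    mean = c(1, 9, 4))
  expect_identical(top_expression_tiles(tbl, "g", 2), c("b", "c"))
})
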