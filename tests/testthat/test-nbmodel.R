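zero_head <- function(F_, genes, p_mode = "logistic") {
  G <- length(genes)
  nb_head_weights(matrix(0, G, F_), rep(0, G), matrix(0, G, F_), rep(0, G),
                  genes = genes, p_mode = p_mode)
}

test_that("the NB head reproduces closed forms at zero weights", {
  z <- matrix(rnorm(6), 2, 3, dimnames = list(c("s1", "s2"), NULL))
  par <- nb_head_apply(z, zero_head(3, c("g1", "g2")))
  expect_equal(unname(par$r), matrix(log(2), 2, 2), tolerance = 1e-12)
  expect_equal(unname(par$p), matrix(0.5, 2, 2), tolerance = 1e-12)
  # literal softmax mode with zero logits: p_g = 1/G
  par_sm <- nb_head_apply(z, zero_head(3, paste0("g", 1:4), p_mode = "softmax"))
  expect_equal(unname(par_sm$p), matrix(0.25, 2, 4), tolerance = 1e-12)
})

test_that("the head matches a scalar softplus/logistic oracle", {
  set.seed(5)
  F_ <- 4; G <- 3; n <- 6
  z <- matrix(rnorm(n * F_), n, F_, dimnames = list(sprintf("s%d", 1:n), NULL))
  Wr <- matrix(rnorm(G * F_), G); br <- rnorm(G)
  Wp <- matrix(rnorm(G * F_), G); bp <- rnorm(G)
  head <- nb_head_weights(Wr, br, Wp, bp, genes = paste0("g", 1:G))
  par <- nb_head_apply(z, head)
  for (i in 1:n) for (g in 1:G) {
    u <- sum(Wr[g, ] * z[i, ]) + br[g]
    v <- sum(Wp[g, ] * z[i, ]) + bp[g]
    expect_lt(abs(par$r[i, g] - log1p(exp(-abs(u))) - max(u, 0)), 1e-10)
    expect_lt(abs(par$p[i, g] - 1 / (1 + exp(-v))), 1e-10)
  }
  expect_error(nb_head_apply(z[, 1:3], head), class = "spotnb_shape_error")
})

test_that("NB moments follow mean = r(1-p)/p and std = sqrt(r(1-p))/p", {
  par <- list(r = matrix(c(2, 3)), p = matrix(c(0.5, 0.25)))
  mom <- nb_moments(par)
  expect_equal(as.vector(mom$mean), c(2, 9))
  expect_equal(as.vector(mom$std), c(2, 6))
  # p -> 1 limit: mean vanishes
  mom0 <- nb_moments(list(r = matrix(2), p = matrix(1 - 1e-6)))
  expect_lt(mom0$mean[1], 1e-5)
})

test_that("moments agree with the empirical sampler within 3 SE", {
  par <- structure(list(
    r = matrix(c(3, 5), 1, 2, dimnames = list("s", c("g1", "g2"))),
    p = matrix(c(0.25, 0.6), 1, 2, dimnames = list("s", c("g1", "g2"))),
    gene_names = c("g1", "g2")), class = "nb_params")
  mom <- nb_moments(par)
  n <- 1e5
  draws <- sample_nb(par, n_draws = n, seed = 123)
  for (g in 1:2) {
    x <- draws[, 1, g]
    se_mean <- mom$std[1, g] / sqrt(n)
    expect_lt(abs(mean(x) - mom$mean[1, g]), 3 * se_mean)
    # SE of the sd estimate, normal approximation
    se_sd <- mom$std[1, g] / sqrt(2 * (n - 1))
    expect_lt(abs(sd(x) - mom$std[1, g]), 6 * se_sd)  # skewed counts: roomier
  }
})

test_that("the NLL reproduces the geometric closed forms", {
  par1 <- list(r = matrix(1), p = matrix(0.5))
  expect_equal(nb_negative_log_likelihood(matrix(0), par1), log(2),
               tolerance = 1e-12)
  par2 <- list(r = matrix(2), p = matrix(0.5))
  expect_equal(nb_negative_log_likelihood(matrix(1), par2), log(4),
               tolerance = 1e-12)
  expect_error(nb_negative_log_likelihood(matrix(-1), par1),
               class = "spotnb_validation_error")
})

test_that("the NLL matches an independent log-pmf oracle on 1000 triples", {
  set.seed(77)
  r <- runif(1000, 0.1, 50)
  p <- runif(1000, 0.02, 0.98)
  x <- rpois(1000, 20)
  ours <- vapply(1:1000, function(i)
    nb_negative_log_likelihood(matrix(x[i]), list(r = matrix(r[i]), p = matrix(p[i]))),
    numeric(1))
  expect_lt(max(abs(ours - oracle_nb_nll(x, r, p))), 1e-8)
})

test_that("analytic NLL gradients match numerical differentiation", {
  set.seed(12)
  for (i in 1:20) {
    r <- runif(1, 0.3, 20); p <- runif(1, 0.05, 0.95); x <- rpois(1, 10)
    g <- spotnb:::nb_nll_grad(x, r, p)
    f <- function(rr, pp) nb_negative_log_likelihood(
      matrix(x), list(r = matrix(rr), p = matrix(pp)))
    h <- 1e-6
    num_dr <- (f(r + h, p) - f(r - h, p)) / (2 * h)
    num_dp <- (f(r, p + h) - f(r, p - h)) / (2 * h)
    expect_equal(g$dr, num_dr, tolerance = 1e-5)
    expect_equal(g$dp, num_dp, tolerance = 1e-5)
  }
})

test_that("training fits iid NB counts to the method-of-moments mean", {
  set.seed(21)
  n <- 2000
  x <- rnbinom(n, size = 5, prob = 0.4)
  counts <- expression_matrix(matrix(x, n, 1,
    dimnames = list(sprintf("s%04d", 1:n), "g")))
  feats <- matrix(1, n, 1, dimnames = list(sprintf("s%04d", 1:n), "const"))
  m <- train_nb_head(feats, counts, epochs = 150, lr = 0.05, seed = 3)
  mu_hat <- nb_moments(nb_head_apply(feats, m))$mean[1, 1]
  expect_lt(abs(mu_hat - mean(x)) / mean(x), 0.05)
  hist <- attr(m, "loss_history")
  expect_lt(hist[length(hist)], hist[1])
})

test_that("all-zero counts drive the fitted mean to zero", {
  n <- 200
  counts <- expression_matrix(matrix(0L, n, 1,
    dimnames = list(sprintf("s%03d", 1:n), "g")))
  feats <- matrix(1, n, 1, dimnames = list(sprintf("s%03d", 1:n), "const"))
  m <- train_nb_head(feats, counts, epochs = 80, lr = 0.1, seed = 4)
  mu_hat <- nb_moments(nb_head_apply(feats, m))$mean[1, 1]
  expect_lt(mu_hat, 0.05)
})

test_that("training is deterministic under a fixed seed", {
  sl <- small_slide()
  f <- small_features()
  m1 <- train_nb_head(f, sl$counts, epochs = 5, lr = 0.05, seed = 99)
  m2 <- train_nb_head(f, sl$counts, epochs = 5, lr = 0.05, seed = 99)
  expect_identical(m1$Wr, m2$Wr)
  expect_identical(m1$Wp, m2$Wp)
  m3 <- train_nb_head(f, sl$counts, epochs = 5, lr = 0.05, seed = 100)
  expect_gt(max(abs(m1$Wr - m3$Wr)), 0)
})

test_that("fine-tuning the feature adapter trains jointly and helps fit", {
  sl <- small_slide()
  f <- small_features()
  m <- train_nb_head(f, sl$counts, epochs = 20, lr = 0.05, seed = 2,
                     fine_tune_extractor = TRUE)
  expect_false(is.null(m$adapter))
  hist <- attr(m, "loss_history")
  expect_lt(hist[length(hist)], hist[1])
  pr <- predict_expression(f, m)
  expect_true(all(is.finite(pr$table$mean)))
})

test_that("predictions round-trip through CSV and models through JSON", {
  sl <- small_slide()
  f <- small_features()
  m <- train_nb_head(f, sl$counts, epochs = 10, lr = 0.05, seed = 1)
  pr <- predict_expression(f, m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions(pr$params, path)
  back <- read_predictions(path)
  expect_equal(back$mean, pr$table$mean, tolerance = 1e-9)
  expect_equal(back$r, pr$table$r, tolerance = 1e-9)
  mpath <- withr::local_tempfile(fileext = ".json")
  save_model(m, mpath)
  m2 <- load_model(mpath)
  pr2 <- predict_expression(f, m2)
  expect_equal(pr2$table$mean, pr$table$mean, tolerance = 1e-9)
  expect_equal(pr2$params$r[1, ], pr$params$r[1, ], tolerance = 1e-12)
})

test_that("the empirical mean of sampled counts matches mu within 3 SE", {
  sl <- small_slide()
  f <- small_features()
  m <- train_nb_head(f, sl$counts, epochs = 10, lr = 0.05, seed = 1)
  par <- nb_head_apply(f[1:2, , drop = FALSE], m)
  mom <- nb_moments(par)
  n <- 1e5
  draws <- sample_nb(par, n_draws = n, seed = 8)
  for (i in 1:2) for (g in seq_along(par$gene_names)) {
    se <- mom$std[i, g] / sqrt(n)
    expect_lt(abs(mean(draws[, i, g]) - mom$mean[i, g]), 3 * se)
  }
})

test_that("top_variable_genes ranks by variance", {
  m <- expression_matrix(matrix(c(1, 1, 1, 0, 10, 40, 2, 3, 4), 3,
    dimnames = list(c("a", "b", "c"), c("flat", "wild", "mid"))))
  expect_identical(top_variable_genes(m, 2), c("wild", "mid"))
})
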