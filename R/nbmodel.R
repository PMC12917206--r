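## The negative-binomial regression head.
##
## Each gene g gets a pair of affine maps from the latent features z:
##   r_g = softplus(w_r.z + b_r)            ("number of successes", > 0)
##   p_g = sigmoid(w_p.z + b_p)             (success probability, (0,1))
## giving the predictive distribution X_g | s ~ NB(r_g, p_g) with
##   mean  mu    = r (1 - p) / p
##   sd    sigma = sqrt(r (1 - p)) / p
## The head is trained by minimising the NB negative log-likelihood with
## minibatch Adam. An optional literal softmax-across-genes mapping for p
## is provided for fidelity experiments (it couples genes through
## sum_g p_g = 1 and is not the default).

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) plogis(x)

R_CLAMP <- 1e-6
P_CLAMP <- 1e-6

#' Construct NB head weights
#'
#' @param Wr,Wp G x F weight matrices for the r- and p-maps.
#' @param br,bp length-G biases.
#' @param genes gene names (length G).
#' @param p_mode `"logistic"` (elementwise, default) or `"softmax"`
#'   (literal softmax across genes).
#' @param center,scale optional length-F feature standardisation applied
#'   before the affine maps (stored from training).
#' @param adapter optional linear feature adapter `list(W = FxF, b = F)`
#'   trained when the extractor is fine-tuned.
#' @param seed training seed (bookkeeping).
#' @return list of class `nb_head_weights`.
#' @export
nb_head_weights <- function(Wr, br, Wp, bp, genes,
                            p_mode = c("logistic", "softmax"),
                            center = NULL, scale = NULL, adapter = NULL,
                            seed = NA_integer_) {
  p_mode <- match.arg(p_mode)
  G <- length(genes); F_ <- ncol(Wr)
  stopifnot(nrow(Wr) == G, identical(dim(Wp), dim(Wr)),
            length(br) == G, length(bp) == G)
  structure(list(Wr = Wr, br = br, Wp = Wp, bp = bp, genes = genes,
                 input_dim = F_, p_mode = p_mode, center = center,
                 scale = scale, adapter = adapter, seed = seed),
            class = "nb_head_weights")
}

# standardise + adapter, shared by forward pass and training
head_transform_features <- function(features, head) {
  z <- unclass(features)[, , drop = FALSE]
  if (!is.null(head$center))
    z <- sweep(sweep(z, 2, head$center), 2, head$scale, "/")
  if (!is.null(head$adapter))
    z <- sweep(z %*% t(head$adapter$W), 2, head$adapter$b, "+")
  z
}

#' Apply the NB head to latent features
#'
#' Computes per-spot per-gene NB parameters: `r = softplus(affine(z))`
#' and `p` mapped into (0,1) elementwise by the logistic function (or by
#' a literal softmax across genes when the head was built in softmax
#' mode). Outputs are clamped to `[1e-6, Inf)` and `[1e-6, 1 - 1e-6]`.
#'
#' @param features spots x F matrix ([extract_features] output).
#' @param head an [nb_head_weights].
#' @return list of class `nb_params` with matrices `r` and `p`
#'   (spots x genes) and `gene_names`.
#' @export
nb_head_apply <- function(features, head) {
  z <- head_transform_features(features, head)
  if (ncol(z) != ncol(head$Wr))
    stop_spotnb(sprintf("feature dim %d does not match head input dim %d",
                        ncol(z), ncol(head$Wr)), "spotnb_shape_error")
  u <- z %*% t(head$Wr)
  v <- z %*% t(head$Wp)
  u <- sweep(u, 2, head$br, "+")
  v <- sweep(v, 2, head$bp, "+")
  r <- pmax(softplus(u), R_CLAMP)
  p <- if (head$p_mode == "softmax") {
    ev <- exp(v - apply(v, 1, max))
    ev / rowSums(ev)
  } else {
    sigmoid(v)
  }
  p <- pmin(pmax(p, P_CLAMP), 1 - P_CLAMP)
  dimnames(r) <- dimnames(p) <- list(rownames(features), head$genes)
  structure(list(r = r, p = p, gene_names = head$genes), class = "nb_params")
}

#' NB distribution moments
#'
#' `mean = r (1 - p) / p`, `std = sqrt(r (1 - p)) / p`.
#'
#' @param params an `nb_params` object (or list with `r`, `p`).
#' @return list with `mean` and `std` matrices shaped like `r`.
#' @export
nb_moments <- function(params) {
  r <- params$r; p <- params$p
  list(mean = r * (1 - p) / p, std = sqrt(r * (1 - p)) / p)
}

#' NB negative log-likelihood
#'
#' The training loss: for observed count x and parameters (r, p),
#' `lgamma(r) + lgamma(x + 1) - lgamma(r + x) - r log(p) - x log(1 - p)`,
#' summed (or averaged) over all spots and genes. This equals
#' `-log pmf` for the NB pmf
#' `Gamma(x + r) / (Gamma(r) x!) * p^r * (1 - p)^x`.
#'
#' @param counts spots x genes matrix of observed counts, aligned to
#'   `params` (matched by dimnames when present).
#' @param params an `nb_params` object.
#' @param reduction `"sum"` (default) or `"mean"` over entries.
#' @return scalar loss (finite for clamped parameters).
#' @export
nb_negative_log_likelihood <- function(counts, params, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  x <- unclass(counts)
  if (!is.null(rownames(x)) && !is.null(rownames(params$r))) {
    if (!setequal(rownames(x), rownames(params$r)) ||
        !setequal(colnames(x), colnames(params$r)))
      stop_spotnb("counts and params are not aligned", "spotnb_alignment_error")
    x <- x[rownames(params$r), colnames(params$r), drop = FALSE]
  }
  if (any(x < 0))
    stop_spotnb("negative counts", "spotnb_validation_error")
  ll <- lgamma(params$r) + lgamma(x + 1) - lgamma(params$r + x) -
    params$r * log(params$p) - x * log1p(-params$p)
  if (reduction == "sum") sum(ll) else mean(ll)
}

# Gradient of the summed NLL wrt (r, p), elementwise:
#   dl/dr = digamma(r) - digamma(r + x) - log(p)
#   dl/dp = -r/p + x/(1 - p)
nb_nll_grad <- function(x, r, p) {
  list(dr = digamma(r) - digamma(r + x) - log(p),
       dp = -r / p + x / (1 - p))
}

#' Train the NB head on latent features and raw counts
#'
#' Minimises the NB negative log-likelihood with minibatch Adam.
#' Features are standardised (training statistics are stored in the
#' returned head and re-applied at prediction time). With
#' `fine_tune_extractor = TRUE` a linear feature adapter (F x F affine
#' map) is trained jointly with the head, playing the role of the
#' trainable tail of the image extractor.
#'
#' @param features spots x F matrix.
#' @param counts spots x genes [expression_matrix] (raw counts).
#' @param genes optional subset of genes to train on.
#' @param batch_size minibatch size (default 64).
#' @param epochs training epochs (default 50).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed controlling initialisation and shuffling;
#'   training is deterministic for a fixed seed (single-threaded).
#' @param fine_tune_extractor train the linear feature adapter jointly.
#' @param p_mode `"logistic"` (default) or `"softmax"` p-mapping.
#' @param verbose print per-epoch loss.
#' @return An [nb_head_weights] with a `loss_history` attribute (mean
#'   per-entry NLL per epoch).
#' @export
train_nb_head <- function(features, counts, genes = NULL, batch_size = 64L,
                          epochs = 50L, lr = 1e-3, seed = 0L,
                          fine_tune_extractor = FALSE,
                          p_mode = c("logistic", "softmax"), verbose = FALSE) {
  p_mode <- match.arg(p_mode)
  z0 <- unclass(features)[, , drop = FALSE]
  x_all <- unclass(counts)[, , drop = FALSE]
  if (!is.null(genes)) x_all <- x_all[, genes, drop = FALSE]
  if (ncol(x_all) == 0) stop_spotnb("gene list is empty", "spotnb_validation_error")
  if (nrow(z0) < 2) stop_spotnb("need >= 2 spots", "spotnb_validation_error")
  if (!setequal(rownames(z0), rownames(x_all)))
    stop_spotnb("features and counts cover different spots", "spotnb_alignment_error")
  x_all <- x_all[rownames(z0), , drop = FALSE]
  gene_names <- colnames(x_all)
  n <- nrow(z0); F_ <- ncol(z0); G <- ncol(x_all)

  center <- colMeans(z0)
  scale <- apply(z0, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1
  z_std <- sweep(sweep(z0, 2, center), 2, scale, "/")

  with_seed(seed, {
    theta <- list(
      Wr = matrix(rnorm(G * F_, sd = 0.1 / sqrt(F_)), G, F_),
      br = rep(log(exp(1) - 1), G),          # softplus^{-1}(1)
      Wp = matrix(rnorm(G * F_, sd = 0.1 / sqrt(F_)), G, F_),
      # p = r/(r+mu) at r = 1 matches each gene's mean count at init
      bp = -log(pmax(colMeans(x_all), 1e-2))
    )
    if (fine_tune_extractor)
      theta$adapter <- list(W = diag(F_) + matrix(rnorm(F_ * F_, sd = 0.01), F_, F_),
                            b = rep(0, F_))

    adam_m <- rapply(theta, function(x) x * 0, how = "replace")
    adam_v <- adam_m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
    history <- numeric(epochs)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        z <- z_std[idx, , drop = FALSE]
        if (fine_tune_extractor)
          z2 <- sweep(z %*% t(theta$adapter$W), 2, theta$adapter$b, "+")
        else z2 <- z
        x <- x_all[idx, , drop = FALSE]
        B <- nrow(z)

        u <- sweep(z2 %*% t(theta$Wr), 2, theta$br, "+")
        v <- sweep(z2 %*% t(theta$Wp), 2, theta$bp, "+")
        r <- pmax(softplus(u), R_CLAMP)
        p <- if (p_mode == "softmax") {
          ev <- exp(v - apply(v, 1, max)); ev / rowSums(ev)
        } else sigmoid(v)
        p <- pmin(pmax(p, P_CLAMP), 1 - P_CLAMP)

        l <- lgamma(r) + lgamma(x + 1) - lgamma(r + x) -
          r * log(p) - x * log1p(-p)
        if (!all(is.finite(l)))
          stop_spotnb(sprintf(
            "non-finite loss in epoch %d (lr = %g; r range [%g, %g], p range [%g, %g]); try a smaller learning rate",
            ep, lr, min(r), max(r), min(p), max(p)), "spotnb_numeric_error")
        ep_loss <- ep_loss + sum(l); ep_n <- ep_n + length(l)

        g <- nb_nll_grad(x, r, p)
        dU <- g$dr * sigmoid(u)                       # d softplus
        dV <- if (p_mode == "softmax") {
          p * (g$dp - rowSums(g$dp * p))
        } else {
          g$dp * p * (1 - p)
        }
        grad <- list(
          Wr = crossprod(dU, z2) / B, br = colSums(dU) / B,
          Wp = crossprod(dV, z2) / B, bp = colSums(dV) / B
        )
        if (fine_tune_extractor) {
          dZ2 <- (dU %*% theta$Wr + dV %*% theta$Wp)
          grad$adapter <- list(W = crossprod(dZ2, z) / B,
                               b = colSums(dZ2) / B)
        }

        step <- step + 1L
        for (nm in names(grad)) {
          if (nm == "adapter") {
            for (sub in c("W", "b")) {
              adam_m$adapter[[sub]] <- b1 * adam_m$adapter[[sub]] + (1 - b1) * grad$adapter[[sub]]
              adam_v$adapter[[sub]] <- b2 * adam_v$adapter[[sub]] + (1 - b2) * grad$adapter[[sub]]^2
              mh <- adam_m$adapter[[sub]] / (1 - b1^step)
              vh <- adam_v$adapter[[sub]] / (1 - b2^step)
              theta$adapter[[sub]] <- theta$adapter[[sub]] - lr * mh / (sqrt(vh) + eps)
            }
          } else {
            adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grad[[nm]]
            adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grad[[nm]]^2
            mh <- adam_m[[nm]] / (1 - b1^step)
            vh <- adam_v[[nm]] / (1 - b2^step)
            theta[[nm]] <- theta[[nm]] - lr * mh / (sqrt(vh) + eps)
          }
        }
      }
      history[ep] <- ep_loss / ep_n
      if (verbose) message(sprintf("epoch %3d  mean NLL %.5f", ep, history[ep]))
    }

    head <- nb_head_weights(theta$Wr, theta$br, theta$Wp, theta$bp,
                            genes = gene_names, p_mode = p_mode,
                            center = center, scale = scale,
                            adapter = theta$adapter, seed = seed)
    attr(head, "loss_history") <- history
    head
  })
}

#' Predict per-spot expression distributions
#'
#' Applies a trained model to latent features (or to a [tile_set] when
#' the model carries an extractor spec) and returns NB parameters and a
#' long-format moments table.
#'
#' @param x a `latent_features` matrix or a [tile_set].
#' @param model an [nb_head_weights], optionally with an attached
#'   `extractor` attribute ([extractor_spec]).
#' @return list with `params` (`nb_params`) and `table` (data.frame
#'   `spot_id, gene, r, p, mean, std`, sorted).
#' @export
predict_expression <- function(x, model) {
  if (inherits(x, "tile_set")) {
    spec <- attr(model, "extractor") %||% extractor_spec("handcrafted")
    x <- extract_features(x, spec)
  }
  params <- nb_head_apply(x, model)
  mom <- nb_moments(params)
  tbl <- data.frame(
    spot_id = rep(rownames(params$r), times = ncol(params$r)),
    gene = rep(colnames(params$r), each = nrow(params$r)),
    r = as.vector(params$r), p = as.vector(params$p),
    mean = as.vector(mom$mean), std = as.vector(mom$std),
    stringsAsFactors = FALSE
  )
  tbl <- tbl[order(tbl$spot_id, tbl$gene), , drop = FALSE]
  rownames(tbl) <- NULL
  list(params = params, table = tbl)
}

#' Sample counts from predicted NB distributions
#'
#' @param params an `nb_params` object.
#' @param n_draws draws per (spot, gene) cell.
#' @param seed RNG seed.
#' @return array of dim (n_draws, spots, genes).
#' @export
sample_nb <- function(params, n_draws = 1L, seed = 0L) {
  with_seed(seed, {
    d <- dim(params$r)
    draws <- array(
      rnbinom(n_draws * prod(d),
              size = rep(as.vector(params$r), each = n_draws),
              prob = rep(as.vector(params$p), each = n_draws)),
      dim = c(n_draws, d))
    dimnames(draws) <- c(list(NULL), dimnames(params$r))
    draws
  })
}

#' Select the most variable genes
#' @param counts an [expression_matrix].
#' @param n number of genes to keep.
#' @return character vector of gene names, by decreasing variance.
#' @export
top_variable_genes <- function(counts, n = 100L) {
  v <- apply(unclass(counts), 2, stats::var)
  names(sort(v, decreasing = TRUE))[seq_len(min(n, length(v)))]
}

#' Serialise a trained model to JSON
#' @param model an [nb_head_weights].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$loss_history <- attr(model, "loss_history")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model serialised by [save_model]
#' @param path JSON path.
#' @return an [nb_head_weights].
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nr) if (is.matrix(x)) x else matrix(x, nrow = nr)
  G <- length(obj$genes)
  head <- nb_head_weights(
    Wr = as_mat(obj$Wr, G), br = obj$br,
    Wp = as_mat(obj$Wp, G), bp = obj$bp,
    genes = obj$genes, p_mode = obj$p_mode,
    center = obj$center, scale = obj$scale,
    adapter = if (!is.null(obj$adapter$W))
      list(W = as_mat(obj$adapter$W, length(obj$adapter$b)),
           b = obj$adapter$b),
    seed = obj$seed %||% NA_integer_)
  attr(head, "loss_history") <- obj$loss_history
  head
}
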