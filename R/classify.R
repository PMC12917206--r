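## High/low expression classification. Expression is z-scored per gene
## and binarised at zero (High iff z > 0; the tie z = 0 goes to Low).
## A per-gene elastic-net logistic regression on the latent features
## minimises
##   L(beta, b) = meanBCE(y, sigmoid(X beta + b))
##                + omega * ((1 - alpha) sum(beta^2) + alpha sum(|beta|))
## with the intercept unpenalised. The convex solve is delegated to
## glmnet under an exact reparameterisation (see train_elastic_net).

#' Binarise expression into High/Low labels by per-gene z-scores
#'
#' z = (x - mu) / sigma per gene across spots; label is "High" iff
#' z > 0 and "Low" otherwise. When `stats` (training statistics) is
#' supplied they are reused, so test spots are labelled on the training
#' scale.
#'
#' @param expr spots x genes matrix (raw counts by default; any
#'   monotone-affine transform yields identical labels).
#' @param stats optional list with `mean` and `sd` named per gene, as
#'   stored in a previous result's `stats` field.
#' @return list of class `binary_label_matrix` with `labels` (character
#'   matrix "High"/"Low"), `z`, and `stats`.
#' @export
binarize_expression <- function(expr, stats = NULL) {
  x <- unclass(expr)[, , drop = FALSE]
  genes <- colnames(x)
  if (is.null(stats)) {
    mu <- colMeans(x)
    sg <- apply(x, 2, stats::sd)
  } else {
    mu <- stats$mean[genes]; sg <- stats$sd[genes]
  }
  bad <- genes[!is.finite(sg) | sg <= 0]
  if (length(bad))
    stop_spotnb(sprintf("constant gene(s), z-score undefined: %s",
                        paste(bad, collapse = ", ")),
                "spotnb_validation_error")
  z <- sweep(sweep(x, 2, mu), 2, sg, "/")
  labels <- ifelse(z > 0, "High", "Low")
  dimnames(labels) <- dimnames(x)
  structure(list(labels = labels, z = z,
                 stats = list(mean = mu, sd = sg)),
            class = "binary_label_matrix")
}

#' Elastic-net logistic objective
#'
#' `meanBCE + omega * ((1 - alpha) * sum(beta^2) + alpha * sum(|beta|))`.
#' At `alpha = 1` the penalty reduces to the pure L1 (lasso) term, at
#' `alpha = 0` to the pure L2 (ridge) term. The intercept is not
#' penalised.
#'
#' @param beta coefficient vector (length F).
#' @param b intercept.
#' @param X spots x F feature matrix.
#' @param y 0/1 labels (1 = High).
#' @param alpha mixing parameter in \[0, 1\].
#' @param omega regularisation strength (>= 0).
#' @return scalar objective value.
#' @export
elastic_net_objective <- function(beta, b, X, y, alpha, omega) {
  eta <- as.vector(X %*% beta) + b
  # numerically stable mean binary cross-entropy
  bce <- mean((1 - y) * eta + log1p(exp(-abs(eta))) + pmax(-eta, 0))
  bce + omega * ((1 - alpha) * sum(beta^2) + alpha * sum(abs(beta)))
}

#' Train per-gene elastic-net logistic classifiers
#'
#' For each gene, fits the objective of [elastic_net_objective] on the
#' latent features against the High/Low labels. The solve uses glmnet's
#' coordinate descent under the exact reparameterisation
#' `lambda = omega * (2 - alpha)`, `alpha_glmnet = alpha / (2 - alpha)`,
#' which makes glmnet's penalised objective identical to ours. Features
#' are not re-standardised (embeddings are used as-is) and the intercept
#' is unpenalised.
#'
#' @param features spots x F matrix.
#' @param labels a [binarize_expression] result (training spots).
#' @param alpha elastic-net mixing in \[0, 1\] (default 0.5).
#' @param omega regularisation strength (default 0.1).
#' @param seed stored for bookkeeping (the solver is deterministic).
#' @param thresh glmnet convergence threshold.
#' @return list of class `elastic_net_classifier`: per-gene `beta`,
#'   `intercept`, plus `alpha`, `omega` and the label statistics.
#' @export
train_elastic_net <- function(features, labels, alpha = 0.5, omega = 0.1,
                              seed = 0L, thresh = 1e-10) {
  if (alpha < 0 || alpha > 1)
    stop_spotnb("alpha must lie in [0, 1]", "spotnb_parameter_error")
  if (omega < 0)
    stop_spotnb("omega must be >= 0", "spotnb_parameter_error")
  X <- unclass(features)[, , drop = FALSE]
  lab <- labels$labels
  if (!setequal(rownames(X), rownames(lab)))
    stop_spotnb("features and labels cover different spots", "spotnb_alignment_error")
  lab <- lab[rownames(X), , drop = FALSE]
  genes <- colnames(lab)
  lambda_g <- omega * (2 - alpha)
  alpha_g <- if (lambda_g > 0) alpha / (2 - alpha) else 0
  fits <- lapply(genes, function(g) {
    y <- as.integer(lab[, g] == "High")
    if (length(unique(y)) < 2)
      stop_spotnb(sprintf("gene %s has a single class", g),
                  "spotnb_validation_error")
    if (lambda_g > 0) {
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha_g,
                            lambda = lambda_g, standardize = FALSE,
                            thresh = thresh, maxit = 1e6)
      list(beta = as.vector(fit$beta), intercept = as.vector(fit$a0))
    } else {
      # unpenalised logistic fit
      fit <- stats::glm.fit(cbind(1, X), y, family = stats::binomial())
      list(beta = fit$coefficients[-1], intercept = fit$coefficients[1])
    }
  })
  names(fits) <- genes
  structure(list(fits = fits, alpha = alpha, omega = omega,
                 feature_names = colnames(X), stats = labels$stats,
                 seed = seed),
            class = "elastic_net_classifier")
}

#' Predict the probability of High expression
#'
#' Logistic of the affine score `beta' x + b` per spot.
#'
#' @param features spots x F matrix.
#' @param classifier a [train_elastic_net] result.
#' @param genes genes to predict (default: all trained).
#' @return spots x genes matrix of probabilities in (0, 1).
#' @export
predict_class_prob <- function(features, classifier, genes = NULL) {
  X <- unclass(features)[, , drop = FALSE]
  genes <- genes %||% names(classifier$fits)
  p <- ncol(X)
  out <- sapply(genes, function(g) {
    fit <- classifier$fits[[g]]
    if (is.null(fit))
      stop_spotnb(sprintf("gene %s not in classifier", g), "spotnb_parameter_error")
    if (length(fit$beta) != p)
      stop_spotnb(sprintf("feature dim %d does not match classifier dim %d",
                          p, length(fit$beta)), "spotnb_shape_error")
    plogis(as.vector(X %*% fit$beta) + fit$intercept)
  })
  out <- matrix(out, nrow = nrow(X), dimnames = list(rownames(X), genes))
  out
}
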