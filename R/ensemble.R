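## Seeded model replicates, ensemble pooling and the law-of-total-variance
## uncertainty decomposition: for an ensemble of models Theta,
##   V[X | s] = V[ E[X | s, Theta] ]  +  E[ V[X | s, Theta] ]
##              \__ epistemic ____/      \___ aleatoric ___/
## Epistemic uncertainty is the population (divide-by-M) variance across
## members of the predicted NB means; aleatoric is the member-average of
## the predicted NB variances.

#' Train an ensemble of seeded NB-head replicates
#'
#' Trains `M` replicates of [train_nb_head] on identical data and
#' configuration, differing only in the seed (`base_seed .. base_seed +
#' M - 1`). A replicate whose training aborts with a non-finite loss is
#' excluded with a warning.
#'
#' @param features spots x F matrix.
#' @param counts spots x genes [expression_matrix].
#' @param M number of replicates (default 30).
#' @param base_seed seed of the first replicate.
#' @param ... passed to [train_nb_head] (epochs, lr, ...).
#' @return list of class `ensemble_set` with `models` and `seeds`.
#' @export
train_ensemble <- function(features, counts, M = 30L, base_seed = 0L, ...) {
  if (M < 1) stop_spotnb("M must be >= 1", "spotnb_parameter_error")
  seeds <- base_seed + seq_len(M) - 1L
  models <- list(); kept <- integer()
  for (i in seq_len(M)) {
    m <- tryCatch(train_nb_head(features, counts, seed = seeds[i], ...),
                  spotnb_numeric_error = function(e) {
                    warning(sprintf("replicate %d (seed %d) failed: %s",
                                    i, seeds[i], conditionMessage(e)))
                    NULL
                  })
    if (!is.null(m)) { models[[length(models) + 1L]] <- m; kept <- c(kept, seeds[i]) }
  }
  if (!length(models))
    stop_spotnb("all ensemble replicates failed", "spotnb_numeric_error")
  structure(list(models = models, seeds = kept), class = "ensemble_set")
}

#' @export
length.ensemble_set <- function(x) length(x$models)

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("<ensemble_set> %d replicate(s), seeds %s\n", length(x),
              paste(x$seeds, collapse = ", ")))
  invisible(x)
}

#' Randomly pool ensemble members into groups
#'
#' Draws `n_groups` random subsets of `group_size` members (without
#' replacement within a group), seeded. Pooling by averaging member
#' means is done downstream by [ensemble_mean].
#'
#' @param set an [train_ensemble] result.
#' @param group_size members per group (default 5).
#' @param n_groups number of groups (default `floor(M / group_size)`).
#' @param seed RNG seed for the grouping.
#' @return list of `ensemble_set` groups.
#' @export
pool_ensembles <- function(set, group_size = 5L, n_groups = NULL, seed = 0L) {
  M <- length(set)
  if (group_size > M)
    stop_spotnb("group_size exceeds the number of members", "spotnb_parameter_error")
  n_groups <- n_groups %||% (M %/% group_size)
  with_seed(seed, {
    lapply(seq_len(n_groups), function(i) {
      idx <- sample.int(M, group_size)
      structure(list(models = set$models[idx], seeds = set$seeds[idx]),
                class = "ensemble_set")
    })
  })
}

# per-member NB params on a feature matrix; members may also be given as
# precomputed nb_params
member_params <- function(group, features = NULL) {
  members <- if (inherits(group, "ensemble_set")) group$models else group
  lapply(members, function(m) {
    if (inherits(m, "nb_params")) m
    else {
      if (is.null(features))
        stop_spotnb("features required to evaluate ensemble members",
                    "spotnb_parameter_error")
      nb_head_apply(features, m)
    }
  })
}

#' Ensemble mean prediction
#'
#' Arithmetic mean over members of the per-spot per-gene NB means. Only
#' the mean is pooled; no ensemble-level (r, p) pair is synthesised.
#'
#' @param group an `ensemble_set` (or list of models / `nb_params`).
#' @param features spots x F matrix (omit if members are `nb_params`).
#' @return spots x genes matrix of pooled means.
#' @export
ensemble_mean <- function(group, features = NULL) {
  ps <- member_params(group, features)
  if (!length(ps)) stop_spotnb("empty ensemble group", "spotnb_parameter_error")
  mus <- lapply(ps, function(p) nb_moments(p)$mean)
  Reduce(`+`, mus) / length(mus)
}

#' Decompose ensemble predictive uncertainty
#'
#' Per spot and gene: `epistemic` is the population variance across
#' members of the NB means, `aleatoric` the member-average of the NB
#' variances, and `total = aleatoric + epistemic` (exactly, by
#' construction). A single-member group has zero epistemic uncertainty.
#'
#' @inheritParams ensemble_mean
#' @return list of class `uncertainty_result` with matrices `mean`,
#'   `aleatoric`, `epistemic`, `total`.
#' @export
decompose_uncertainty <- function(group, features = NULL) {
  ps <- member_params(group, features)
  M <- length(ps)
  if (!M) stop_spotnb("empty ensemble group", "spotnb_parameter_error")
  moms <- lapply(ps, nb_moments)
  mus <- lapply(moms, `[[`, "mean")
  vars <- lapply(moms, function(m) m$std^2)
  mu_bar <- Reduce(`+`, mus) / M
  # population variance on deviations from the first member: shift
  # invariant, and exactly zero when all member means coincide
  devs <- lapply(mus, function(m) m - mus[[1]])
  dev_bar <- Reduce(`+`, devs) / M
  epistemic <- Reduce(`+`, lapply(devs, function(d) (d - dev_bar)^2)) / M
  aleatoric <- Reduce(`+`, vars) / M
  structure(list(mean = mu_bar, aleatoric = aleatoric,
                 epistemic = epistemic, total = aleatoric + epistemic),
            class = "uncertainty_result")
}

#' Write an uncertainty decomposition to CSV
#' @param unc an [decompose_uncertainty] result.
#' @param path output CSV (columns spot_id, gene, mean, aleatoric,
#'   epistemic, total).
#' @return `path`, invisibly.
#' @export
write_uncertainty <- function(unc, path) {
  df <- data.frame(
    spot_id = rep(rownames(unc$mean), times = ncol(unc$mean)),
    gene = rep(colnames(unc$mean), each = nrow(unc$mean)),
    mean = as.vector(unc$mean), aleatoric = as.vector(unc$aleatoric),
    epistemic = as.vector(unc$epistemic), total = as.vector(unc$total),
    stringsAsFactors = FALSE)
  df <- df[order(df$spot_id, df$gene), , drop = FALSE]
  data.table::fwrite(df, path)
  invisible(path)
}
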