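#' Fit a linear discriminant model
#'
#' From-scratch linear discriminant analysis with a shared within-group
#' covariance. Group means and the pooled within-group covariance (divisor
#' n - G, the unbiased pooled estimator) are estimated, and discriminant
#' scalings are obtained as the leading eigenvectors of the within/between
#' generalised eigenproblem, normalised so the projected training data have
#' unit within-group variance on every discriminant. There are
#' m = min(G - 1, p) discriminant functions.
#'
#' Because the sign of a discriminant is mathematically arbitrary (and does
#' differ between statistical programs), each scaling is oriented so that its
#' largest-magnitude loading is positive, making outputs reproducible.
#'
#' If the pooled covariance is singular (for example when an attribute column
#' is constant) a small ridge `eps * trace/p` is added to the diagonal with a
#' warning; all-zero columns are additionally reported by name.
#'
#' @param X numeric matrix (n x p) of predictors; an `attribute_matrix`
#'   works directly. Column order is fixed by the model.
#' @param groups group label per row (coerced to factor; >= 2 groups, each
#'   with >= 2 members).
#' @param priors `"proportional"` (to group size, the default),
#'   `"uniform"`, or an explicit numeric vector over the groups (summing
#'   to 1).
#' @param ridge_eps ridge constant used only on singular pooled covariance.
#' @return An object of class `lda_model` with elements `group_labels`,
#'   `priors`, `means` (G x p), `pooled_cov` (p x p), `scalings` (p x m),
#'   `xbar` (training grand mean), `training_sizes`, `centroids` (group means
#'   in discriminant space).
#' @export
fit_lda <- function(X, groups, priors = "proportional", ridge_eps = 1e-8) {
  X <- as.matrix(unclass(X))
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X)))
    stop("non-finite values in predictor matrix", call. = FALSE)
  groups <- factor(groups)
  if (nrow(X) != length(groups))
    stop("groups must have one label per row of X", call. = FALSE)
  G <- nlevels(groups)
  p <- ncol(X)
  n <- nrow(X)
  if (G < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("every group needs >= 2 members; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)

  pri <- if (is.character(priors)) {
    switch(match.arg(priors, c("proportional", "uniform")),
           proportional = as.numeric(sizes) / n,
           uniform = rep(1 / G, G))
  } else {
    if (length(priors) != G || abs(sum(priors) - 1) > 1e-8)
      stop("explicit priors must have one entry per group and sum to 1",
           call. = FALSE)
    as.numeric(priors)
  }
  names(pri) <- levels(groups)

  means <- do.call(rbind, lapply(levels(groups), function(g) {
    colMeans(X[groups == g, , drop = FALSE])
  }))
  dimnames(means) <- list(levels(groups), colnames(X))

  # pooled within-group covariance, divisor n - G
  W <- matrix(0, p, p)
  for (g in levels(groups)) {
    Xg <- sweep(X[groups == g, , drop = FALSE], 2L, means[g, ])
    W <- W + crossprod(Xg)
  }
  W <- W / (n - G)
  dimnames(W) <- list(colnames(X), colnames(X))

  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch) || rcond(W) < 1e-12) {
    zero_cols <- colnames(X)[apply(X, 2L, function(v) all(v == 0))]
    if (length(zero_cols))
      warning("all-zero predictor column(s): ",
              paste(zero_cols, collapse = ", "), call. = FALSE)
    warning(sprintf(
      "pooled within-group covariance is (near-)singular; adding ridge %g * trace/p",
      ridge_eps), call. = FALSE)
    W <- W + diag(ridge_eps * sum(diag(W)) / p, p)
    ch <- chol(W)
  }

  # between-group scatter of group means about the grand mean, size-weighted
  xbar <- colMeans(X)
  Mc <- sweep(means, 2L, xbar)
  B <- crossprod(Mc * sqrt(as.numeric(sizes)))

  # solve W^{-1} B via the symmetric whitened problem
  Winv_half <- backsolve(ch, diag(p))        # W = ch' ch, so this is ch^{-1}
  Bstar <- t(Winv_half) %*% B %*% Winv_half
  eig <- eigen((Bstar + t(Bstar)) / 2, symmetric = TRUE)
  m <- min(G - 1L, p)
  scalings <- Winv_half %*% eig$vectors[, seq_len(m), drop = FALSE]
  # normalise to unit within-group variance: a' W a = 1
  norms <- sqrt(colSums(scalings * (W %*% scalings)))
  scalings <- sweep(scalings, 2L, norms, "/")
  # deterministic sign: largest-|loading| positive
  for (j in seq_len(m)) {
    i <- which.max(abs(scalings[, j]))
    if (scalings[i, j] < 0) scalings[, j] <- -scalings[, j]
  }
  dimnames(scalings) <- list(colnames(X), paste0("LD", seq_len(m)))

  model <- structure(
    list(group_labels = levels(groups), priors = pri, means = means,
         pooled_cov = W, scalings = scalings, xbar = xbar,
         training_sizes = as.numeric(sizes), m = m, p = p),
    class = "lda_model"
  )
  model$centroids <- project(model, means)
  model
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: %d groups, %d predictors, %d discriminant function(s)\n",
              length(x$group_labels), x$p, x$m))
  cat("  groups:", paste(sprintf("%s (n=%d)", x$group_labels,
                                 x$training_sizes), collapse = ", "), "\n")
  cat("  priors:", paste(sprintf("%.3f", x$priors), collapse = ", "), "\n")
  invisible(x)
}

check_projectable <- function(model, X) {
  X <- as.matrix(unclass(X))
  storage.mode(X) <- "double"
  if (ncol(X) != model$p)
    stop("expected ", model$p, " predictor columns, got ", ncol(X),
         call. = FALSE)
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), colnames(model$means)))
    stop("predictor columns do not match the model: expected ",
         paste(colnames(model$means), collapse = ", "), "; got ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("non-finite values in predictor matrix", call. = FALSE)
  X
}

#' Project samples onto the discriminant functions
#'
#' Scores are `(X - grand training mean) %*% scalings`: unstandardised
#' discriminant scores, zero at the training grand mean.
#'
#' @param model an `lda_model`.
#' @param X matrix with the model's predictor columns in model order.
#' @return numeric matrix n x m of discriminant scores.
#' @export
project <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  X <- check_projectable(model, X)
  sweep(X, 2L, model$xbar) %*% model$scalings
}

#' Posterior group probabilities under the shared-covariance Gaussian model
#'
#' Computed in the sphered discriminant space, where the shared covariance is
#' the identity: `p_k(x) proportional to prior_k * exp(-||z(x) - z_k||^2 / 2)`
#' with `z_k` the group centroid. Because the discriminant space captures
#' every between-mean direction, this equals the full p-dimensional
#' shared-covariance Gaussian posterior. Rows are normalised with a
#' log-sum-exp guard.
#'
#' @inheritParams project
#' @return numeric matrix n x G of posteriors; rows sum to 1.
#' @export
posterior <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  Z <- project(model, X)
  C <- model$centroids
  logp <- vapply(seq_along(model$group_labels), function(k) {
    -0.5 * rowSums(sweep(Z, 2L, C[k, ])^2) + log(model$priors[k])
  }, numeric(nrow(Z)))
  logp <- matrix(logp, nrow = nrow(Z),
                 ncol = length(model$group_labels))
  dimnames(logp) <- list(
    if (nrow(Z)) rownames(Z) %||% rownames(as.matrix(unclass(X))),
    model$group_labels)
  if (nrow(logp) == 0L) return(logp)
  mx <- apply(logp, 1L, max)
  un <- exp(logp - mx)
  un / rowSums(un)
}

#' Classify samples with an LDA model
#'
#' The class is the posterior argmax; exact ties are broken towards the
#' lowest group index.
#'
#' @inheritParams project
#' @return character vector of group labels, one per row.
#' @export
predict_class <- function(model, X) {
  post <- posterior(model, X)
  if (nrow(post) == 0L) return(character())
  model$group_labels[apply(post, 1L, which.max)]
}
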