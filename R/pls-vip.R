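#' Single-response partial least squares by NIPALS
#'
#' Fits PLS1 regression of one response on a predictor matrix with the
#' classical NIPALS algorithm: both blocks are autoscaled (mean 0, sd 1),
#' then for each component the weight vector `w = X'y / ||X'y||` defines a
#' score `t = Xw`, predictor loadings `p = X't/(t't)` and response loading
#' `q = y't/(t't)`, after which both X and y are deflated. For a single
#' response this is algebraically equivalent to SIMPLS. Fitting is fully
#' deterministic.
#'
#' @param X Numeric sample x predictor matrix; no constant column.
#' @param y Numeric response vector, one value per row of `X`.
#' @param n_components Number of latent components, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return A list of class `pls1_fit` with weights `W`, predictor loadings
#'   `P`, response loadings `q`, scores `T` (mutually orthogonal columns),
#'   the standardization constants, per-component explained fractions of
#'   response variance `explained_y_variance`, regression coefficients on
#'   the original scale, and fitted values.
#' @export
fit_pls1 <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n_components < 1 || n_components > min(n - 1, p)) {
    stop("n_components must lie in [1, min(samples - 1, predictors)]",
         call. = FALSE)
  }
  x_sds <- apply(X, 2, stats::sd)
  if (any(x_sds == 0)) {
    stop("constant predictor(s): ",
         paste(colnames(X)[x_sds == 0], collapse = ", "), call. = FALSE)
  }
  y_sd <- stats::sd(y)
  if (y_sd == 0) stop("constant response", call. = FALSE)
  x_means <- colMeans(X); y_mean <- mean(y)
  Xs <- sweep(sweep(X, 2, x_means), 2, x_sds, "/")
  ys <- (y - y_mean) / y_sd
  ss_y_total <- sum(ys^2)

  A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A); ssy <- numeric(A)
  Xc <- Xs; yc <- ys
  for (k in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop("response residual is orthogonal to predictors at component ", k,
           "; reduce n_components", call. = FALSE)
    }
    w <- w / nw
    t_k <- Xc %*% w
    tt <- sum(t_k^2)
    p_k <- crossprod(Xc, t_k) / tt
    q_k <- sum(yc * t_k) / tt
    Xc <- Xc - tcrossprod(t_k, p_k)
    yc <- yc - q_k * t_k
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- t_k
    q[k] <- q_k
    ssy[k] <- q_k^2 * tt / ss_y_total
  }
  pred_names <- colnames(X)
  if (is.null(pred_names)) pred_names <- paste0("x", seq_len(p))
  dimnames(W) <- dimnames(P) <- list(pred_names, paste0("comp", seq_len(A)))

  # coefficients in standardized space, then back to original units
  B_std <- W %*% solve(crossprod(P, W), q)
  coef <- as.numeric(B_std) * y_sd / x_sds
  intercept <- y_mean - sum(coef * x_means)
  fitted <- as.numeric(X %*% coef) + intercept

  structure(list(n_components = A, W = W, P = P, q = q, T = Tm,
                 x_means = x_means, x_sds = x_sds,
                 y_mean = y_mean, y_sd = y_sd,
                 explained_y_variance = ssy,
                 coefficients = stats::setNames(coef, pred_names),
                 intercept = intercept,
                 fitted = fitted),
            class = "pls1_fit")
}

#' @export
predict.pls1_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$coefficients) + object$intercept
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_k(SSY_k * w_jk^2) / sum_k(SSY_k))`, where `SSY_k`
#' is the response sum of squares explained by component `k` and the
#' weights are unit-norm per component. Squared VIP scores average to 1
#' over the `p` predictors, so VIP > 1 marks predictors contributing more
#' than average; the default threshold follows that convention.
#'
#' @param model A [fit_pls1()] model.
#' @param threshold Selection threshold (default 1).
#' @return A list of class `vip_result` with `scores` (named vector) and
#'   `selected` (names with `VIP > threshold`).
#' @export
vip_scores <- function(model, threshold = 1) {
  stopifnot(inherits(model, "pls1_fit"))
  ssy <- model$explained_y_variance
  if (sum(ssy) <= 0) {
    stop("model explains no response variance; VIP undefined", call. = FALSE)
  }
  p <- nrow(model$W)
  vip <- sqrt(p * as.numeric(model$W^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(model$W)
  structure(list(scores = vip,
                 selected = names(vip)[vip > threshold],
                 threshold = threshold),
            class = "vip_result")
}

#' Choose the PLS component count by cross-validated RMSEP
#'
#' K-fold cross-validation of [fit_pls1()], returning the component count
#' with the smallest root-mean-squared prediction error; exact ties break
#' toward fewer components. Fold assignment is the only source of
#' randomness and is controlled by `seed`.
#'
#' @param X,y As in [fit_pls1()].
#' @param max_components Largest count to consider.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for fold shuffling.
#' @return The selected component count.
#' @export
choose_components <- function(X, y, max_components = NULL, folds = 5,
                              seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  if (is.null(max_components)) max_components <- min(n - 1, ncol(X))
  max_components <- min(max_components, ncol(X))
  set.seed(substream_seed(seed, "cvfolds"))
  fold_id <- sample(rep_len(seq_len(folds), n))
  # smallest training split still has to support max_components
  max_components <- min(max_components, n - max(tabulate(fold_id, folds)) - 1)
  if (max_components < 1) stop("too few samples for cross-validation",
                               call. = FALSE)
  sse <- numeric(max_components)
  for (f in seq_len(folds)) {
    train <- fold_id != f
    for (a in seq_len(max_components)) {
      fit <- fit_pls1(X[train, , drop = FALSE], y[train], a)
      pred <- predict(fit, X[!train, , drop = FALSE])
      sse[a] <- sse[a] + sum((y[!train] - pred)^2)
    }
  }
  rmse <- sqrt(sse / n)
  which(rmse <= min(rmse) + 1e-12)[1]
}
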