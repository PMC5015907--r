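#' Random Fourier feature map for the Gaussian kernel
#'
#' Draws the frequency matrix and phases of the randomized cosine feature map
#' `z(x) = sqrt(2/D) * cos(Omega x + phi)` whose inner products approximate
#' the Gaussian kernel `exp(-||x - y||^2 / (2 sigma^2))`. The base frequencies
#' are drawn once from a standard normal and divided by `sigma`, so maps built
#' from the same seed share their random draws across bandwidths -- this keeps
#' a bandwidth grid search smooth in sigma. Reconstruction from
#' `(seed, sigma, n_features, d)` is bit-identical.
#'
#' @param d input dimensionality (number of channels).
#' @param n_features number of random features D.
#' @param sigma Gaussian kernel standard deviation.
#' @param seed integer RNG seed.
#' @return An object of class `rff_map`.
#' @export
rff_map <- function(d, n_features, sigma, seed) {
  if (n_features <= 0) stop("n_features must be positive", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  base <- matrix(stats::rnorm(n_features * d), n_features, d)
  phase <- stats::runif(n_features, 0, 2 * pi)
  structure(list(omega = base / sigma, phase = phase, sigma = sigma,
                 n_features = n_features, d = d, seed = seed),
            class = "rff_map")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate a random Fourier feature map
#'
#' @param map an [rff_map()].
#' @param X numeric matrix (samples x d) or a single d-vector.
#' @return Feature matrix (samples x D); every row has norm at most sqrt(2).
#' @export
rff_features <- function(map, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != map$d) stop("input dimensionality mismatch", call. = FALSE)
  proj <- tcrossprod(X, map$omega)            # n x D
  sqrt(2 / map$n_features) * cos(sweep(proj, 2, map$phase, `+`))
}

gauss_kernel <- function(X, Y, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

ridge_solve <- function(Z, Y, lambda) {
  D <- ncol(Z); n <- nrow(Z)
  if (D <= n) {
    G <- crossprod(Z)
    diag(G) <- diag(G) + lambda
    solve(G, crossprod(Z, Y))
  } else {
    # dual route, cheaper when features outnumber samples
    G <- tcrossprod(Z)
    diag(G) <- diag(G) + lambda
    crossprod(Z, solve(G, Y))
  }
}

#' Fit an intent-detection regressor
#'
#' Closed-form ridge solutions, multi-output (all DOF targets solved jointly),
#' without intercept -- the training set always contains an explicit rest
#' class at target zero. Three kinds are available:
#' \describe{
#'   \item{`"rr"`}{linear ridge regression on the raw envelope channels;}
#'   \item{`"rr-rff"`}{ridge regression on a random-Fourier-feature
#'     approximation of the Gaussian kernel -- model size depends on the
#'     feature count D, not on the training-set size, which matters because
#'     LET-augmented sets grow combinatorially with the number of DOFs;}
#'   \item{`"krr"`}{exact Gaussian-kernel ridge regression (a least-squares
#'     support vector machine), fit in the dual; serves as the exact-kernel
#'     reference for `"rr-rff"`.}
#' }
#'
#' @param training a `training_set` from [build_training_set()], or a list
#'   with matrices `X` and `Y`.
#' @param kind `"rr"`, `"rr-rff"` or `"krr"`.
#' @param lambda ridge penalty (> 0, default 1).
#' @param sigma Gaussian kernel standard deviation (kernel kinds only).
#' @param n_features number of random features D for `"rr-rff"` (default 500).
#' @param seed RNG seed for the feature map.
#' @return An object of class `myo_regressor`.
#' @export
fit_regressor <- function(training, kind = c("rr-rff", "rr", "krr"),
                          lambda = 1, sigma = 1, n_features = 500, seed = 1) {
  kind <- match.arg(kind)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  xy <- if (inherits(training, "training_set")) as_xy(training) else training
  X <- as.matrix(xy$X); Y <- as.matrix(xy$Y)
  if (nrow(X) == 0) stop("empty training set", call. = FALSE)
  dof_order <- colnames(Y)
  model <- switch(kind,
    "rr" = list(W = ridge_solve(X, Y, lambda)),
    "rr-rff" = {
      map <- rff_map(ncol(X), n_features, sigma, seed)
      list(W = ridge_solve(rff_features(map, X), Y, lambda), rff = map)
    },
    "krr" = {
      K <- gauss_kernel(X, X, sigma)
      diag(K) <- diag(K) + lambda
      list(A = solve(K, Y), Xtrain = X, sigma = sigma)
    })
  structure(c(model, list(kind = kind, lambda = lambda, d = ncol(X),
                          dof_order = dof_order)),
            class = "myo_regressor")
}

#' @export
print.myo_regressor <- function(x, ...) {
  cat(sprintf("<myo_regressor> %s (lambda = %g%s), %d inputs -> %d DOFs\n",
              x$kind, x$lambda,
              if (!is.null(x$rff)) sprintf(", sigma = %g, D = %d",
                                           x$rff$sigma, x$rff$n_features)
              else if (x$kind == "krr") sprintf(", sigma = %g", x$sigma) else "",
              x$d, length(x$dof_order)))
  invisible(x)
}

#' Predict DOF activations
#'
#' Raw (unclipped) predictions; clipping to `[0, 1]` is a display concern for
#' the online layer, never applied when computing evaluation errors.
#'
#' @param object a `myo_regressor`.
#' @param newdata numeric matrix (samples x d) or a single d-vector.
#' @param clip clamp predictions into `[0, 1]` (default `FALSE`).
#' @param ... unused.
#' @return Numeric matrix (samples x K).
#' @export
predict.myo_regressor <- function(object, newdata, clip = FALSE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) stop("input dimensionality mismatch", call. = FALSE)
  Yhat <- switch(object$kind,
    "rr" = newdata %*% object$W,
    "rr-rff" = rff_features(object$rff, newdata) %*% object$W,
    "krr" = gauss_kernel(newdata, object$Xtrain, object$sigma) %*% object$A)
  colnames(Yhat) <- object$dof_order
  if (clip) Yhat <- pmin(pmax(Yhat, 0), 1)
  Yhat
}

#' Normalised root-mean-squared error
#'
#' `sqrt(mean((yhat - y)^2)) / (y_max - y_min)`. Multi-output errors are
#' pooled: every (sample, DOF) squared error enters one common mean, so a
#' single scalar summarises all DOFs.
#'
#' @param predicted,target numeric matrices (or vectors) of equal shape.
#' @param y_max,y_min normalisation range of the target (defaults 1 and 0,
#'   the stimulus range).
#' @return Scalar nRMSE, nonnegative.
#' @export
nrmse <- function(predicted, target, y_max = 1, y_min = 0) {
  predicted <- as.matrix(predicted); target <- as.matrix(target)
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
  if (!all(dim(predicted) == dim(target)))
    stop("predicted and target shapes differ", call. = FALSE)
  if (y_max <= y_min) stop("y_max must exceed y_min", call. = FALSE)
  sqrt(mean((predicted - target)^2)) / (y_max - y_min)
}

#' Bandwidth grid for the kernel standard deviation
#'
#' The variable-step search grid for sigma: step 0.05 on `[0.05, 1]`,
#' 0.1 on `(1, 3]` and 0.2 on `(3, 6]` -- finer where the kernel is more
#' sensitive to the bandwidth. 55 strictly increasing values in total, with
#' the range boundaries 1.0 and 3.0 appearing once each.
#'
#' @return Numeric vector of length 55.
#' @export
sigma_grid <- function() {
  round(c(seq(0.05, 1, by = 0.05),
          seq(1.1, 3, by = 0.1),
          seq(3.2, 6, by = 0.2)), 2)
}

split_train_test_clusters <- function(clusters, test_rep, dof_order) {
  reps <- vapply(clusters, `[[`, integer(1), "repetition")
  list(train = clusters[reps != test_rep], test = clusters[reps == test_rep])
}

labelled_parts <- function(clusters, combos, dof_order) {
  pooled <- pool_clusters_by_key(clusters, dof_order)
  singles <- pooled[names(pooled) %in% dof_order]
  combo_keys <- vapply(combos, function(m) cluster_key(m, dof_order), "")
  multis <- pooled[names(pooled) %in% combo_keys]
  list(rest = pooled[["rest"]], singles = singles, multis = multis)
}

#' Repetition-wise cross-validation of a training flavor
#'
#' Evaluates a training-set flavor the way time-correlated physiological data
#' demand: whole repetitions are held out, never individual samples, because
#' low-pass filtering makes neighbouring samples strongly dependent. For each
#' fold, the held-out repetition supplies the test data -- always the full
#' measured single- *and* multi-DOF material with multi-hot targets -- while
#' the remaining repetitions are assembled into the requested training flavor
#' (`"SF"`, `"MF"`, `"LET1"`, `"LETm"`). For LET flavors, combination weights
#' are taken from `alpha` when given (a population/"general" table) or fitted
#' on the training repetitions of the fold otherwise ("individual" weights,
#' never contaminated by the test repetition).
#'
#' @param clusters list of [activation_cluster()]s for one subject, spanning
#'   at least two repetition ids.
#' @param combos list of character vectors naming the multi-DOF combinations
#'   in play.
#' @param flavor training-set flavor, see [build_training_set()].
#' @param dof_order DOF ordering defining the target layout.
#' @param alpha optional per-subject weight set (list with `single`, `multi`,
#'   `grouped`), e.g. from [alpha_for()] on a general-mode table.
#' @param kind,lambda,sigma,n_features,seed regressor configuration, see
#'   [fit_regressor()].
#' @param use_grouped for `"LET1"`, use cardinality-grouped weights
#'   (default `TRUE`).
#' @return An object of class `cv_result`: `per_fold` named nRMSE vector,
#'   `mean`, `sd`, `folds`, `flavor`, `kind`.
#' @export
repetition_cv <- function(clusters, combos, flavor, dof_order,
                          alpha = NULL, kind = "rr-rff", lambda = 1,
                          sigma = 1, n_features = 500, seed = 1,
                          use_grouped = TRUE) {
  reps <- sort(unique(vapply(clusters, `[[`, integer(1), "repetition")))
  if (length(reps) < 2)
    stop("repetition-wise CV needs at least two repetitions", call. = FALSE)
  per_fold <- stats::setNames(numeric(length(reps)), paste0("rep", reps))
  for (i in seq_along(reps)) {
    parts <- split_train_test_clusters(clusters, reps[i], dof_order)
    tr <- labelled_parts(parts$train, combos, dof_order)
    te <- labelled_parts(parts$test, combos, dof_order)
    for (need in c(dof_order, vapply(combos, function(m) cluster_key(m, dof_order), ""))) {
      if (need %in% dof_order && is.null(tr$singles[[need]]))
        stop(sprintf("repetition fold %d is missing activation %s", reps[i], need),
             call. = FALSE)
    }
    a <- alpha
    if (is.null(a) && flavor %in% c("LET1", "LETm")) {
      cents <- lapply(tr$singles, cluster_centroid)
      single <- stats::setNames(rep(NA_real_, length(combos)),
                                vapply(combos, function(m) cluster_key(m, dof_order), ""))
      multi <- stats::setNames(vector("list", length(combos)), names(single))
      for (j in seq_along(combos)) {
        key <- names(single)[j]
        if (is.null(tr$multis[[key]]))
          stop("cannot fit weights: no measured multi-DOF cluster for ", key,
               call. = FALSE)
        mc <- cluster_centroid(tr$multis[[key]])
        sc <- cents[combos[[j]]]
        single[key] <- fit_alpha_single(sc, mc)
        multi[[key]] <- fit_alpha_multi(do.call(rbind, sc), mc)
      }
      g <- group_alphas(single)
      a <- list(single = single, multi = multi,
                grouped = stats::setNames(g$mean, g$cardinality))
    }
    training <- build_training_set(tr$rest, tr$singles, combos, flavor,
                                   alpha = a, multis = tr$multis,
                                   dof_order = dof_order,
                                   use_grouped = use_grouped)
    test_set <- build_training_set(te$rest, te$singles, combos, "MF",
                                   multis = te$multis, dof_order = dof_order)
    model <- fit_regressor(training, kind = kind, lambda = lambda,
                           sigma = sigma, n_features = n_features, seed = seed)
    xy <- as_xy(test_set)
    per_fold[i] <- nrmse(predict(model, xy$X), xy$Y)
  }
  structure(list(per_fold = per_fold, mean = mean(per_fold),
                 sd = stats::sd(per_fold), folds = reps,
                 flavor = flavor, kind = kind),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s: mean nRMSE %.4f (sd %.4f) over %d folds\n",
              x$flavor, x$kind, x$mean, x$sd, length(x$per_fold)))
  invisible(x)
}

#' Grid search over the kernel bandwidth
#'
#' Evaluates the repetition-wise CV error for every bandwidth on the grid and
#' returns the minimiser, breaking ties towards the smallest sigma. Because
#' the CV error curve typically has a flat plateau around its minimum, the
#' search also reports every sigma whose mean error is within 0.05 of the
#' minimum. The random-feature seed is held fixed across the whole grid, so
#' the error curve is not jittered by resampled frequencies.
#'
#' @inheritParams repetition_cv
#' @param grid bandwidth candidates, default [sigma_grid()].
#' @return List with `sigma_opt`, `plateau` (vector of sigmas within
#'   `min + 0.05`) and `table` (data.frame of sigma and mean nRMSE).
#' @export
grid_search_sigma <- function(clusters, combos, flavor, dof_order,
                              alpha = NULL, kind = "rr-rff", lambda = 1,
                              n_features = 500, seed = 1,
                              grid = sigma_grid(), use_grouped = TRUE) {
  means <- vapply(grid, function(s) {
    repetition_cv(clusters, combos, flavor, dof_order, alpha = alpha,
                  kind = kind, lambda = lambda, sigma = s,
                  n_features = n_features, seed = seed,
                  use_grouped = use_grouped)$mean
  }, numeric(1))
  best <- which.min(means)                    # first minimum = smallest sigma
  list(sigma_opt = grid[best],
       plateau = grid[means <= means[best] + 0.05],
       table = data.frame(sigma = grid, nrmse = means))
}
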