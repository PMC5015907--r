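#' Linear combination of single-DOF clusters with one shared weight
#'
#' The single-alpha model of a multi-DOF activation: the synthetic cluster is
#' `alpha * (X_1 + X_2 + ... + X_k)`, the row-wise sum of the single-DOF
#' clusters scaled by one common weight. Clusters of unequal length are
#' truncated to the shortest (first rows kept), a deterministic,
#' order-preserving alignment.
#'
#' @param clusters list of two or more [activation_cluster()] objects with
#'   equal channel count.
#' @param alpha positive scalar combination weight.
#' @return A synthetic `activation_cluster` labelled with the union of the
#'   input DOF sets.
#' @export
combine_single_alpha <- function(clusters, alpha) {
  if (length(clusters) < 2) stop("need at least two clusters", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive scalar", call. = FALSE)
  combine_clusters(clusters, rep(alpha, length(clusters)))
}

#' Linear combination of single-DOF clusters with one weight per cluster
#'
#' The multi-alpha model: the synthetic cluster is
#' `alpha_1 * X_1 + ... + alpha_k * X_k`, a row-wise weighted sum with one
#' weight per member DOF. With all weights equal it reduces to the
#' single-alpha model.
#'
#' @param clusters list of [activation_cluster()] objects.
#' @param alphas numeric vector, one weight per cluster.
#' @return A synthetic `activation_cluster` labelled with the union of DOFs.
#' @export
combine_multi_alpha <- function(clusters, alphas) {
  if (length(alphas) != length(clusters))
    stop("need exactly one weight per cluster", call. = FALSE)
  combine_clusters(clusters, alphas)
}

combine_clusters <- function(clusters, weights) {
  dims <- vapply(clusters, function(cl) ncol(cl$data), integer(1))
  if (length(unique(dims)) != 1)
    stop("clusters have mismatching channel counts", call. = FALSE)
  nmin <- min(vapply(clusters, function(cl) nrow(cl$data), integer(1)))
  acc <- matrix(0, nmin, dims[1])
  for (i in seq_along(clusters))
    acc <- acc + weights[i] * clusters[[i]]$data[seq_len(nmin), , drop = FALSE]
  dofs <- unique(unlist(lapply(clusters, `[[`, "dofs")))
  levels <- stats::setNames(rep(1, length(dofs)), dofs)
  for (cl in clusters) levels[cl$dofs] <- cl$levels[cl$dofs]
  activation_cluster(acc, dofs = dofs, levels = levels,
                     repetition = clusters[[1]]$repetition,
                     subject = clusters[[1]]$subject)
}

#' Closed-form single-alpha estimate
#'
#' The best single weight in the least-squares sense: the scalar projection of
#' the multi-DOF centroid onto the vector sum of the single-DOF centroids,
#' `alpha = <m, s> / <s, s>` with `s = sum of single centroids`. This
#' minimises the Euclidean distance `|| m - alpha * s ||` and is
#' scale-equivariant: rescaling all centroids by a common factor leaves alpha
#' unchanged.
#'
#' @param single_centroids list of numeric centroid vectors (or a matrix with
#'   one centroid per row).
#' @param multi_centroid numeric centroid vector of the measured multi-DOF
#'   cluster.
#' @return Scalar alpha.
#' @export
fit_alpha_single <- function(single_centroids, multi_centroid) {
  s <- sum_centroids(single_centroids)
  if (length(s) != length(multi_centroid))
    stop("centroid dimensionalities differ", call. = FALSE)
  ss <- sum(s * s)
  if (ss == 0)
    stop("degenerate geometry: single-DOF centroids sum to the zero vector",
         call. = FALSE)
  sum(multi_centroid * s) / ss
}

#' Closed-form multi-alpha estimate
#'
#' One weight per member DOF: the ordinary least-squares coefficients of the
#' multi-DOF centroid regressed on the stacked single-DOF centroids, i.e. the
#' orthogonal projection of the multi centroid onto the hyperplane they span.
#' Requires the signal dimensionality d to be at least the number k of
#' single-DOF activations involved. A (numerically) singular Gram matrix --
#' collinear centroids, plausible with strongly correlated muscles -- falls
#' back to the minimum-norm pseudo-inverse solution with a warning.
#'
#' @inheritParams fit_alpha_single
#' @return Numeric vector of k weights, named after the input centroids when
#'   they carry names.
#' @export
fit_alpha_multi <- function(single_centroids, multi_centroid) {
  B <- stack_centroids(single_centroids)            # k x d
  k <- nrow(B); d <- ncol(B)
  if (k > d)
    stop("more single-DOF activations than signal dimensions (k > d)", call. = FALSE)
  if (d != length(multi_centroid))
    stop("centroid dimensionalities differ", call. = FALSE)
  G <- tcrossprod(B)                                # k x k Gram matrix
  rhs <- B %*% multi_centroid
  a <- if (rcond(G) < 1e-12) {
    warning("collinear single-DOF centroids; using minimum-norm solution",
            call. = FALSE)
    MASS::ginv(G) %*% rhs
  } else {
    solve(G, rhs)
  }
  stats::setNames(drop(a), rownames(B))
}

sum_centroids <- function(x) {
  if (is.matrix(x)) return(colSums(x))
  Reduce(`+`, lapply(x, as.numeric))
}

stack_centroids <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, as.numeric))
}

combo_cardinality <- function(keys) {
  lengths(strsplit(keys, "+", fixed = TRUE))
}

#' Group single-alpha estimates by combination cardinality
#'
#' Per-combination weights of the single-alpha model cluster tightly by the
#' number of DOFs involved, so the model can be simplified from one weight per
#' combination to one weight per cardinality (pairs, triples, quadruples).
#' The spread is reported as the population standard deviation, so a group of
#' one has sd 0.
#'
#' @param per_combo named numeric vector of alpha values; names are combo keys
#'   such as `"ThFl+InFl"` (members joined with `+`). Values from several
#'   subjects may simply be concatenated.
#' @return A data.frame with columns `cardinality`, `mean`, `sd`, `n`.
#' @export
group_alphas <- function(per_combo) {
  per_combo <- per_combo[!is.na(per_combo)]
  if (length(per_combo) == 0) stop("no alpha values to group", call. = FALSE)
  card <- combo_cardinality(names(per_combo))
  res <- lapply(sort(unique(card)), function(k) {
    v <- per_combo[card == k]
    data.frame(cardinality = k, mean = mean(v),
               sd = sqrt(mean((v - mean(v))^2)), n = length(v))
  })
  do.call(rbind, res)
}

pool_clusters_by_key <- function(clusters, dof_order) {
  keys <- vapply(clusters, cluster_key, "", dof_order = dof_order)
  pooled <- lapply(split(clusters, keys), function(grp) {
    activation_cluster(do.call(rbind, lapply(grp, `[[`, "data")),
                       dofs = grp[[1]]$dofs, levels = grp[[1]]$levels,
                       repetition = grp[[1]]$repetition,
                       subject = grp[[1]]$subject)
  })
  pooled
}

fit_subject_alphas <- function(clusters, combos, dof_order,
                               subtract_rest = FALSE) {
  pooled <- pool_clusters_by_key(clusters, dof_order)
  cents <- lapply(pooled, cluster_centroid)
  rest <- cents[["rest"]]
  adjust <- function(v) {
    if (subtract_rest && !is.null(rest)) v - rest else v
  }
  single <- stats::setNames(rep(NA_real_, length(combos)),
                            vapply(combos, paste, "", collapse = "+"))
  multi <- stats::setNames(vector("list", length(combos)), names(single))
  errors <- character()
  for (i in seq_along(combos)) {
    members <- combos[[i]]
    key <- names(single)[i]
    have <- members %in% names(cents)
    if (!all(have) || is.null(cents[[key]])) {
      errors <- c(errors, sprintf("missing cluster(s) for combo %s", key))
      next
    }
    sc <- lapply(members, function(m) adjust(cents[[m]]))
    names(sc) <- members
    mc <- adjust(cents[[key]])
    single[key] <- fit_alpha_single(sc, mc)
    multi[[key]] <- fit_alpha_multi(do.call(rbind, sc), mc)
  }
  list(single = single, multi = multi, errors = errors)
}

#' Estimate combination weights across a cohort
#'
#' Fits the single- and multi-alpha model weights for every requested
#' multi-DOF combination, either per subject on that subject's own data
#' (`mode = "individual"`) or, for each target subject, as the average of the
#' fits of all *other* subjects (`mode = "general"`, the leave-one-subject-out
#' population model that a new user would receive "out of the box").
#' Repetitions are pooled per subject before taking centroids.
#'
#' @param clusters_by_subject named list: one list of
#'   [activation_cluster()]s per subject (all repetitions together).
#' @param combos list of character vectors, each naming the member DOFs of a
#'   multi-DOF combination.
#' @param mode `"individual"` or `"general"`.
#' @param dof_order character vector fixing DOF ordering in combo keys.
#' @param subtract_rest subtract the rest centroid from all centroids before
#'   fitting (off by default).
#' @return An object of class `alpha_table`: a list with `mode`,
#'   `per_subject` (per target subject: `single` named vector, `multi` named
#'   list, `grouped` named vector by cardinality), `pooled` (grouping of all
#'   individual fits, see [group_alphas()]) and `errors`.
#' @export
estimate_alphas <- function(clusters_by_subject, combos,
                            mode = c("individual", "general"),
                            dof_order = NULL, subtract_rest = FALSE) {
  mode <- match.arg(mode)
  subjects <- names(clusters_by_subject)
  if (is.null(subjects)) stop("clusters_by_subject must be a named list", call. = FALSE)
  fits <- lapply(clusters_by_subject, fit_subject_alphas, combos = combos,
                 dof_order = dof_order, subtract_rest = subtract_rest)
  grouped_of <- function(single) {
    if (all(is.na(single))) return(stats::setNames(numeric(0), character(0)))
    g <- group_alphas(single)
    stats::setNames(g$mean, g$cardinality)
  }
  per_subject <- stats::setNames(vector("list", length(subjects)), subjects)
  for (s in subjects) {
    if (mode == "individual") {
      f <- fits[[s]]
      per_subject[[s]] <- list(single = f$single, multi = f$multi,
                               grouped = grouped_of(f$single))
    } else {
      donors <- setdiff(subjects, s)
      if (length(donors) == 0)
        stop("general mode needs at least two subjects", call. = FALSE)
      single <- rowMeans(do.call(cbind, lapply(fits[donors], `[[`, "single")),
                         na.rm = TRUE)
      keys <- names(fits[[donors[1]]]$single)
      multi <- stats::setNames(lapply(keys, function(k) {
        mats <- do.call(rbind, lapply(fits[donors], function(f) f$multi[[k]]))
        if (is.null(mats)) NULL else colMeans(mats)
      }), keys)
      per_subject[[s]] <- list(single = single, multi = multi,
                               grouped = grouped_of(single))
    }
  }
  all_single <- unlist(lapply(fits, `[[`, "single"), use.names = FALSE)
  names(all_single) <- rep(names(fits[[1]]$single), length(fits))
  structure(list(mode = mode,
                 per_subject = per_subject,
                 pooled = group_alphas(all_single),
                 errors = unlist(lapply(fits, `[[`, "errors"))),
            class = "alpha_table")
}

#' @export
print.alpha_table <- function(x, ...) {
  cat(sprintf("<alpha_table> mode %s, %d subjects\n", x$mode, length(x$per_subject)))
  print(x$pooled)
  if (length(x$errors)) cat("errors:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

#' Extract one subject's combination weights from an alpha table
#'
#' @param table an `alpha_table` from [estimate_alphas()].
#' @param subject subject name; defaults to the first.
#' @return List with `single`, `multi` and `grouped` components for the
#'   requested subject.
#' @export
alpha_for <- function(table, subject = NULL) {
  stopifnot(inherits(table, "alpha_table"))
  if (is.null(subject)) subject <- names(table$per_subject)[1]
  a <- table$per_subject[[subject]]
  if (is.null(a)) stop("unknown subject: ", subject, call. = FALSE)
  a
}

#' Serialize an alpha table to JSON
#'
#' @param table an `alpha_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alpha_table <- function(table, path) {
  obj <- list(mode = table$mode,
              # named atomic vectors must become lists to serialize as
              # JSON objects (arrays would drop the combo keys)
              per_subject = lapply(table$per_subject, function(a) list(
                single = as.list(a$single),
                multi = lapply(a$multi, function(v)
                  if (is.null(v)) NULL else unname(v)),
                grouped = as.list(a$grouped))),
              pooled = table$pooled,
              errors = table$errors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an alpha table from JSON
#'
#' @param path file written by [write_alpha_table()].
#' @return An `alpha_table`.
#' @export
read_alpha_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  per_subject <- lapply(obj$per_subject, function(a) {
    list(single = unlist(a$single),
         multi = lapply(a$multi, unlist),
         grouped = unlist(a$grouped))
  })
  structure(list(mode = obj$mode, per_subject = per_subject,
                 pooled = as.data.frame(obj$pooled),
                 errors = unlist(obj$errors)),
            class = "alpha_table")
}

#' Assemble a training set for intent detection
#'
#' Builds the (cluster, target) pairs an on-off regressor is trained on. All
#' flavors share the base single-finger entries: the rest cluster with the
#' all-zero target and each single-DOF cluster with its unit target vector.
#' `"MF"` additionally uses the *measured* multi-DOF clusters; `"LET1"` and
#' `"LETm"` instead *synthesize* those clusters from the single-DOF ones via
#' [combine_single_alpha()] / [combine_multi_alpha()] -- the LET augmentation,
#' which spares the user from ever producing multi-DOF activations during
#' training. Targets are multi-hot: 1 on every member DOF of a combination.
#'
#' @param rest rest [activation_cluster()].
#' @param singles named list of single-DOF clusters, one per DOF.
#' @param combos list of character vectors naming multi-DOF combinations
#'   (may be empty for `"SF"`).
#' @param flavor `"SF"`, `"MF"`, `"LET1"` or `"LETm"`.
#' @param alpha per-subject weight set (list with `single`, `multi`,
#'   `grouped`), e.g. from [alpha_for()]; required for LET flavors.
#' @param multis named list of measured multi-DOF clusters keyed by combo key;
#'   required for `"MF"`.
#' @param dof_order DOF ordering defining the target-vector layout; defaults
#'   to `names(singles)`.
#' @param use_grouped for `"LET1"`: use the cardinality-grouped weight
#'   (default, mirroring the population model used online) rather than the
#'   per-combination weight.
#' @return An object of class `training_set` with fields `entries` (list of
#'   `list(cluster, target)`), `flavor` and `dof_order`.
#' @export
build_training_set <- function(rest, singles, combos = list(),
                               flavor = c("SF", "MF", "LET1", "LETm"),
                               alpha = NULL, multis = NULL,
                               dof_order = names(singles),
                               use_grouped = TRUE) {
  flavor <- match.arg(flavor)
  K <- length(dof_order)
  target <- function(dofs) {
    y <- stats::setNames(rep(0, K), dof_order)
    y[dofs] <- 1
    y
  }
  entries <- list(list(cluster = rest, target = target(character())))
  for (dof in dof_order) {
    if (is.null(singles[[dof]]))
      stop("missing single-DOF cluster for ", dof, call. = FALSE)
    entries[[length(entries) + 1L]] <-
      list(cluster = singles[[dof]], target = target(dof))
  }
  if (flavor != "SF") {
    for (members in combos) {
      key <- cluster_key(members, dof_order)
      cl <- switch(flavor,
        MF = {
          if (is.null(multis[[key]]))
            stop("missing measured multi-DOF cluster for combo ", key, call. = FALSE)
          multis[[key]]
        },
        LET1 = {
          a <- if (use_grouped) alpha$grouped[[as.character(length(members))]]
               else alpha$single[[key]]
          if (is.null(a) || is.na(a))
            stop("missing single-alpha weight for combo ", key, call. = FALSE)
          combine_single_alpha(singles[members], a)
        },
        LETm = {
          a <- alpha$multi[[key]]
          if (is.null(a))
            stop("missing multi-alpha weights for combo ", key, call. = FALSE)
          combine_multi_alpha(singles[members], a)
        })
      entries[[length(entries) + 1L]] <- list(cluster = cl, target = target(members))
    }
  }
  structure(list(entries = entries, flavor = flavor, dof_order = dof_order),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> flavor %s: %d entries, DOFs %s\n",
              x$flavor, length(x$entries), paste(x$dof_order, collapse = ", ")))
  invisible(x)
}

#' Flatten a training set into input and target matrices
#'
#' @param training a `training_set`.
#' @return List with `X` (samples x channels) and `Y` (samples x DOFs).
#' @export
as_xy <- function(training) {
  stopifnot(inherits(training, "training_set"))
  X <- do.call(rbind, lapply(training$entries, function(e) e$cluster$data))
  Y <- do.call(rbind, lapply(training$entries, function(e) {
    matrix(e$target, nrow(e$cluster$data), length(e$target), byrow = TRUE)
  }))
  colnames(Y) <- training$dof_order
  list(X = X, Y = Y)
}

#' Export a training set as CSV
#'
#' One row per sample: channel columns followed by target columns `y_<dof>`.
#'
#' @param training a `training_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_training_set_csv <- function(training, path) {
  xy <- as_xy(training)
  df <- as.data.frame(xy$X)
  names(df) <- sprintf("ch%02d", seq_len(ncol(xy$X)))
  y <- as.data.frame(xy$Y)
  names(y) <- paste0("y_", training$dof_order)
  utils::write.csv(cbind(df, y), path, row.names = FALSE)
  invisible(path)
}
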