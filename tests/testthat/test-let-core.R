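test_that("cluster combination follows the linear model on rows and centroids", {
  a <- activation_cluster(matrix(c(1, 0, 0, 0), 1, 4), dofs = "A")
  b <- activation_cluster(matrix(c(0, 1, 0, 0), 1, 4), dofs = "B")
  comb <- combine_single_alpha(list(a, b), 0.5)
  expect_equal(comb$data, matrix(c(0.5, 0.5, 0, 0), 1, 4))
  expect_setequal(comb$dofs, c("A", "B"))
  # alpha = 1 with an all-zero partner copies the first cluster
  z <- activation_cluster(matrix(0, 3, 4), dofs = "B")
  big <- activation_cluster(matrix(runif(20), 5, 4), dofs = "A")
  expect_equal(combine_single_alpha(list(big, z), 1)$data, big$data[1:3, ])
  # centroid linearity oracle at alpha = 0.53
  set.seed(8)
  c1 <- make_cluster(runif(6), n = 30, spread = 0.1, dofs = "A")
  c2 <- make_cluster(runif(6), n = 40, spread = 0.1, dofs = "B")
  out <- combine_single_alpha(list(c1, c2), 0.53)
  trunc_cent <- colMeans(c1$data[1:30, ]) + colMeans(c2$data[1:30, ])
  expect_equal(cluster_centroid(out), 0.53 * trunc_cent)
  expect_error(combine_single_alpha(list(c1), 0.5), "two clusters")
  expect_error(combine_single_alpha(list(c1, c2), -1), "positive")
})

test_that("multi-weight combination generalises the single-weight one", {
  set.seed(9)
  cls <- lapply(1:3, function(i)
    make_cluster(runif(5), n = 25, spread = 0.05, dofs = LETTERS[i]))
  # weights (1, 0) reproduce the first cluster
  two <- combine_multi_alpha(cls[1:2], c(1, 0))
  expect_equal(two$data, cls[[1]]$data)
  # equal weights coincide with the single-weight model
  expect_equal(combine_multi_alpha(cls[1:2], c(0.5, 0.5))$data,
               combine_single_alpha(cls[1:2], 0.5)$data)
  # weighted centroid oracle for three clusters
  w <- c(0.3, 0.3, 0.4)
  out <- combine_multi_alpha(cls, w)
  expected <- Reduce(`+`, Map(function(cl, wi) wi * cluster_centroid(cl), cls, w))
  expect_equal(cluster_centroid(out), expected)
  expect_error(combine_multi_alpha(cls, c(1, 2)), "one weight per cluster")
})

test_that("single-weight estimate is the projection and matches a grid-search oracle", {
  expect_equal(fit_alpha_single(list(c(1, 0), c(0, 1)), c(0.5, 0.5)), 0.5)
  s <- c(0.3, 1.2, 0.1)
  expect_equal(fit_alpha_single(list(s / 2, s / 2), s), 1)
  # fine-grid 1-D minimiser of the Euclidean objective
  set.seed(10)
  singles <- lapply(1:2, function(i) abs(rnorm(10)))
  multi <- abs(rnorm(10))
  a_hat <- fit_alpha_single(singles, multi)
  grid <- seq(0.001, 2, by = 0.001)
  ssum <- singles[[1]] + singles[[2]]
  obj <- vapply(grid, function(a) sum((multi - a * ssum)^2), numeric(1))
  expect_lt(abs(a_hat - grid[which.min(obj)]), 0.001)
  # scale equivariance
  expect_equal(fit_alpha_single(lapply(singles, `*`, 7), multi * 7), a_hat)
  expect_error(fit_alpha_single(list(c(0, 0), c(0, 0)), c(1, 1)), "degenerate")
})

test_that("multi-weight estimate solves least squares and nests the single-weight model", {
  expect_equal(unname(fit_alpha_multi(list(c(1, 0), c(0, 1)), c(0.3, 0.7))),
               c(0.3, 0.7))
  # k = 1 reduces to the single-weight projection
  v <- c(1, 2, 0.5)
  m <- c(0.9, 1.7, 0.8)
  expect_equal(unname(fit_alpha_multi(list(v), m)),
               fit_alpha_single(list(v), m))
  # independent normal-equations oracle + nesting on random full-rank data
  set.seed(11)
  for (k in 2:4) {
    B <- abs(matrix(rnorm(k * 10), k, 10))
    multi <- abs(rnorm(10))
    a <- fit_alpha_multi(asplit(B, 1), multi)
    oracle <- solve(B %*% t(B)) %*% (B %*% multi)
    expect_equal(unname(a), drop(oracle), tolerance = 1e-8)
    res_multi <- sum((multi - drop(crossprod(B, a)))^2)
    a1 <- fit_alpha_single(asplit(B, 1), multi)
    res_single <- sum((multi - a1 * colSums(B))^2)
    expect_lte(res_multi, res_single + 1e-12)
  }
  expect_error(fit_alpha_multi(asplit(matrix(runif(20), 5, 4), 1), runif(4)),
               "k > d")
  # collinear centroids fall back to the minimum-norm solution
  expect_warning(
    a <- fit_alpha_multi(list(c(1, 1, 0), c(1, 1, 0)), c(2, 2, 0)),
    "collinear")
  expect_equal(sum(a), 2, tolerance = 1e-8)
})

test_that("grouping averages by cardinality with population-sd convention", {
  g <- group_alphas(c("A+B" = 0.4, "C+D" = 0.6))
  expect_equal(g$mean, 0.5)
  expect_equal(g$sd, 0.1)
  g1 <- group_alphas(c("A+B+C" = 0.37))
  expect_equal(g1$sd, 0)
  expect_equal(g1$cardinality, 3)
  # Monte-Carlo: many pair weights around 0.53 group close to the truth
  set.seed(12)
  vals <- setNames(rnorm(60, 0.53, 0.02),
                   rep(sapply(pair_combos(), paste, collapse = "+"), 10))
  expect_lt(abs(group_alphas(vals)$mean - 0.53), 0.03)
})

test_that("cohort weight estimation: individual fits match direct calls, general is leave-one-out", {
  cls <- small_cluster_set(n_reps = 2, seed = 21)
  combos <- list(c("A", "B"))
  one <- estimate_alphas(list(S1 = cls), combos, mode = "individual",
                         dof_order = c("A", "B"))
  # direct fit on pooled centroids
  pooled <- lapply(split(cls, vapply(cls, cluster_key, "")), function(g)
    do.call(rbind, lapply(g, function(x) x$data)))
  direct <- fit_alpha_single(list(colMeans(pooled[["A"]]), colMeans(pooled[["B"]])),
                             colMeans(pooled[["A+B"]]))
  expect_equal(unname(one$per_subject$S1$single["A+B"]), direct)
  # two identical subjects: each general value equals the other's individual fit
  two <- estimate_alphas(list(S1 = cls, S2 = cls), combos, mode = "general",
                         dof_order = c("A", "B"))
  expect_equal(two$per_subject$S1$single, one$per_subject$S1$single)
  expect_error(estimate_alphas(list(S1 = cls), combos, mode = "general"),
               "at least two subjects")
  # a missing multi-DOF cluster is reported per combo, others proceed
  no_multi <- Filter(function(cl) length(cl$dofs) < 2, cls)
  tab <- estimate_alphas(list(S1 = cls, S2 = no_multi),
                         combos, mode = "individual", dof_order = c("A", "B"))
  expect_match(tab$errors, "A\\+B")
  expect_false(is.na(tab$per_subject$S1$single["A+B"]))
})

test_that("general and individual weights agree on a homogeneous cohort", {
  coh <- make_cohort(6, seed = 77, routine = routine_calibration(repetitions = 2),
                     alpha_spread = 0)
  cl <- cohort_clusters(coh)
  combos <- calib_combos()
  ind <- estimate_alphas(cl, combos, mode = "individual", dof_order = test_dofs)
  gen <- estimate_alphas(cl, combos, mode = "general", dof_order = test_dofs)
  for (s in names(cl))
    expect_equal(gen$per_subject[[s]]$single, ind$per_subject[[s]]$single,
                 tolerance = 0.05)
})

test_that("training sets carry on-off targets in every flavor", {
  cls <- small_cluster_set(n_reps = 1, seed = 31)
  rest <- cls[[1]]; singles <- list(A = cls[[2]], B = cls[[3]])
  multis <- list("A+B" = cls[[4]])
  alpha <- list(single = c("A+B" = 0.5), multi = list("A+B" = c(0.5, 0.5)),
                grouped = c("2" = 0.5))
  sf <- build_training_set(rest, singles, flavor = "SF")
  expect_length(sf$entries, 3)
  expect_equal(lapply(sf$entries, function(e) unname(e$target)),
               list(c(0, 0), c(1, 0), c(0, 1)))
  let1 <- build_training_set(rest, singles, list(c("A", "B")), "LET1",
                             alpha = alpha)
  expect_length(let1$entries, 4)
  expect_equal(unname(let1$entries[[4]]$target), c(1, 1))
  # synthesized cluster centroid = grouped alpha times sum of single centroids
  expect_equal(cluster_centroid(let1$entries[[4]]$cluster),
               0.5 * (cluster_centroid(singles$A) + cluster_centroid(singles$B)))
  mf <- build_training_set(rest, singles, list(c("A", "B")), "MF",
                           multis = multis)
  expect_identical(mf$entries[[4]]$cluster, multis[["A+B"]])
  letm <- build_training_set(rest, singles, list(c("A", "B")), "LETm",
                             alpha = alpha)
  expect_equal(letm$entries[[4]]$cluster$data, let1$entries[[4]]$cluster$data)
  # every target is binary, rest all-zero, SF at most one active entry
  for (ts in list(sf, mf, let1, letm)) {
    for (e in ts$entries) expect_true(all(e$target %in% c(0, 1)))
  }
  expect_error(build_training_set(rest, singles, list(c("A", "B")), "MF"),
               "A\\+B")
  expect_error(build_training_set(rest, singles, list(c("A", "B")), "LET1",
                                  alpha = list(single = c(), grouped = c())),
               "A\\+B")
})

test_that("the exp-2 style LET set has seven entries with grouped-weight centroids", {
  set.seed(33)
  d <- 8
  dirs <- lapply(1:3, function(i) abs(rnorm(d)))
  rest <- make_cluster(rep(0.05, d), n = 15)
  singles <- setNames(lapply(dirs, function(v)
    make_cluster(v, n = 15, spread = 0.01)), c("ThFl", "InFl", "LiFl"))
  for (nm in names(singles)) singles[[nm]]$dofs <- nm
  combos <- pair_combos(c("ThFl", "InFl", "LiFl"))
  alpha <- list(grouped = c("2" = 0.53))
  ts <- build_training_set(rest, singles, combos, "LET1", alpha = alpha)
  expect_length(ts$entries, 7)
  for (i in 5:7) {
    members <- names(which(ts$entries[[i]]$target == 1))
    expected <- 0.53 * Reduce(`+`, lapply(singles[members], cluster_centroid))
    expect_equal(cluster_centroid(ts$entries[[i]]$cluster), expected)
  }
})

test_that("alpha tables and training sets serialize and round-trip", {
  cls <- small_cluster_set(n_reps = 2, seed = 41)
  tab <- estimate_alphas(list(S1 = cls, S2 = cls), list(c("A", "B")),
                         mode = "individual", dof_order = c("A", "B"))
  path <- withr::local_tempfile(fileext = ".json")
  write_alpha_table(tab, path)
  back <- read_alpha_table(path)
  expect_equal(back$per_subject$S1$single, tab$per_subject$S1$single)
  expect_equal(back$per_subject$S2$multi[["A+B"]],
               unname(tab$per_subject$S2$multi[["A+B"]]), ignore_attr = TRUE)
  expect_equal(back$pooled$mean, tab$pooled$mean)
  ts <- build_training_set(cls[[1]], list(A = cls[[2]], B = cls[[3]]),
                           flavor = "SF")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_training_set_csv(ts, csv)
  df <- read.csv(csv)
  xy <- as_xy(ts)
  expect_equal(nrow(df), nrow(xy$X))
  expect_equal(df$y_A, unname(xy$Y[, "A"]))
})
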