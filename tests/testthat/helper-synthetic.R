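# Shared fixture builders. Everything is generated in code at test time.

test_dofs <- c("ThOp", "ThFl", "InFl", "LiFl")

pair_combos <- function(dofs = test_dofs) {
  utils::combn(dofs, 2, simplify = FALSE)
}

calib_combos <- function(dofs = test_dofs) {
  c(pair_combos(dofs),
    list(dofs[c(1, 2, 3)], dofs[c(2, 3, 4)], dofs))
}

# A deterministic cluster with given centroid and tiny spread
make_cluster <- function(centroid, n = 20, dofs = character(), spread = 0,
                         repetition = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(centroid)
  data <- matrix(rep(centroid, each = n), n, d)
  if (spread > 0) data <- data + matrix(rnorm(n * d, 0, spread), n, d)
  activation_cluster(data, dofs = dofs, repetition = repetition)
}

# A small two-DOF synthetic subject cluster set spanning several repetitions,
# built directly (no recording simulation) for fast regression tests.
small_cluster_set <- function(n_reps = 3, n = 60, noise = 0.03, seed = 1,
                              alpha = 0.5) {
  set.seed(seed)
  d <- 6
  dir_a <- c(1, 0.2, 0, 0, 0.1, 0)
  dir_b <- c(0, 0.1, 1, 0.3, 0, 0)
  rest <- rep(0.05, d)
  out <- list()
  for (r in seq_len(n_reps)) {
    add <- function(centroid, dofs) {
      cl <- make_cluster(centroid, n = n, dofs = dofs, spread = noise,
                         repetition = r)
      out[[length(out) + 1L]] <<- cl
    }
    add(rest, character())
    add(rest + dir_a, "A")
    add(rest + dir_b, "B")
    add(rest + alpha * (dir_a + dir_b), c("A", "B"))
  }
  out
}
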