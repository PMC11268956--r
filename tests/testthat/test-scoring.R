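# Mixture-density head: constraints, closed forms, oracle equivalence and
# rigid invariance of the confidence score.

random_mdn_output <- function(n_pairs = 20L, n_comp = 4L, seed = 1L) {
  set.seed(seed)
  out <- list(mu = matrix(runif(n_pairs * n_comp, 0.5, 10), n_pairs),
              sigma = matrix(runif(n_pairs * n_comp, 0.2, 3), n_pairs),
              pi = NULL)
  raw <- matrix(rnorm(n_pairs * n_comp), n_pairs)
  out$pi <- exp(raw) / rowSums(exp(raw))
  class(out) <- "mdn_output"
  out
}

test_that("head outputs satisfy the mixture constraints", {
  task <- small_task(seed = 1L)
  pt <- prepare_task_t(task)
  model <- init_model(tiny_config(), seed = 0L)
  enc <- encode_task(model, pt)
  out <- mdn_head(enc$loop_h, enc$merged, model)
  pi_v <- loopcraft:::ad_val(out$pi)
  expect_equal(rowSums(pi_v), rep(1, nrow(pi_v)), tolerance = 1e-6)
  expect_gt(min(loopcraft:::ad_val(out$sigma)), 0.1)
  expect_gt(min(loopcraft:::ad_val(out$mu)), 0)
  expect_equal(nrow(pi_v), sum(pt$agraph$loop_atom) *
                 length(pt$rgraph$keys))
})

test_that("one-component mixture at its mean gives the Gaussian closed
           form", {
  for (s in c(0.5, 1, 2.5)) {
    out <- list(mu = matrix(c(3, 1), 1L), sigma = matrix(c(s, 1), 1L),
                pi = matrix(c(1, 0), 1L))
    class(out) <- "mdn_output"
    expect_equal(mdn_nll(out, 3), log(s * sqrt(2 * pi)), tolerance = 1e-9)
    # a zero-weight component is inert
    out2 <- list(mu = matrix(c(3, 99), 1L), sigma = matrix(c(s, 7), 1L),
                 pi = matrix(c(1, 0), 1L))
    class(out2) <- "mdn_output"
    expect_equal(mdn_nll(out2, 3), mdn_nll(out, 3), tolerance = 1e-12)
  }
})

test_that("NLL decreases as a component mean approaches the observation", {
  d <- 5
  mus <- seq(1, 5, by = 0.5)
  nlls <- vapply(mus, function(m) {
    out <- list(mu = matrix(m, 1L), sigma = matrix(1, 1L),
                pi = matrix(1, 1L))
    class(out) <- "mdn_output"
    mdn_nll(out, d)
  }, 0)
  expect_true(all(diff(nlls) < 0))
})

test_that("pair minimum distances equal the triple-loop oracle", {
  set.seed(3)
  for (rep in 1:20) {
    L <- sample(2:6, 1L)
    P <- sample(2:5, 1L)
    loop <- matrix(rnorm(L * 3, sd = 5), L)
    res_list <- lapply(seq_len(P), function(i)
      matrix(rnorm(sample(3:8, 1L) * 3, sd = 5), ncol = 3L))
    got <- pair_min_distances(loop, res_list)
    k <- 0L
    for (p in seq_len(P)) for (l in seq_len(L)) {
      k <- k + 1L
      best <- Inf
      for (a in seq_len(nrow(res_list[[p]]))) {
        best <- min(best, sqrt(sum((loop[l, ] - res_list[[p]][a, ])^2)))
      }
      expect_equal(got[k], best, tolerance = 1e-6)
    }
  }
  # single-atom residue: plain Euclidean distance
  expect_equal(pair_min_distances(matrix(c(0, 0, 0), 1L),
                                  list(matrix(c(3, 4, 0), 1L))), 5)
  # invariance under a joint rigid transform
  R <- loopcraft:::random_rotation(); t <- c(1, 2, 3)
  loop <- matrix(rnorm(9), 3L)
  res_list <- list(matrix(rnorm(12), 4L))
  d0 <- pair_min_distances(loop, res_list)
  d1 <- pair_min_distances(sweep(loop %*% t(R), 2L, t, "+"),
                           lapply(res_list, function(X)
                             sweep(X %*% t(R), 2L, t, "+")))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("NLL matches a direct per-pair scalar-loop implementation", {
  out <- random_mdn_output(n_pairs = 25L, seed = 7L)
  set.seed(8)
  d <- runif(25L, 0.5, 15)
  direct <- -mean(vapply(which(d <= 12), function(i) {
    log(sum(out$pi[i, ] * stats::dnorm(d[i], out$mu[i, ], out$sigma[i, ])))
  }, 0))
  expect_equal(mdn_nll(out, d), direct, tolerance = 1e-6)
  # the confidence score is the full-pair sum with opposite sign
  direct_sum <- sum(vapply(seq_along(d), function(i) {
    log(sum(out$pi[i, ] * stats::dnorm(d[i], out$mu[i, ], out$sigma[i, ])))
  }, 0))
  expect_equal(mdn_score(out, d), direct_sum, tolerance = 1e-6)
})

test_that("score is maximized at the mixture's highest-density distance", {
  out <- list(mu = matrix(c(2, 6), 1L), sigma = matrix(c(0.5, 2), 1L),
              pi = matrix(c(0.8, 0.2), 1L))
  class(out) <- "mdn_output"
  grid <- seq(0.1, 10, by = 0.01)
  scores <- vapply(grid, function(d) mdn_score(out, d), 0)
  dens <- function(d) sum(out$pi * stats::dnorm(d, out$mu, out$sigma))
  expect_equal(grid[which.max(scores)],
               grid[which.max(vapply(grid, dens, 0))])
})

test_that("score and its conformation ranking are rigid-invariant", {
  task <- small_task(seed = 2L)
  pt <- prepare_task_t(task)
  model <- init_model(tiny_config(), seed = 1L)
  enc <- encode_task(model, pt)
  out <- mdn_head(enc$loop_h, enc$merged, model)
  confs <- lapply(1:3, function(s)
    init_loop_reconstruction(task$structure, task$spec, seed = s)$coords)
  scores <- vapply(confs, function(X)
    mdn_score(out, pair_min_distances(X, pt$res_coord_list)), 0)
  set.seed(21)
  R <- loopcraft:::random_rotation(); t <- c(2, -1, 4)
  st_r <- transform_structure(task$structure, R, t)
  pt_r <- prepare_task_t(list(structure = st_r, spec = task$spec,
                              truth = sweep(task$truth %*% t(R), 2, t, "+")))
  enc_r <- encode_task(model, pt_r)
  out_r <- mdn_head(enc_r$loop_h, enc_r$merged, model)
  scores_r <- vapply(confs, function(X)
    mdn_score(out_r, pair_min_distances(
      sweep(X %*% t(R), 2L, t, "+"), pt_r$res_coord_list)), 0)
  expect_equal(scores_r, scores, tolerance = 1e-4)
  expect_equal(order(scores_r), order(scores))
})
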