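# Generator properties: graph normalization, gating limits, exact
# translation equivariance, numeric rotation equivariance, frozen residue
# coordinates, determinism and the identity limit.

make_gen_setup <- function(seed = 1L, coord_init = "random") {
  task <- small_task(seed = seed)
  pt <- prepare_task_t(task)
  model <- init_model(tiny_config(), seed = seed, coord_init = coord_init)
  enc <- encode_task(model, pt)
  ini <- init_loop_reconstruction(task$structure, task$spec, seed = seed)
  ig <- build_interaction_graph(enc$loop_h, ini, enc$merged, pt$rgraph)
  list(task = task, pt = pt, model = model, enc = enc, ini = ini, ig = ig)
}

test_that("generator state initialization normalizes per channel", {
  s <- make_gen_setup(1L)
  st <- init_generator_state(s$ig, s$model)
  expect_equal(ncol(st$h), 16L)
  expect_equal(ncol(st$e), 16L)
  # at unit gain and zero bias the graph norm has zero mean per channel
  m2 <- s$model
  m2$egnn$init_norm$gamma$value <- matrix(1, 1L, 16L)
  m2$egnn$init_norm$beta$value <- matrix(0, 1L, 16L)
  st2 <- init_generator_state(s$ig, m2)
  expect_equal(colMeans(st2$h), rep(0, 16L), tolerance = 1e-10)
  expect_equal(apply(st2$h, 2L, function(x) mean(x^2)), rep(1, 16L),
               tolerance = 1e-3)
  # constant features normalize to zero
  ig3 <- s$ig
  ig3$h0 <- matrix(5, nrow(loopcraft:::ad_val(s$ig$h0)), 16L)
  st3 <- init_generator_state(ig3, m2)
  expect_equal(max(abs(st3$h)), 0, tolerance = 1e-10)
})

test_that("gate limits recover the closed and open forms", {
  set.seed(4)
  d <- 8L
  p <- loopcraft:::gate_init(d)
  h_new <- matrix(rnorm(40), 5L, d)
  h_old <- matrix(rnorm(40), 5L, d)
  norm_ref <- function(x) loopcraft:::ad_norm_affine(x, p$norm)
  # closed gate (bias -> -inf): output = GraphNorm(h_old)
  p$lin$W$value <- p$lin$W$value * 0
  p$lin$b$value <- matrix(-1e3, 1L, d)
  expect_equal(gate_combine(h_new, h_old, p), norm_ref(h_old),
               tolerance = 1e-8)
  # open gate: output = GraphNorm(h_new + h_old)
  p$lin$b$value <- matrix(1e3, 1L, d)
  expect_equal(gate_combine(h_new, h_old, p), norm_ref(h_new + h_old),
               tolerance = 1e-8)
  expect_equal(dim(gate_combine(h_new, h_old, p)), c(5L, d))
  expect_error(gate_combine(h_new, h_old[, 1:4], p), "width")
})

test_that("global translation of all coordinates translates the output
           exactly", {
  s <- make_gen_setup(2L)
  out <- generate_conformation(s$ig, s$model)
  t <- c(11, -7, 3)
  ig_t <- s$ig
  ig_t$x0 <- sweep(s$ig$x0, 2L, t, "+")
  ig_t$e0 <- loopcraft:::interaction_edge_features(ig_t, ig_t$x0, FALSE)
  out_t <- generate_conformation(ig_t, s$model)
  expect_equal(out_t$coords, sweep(out$coords, 2L, t, "+"),
               tolerance = 1e-9)
})

test_that("global rotation of all inputs rotates the output", {
  s <- make_gen_setup(3L)
  out <- generate_conformation(s$ig, s$model)
  set.seed(8)
  R <- loopcraft:::random_rotation()
  ig_r <- s$ig
  ig_r$x0 <- s$ig$x0 %*% t(R)
  ig_r$e0 <- loopcraft:::interaction_edge_features(ig_r, ig_r$x0, FALSE)
  out_r <- generate_conformation(ig_r, s$model)
  expect_equal(out_r$coords, out$coords %*% t(R), tolerance = 1e-3)
})

test_that("two collinear nodes only displace along their axis", {
  # a minimal hand-built interaction state: 2 loop atoms on the x axis
  model <- init_model(tiny_config(), seed = 5L, coord_init = "random")
  h0 <- matrix(rnorm(32), 2L, 16L)
  ig <- structure(list(
    n_loop = 2L, n_res = 0L,
    src = c(1L, 2L), dst = c(2L, 1L), type = c(1L, 1L),
    h0 = h0, x0 = rbind(c(0, 0, 0), c(2.5, 0, 0)),
    node_kind = rep("loop_atom", 2L)), class = "interaction_graph")
  ig$e0 <- loopcraft:::interaction_edge_features(ig, ig$x0, FALSE)
  st <- init_generator_state(ig, model)
  st2 <- egnn_layer(st, model$egnn$layers[[1]], model$config)
  moved <- st2$x - ig$x0
  expect_true(all(abs(moved[, 2:3]) < 1e-12))
})

test_that("residue coordinates are frozen through the whole generation", {
  s <- make_gen_setup(4L)
  out <- generate_conformation(s$ig, s$model)
  expect_identical(out$residue_coords, s$pt$rgraph$coords)
})

test_that("generation is deterministic and zero coordinate heads are the
           identity", {
  s <- make_gen_setup(5L)
  a <- generate_conformation(s$ig, s$model)
  b <- generate_conformation(s$ig, s$model)
  expect_identical(a$coords, b$coords)
  # zero-initialized coordinate heads leave the initialization unchanged
  s0 <- make_gen_setup(5L, coord_init = "zero")
  out0 <- generate_conformation(s0$ig, s0$model)
  expect_equal(out0$coords, s0$ini$coords, tolerance = 1e-12)
  expect_error(generate_conformation(s$ig, s$model, recycles = 0L), ">= 1")
})

test_that("permuting interaction nodes permutes the outputs", {
  s <- make_gen_setup(6L)
  out <- generate_conformation(s$ig, s$model)
  set.seed(9)
  n <- s$ig$n_loop + s$ig$n_res
  # permute within kinds so the loop/residue split stays valid
  perm <- c(sample(s$ig$n_loop), s$ig$n_loop + sample(s$ig$n_res))
  inv <- order(perm)
  ig_p <- s$ig
  ig_p$h0 <- loopcraft:::ad_val(s$ig$h0)[perm, , drop = FALSE]
  ig_p$x0 <- s$ig$x0[perm, , drop = FALSE]
  ig_p$src <- inv[s$ig$src]
  ig_p$dst <- inv[s$ig$dst]
  ig_p$e0 <- loopcraft:::interaction_edge_features(ig_p, ig_p$x0, FALSE)
  out_p <- generate_conformation(ig_p, s$model)
  full <- loopcraft:::ad_val(out$coords_node)
  full_p <- loopcraft:::ad_val(out_p$coords_node)
  expect_equal(full_p[inv, ], full, tolerance = 1e-8)
})
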