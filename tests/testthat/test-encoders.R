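# Encoder properties: the atom encoder is coordinate-free and permutation
# equivariant; the GVP residue encoder is E(3)-invariant in its scalar
# track and rotation-equivariant in its vector track; the hierarchical
# merge is a segment sum.

test_that("graph transformer output shapes and coordinate independence", {
  task <- small_task(seed = 1L)
  pt <- prepare_task_t(task)
  model <- init_model(tiny_config(), seed = 0L)
  out <- encode_atoms_gt(pt$agraph, model)
  expect_equal(dim(out$h), c(nrow(pt$agraph$node_s), 16L))
  expect_equal(dim(out$e), c(length(pt$agraph$src), 16L))
  # moving every atom leaves the encoding untouched (purely topological)
  ag2 <- pt$agraph
  ag2$coords <- ag2$coords + 100
  out2 <- encode_atoms_gt(ag2, model)
  expect_identical(out$h, out2$h)
})

test_that("graph transformer is permutation equivariant", {
  task <- small_task(seed = 2L)
  pt <- prepare_task_t(task)
  model <- init_model(tiny_config(), seed = 1L)
  ag <- pt$agraph
  out <- encode_atoms_gt(ag, model)
  set.seed(3)
  perm <- sample(nrow(ag$node_s))
  inv <- order(perm)
  ag_p <- ag
  ag_p$node_s <- ag$node_s[perm, , drop = FALSE]
  ag_p$src <- inv[ag$src]
  ag_p$dst <- inv[ag$dst]
  out_p <- encode_atoms_gt(ag_p, model)
  expect_equal(out_p$h[inv[seq_len(nrow(ag$node_s))], ], out$h,
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("GVP scalars are rigid-invariant and vectors equivariant", {
  task <- small_task(seed = 1L)
  pk <- select_surface_pocket(task$structure, task$spec)
  model <- init_model(tiny_config(), seed = 2L)
  rg <- build_residue_graph(task$structure, pk)
  out <- encode_residues_gvp(rg, model)
  set.seed(11)
  R <- loopcraft:::random_rotation(); t <- c(-4, 6, 1)
  rg_r <- build_residue_graph(transform_structure(task$structure, R, t), pk)
  out_r <- encode_residues_gvp(rg_r, model)
  expect_equal(out_r$s, out$s, tolerance = 1e-4)
  v_h <- model$config$gvp_v
  rot <- out$v
  for (c in seq_len(v_h)) {
    j <- (3 * (c - 1) + 1):(3 * c)
    rot[, j] <- out$v[, j, drop = FALSE] %*% t(R)
  }
  expect_equal(out_r$v, rot, tolerance = 1e-4)
  # pure translation: everything unchanged (features are displacement-based)
  rg_t <- build_residue_graph(transform_structure(task$structure, diag(3),
                                                  c(9, 9, 9)), pk)
  out_t <- encode_residues_gvp(rg_t, model)
  expect_equal(out_t$s, out$s, tolerance = 1e-10)
  expect_equal(out_t$v, out$v, tolerance = 1e-10)
})

test_that("zero vector features contribute zero norms to the scalar path", {
  set.seed(1)
  p <- loopcraft:::gvp_unit_init(4L, 2L, 4L, 2L)
  fs <- matrix(rnorm(12), 3L, 4L)
  fv <- matrix(0, 3L, 6L)
  out <- loopcraft:::gvp_unit(fs, fv, p)
  # same scalars as explicitly concatenating zero norms
  manual <- cbind(fs, matrix(0, 3L, p$v_hidden)) %*%
    loopcraft:::ad_val(p$sv$W) +
    matrix(loopcraft:::ad_val(p$sv$b), 3L, 4L, byrow = TRUE)
  expect_equal(out$s, manual, tolerance = 1e-6)
  expect_true(all(out$v == 0))
})

test_that("hierarchical merge equals a per-residue loop and is atom-order
           symmetric", {
  set.seed(5)
  model <- init_model(tiny_config(), seed = 3L)
  n_res <- 4L; n_atoms <- 12L; d <- 16L
  atom_h <- matrix(rnorm(n_atoms * d), n_atoms, d)
  res_s <- matrix(rnorm(n_res * model$config$gvp_s), n_res)
  a2r <- rep(seq_len(n_res), each = 3L)
  merged <- merge_hierarchical(res_s, atom_h, a2r, n_res, model)
  # brute-force per-residue loop oracle
  W1 <- loopcraft:::ad_val(model$fmb$lin1$W)
  b1 <- loopcraft:::ad_val(model$fmb$lin1$b)
  W2 <- loopcraft:::ad_val(model$fmb$lin2$W)
  b2 <- loopcraft:::ad_val(model$fmb$lin2$b)
  leaky <- function(x) ifelse(x > 0, x, 0.01 * x)
  for (i in seq_len(n_res)) {
    s <- colSums(atom_h[a2r == i, , drop = FALSE])
    z <- c(res_s[i, ], s) %*% W1 + b1
    o <- leaky(z) %*% W2 + b2
    expect_equal(merged[i, ], as.numeric(o), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # permuting atoms within residues changes nothing
  perm <- c(3:1, 6:4, 9:7, 12:10)
  merged_p <- merge_hierarchical(res_s, atom_h[perm, ], a2r[perm], n_res,
                                 model)
  expect_equal(merged_p, merged, tolerance = 1e-12)
  # opposite embeddings cancel in the sum
  cancel_h <- rbind(atom_h[1, ], -atom_h[1, ])
  m1 <- merge_hierarchical(res_s[1, , drop = FALSE], cancel_h, c(1L, 1L),
                           1L, model)
  m0 <- merge_hierarchical(res_s[1, , drop = FALSE],
                           matrix(0, 2L, d), c(1L, 1L), 1L, model)
  expect_equal(m1, m0, tolerance = 1e-10)
  expect_error(merge_hierarchical(res_s, atom_h, rep(1L, n_atoms), n_res,
                                  model), "zero atoms")
})

test_that("loop embedding extraction is an index gather", {
  set.seed(2)
  h <- matrix(rnorm(40), 10L, 4L)
  mask <- rep(c(TRUE, FALSE), 5L)
  expect_equal(extract_loop_embeddings(h, mask), h[which(mask), ])
  expect_equal(extract_loop_embeddings(h, rep(TRUE, 10L)), h)
  expect_error(extract_loop_embeddings(h, rep(FALSE, 10L)), "no atoms")
  expect_error(extract_loop_embeddings(h, TRUE), "length")
})

test_that("encoders are deterministic in inference mode", {
  task <- small_task(seed = 1L)
  pt <- prepare_task_t(task)
  model <- init_model(tiny_config(), seed = 0L)
  a <- encode_task(model, pt)
  b <- encode_task(model, pt)
  expect_identical(a$gt$h, b$gt$h)
  expect_identical(a$merged, b$merged)
})
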