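# Losses, loss composition, early stopping and gradient correctness.

test_that("cross-entropy reaches its closed forms", {
  # uniform logits over C classes -> log C
  for (C in c(2L, 5L)) {
    logits <- matrix(0, 7L, C)
    labels <- rep(1L, 7L)
    expect_equal(loopcraft:::as_scalar(loopcraft:::cross_entropy(logits,
                                                                 labels)),
                 log(C), tolerance = 1e-9)
  }
  # near-one-hot logits -> loss near 0
  logits <- matrix(-50, 4L, 3L)
  labels <- c(1L, 2L, 3L, 2L)
  logits[cbind(1:4, labels)] <- 50
  expect_lt(loopcraft:::as_scalar(loopcraft:::cross_entropy(logits, labels)),
            1e-8)
  # hand-computed 3-sample toy batch
  logits <- rbind(c(1, 2), c(0, 0), c(-1, 3))
  labels <- c(2L, 1L, 1L)
  hand <- -(log(exp(2) / (exp(1) + exp(2))) + log(0.5) +
              log(exp(-1) / (exp(-1) + exp(3)))) / 3
  expect_equal(loopcraft:::as_scalar(loopcraft:::cross_entropy(logits,
                                                               labels)),
               hand, tolerance = 1e-9)
  expect_error(loopcraft:::cross_entropy(logits, c(1L, 2L)), "mismatch")
})

test_that("auxiliary losses classify elements and bond types", {
  task <- small_task(seed = 1L)
  pt <- prepare_task_t(task)
  model <- init_model(tiny_config(), seed = 0L)
  enc <- encode_task(model, pt)
  aux <- auxiliary_losses(enc$gt$h, enc$gt$e, pt$agraph$elem_class,
                          pt$agraph$bond_class, model)
  expect_gt(loopcraft:::as_scalar(aux$L_atom), 0)
  expect_gt(loopcraft:::as_scalar(aux$L_bond), 0)
})

test_that("rmsd_loss matches analytic cases", {
  X <- matrix(rnorm(30), 10L)
  expect_equal(rmsd_loss(X, X), 0)
  off <- X
  off[, 1] <- off[, 1] + 1
  expect_equal(rmsd_loss(off, X), 1, tolerance = 1e-12)
  expect_error(rmsd_loss(X[1:3, ], X), "shapes")
})

test_that("loss composition reproduces the stage formulas exactly", {
  parts <- list(L_MDN = matrix(2.5), L_atom = matrix(1.2),
                L_bond = matrix(0.8), L_rmsd = matrix(3))
  c1 <- train_config(stage = 1L, seed = 0L)
  r1 <- compute_losses(parts, c1)
  expect_equal(loopcraft:::as_scalar(r1$total),
               2.5 + 0.001 * 1.2 + 0.001 * 0.8)
  c2 <- train_config(stage = 2L, seed = 0L)
  r2 <- compute_losses(parts, c2)
  expect_equal(loopcraft:::as_scalar(r2$total),
               3 + 2.5 + 0.001 * 1.2 + 0.001 * 0.8)
  # stage difference is exactly the coordinate loss
  expect_equal(loopcraft:::as_scalar(r2$total) -
                 loopcraft:::as_scalar(r1$total), 3)
  # recombination from the report fields
  expect_equal(loopcraft:::as_scalar(r2$total),
               r2$L_rmsd + r2$L_MDN + 0.001 * r2$L_atom +
                 0.001 * r2$L_bond)
  # zero auxiliaries: total collapses to the MDN term
  p0 <- list(L_MDN = matrix(2.5), L_atom = matrix(0), L_bond = matrix(0))
  expect_equal(loopcraft:::as_scalar(compute_losses(p0, c1)$total), 2.5)
  expect_error(compute_losses(p0, c2), "coordinate loss")
})

test_that("training stops after patience epochs without improvement", {
  tasks <- lapply(0:1, function(s) small_task(seed = s))
  cfg <- tiny_config()
  # lr = 0 never improves after epoch 1: patience 1 stops at epoch 2
  res <- train_model(tasks, train_config(stage = 1L, epochs = 10L,
                                         patience = 1L, lr = 1e-12,
                                         batch_size = 2L, seed = 1L,
                                         val_fraction = 0.5),
                     model_config = cfg)
  expect_lte(nrow(res$log), 3L)
})

test_that("fixed seeds reproduce the first training epoch exactly", {
  tasks <- list(small_task(seed = 0L))
  cfg <- tiny_config()
  r1 <- train_model(tasks, train_config(stage = 1L, epochs = 1L,
                                        batch_size = 1L, seed = 5L,
                                        val_fraction = 0),
                    model_config = cfg)
  r2 <- train_model(tasks, train_config(stage = 1L, epochs = 1L,
                                        batch_size = 1L, seed = 5L,
                                        val_fraction = 0),
                    model_config = cfg)
  expect_identical(r1$log$train_loss, r2$log$train_loss)
  expect_error(train_model(list(), train_config(stage = 1L)), "empty")
  expect_error(train_model(tasks, train_config(stage = 2L)), "stage-1")
})

test_that("backpropagated gradients match finite differences", {
  task <- small_task(seed = 1L)
  pt <- prepare_task_t(task)
  cfg <- tiny_config(recycles = 1L)
  model <- init_model(cfg, seed = 0L, coord_init = "random")
  tcfg <- train_config(stage = 2L, seed = 0L)
  ini <- init_loop_reconstruction(task$structure, task$spec, seed = 1L)
  loss_fn <- function() {
    loopcraft:::as_scalar(compute_losses(
      loopcraft:::task_loss_parts(model, pt, tcfg, ini), tcfg)$total)
  }
  tp <- loopcraft:::ad_tape_begin()
  rep_ <- compute_losses(loopcraft:::task_loss_parts(model, pt, tcfg, ini),
                         tcfg)
  loopcraft:::ad_tape_end()
  loopcraft:::ad_backward(rep_$total, tp)
  targets <- list(model$gt$layers[[1]]$WQ, model$gvp$layers[[1]]$msg1$Wv0,
                  model$fmb$lin1$W, model$egnn$layers[[1]]$x2$W,
                  model$mdn$mu$W)
  set.seed(42)
  h <- 1e-5
  for (p in targets) {
    i <- sample(length(p$value), 1L)
    g_bp <- p$grad[i]
    v0 <- p$value[i]
    p$value[i] <- v0 + h; up <- loss_fn()
    p$value[i] <- v0 - h; dn <- loss_fn()
    p$value[i] <- v0
    g_fd <- (up - dn) / (2 * h)
    expect_equal(g_bp, g_fd, tolerance = 1e-3)
  }
})
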