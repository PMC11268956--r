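# Pocket-selection geometry and loop initialization statistics.

test_that("pocket radius follows max(half separation, min(2L, 16))", {
  # synthetic two-anchor geometry: place single-atom anchor residues at a
  # controlled separation and loop residues far away
  make_fake <- function(sep, loop_len) {
    res <- list()
    res[[1]] <- new_residue(0L, "ALA", "A", list(
      new_atom("CA", "C", c(0, 0, 0))))
    for (i in seq_len(loop_len)) {
      res[[i + 1L]] <- new_residue(i, "ALA", "A", list(
        new_atom("CA", "C", c(50 + i, 0, 0))))
    }
    res[[loop_len + 2L]] <- new_residue(loop_len + 1L, "ALA", "A", list(
      new_atom("CA", "C", c(sep, 0, 0))))
    list(structure = protein_structure(list(A = res)),
         spec = loop_spec("A", 1L, loop_len))
  }
  f <- make_fake(12, 5L)
  expect_equal(select_surface_pocket(f$structure, f$spec)$radius,
               max(6, 10))   # = 10
  f <- make_fake(12, 10L)
  expect_equal(select_surface_pocket(f$structure, f$spec)$radius,
               max(6, min(20, 16)))  # = 16
  f <- make_fake(60, 10L)
  expect_equal(select_surface_pocket(f$structure, f$spec)$radius, 30)
})

test_that("anchors are always in the pocket and loop residues never are", {
  for (s in c(1L, 4L)) {
    task <- small_task(seed = s)
    pk <- select_surface_pocket(task$structure, task$spec)
    anchors <- paste0("A:", task$spec$anchors)
    loops <- paste0("A:", task$spec$start:task$spec$end)
    expect_true(all(anchors %in% pk$residue_ids))
    expect_false(any(loops %in% pk$residue_ids))
  }
})

test_that("surface pocket selection is deterministic", {
  task <- small_task(seed = 2L)
  expect_identical(select_surface_pocket(task$structure, task$spec),
                   select_surface_pocket(task$structure, task$spec))
})

test_that("refinement pocket is a monotone distance filter around the loop", {
  task <- small_task(seed = 1L)
  raw <- task$truth
  pk12 <- select_refinement_pocket(task$structure, task$spec, raw)
  pk8 <- select_refinement_pocket(task$structure, task$spec, raw, cutoff = 8)
  expect_true(all(pk8$residue_ids %in% pk12$residue_ids))
  expect_true(all(paste0("A:", task$spec$anchors) %in% pk12$residue_ids))
  far <- raw + 500
  expect_warning(pk0 <- select_refinement_pocket(task$structure, task$spec,
                                                 far), "empty")
  expect_length(pk0$residue_ids, 0L)
  expect_error(select_refinement_pocket(task$structure, task$spec,
                                        raw[0, , drop = FALSE]), "nonempty")
})

test_that("reconstruction init places residue centers on the anchor axis", {
  # anchors at known positions: centers must divide the segment uniformly
  res <- list(
    new_residue(0L, "ALA", "A", list(new_atom("CA", "C", c(0, 0, 0)))),
    new_residue(1L, "ALA", "A", list(new_atom("CA", "C", c(10, 10, 10)))),
    new_residue(2L, "ALA", "A", list(new_atom("CA", "C", c(20, 20, 20)))),
    new_residue(3L, "ALA", "A", list(new_atom("CA", "C", c(30, 30, 30)))),
    new_residue(4L, "ALA", "A", list(new_atom("CA", "C", c(0, 0, 8)))))
  st <- protein_structure(list(A = res))
  sp <- loop_spec("A", 1L, 3L)
  st$chains$A[[1]]$atoms[[1]]$coords <- c(0, 0, 0)
  st$chains$A[[5]]$atoms[[1]]$coords <- c(0, 0, 8)
  centers <- t(sapply(1:3, function(i) c(0, 0, 8) * i / 4))
  draws <- lapply(1:50, function(s)
    init_loop_reconstruction(st, sp, sd = 0.5, seed = s)$coords)
  mean_pos <- Reduce(`+`, draws) / length(draws)
  expect_equal(unname(mean_pos), centers, tolerance = 0.5)
  # sd -> 0 limit: atoms collapse onto the centers
  tiny <- init_loop_reconstruction(st, sp, sd = 1e-9, seed = 1L)$coords
  expect_equal(unname(tiny), centers, tolerance = 1e-6)
  expect_error(init_loop_reconstruction(st, sp, sd = 0), "positive")
})

test_that("initialization sample moments match the requested Gaussian", {
  task <- small_task(seed = 1L)
  # reconstruction mode, sd = 1.75: per-axis SD within 5% over 10^4 draws
  n_draw <- 350L  # 350 draws x 30 atoms = 10500 deviations per axis
  devs <- lapply(seq_len(n_draw), function(s) {
    ini <- init_loop_reconstruction(task$structure, task$spec, seed = s)
    ctr <- init_loop_reconstruction(task$structure, task$spec, sd = 1e-12,
                                    seed = 1L)$coords
    ini$coords - ctr
  })
  D <- do.call(rbind, devs)
  expect_equal(apply(D, 2L, stats::sd), rep(1.75, 3), tolerance = 0.05)

  # refinement mode: mean within 0.1 A of the raw centroid, SD 4
  raw <- task$truth
  D2 <- do.call(rbind, lapply(seq_len(n_draw), function(s)
    init_loop_refinement(raw, seed = s)$coords))
  expect_equal(colMeans(D2), colMeans(raw), tolerance = 0.1,
               ignore_attr = TRUE)
  expect_equal(apply(sweep(D2, 2L, colMeans(raw)), 2L, stats::sd),
               rep(4, 3), tolerance = 0.05 * 4)

  # multiconf mode: SD 7
  D3 <- do.call(rbind, lapply(init_multiconf(
    task$structure, task$spec, n = n_draw, seeds = seq_len(n_draw)),
    function(ini) ini$coords))
  ctr <- init_loop_reconstruction(task$structure, task$spec, sd = 1e-12,
                                  seed = 1L)$coords
  devs3 <- D3 - do.call(rbind, rep(list(ctr), n_draw))
  expect_equal(apply(devs3, 2L, stats::sd), rep(7, 3), tolerance = 0.05 * 7)
})

test_that("initializations are pure functions of their seed", {
  task <- small_task(seed = 1L)
  a <- init_loop_reconstruction(task$structure, task$spec, seed = 42L)
  b <- init_loop_reconstruction(task$structure, task$spec, seed = 42L)
  expect_identical(a$coords, b$coords)
  r1 <- init_loop_refinement(task$truth, seed = 9L)
  r2 <- init_loop_refinement(task$truth, seed = 9L)
  expect_identical(r1$coords, r2$coords)
})

test_that("multiconf returns n distinct conformations and rejects dup seeds", {
  task <- small_task(seed = 1L)
  inis <- init_multiconf(task$structure, task$spec, n = 5L)
  expect_length(inis, 5L)
  for (i in 1:4) {
    expect_gt(sqrt(mean((inis[[i]]$coords - inis[[i + 1]]$coords)^2)), 0)
  }
  expect_error(init_multiconf(task$structure, task$spec, n = 2L,
                              seeds = c(3L, 3L)), "distinct")
})
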