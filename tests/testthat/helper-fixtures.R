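# Shared test fixtures: small models and tasks, rigid-transform helpers.

tiny_config <- function(...) {
  defaults <- list(d = 16L, heads = 2L, gt_layers = 2L, gvp_s = 16L,
                   gvp_v = 2L, gvp_layers = 1L, gvp_es = 8L, d_seq = 4L,
                   egnn_layers = 2L, recycles = 2L, mdn_comp = 4L,
                   mdn_width = 16L, dropout = 0)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

small_task <- function(seed = 1L, loop_len = 6L) {
  make_loop_task(8L, loop_len, 8L, seed = seed)
}

transform_structure <- function(st, R, t) {
  for (cid in names(st$chains)) {
    for (ri in seq_along(st$chains[[cid]])) {
      for (ai in seq_along(st$chains[[cid]][[ri]]$atoms)) {
        x <- st$chains[[cid]][[ri]]$atoms[[ai]]$coords
        st$chains[[cid]][[ri]]$atoms[[ai]]$coords <- as.numeric(R %*% x + t)
      }
    }
  }
  st
}

# run the full encoder stack on a prepared task
encode_task <- function(model, pt) {
  gt <- encode_atoms_gt(pt$agraph, model)
  gv <- encode_residues_gvp(pt$rgraph, model)
  merged <- merge_hierarchical(gv$s, gt$h, pt$atom2pocket,
                               length(pt$rgraph$keys), model)
  loop_h <- extract_loop_embeddings(gt$h, pt$agraph$loop_atom)
  list(gt = gt, gv = gv, merged = merged, loop_h = loop_h)
}

prepare_task_t <- function(task) loopcraft:::prepare_task(task)
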