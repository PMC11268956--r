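# Conformation generator: attention-augmented E(n)-equivariant message
# passing over the interaction graph, with gated residual updates and
# recycling.  Coordinates are updated for loop-atom nodes only; residue
# nodes provide fixed context.  All coordinate updates are sums of scaled
# unit difference vectors ("pseudo-forces"), which makes the block exactly
# translation-equivariant and rotation-equivariant to float precision.

#' Initialize the generator state from an interaction graph
#'
#' Node embeddings are graph-normalized; edge features pass a linear layer.
#'
#' @param igraph an `interaction_graph`.
#' @param model a `loop_model` (uses `model$egnn`).
#' @return a `generator_state` with `h`, `e`, `x` and the frozen residue
#'   coordinate block.
#' @export
init_generator_state <- function(igraph, model) {
  p <- model$egnn
  h <- ad_norm_affine(igraph$h0, p$init_norm)
  e <- ad_lin(igraph$e0, p$init_e)
  structure(list(h = h, e = e, x = igraph$x0,
                 n_loop = igraph$n_loop, n_res = igraph$n_res,
                 src = igraph$src, dst = igraph$dst, type = igraph$type,
                 si = seg_index(igraph$dst)),
            class = "generator_state")
}

#' Gated combination of a candidate update with the previous embeddings
#'
#' `g = sigmoid(linear(concat(h_new, h_old, h_new - h_old)))` followed by
#' `GraphNorm(g * h_new + h_old)`.
#'
#' @param h_new candidate embeddings.
#' @param h_old previous embeddings (equal width).
#' @param params gate parameters (`lin`, `norm`).
#' @param dropout dropout rate applied inside the gate during training.
#' @return combined embeddings, same width.
#' @export
gate_combine <- function(h_new, h_old, params, dropout = 0) {
  if (ncol(ad_val(h_new)) != ncol(ad_val(h_old))) {
    stop("gate inputs must have equal widths")
  }
  z <- ad_cbind(h_new, h_old, ad_sub(h_new, h_old))
  g <- ad_sigmoid(ad_dropout(ad_lin(z, params$lin), dropout))
  ad_norm_affine(ad_add(ad_mul(g, h_new), h_old), params$norm)
}

#' One EGNN layer
#'
#' Messages combine edge embeddings with squared inter-node distances; keys
#' are gated by the message, attention weights are elementwise
#' `q * k / sqrt(d_k)`, and the per-channel softmax of their squares drives
#' the edge update.  Nodes aggregate `w * v` by summation and pass a gate;
#' coordinates of loop-atom nodes move along epsilon-normalized difference
#' vectors scaled by a per-head scalar MLP of the attention weights.
#'
#' @param state a `generator_state`.
#' @param lp layer parameters (one entry of `model$egnn$layers`).
#' @param cfg the `model_config`.
#' @return the updated state.
#' @export
egnn_layer <- function(state, lp, cfg) {
  drop <- cfg$dropout
  H <- cfg$heads
  dk <- cfg$d %/% H
  src <- state$src; dst <- state$dst
  n <- state$n_loop + state$n_res
  h <- state$h; e <- state$e; x <- state$x

  q <- ad_lin(h, lp$Q)
  k <- ad_lin(h, lp$K)
  v <- ad_lin(h, lp$V)
  dif <- ad_sub(ad_rows(x, dst), ad_rows(x, src))
  dist2 <- ad_rowsum_all(ad_square(dif))
  # squared distances enter the message in nm^2 to keep a sane dynamic range
  m <- ad_lin(ad_leaky_relu(ad_dropout(
    ad_lin(ad_cbind(e, ad_scale(dist2, 0.01)), lp$m1), drop)), lp$m2)
  kg <- ad_mul(ad_rows(k, src), m)
  w <- ad_scale(ad_mul(ad_rows(q, dst), kg), 1 / sqrt(dk))
  alpha <- ad_segment_softmax(ad_square(w), state$si)
  msg <- ad_segment_sum(ad_mul(w, ad_rows(v, src)), dst, n)
  h_hat <- ad_dropout(ad_lin(msg, lp$Wh), drop)
  h_new <- gate_combine(h_hat, h, lp$gate, drop)
  e_new <- ad_lin(alpha, lp$We)

  # coordinate update (loop-atom nodes only)
  nrm <- ad_sqrt(ad_add(dist2, matrix(1e-16, nrow(ad_val(dist2)), 1L)))
  unit <- ad_scale_rows(dif, ad_recip(ad_add(
    nrm, matrix(1e-8, nrow(ad_val(nrm)), 1L))))
  shead <- vector("list", H)
  for (hd in seq_len(H)) {
    widx <- ((hd - 1L) * dk + 1L):(hd * dk)
    shead[[hd]] <- ad_lin(ad_leaky_relu(ad_dropout(
      ad_lin(ad_cols(w, widx), lp$x1), drop)), lp$x2)
  }
  scal <- ad_matmul(do.call(ad_cbind, shead), lp$WH)
  dx <- ad_segment_sum(ad_scale_rows(unit, scal), dst, n)
  mask <- matrix(0, n, 3L)
  mask[seq_len(state$n_loop), ] <- 1
  x_new <- ad_add(x, ad_mul(dx, mask))

  state$h <- h_new; state$e <- e_new; state$x <- x_new
  state
}

#' Generate a loop conformation by recycled EGNN refinement
#'
#' Runs `recycles` passes of the stacked EGNN layers.  At the start of every
#' recycle after the first, node embeddings are gate-combined with the raw
#' (recycle-zero) embeddings and the loop-incident edge distance features
#' are refreshed from the current coordinates.  Gradients flow only through
#' the final recycle; earlier recycles are detached at the boundary.
#' Residue-node coordinates are bit-identical before and after.
#'
#' @param igraph an `interaction_graph`.
#' @param model a `loop_model`.
#' @param recycles overrides `model$config$recycles` if given.
#' @return list with `coords` (final loop-atom coordinates), `trajectory`
#'   (per-recycle loop coordinates) and `h` (final node embeddings).
#' @export
generate_conformation <- function(igraph, model, recycles = NULL) {
  cfg <- model$config
  R <- if (is.null(recycles)) cfg$recycles else as.integer(recycles)
  if (R < 1L) stop("recycles must be >= 1")
  p <- model$egnn
  state <- init_generator_state(igraph, model)
  raw_h <- state$h
  traj <- vector("list", R)
  detach <- isTRUE(cfg$recycle_detach)
  for (r in seq_len(R)) {
    # with recycle_detach, gradients flow only through the final recycle and
    # earlier recycles run off-tape entirely; the raw embeddings stay
    # attached at the final boundary so encoder gradients flow through the
    # recycle gate
    saved_tape <- NULL
    if (detach && ad_recording() && r < R) {
      saved_tape <- .ad$tape
      .ad$tape <- NULL
    }
    if (r > 1L) {
      h_in <- if (detach) ad_detach(state$h) else state$h
      if (detach) state$x <- ad_detach(state$x)
      state$h <- gate_combine(h_in, raw_h, p$recycle_gate, cfg$dropout)
      ef_x <- if (detach || !is_nd(state$x)) ad_val(state$x) else
        ad_detach(state$x)
      ef <- interaction_edge_features(igraph, ef_x, refresh_cross = TRUE)
      state$e <- ad_lin(ef, p$init_e)
    }
    for (lp in p$layers) {
      state <- egnn_layer(state, lp, cfg)
    }
    if (!is.null(saved_tape)) .ad$tape <- saved_tape
    traj[[r]] <- ad_val(state$x)[seq_len(state$n_loop), , drop = FALSE]
  }
  list(coords_node = state$x,
       coords = ad_val(state$x)[seq_len(state$n_loop), , drop = FALSE],
       residue_coords = ad_val(state$x)[state$n_loop + seq_len(state$n_res),
                                        , drop = FALSE],
       trajectory = traj, h = state$h)
}
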