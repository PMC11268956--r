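# Encoders: graph transformer over the covalent atom graph, geometric
# vector perceptrons over the residue KNN graph, and the hierarchical
# feature merge.

#' Encode the atom graph with the graph transformer
#'
#' Six layers of edge-featured multi-head attention over covalent
#' neighborhoods.  Per layer: batch-normalized node/edge projections to
#' per-head queries, keys, values and edge gates; attention weights are the
#' per-channel softmax over in-neighbors of (q * k) / sqrt(d_k) gated by the
#' edge features; nodes aggregate w * v by summation with a residual, edges
#' update from the concatenated attention weights, and both pass through a
#' SiLU feed-forward residual block.  The encoder is purely topological:
#' coordinates never enter.
#'
#' @param graph an `atom_graph`.
#' @param model a `loop_model` (uses `model$gt`).
#' @return list with `h` (n_atoms x d) and `e` (n_edges x d) embeddings.
#' @export
encode_atoms_gt <- function(graph, model) {
  p <- model$gt
  cfg <- model$config
  drop <- cfg$dropout
  dk <- cfg$d %/% cfg$heads
  n <- nrow(graph$node_s)
  h <- ad_lin(graph$node_s, p$proj_h)
  e <- ad_lin(graph$edge_s, p$proj_e)
  src <- graph$src; dst <- graph$dst
  si <- seg_index(dst)
  for (lp in p$layers) {
    hn <- ad_norm_affine(h, lp$norm_h)
    en <- ad_norm_affine(e, lp$norm_e)
    q <- ad_matmul(hn, lp$WQ)
    k <- ad_matmul(hn, lp$WK)
    v <- ad_matmul(hn, lp$WV)
    eg <- ad_matmul(en, lp$WE)
    logits <- ad_mul(ad_scale(ad_mul(ad_rows(q, dst), ad_rows(k, src)),
                              1 / sqrt(dk)), eg)
    w <- ad_segment_softmax(logits, si)
    msg <- ad_segment_sum(ad_mul(w, ad_rows(v, src)), dst, n)
    h_hat <- ad_add(h, ad_matmul(ad_dropout(msg, drop), lp$Wh0))
    e_hat <- ad_add(e, ad_matmul(ad_dropout(w, drop), lp$We0))
    h <- ad_add(h_hat, ad_lin(ad_dropout(ad_silu(ad_lin(
      ad_norm_affine(h_hat, lp$ffn_norm_h), lp$Wh1)), drop), lp$Wh2))
    e <- ad_add(e_hat, ad_lin(ad_dropout(ad_silu(ad_lin(
      ad_norm_affine(e_hat, lp$ffn_norm_e), lp$We1)), drop), lp$We2))
  }
  list(h = h, e = e)
}

# one geometric-vector-perceptron unit: scalars mix with vector channel
# norms; vector channels are linearly mixed and (optionally) gated by a
# sigmoid of their norms.  With activate = FALSE both tracks are linear.
gvp_unit <- function(fs, fv, p, activate = FALSE) {
  fv1 <- ad_vec_mix(fv, p$Wv0, p$v_in, p$v_hidden)
  fv2 <- ad_vec_mix(fv1, p$Wv1, p$v_hidden, p$v_out)
  s1 <- ad_vec_norm(fv1, p$v_hidden)
  fs_out <- ad_lin(ad_cbind(fs, s1), p$sv)
  if (activate) {
    fs_out <- ad_relu(fs_out)
    s2 <- ad_vec_norm(fv2, p$v_out)
    fv2 <- ad_vec_gate(fv2, ad_sigmoid(s2), p$v_out)
  }
  list(s = fs_out, v = fv2)
}

#' Encode the pocket residue graph with geometric vector perceptrons
#'
#' The sequence embedding is concatenated to the scalar node features, both
#' node and edge tracks pass an initialization GVP with layer normalization,
#' then a stack of message-passing layers: a 3-stage GVP message over
#' concatenated (target, edge, source) features, mean aggregation over
#' in-neighbors, a residual with layer norm, and a 2-stage GVP feed-forward.
#' Scalar outputs are E(3)-invariant; vector outputs rotate with the input.
#'
#' @param graph a `residue_graph`.
#' @param model a `loop_model` (uses `model$gvp`).
#' @return list with `s` (n_res x gvp_s) and `v` (n_res x 3*gvp_v).
#' @export
encode_residues_gvp <- function(graph, model) {
  p <- model$gvp
  cfg <- model$config
  drop <- cfg$dropout
  v_h <- cfg$gvp_v
  n <- nrow(graph$node_s)
  hseq <- ad_rows(p$seq_emb, graph$seq_codes)
  hs <- ad_cbind(graph$node_s, hseq)
  nd <- gvp_unit(ad_layernorm_affine(hs, p$node_ln),
                 ad_vec_rms_norm(graph$node_v, RES_VEC_CH),
                 p$node_init)
  ed <- gvp_unit(ad_layernorm_affine(graph$edge_s, p$edge_ln),
                 ad_vec_rms_norm(graph$edge_v, EDGE_VEC_CH),
                 p$edge_init)
  hs <- nd$s; hv <- nd$v
  es <- ed$s; ev <- ed$v
  src <- graph$src; dst <- graph$dst
  for (lp in p$layers) {
    ms <- ad_cbind(ad_rows(hs, dst), es, ad_rows(hs, src))
    mv <- ad_cbind(ad_rows(hv, dst), ev, ad_rows(hv, src))
    m1 <- gvp_unit(ms, mv, lp$msg1, activate = TRUE)
    m2 <- gvp_unit(m1$s, m1$v, lp$msg2, activate = TRUE)
    m3 <- gvp_unit(m2$s, m2$v, lp$msg3, activate = FALSE)
    ags <- ad_segment_mean(m3$s, dst, n)
    agv <- ad_segment_mean(m3$v, dst, n)
    f0s <- ad_layernorm_affine(ad_add(hs, ad_dropout(ags, drop)), lp$ln1)
    f0v <- ad_vec_rms_norm(ad_add(hv, ad_dropout(agv, drop)), v_h)
    f1 <- gvp_unit(f0s, f0v, lp$ffn1, activate = TRUE)
    f2 <- gvp_unit(f1$s, f1$v, lp$ffn2, activate = FALSE)
    hs <- ad_layernorm_affine(ad_add(hs, ad_dropout(f2$s, drop)), lp$ln2)
    hv <- ad_vec_rms_norm(ad_add(hv, ad_dropout(f2$v, drop)), v_h)
  }
  list(s = hs, v = hv)
}

#' Merge atom-level embeddings into residue embeddings
#'
#' For every pocket residue the embeddings of its atoms are summed,
#' concatenated to the residue embedding, and passed through a two-layer
#' feature-merging block (linear, leaky ReLU, linear).
#'
#' @param residue_s residue scalar embeddings (n_res x gvp_s).
#' @param atom_h atom embeddings (n_atoms x d) from [encode_atoms_gt()].
#' @param atom2res integer map from atom row to residue row; atoms with NA
#'   are excluded (e.g. loop atoms, which are not merged into residues).
#' @param n_res residue count.
#' @param model a `loop_model` (uses `model$fmb`).
#' @return merged residue embeddings (n_res x d).
#' @export
merge_hierarchical <- function(residue_s, atom_h, atom2res, n_res, model) {
  ok <- !is.na(atom2res)
  if (!any(ok)) stop("no atoms mapped to residues")
  cnt <- tabulate(atom2res[ok], nbins = n_res)
  if (any(cnt == 0L)) stop("residue with zero atoms cannot be merged")
  sums <- ad_segment_sum(ad_rows(atom_h, which(ok)),
                         atom2res[ok], n_res)
  m <- ad_cbind(residue_s, sums)
  ad_lin(ad_leaky_relu(ad_lin(m, model$fmb$lin1)), model$fmb$lin2)
}

#' Select loop-atom embeddings by mask
#'
#' @param atom_h atom embeddings (n_atoms x d).
#' @param mask logical vector over atom rows.
#' @return the masked rows, in original atom order.
#' @export
extract_loop_embeddings <- function(atom_h, mask) {
  if (length(mask) != nrow(ad_val(atom_h))) {
    stop("mask length must equal the atom count")
  }
  if (!any(mask)) stop("loop mask selects no atoms")
  ad_rows(atom_h, which(mask))
}
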