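# Model configuration and parameter initialization.
#
# Default widths: shared node width d = 128 with 4 attention heads in both
# the atom encoder and the generator, GVP scalar width 128 with 16 vector
# channels and 3 message-passing layers, 10 mixture components.  Layer
# counts (6 graph-transformer layers, 8 EGNN layers) are fixed by the
# architecture; widths, heads, recycles and dropout are tunable.

ATOM_FEAT_DIM <- 44L   # element(5) + residue(20) + backbone(1) + degree(6) +
                       # atom name(6) + position encoding(6)
BOND_FEAT_DIM <- 2L
RES_SCALAR_DIM <- 29L  # residue(20) + dihedral sin/cos(6) + validity(3)
RES_VEC_CH <- 3L
EDGE_SCALAR_DIM <- 18L # rbf(16) + separation(1) + same-chain(1)
EDGE_VEC_CH <- 1L
IEDGE_FEAT_DIM <- 4L   # edge type one-hot(3) + distance(1)
N_RES_TYPES <- 21L     # 20 canonical + unknown

#' Model configuration
#'
#' @param d node embedding width shared by the atom encoder and generator.
#' @param heads attention head count (must divide `d`).
#' @param gt_layers graph-transformer depth.
#' @param gvp_s,gvp_v GVP scalar width and vector channel count.
#' @param gvp_layers number of GVP message-passing layers.
#' @param gvp_es edge scalar width inside the GVP stack.
#' @param d_seq sequence-embedding width.
#' @param egnn_layers generator depth per recycle.
#' @param recycles number of recycling iterations (>= 1).
#' @param mdn_comp mixture components of the distance head.
#' @param mdn_width pair-embedding width of the distance head.
#' @param dropout dropout rate used during training.
#' @param loop_k loop-atom neighbor count in the interaction graph;
#'   `Inf` (default) fully connects loop atoms, a finite value keeps the
#'   K nearest loop-atom neighbors at construction (bounds edge count for
#'   long loops).
#' @param recycle_detach if TRUE, gradients are stopped at recycle
#'   boundaries (bounding tape size at the cost of a non-stationary input
#'   distribution for the final recycle); if FALSE (default) gradients flow
#'   through all recycles.
#' @export
model_config <- function(d = 128L, heads = 4L, gt_layers = 6L,
                         gvp_s = 128L, gvp_v = 16L, gvp_layers = 3L,
                         gvp_es = 32L, d_seq = 16L,
                         egnn_layers = 8L, recycles = 3L,
                         mdn_comp = 10L, mdn_width = 64L, dropout = 0.1,
                         loop_k = Inf, recycle_detach = FALSE) {
  if (d %% heads != 0L) stop("d must be divisible by heads")
  if (recycles < 1L) stop("recycles must be >= 1")
  if (gvp_v < 1L) stop("vector multiplicity must be >= 1")
  structure(list(d = as.integer(d), heads = as.integer(heads),
                 gt_layers = as.integer(gt_layers),
                 gvp_s = as.integer(gvp_s), gvp_v = as.integer(gvp_v),
                 gvp_layers = as.integer(gvp_layers),
                 gvp_es = as.integer(gvp_es), d_seq = as.integer(d_seq),
                 egnn_layers = as.integer(egnn_layers),
                 recycles = as.integer(recycles),
                 mdn_comp = as.integer(mdn_comp),
                 mdn_width = as.integer(mdn_width), dropout = dropout,
                 loop_k = loop_k, recycle_detach = isTRUE(recycle_detach)),
            class = "model_config")
}

gvp_unit_init <- function(s_in, v_in, s_out, v_out) {
  v_hidden <- max(v_in, v_out)
  list(Wv0 = ad_param(matrix(stats::rnorm(v_in * v_hidden,
                                          sd = sqrt(2 / (v_in + v_hidden))),
                             v_in, v_hidden)),
       Wv1 = ad_param(matrix(stats::rnorm(v_hidden * v_out,
                                          sd = sqrt(2 / (v_hidden + v_out))),
                             v_hidden, v_out)),
       sv = lin_init(s_in + v_hidden, s_out),
       v_hidden = v_hidden, v_in = v_in, v_out = v_out)
}

gate_init <- function(d) {
  list(lin = lin_init(3L * d, d), norm = norm_init(d))
}

#' Initialize model parameters
#'
#' @param config a [model_config()].
#' @param seed integer seed for the deterministic Glorot initialization.
#' @param coord_init `"zero"` (default) zero-initializes the final
#'   projection of every coordinate-update head, so an untrained model
#'   leaves coordinates unchanged and updates grow only as training demands
#'   them; `"random"` uses Glorot initialization there too.
#' @return a `loop_model` (nested list of parameter tensors).
#' @export
init_model <- function(config, seed = 0L, coord_init = c("zero", "random")) {
  coord_init <- match.arg(coord_init)
  set.seed(seed)
  d <- config$d
  gt <- list(
    proj_h = lin_init(ATOM_FEAT_DIM, d),
    proj_e = lin_init(BOND_FEAT_DIM, d),
    layers = lapply(seq_len(config$gt_layers), function(l) list(
      norm_h = norm_init(d), norm_e = norm_init(d),
      WQ = lin_init(d, d, bias = FALSE)$W,
      WK = lin_init(d, d, bias = FALSE)$W,
      WV = lin_init(d, d, bias = FALSE)$W,
      WE = lin_init(d, d, bias = FALSE)$W,
      Wh0 = lin_init(d, d, bias = FALSE)$W,
      We0 = lin_init(d, d, bias = FALSE)$W,
      ffn_norm_h = norm_init(d),
      Wh1 = lin_init(d, 2L * d), Wh2 = lin_init(2L * d, d),
      ffn_norm_e = norm_init(d),
      We1 = lin_init(d, 2L * d), We2 = lin_init(2L * d, d)
    ))
  )
  s_h <- config$gvp_s; v_h <- config$gvp_v; s_e <- config$gvp_es
  s_in <- RES_SCALAR_DIM + config$d_seq
  gvp <- list(
    seq_emb = ad_param(matrix(stats::rnorm(N_RES_TYPES * config$d_seq,
                                           sd = 0.1),
                              N_RES_TYPES, config$d_seq)),
    node_ln = norm_init(s_in),
    node_init = gvp_unit_init(s_in, RES_VEC_CH, s_h, v_h),
    edge_ln = norm_init(EDGE_SCALAR_DIM),
    edge_init = gvp_unit_init(EDGE_SCALAR_DIM, EDGE_VEC_CH, s_e, EDGE_VEC_CH),
    layers = lapply(seq_len(config$gvp_layers), function(l) list(
      msg1 = gvp_unit_init(2L * s_h + s_e, 2L * v_h + EDGE_VEC_CH, s_h, v_h),
      msg2 = gvp_unit_init(s_h, v_h, s_h, v_h),
      msg3 = gvp_unit_init(s_h, v_h, s_h, v_h),
      ln1 = norm_init(s_h),
      ffn1 = gvp_unit_init(s_h, v_h, 4L * s_h, 2L * v_h),
      ffn2 = gvp_unit_init(4L * s_h, 2L * v_h, s_h, v_h),
      ln2 = norm_init(s_h)
    ))
  )
  fmb <- list(lin1 = lin_init(s_h + d, d), lin2 = lin_init(d, d))
  mdn <- list(
    pair = lin_init(2L * d, config$mdn_width),
    bn = norm_init(config$mdn_width),
    mu = lin_init(config$mdn_width, config$mdn_comp),
    sigma = lin_init(config$mdn_width, config$mdn_comp),
    pi = lin_init(config$mdn_width, config$mdn_comp)
  )
  aux <- list(atom = lin_init(d, 5L), bond = lin_init(d, 2L))
  dk <- d %/% config$heads
  egnn <- list(
    init_norm = norm_init(d),
    init_e = lin_init(IEDGE_FEAT_DIM, d),
    recycle_gate = gate_init(d),
    layers = lapply(seq_len(config$egnn_layers), function(l) list(
      Q = lin_init(d, d), K = lin_init(d, d), V = lin_init(d, d),
      m1 = lin_init(d + 1L, d), m2 = lin_init(d, d),
      Wh = lin_init(d, d), We = lin_init(d, d),
      gate = gate_init(d),
      x1 = lin_init(dk, max(dk %/% 2L, 1L)),
      x2 = {
        p <- lin_init(max(dk %/% 2L, 1L), 1L)
        if (coord_init == "zero") {
          p$W$value <- p$W$value * 0
          p$b$value <- p$b$value * 0
        }
        p
      },
      WH = ad_param(matrix(stats::rnorm(config$heads,
                                        sd = sqrt(1 / config$heads)),
                           config$heads, 1L))
    ))
  )
  structure(list(config = config, gt = gt, gvp = gvp, fmb = fmb, mdn = mdn,
                 aux = aux, egnn = egnn),
            class = "loop_model")
}

#' Save model parameters
#'
#' Writes a single-file archive with a format version, the configuration and
#' plain-matrix parameter values.
#' @param model a `loop_model`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "loopcraft-checkpoint", version = 1L,
              config = unclass(model$config),
              params = params_to_values(model[setdiff(names(model),
                                                      "config")]))
  saveRDS(obj, path)
  invisible(path)
}

#' Load model parameters saved by [save_checkpoint()]
#' @param path checkpoint file.
#' @return a `loop_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "loopcraft-checkpoint")) {
    stop("not a loopcraft checkpoint: ", path)
  }
  model <- values_to_params(obj$params)
  model$config <- do.call(model_config, obj$config)
  model <- model[c("config", "gt", "gvp", "fmb", "mdn", "aux", "egnn")]
  class(model) <- "loop_model"
  model
}
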