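# Reverse-mode automatic differentiation on a dynamic tape.
#
# All network blocks in this package are expressed through the `ad_*`
# operations below.  Values are plain numeric matrices; when a tape is
# active, operations additionally record a node carrying a backward
# closure.  Leaf parameters are `ad_param()` nodes whose gradients are
# accumulated in place by `ad_backward()`.  When no tape is active every
# operation degenerates to its plain matrix computation, so the same
# forward code serves both training and inference.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$training <- FALSE

#' @keywords internal
ad_tape_begin <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  .ad$tape <- tp
  invisible(tp)
}

#' @keywords internal
ad_tape_end <- function() {
  tp <- .ad$tape
  .ad$tape <- NULL
  invisible(tp)
}

ad_recording <- function() !is.null(.ad$tape)

ad_set_training <- function(on) {
  .ad$training <- isTRUE(on)
  invisible(on)
}

is_nd <- function(x) inherits(x, "ad_node")

#' @keywords internal
ad_val <- function(x) if (is_nd(x)) x$value else x

ad_node <- function(value, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  class(nd) <- "ad_node"
  if (!is.null(parents)) {
    tp <- .ad$tape
    n <- tp$n + 1L
    if (n > length(tp$nodes)) {
      tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    }
    tp$nodes[[n]] <- nd
    tp$n <- n
  }
  nd
}

#' Create a trainable leaf tensor
#' @keywords internal
ad_param <- function(value) ad_node(as.matrix(value))

#' Run the backward pass for a scalar loss node
#' @keywords internal
ad_backward <- function(loss, tape) {
  stopifnot(is_nd(loss))
  loss$grad <- matrix(1, 1L, 1L)
  if (tape$n == 0L) return(invisible(NULL))
  for (k in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    g <- nd$grad
    if (is.null(g)) next
    gs <- nd$backward(g)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      gj <- gs[[j]]
      if (is_nd(p) && !is.null(gj)) {
        p$grad <- if (is.null(p$grad)) gj else p$grad + gj
      }
    }
    nd$grad <- NULL
  }
  invisible(NULL)
}

# --- elementary operations ---------------------------------------------------

ad_matmul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av %*% bv
  if (!ad_recording()) return(v)
  ad_node(v, list(a, b), function(g) list(
    if (is_nd(a)) g %*% t(bv) else NULL,
    if (is_nd(b)) crossprod(av, g) else NULL))
}

ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av + bv
  if (!ad_recording()) return(v)
  ad_node(v, list(a, b), function(g) list(
    if (is_nd(a)) g else NULL,
    if (is_nd(b)) g else NULL))
}

ad_sub <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av - bv
  if (!ad_recording()) return(v)
  ad_node(v, list(a, b), function(g) list(
    if (is_nd(a)) g else NULL,
    if (is_nd(b)) -g else NULL))
}

ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av * bv
  if (!ad_recording()) return(v)
  ad_node(v, list(a, b), function(g) list(
    if (is_nd(a)) g * bv else NULL,
    if (is_nd(b)) g * av else NULL))
}

ad_div <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av / bv
  if (!ad_recording()) return(v)
  ad_node(v, list(a, b), function(g) list(
    if (is_nd(a)) g / bv else NULL,
    if (is_nd(b)) -g * av / (bv * bv) else NULL))
}

ad_scale <- function(a, s) {
  av <- ad_val(a)
  v <- av * s
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) list(if (is_nd(a)) g * s else NULL))
}

# bias is a 1 x d parameter broadcast over rows
ad_add_bias <- function(a, bias) {
  av <- ad_val(a); bv <- ad_val(bias)
  v <- av + rep(as.numeric(bv), each = nrow(av))
  if (!ad_recording()) return(v)
  ad_node(v, list(a, bias), function(g) list(
    if (is_nd(a)) g else NULL,
    if (is_nd(bias)) matrix(colSums(g), 1L) else NULL))
}

# gamma is a 1 x d parameter multiplying each column
ad_scale_cols <- function(a, gamma) {
  av <- ad_val(a); gv <- as.numeric(ad_val(gamma))
  gr <- rep(gv, each = nrow(av))
  v <- av * gr
  if (!ad_recording()) return(v)
  ad_node(v, list(a, gamma), function(g) list(
    if (is_nd(a)) g * gr else NULL,
    if (is_nd(gamma)) matrix(colSums(g * av), 1L) else NULL))
}

# s is an n x 1 column broadcast across the columns of a
ad_scale_rows <- function(a, s) {
  av <- ad_val(a); sv <- as.numeric(ad_val(s))
  v <- av * sv
  if (!ad_recording()) return(v)
  ad_node(v, list(a, s), function(g) list(
    if (is_nd(a)) g * sv else NULL,
    if (is_nd(s)) matrix(rowSums(g * av), ncol = 1L) else NULL))
}

ad_lin <- function(x, p) ad_add_bias(ad_matmul(x, p$W), p$b)

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_val)
  v <- do.call(cbind, vals)
  if (!ad_recording()) return(v)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(v, args, function(g) {
    lapply(seq_along(args), function(j) {
      if (is_nd(args[[j]])) g[, starts[j]:ends[j], drop = FALSE] else NULL
    })
  })
}

ad_rbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_val)
  v <- do.call(rbind, vals)
  if (!ad_recording()) return(v)
  heights <- vapply(vals, nrow, 1L)
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_node(v, args, function(g) {
    lapply(seq_along(args), function(j) {
      if (is_nd(args[[j]])) g[starts[j]:ends[j], , drop = FALSE] else NULL
    })
  })
}

ad_cols <- function(a, idx) {
  av <- ad_val(a)
  v <- av[, idx, drop = FALSE]
  if (!ad_recording()) return(v)
  nc <- ncol(av)
  ad_node(v, list(a), function(g) {
    if (!is_nd(a)) return(list(NULL))
    out <- matrix(0, nrow(g), nc)
    out[, idx] <- out[, idx] + g
    list(out)
  })
}

ad_rows <- function(a, idx) {
  av <- ad_val(a)
  v <- av[idx, , drop = FALSE]
  if (!ad_recording()) return(v)
  nr <- nrow(av)
  ad_node(v, list(a), function(g) {
    if (!is_nd(a)) return(list(NULL))
    out <- matrix(0, nr, ncol(g))
    rs <- rowsum(g, idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

# --- segment (per-group) operations ------------------------------------------

segment_place <- function(rs, ngroups, d) {
  out <- matrix(0, ngroups, d)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

ad_segment_sum <- function(x, groups, ngroups) {
  xv <- ad_val(x)
  v <- segment_place(rowsum(xv, groups), ngroups, ncol(xv))
  if (!ad_recording()) return(v)
  ad_node(v, list(x), function(g) {
    if (!is_nd(x)) return(list(NULL))
    list(g[groups, , drop = FALSE])
  })
}

ad_segment_mean <- function(x, groups, ngroups) {
  xv <- ad_val(x)
  cnt <- tabulate(groups, nbins = ngroups)
  cnt[cnt == 0L] <- 1L
  v <- segment_place(rowsum(xv, groups), ngroups, ncol(xv)) / cnt
  if (!ad_recording()) return(v)
  ad_node(v, list(x), function(g) {
    if (!is_nd(x)) return(list(NULL))
    list((g / cnt)[groups, , drop = FALSE])
  })
}

# precomputed segment index for repeated grouped reductions over the same
# edge list; ad_segment_* accept either the raw group vector or this object
seg_index <- function(groups) {
  if (is.list(groups)) return(groups)
  sp <- split(seq_along(groups), groups)
  ug <- as.integer(names(sp))
  list(groups = groups, sp = sp, ug = ug,
       gpos = match(groups, ug))
}

# column-wise softmax within groups of rows (e.g. attention over in-neighbors);
# stabilized by a per-group per-column max subtraction
ad_segment_softmax <- function(x, groups) {
  si <- seg_index(groups)
  xv <- ad_val(x)
  M <- matrix(0, length(si$sp), ncol(xv))
  for (gi in seq_along(si$sp)) {
    tm <- t(xv[si$sp[[gi]], , drop = FALSE])
    M[gi, ] <- tm[cbind(seq_len(nrow(tm)), max.col(tm, "first"))]
  }
  e <- exp(xv - M[si$gpos, , drop = FALSE])
  den <- rowsum(e, si$groups)
  y <- e / den[si$gpos, , drop = FALSE]
  dimnames(y) <- NULL
  if (!ad_recording()) return(y)
  ad_node(y, list(x), function(g) {
    if (!is_nd(x)) return(list(NULL))
    t0 <- rowsum(g * y, si$groups)
    list(y * (g - t0[si$gpos, , drop = FALSE]))
  })
}

# --- activations --------------------------------------------------------------

ad_relu <- function(a) {
  av <- ad_val(a)
  v <- pmax(av, 0)
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) list(if (is_nd(a)) g * (av > 0) else NULL))
}

ad_leaky_relu <- function(a, alpha = 0.01) {
  av <- ad_val(a)
  fac <- 1 + (alpha - 1) * (av < 0)
  v <- av * fac
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) {
    list(if (is_nd(a)) g * fac else NULL)
  })
}

ad_sigmoid <- function(a) {
  av <- ad_val(a)
  v <- 1 / (1 + exp(-av))
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) list(if (is_nd(a)) g * v * (1 - v) else NULL))
}

ad_silu <- function(a) {
  av <- ad_val(a)
  s <- 1 / (1 + exp(-av))
  v <- av * s
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) {
    list(if (is_nd(a)) g * (s + av * s * (1 - s)) else NULL)
  })
}

ad_elu <- function(a) {
  av <- ad_val(a)
  neg <- expm1(pmin(av, 0))
  v <- pmax(av, 0) + neg
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) {
    list(if (is_nd(a)) g * ((av > 0) + (av <= 0) * (neg + 1)) else NULL)
  })
}

ad_exp <- function(a) {
  av <- ad_val(a)
  v <- exp(av)
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) list(if (is_nd(a)) g * v else NULL))
}

ad_log <- function(a) {
  av <- ad_val(a)
  v <- log(av)
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) list(if (is_nd(a)) g / av else NULL))
}

ad_sqrt <- function(a) {
  av <- ad_val(a)
  v <- sqrt(av)
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) list(if (is_nd(a)) g / (2 * v) else NULL))
}

ad_square <- function(a) {
  av <- ad_val(a)
  v <- av * av
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) list(if (is_nd(a)) 2 * g * av else NULL))
}

ad_recip <- function(a) {
  av <- ad_val(a)
  v <- 1 / av
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) list(if (is_nd(a)) -g / (av * av) else NULL))
}

# --- reductions ---------------------------------------------------------------

ad_rowsum_all <- function(a) {
  av <- ad_val(a)
  v <- matrix(rowSums(av), ncol = 1L)
  if (!ad_recording()) return(v)
  nc <- ncol(av)
  ad_node(v, list(a), function(g) {
    list(if (is_nd(a)) matrix(g, nrow(g), nc) else NULL)
  })
}

ad_sum_all <- function(a) {
  av <- ad_val(a)
  v <- matrix(sum(av), 1L, 1L)
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) {
    list(if (is_nd(a)) matrix(as.numeric(g), nrow(av), ncol(av)) else NULL)
  })
}

ad_mean_all <- function(a) {
  av <- ad_val(a)
  n <- length(av)
  v <- matrix(sum(av) / n, 1L, 1L)
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) {
    list(if (is_nd(a)) matrix(as.numeric(g) / n, nrow(av), ncol(av)) else NULL)
  })
}

row_max <- function(av) av[cbind(seq_len(nrow(av)), max.col(av, "first"))]

ad_logsumexp_rows <- function(a) {
  av <- ad_val(a)
  m <- row_max(av)
  e <- exp(av - m)
  s <- rowSums(e)
  v <- matrix(m + log(s), ncol = 1L)
  if (!ad_recording()) return(v)
  soft <- e / s
  ad_node(v, list(a), function(g) {
    list(if (is_nd(a)) as.numeric(g) * soft else NULL)
  })
}

ad_softmax_rows <- function(a) {
  av <- ad_val(a)
  m <- row_max(av)
  e <- exp(av - m)
  y <- e / rowSums(e)
  if (!ad_recording()) return(y)
  ad_node(y, list(a), function(g) {
    if (!is_nd(a)) return(list(NULL))
    list(y * (g - rowSums(g * y)))
  })
}

# --- normalization ------------------------------------------------------------

# standardize each column to zero mean / unit (population) sd; the learnable
# affine is applied separately via ad_scale_cols / ad_add_bias
ad_standardize_cols <- function(a, eps = 1e-5) {
  av <- ad_val(a)
  n <- nrow(av)
  mu <- colMeans(av)
  xc <- av - rep(mu, each = n)
  v <- colMeans(xc * xc)
  s <- sqrt(v + eps)
  y <- xc / rep(s, each = n)
  if (!ad_recording()) return(y)
  ad_node(y, list(a), function(g) {
    if (!is_nd(a)) return(list(NULL))
    gm <- colMeans(g)
    gy <- colMeans(g * y)
    gc <- g - rep(gm, each = n) - y * rep(gy, each = n)
    list(gc / rep(s, each = n))
  })
}

# standardize each row (layer norm core)
ad_standardize_rows <- function(a, eps = 1e-5) {
  av <- ad_val(a)
  mu <- rowMeans(av)
  xc <- av - mu
  v <- rowMeans(xc * xc)
  s <- sqrt(v + eps)
  y <- xc / s
  if (!ad_recording()) return(y)
  ad_node(y, list(a), function(g) {
    if (!is_nd(a)) return(list(NULL))
    gm <- rowMeans(g)
    gy <- rowMeans(g * y)
    list((g - gm - y * gy) / s)
  })
}

# --- vector-channel operations (features of shape n x 3*nchan) ----------------

vec_rep_idx <- function(nchan) rep(seq_len(nchan), each = 3L)

# per-channel Euclidean norm -> n x nchan
ad_vec_norm <- function(a, nchan, eps = 1e-8) {
  av <- ad_val(a)
  n <- nrow(av)
  sq <- av * av
  nrm <- matrix(0, n, nchan)
  for (c in seq_len(nchan)) {
    j <- (3L * (c - 1L) + 1L):(3L * c)
    nrm[, c] <- sqrt(sq[, j[1]] + sq[, j[2]] + sq[, j[3]] + eps^2)
  }
  if (!ad_recording()) return(nrm)
  ad_node(nrm, list(a), function(g) {
    if (!is_nd(a)) return(list(NULL))
    gi <- g[, vec_rep_idx(nchan), drop = FALSE]
    ni <- nrm[, vec_rep_idx(nchan), drop = FALSE]
    list(gi * av / ni)
  })
}

vec_mix_expand <- function(Wv, nin, nout) {
  # kronecker(Wv, I3) built by direct indexing (channel-major xyz layout)
  K <- matrix(0, 3L * nin, 3L * nout)
  ci <- rep(seq_len(nin), times = nout)
  di <- rep(seq_len(nout), each = nin)
  for (k in 1:3) {
    K[cbind(3L * (ci - 1L) + k, 3L * (di - 1L) + k)] <- Wv
  }
  K
}

# mix vector channels with a (nin x nout) weight matrix, xyz untouched
ad_vec_mix <- function(a, W, nin, nout) {
  av <- ad_val(a); Wv <- ad_val(W)
  K <- vec_mix_expand(Wv, nin, nout)
  v <- av %*% K
  if (!ad_recording()) return(v)
  ad_node(v, list(a, W), function(g) {
    ga <- if (is_nd(a)) g %*% t(K) else NULL
    gW <- NULL
    if (is_nd(W)) {
      cp <- crossprod(av, g)
      gW <- matrix(0, nin, nout)
      for (c in seq_len(nin)) {
        rc <- 3L * (c - 1L)
        for (d in seq_len(nout)) {
          cd <- 3L * (d - 1L)
          gW[c, d] <- cp[rc + 1L, cd + 1L] + cp[rc + 2L, cd + 2L] +
            cp[rc + 3L, cd + 3L]
        }
      }
    }
    list(ga, gW)
  })
}

# gate each vector channel by a per-channel scalar (s: n x nchan)
ad_vec_gate <- function(a, s, nchan) {
  av <- ad_val(a); sv <- ad_val(s)
  ridx <- vec_rep_idx(nchan)
  v <- av * sv[, ridx, drop = FALSE]
  if (!ad_recording()) return(v)
  ad_node(v, list(a, s), function(g) {
    ga <- if (is_nd(a)) g * sv[, ridx, drop = FALSE] else NULL
    gs <- NULL
    if (is_nd(s)) {
      prod <- g * av
      gs <- prod[, seq(1L, 3L * nchan, by = 3L), drop = FALSE] +
        prod[, seq(2L, 3L * nchan, by = 3L), drop = FALSE] +
        prod[, seq(3L, 3L * nchan, by = 3L), drop = FALSE]
    }
    list(ga, gs)
  })
}

# scale all vector channels of each row by 1/rms of their norms (equivariant
# layer norm for the vector track; no learnable parameters)
ad_vec_rms_norm <- function(a, nchan, eps = 1e-8) {
  av <- ad_val(a)
  ssum <- rowSums(av * av)
  r <- sqrt(ssum / nchan + eps)
  y <- av / r
  if (!ad_recording()) return(y)
  ad_node(y, list(a), function(g) {
    if (!is_nd(a)) return(list(NULL))
    gdot <- rowSums(g * av)
    list(g / r - av * (gdot / (nchan * r^3)))
  })
}

# --- misc ---------------------------------------------------------------------

ad_dropout <- function(a, p) {
  if (!.ad$training || p <= 0) return(a)
  av <- ad_val(a)
  mask <- matrix((stats::runif(length(av)) > p) / (1 - p), nrow(av), ncol(av))
  v <- av * mask
  if (!ad_recording()) return(v)
  ad_node(v, list(a), function(g) list(if (is_nd(a)) g * mask else NULL))
}

ad_detach <- function(a) ad_val(a)

as_scalar <- function(x) as.numeric(ad_val(x))

# --- parameter utilities ------------------------------------------------------

# Glorot-style initialization; all parameter creation is deterministic given
# the RNG state at call time.
lin_init <- function(din, dout, bias = TRUE) {
  sd <- sqrt(2 / (din + dout))
  p <- list(W = ad_param(matrix(stats::rnorm(din * dout, sd = sd), din, dout)))
  if (bias) p$b <- ad_param(matrix(0, 1L, dout))
  p
}

norm_init <- function(d) {
  list(gamma = ad_param(matrix(1, 1L, d)), beta = ad_param(matrix(0, 1L, d)))
}

# batch/graph norm with learnable affine (statistics from the current graph)
ad_norm_affine <- function(x, p) {
  ad_add_bias(ad_scale_cols(ad_standardize_cols(x), p$gamma), p$beta)
}

# layer norm with learnable affine
ad_layernorm_affine <- function(x, p) {
  ad_add_bias(ad_scale_cols(ad_standardize_rows(x), p$gamma), p$beta)
}

# collect all ad_node leaves of a nested parameter list
collect_params <- function(x) {
  if (is_nd(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# map over nested parameter structure, replacing node values
params_to_values <- function(x) {
  if (is_nd(x)) return(x$value)
  if (is.list(x)) return(lapply(x, params_to_values))
  x
}

values_to_params <- function(x) {
  if (is.matrix(x)) return(ad_param(x))
  if (is.list(x)) return(lapply(x, values_to_params))
  x
}

# --- Adam optimizer -----------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0, clip = Inf) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$wd <- weight_decay; st$clip <- clip
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  if (is.finite(opt$clip)) {
    gn2 <- 0
    for (p in opt$params) if (!is.null(p$grad)) gn2 <- gn2 + sum(p$grad^2)
    gn <- sqrt(gn2)
    if (is.finite(gn) && gn > opt$clip) {
      fac <- opt$clip / gn
      for (p in opt$params) if (!is.null(p$grad)) p$grad <- p$grad * fac
    }
  }
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g) || anyNA(g) || any(is.infinite(g))) next
    if (opt$wd > 0) g <- g + opt$wd * p$value
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mh <- opt$m[[i]] / c1
    vh <- opt$v[[i]] / c2
    p$value <- p$value - opt$lr * mh / (sqrt(vh) + opt$eps)
  }
  invisible(NULL)
}
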