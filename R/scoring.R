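# Mixture-density head over loop-atom / pocket-residue pairs.
#
# For every (loop atom, residue) pair the head predicts a 10-component
# Gaussian mixture over their distance (minimum over the residue's heavy
# atoms).  The negative log-likelihood of the true distances is the main
# training signal; at inference the total log-likelihood of the observed
# distances serves as a conformation confidence score (higher is better).

#' Mixture density parameters for all loop-residue pairs
#'
#' Pair features are `dropout(ELU(batchnorm(linear(concat(h_res, h_loop)))))`;
#' means use an ELU + 1 offset (mu > 0), SDs an ELU + 1.1 offset
#' (sigma > 0.1), mixing coefficients a softmax.
#'
#' @param loop_h loop-atom embeddings (L x d).
#' @param res_h residue embeddings (P x d).
#' @param model a `loop_model` (uses `model$mdn`).
#' @return an `mdn_output` with `mu`, `sigma`, `pi` (n_pairs x n_comp) and
#'   the pair index (`pair_loop`, `pair_res`), ordered residue-major.
#' @export
mdn_head <- function(loop_h, res_h, model) {
  p <- model$mdn
  drop <- model$config$dropout
  L <- nrow(ad_val(loop_h)); P <- nrow(ad_val(res_h))
  pair_res <- rep(seq_len(P), each = L)
  pair_loop <- rep(seq_len(L), times = P)
  feats <- ad_cbind(ad_rows(res_h, pair_res), ad_rows(loop_h, pair_loop))
  z <- ad_dropout(ad_elu(ad_norm_affine(ad_lin(feats, p$pair), p$bn)), drop)
  one <- function(m, off) ad_add(ad_elu(ad_lin(z, m)),
                                 matrix(off, L * P, model$config$mdn_comp))
  out <- list(mu = one(p$mu, 1), sigma = one(p$sigma, 1.1),
              pi = ad_softmax_rows(ad_lin(z, p$pi)),
              pair_loop = pair_loop, pair_res = pair_res)
  class(out) <- "mdn_output"
  out
}

#' Minimum heavy-atom distances between loop atoms and residues
#'
#' @param loop_coords L x 3 matrix of loop atom coordinates.
#' @param residue_coord_list list of per-residue heavy-atom coordinate
#'   matrices (pocket order).
#' @return vector of length L * P ordered residue-major, matching
#'   [mdn_head()]'s pair index.
#' @export
pair_min_distances <- function(loop_coords, residue_coord_list) {
  stopifnot(all(is.finite(loop_coords)))
  L <- nrow(loop_coords)
  out <- numeric(L * length(residue_coord_list))
  pos <- 0L
  for (X in residue_coord_list) {
    D <- proxy_crossdist(loop_coords, X)
    out[pos + seq_len(L)] <- -row_max(-D)
    pos <- pos + L
  }
  out
}

mdn_log_prob <- function(out, d) {
  n_comp <- ncol(ad_val(out$mu))
  Dm <- matrix(d, length(d), n_comp)
  zscore <- ad_div(ad_sub(Dm, out$mu), out$sigma)
  log_n <- ad_sub(ad_scale(ad_square(zscore), -0.5),
                  ad_add(ad_log(out$sigma),
                         matrix(0.5 * log(2 * pi), length(d), n_comp)))
  ad_logsumexp_rows(ad_add(ad_log(out$pi), log_n))
}

#' Mixture-density negative log-likelihood
#'
#' Mean over pairs of `-log sum_c pi_c N(d | mu_c, sigma_c)`, restricted to
#' pairs whose true distance is at most `cutoff` (distant pairs carry no
#' structural signal and would otherwise dominate the loss).
#'
#' @param out an `mdn_output`.
#' @param d true pair distances from [pair_min_distances()].
#' @param cutoff training cutoff in Angstrom (default 12); `Inf` disables.
#' @return scalar loss (an ad node while recording, numeric otherwise).
#' @export
mdn_nll <- function(out, d, cutoff = 12) {
  if (any(ad_val(out$sigma) <= 0)) stop("sigma must be positive")
  lp <- mdn_log_prob(out, d)
  keep <- which(d <= cutoff)
  if (length(keep) == 0L) stop("no pair below the distance cutoff")
  res <- ad_scale(ad_mean_all(ad_rows(lp, keep)), -1)
  if (is_nd(res)) res else as.numeric(res)
}

#' Mixture-density confidence score of a conformation
#'
#' Sum over all pairs of the log-likelihood of the observed distances under
#' the predicted mixtures; the negative of this score acts as a statistical
#' potential, so higher scores mean more plausible conformations.
#'
#' @param out an `mdn_output`.
#' @param d observed pair distances.
#' @return numeric scalar.
#' @export
mdn_score <- function(out, d) {
  as.numeric(ad_val(ad_sum_all(mdn_log_prob(out, d))))
}
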