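# Evaluation: optimal rigid superposition, full-atom loop RMSD, success
# rates, empirical CDFs and best-of-N selection.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Returns the proper rotation (reflections excluded by determinant
#' correction) and translation minimizing the RMSD of `mobile` onto
#' `reference`, plus the RMSD after fitting.
#'
#' @param mobile,reference n x 3 coordinate matrices, matched rows, n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3; apply as
#'   `mobile %*% t(rotation) + translation`), and `rmsd`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  if (nrow(mobile) < 3L || nrow(reference) != nrow(mobile)) {
    stop("need matched coordinate sets with at least 3 points")
  }
  mc <- colMeans(mobile); rc <- colMeans(reference)
  A <- sweep(mobile, 2L, mc)
  B <- sweep(reference, 2L, rc)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- rc - as.numeric(Rm %*% mc)
  fitted <- sweep(mobile %*% t(Rm), 2L, t, "+")
  list(rotation = Rm, translation = t,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

structure_coord_df <- function(structure) {
  tb <- atom_table(structure)
  tb$key <- paste(tb$chain, tb$res_index, tb$atom, sep = "\r")
  tb
}

#' Full-atom RMSD over a loop region
#'
#' Atoms are matched by (chain, residue index, atom name); unmatched
#' reference loop atoms are an error.  With `align = "framework"` the
#' optimal superposition is fitted on the shared nonloop heavy atoms before
#' the loop RMSD is computed; with `align = "none"` coordinates are compared
#' in the shared frame directly.
#'
#' @param predicted,reference `protein_structure`s with the same loop atoms.
#' @param spec a [loop_spec()].
#' @param align `"none"` or `"framework"`.
#' @return RMSD in Angstrom.
#' @export
loop_rmsd <- function(predicted, reference, spec, align = c("none",
                                                            "framework")) {
  align <- match.arg(align)
  tp <- structure_coord_df(predicted)
  tr <- structure_coord_df(reference)
  in_loop <- function(tb) tb$chain == spec$chain_id &
    tb$res_index >= spec$start & tb$res_index <= spec$end
  lp <- tp[in_loop(tp), ]; lr <- tr[in_loop(tr), ]
  mi <- match(lr$key, lp$key)
  if (anyNA(mi)) {
    stop("loop atoms missing from prediction: ",
         paste(lr$atom[is.na(mi)], collapse = ", "))
  }
  P <- as.matrix(lp[mi, c("x", "y", "z")])
  Q <- as.matrix(lr[, c("x", "y", "z")])
  if (align == "framework") {
    fp <- tp[!in_loop(tp), ]; fr <- tr[!in_loop(tr), ]
    fi <- match(fr$key, fp$key)
    if (anyNA(fi)) stop("framework atoms missing from prediction")
    fit <- kabsch_superpose(as.matrix(fp[fi, c("x", "y", "z")]),
                            as.matrix(fr[, c("x", "y", "z")]))
    P <- sweep(P %*% t(fit$rotation), 2L, fit$translation, "+")
  }
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Fraction of predictions at or below an RMSD threshold
#'
#' A case with RMSD exactly equal to the threshold counts as a success.
#'
#' @param rmsds numeric vector of RMSDs.
#' @param threshold success threshold in Angstrom (default 2).
#' @export
success_rate <- function(rmsds, threshold = 2) {
  if (length(rmsds) == 0L) stop("empty RMSD list")
  mean(rmsds <= threshold)
}

#' Empirical cumulative distribution of RMSD values
#'
#' @param rmsds numeric vector.
#' @return data.frame of the right-continuous step points `(x, fraction)`
#'   at sorted unique values.
#' @export
rmsd_ecdf <- function(rmsds) {
  if (length(rmsds) == 0L) stop("empty RMSD list")
  x <- sort(unique(rmsds))
  data.frame(x = x,
             fraction = vapply(x, function(t) mean(rmsds <= t), 0))
}

#' Best-of-N conformation selection
#'
#' Reports both the oracle best (minimum RMSD) and the conformation the
#' confidence score would select.
#'
#' @param rmsds per-conformation RMSDs.
#' @param scores per-conformation confidence scores (higher is better).
#' @return list with `min_rmsd`, `best_id` (argmin RMSD) and `selected_id`
#'   (argmax score) plus `selected_rmsd`.
#' @export
best_of_n <- function(rmsds, scores) {
  if (length(rmsds) < 1L || length(scores) != length(rmsds)) {
    stop("need matching nonempty rmsd and score vectors")
  }
  best <- which.min(rmsds)
  sel <- which.max(scores)
  list(min_rmsd = rmsds[best], best_id = best,
       selected_id = sel, selected_rmsd = rmsds[sel])
}
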