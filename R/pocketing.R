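# Pocket selection and loop coordinate initialization.
#
# The pocket is the subset of nonloop residues kept as structural context.
# For reconstruction it is selected deterministically from anchor geometry:
# a sphere around the anchor midpoint whose radius follows
# max(half anchor separation, min(2 * loop_len, 16)) Angstrom, expanded and
# pruned as described below.  For refinement it is a plain 12 Angstrom
# distance filter around the supplied (inaccurate) loop coordinates.
# "Center of mass" is the unweighted centroid over heavy atoms throughout.

res_key <- function(chain, index) paste0(chain, ":", index)

residue_by_key <- function(structure, key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  structure$chains[[parts[1]]][[as.integer(parts[2]) + 1L]]
}

residue_com <- function(residue) {
  X <- do.call(rbind, lapply(residue$atoms, function(a) a$coords))
  colMeans(X)
}

residue_atom_coords <- function(residue) {
  do.call(rbind, lapply(residue$atoms, function(a) a$coords))
}

loop_residue_keys <- function(spec) {
  res_key(spec$chain_id, spec$start:spec$end)
}

nonloop_residue_keys <- function(structure, spec) {
  keys <- character()
  for (cid in names(structure$chains)) {
    for (r in structure$chains[[cid]]) {
      keys <- c(keys, res_key(cid, r$index))
    }
  }
  setdiff(keys, loop_residue_keys(spec))
}

anchor_keys <- function(spec) res_key(spec$chain_id, spec$anchors)

anchor_coms <- function(structure, spec) {
  validate_loop_spec(structure, spec)
  ak <- anchor_keys(spec)
  list(a1 = residue_com(residue_by_key(structure, ak[1])),
       a2 = residue_com(residue_by_key(structure, ak[2])))
}

new_pocket <- function(residue_ids, midpoint, radius) {
  structure(list(residue_ids = sort(unique(residue_ids)),
                 midpoint = midpoint, radius = radius),
            class = "pocket_selection")
}

#' Select the surface pocket around a loop from anchor geometry
#'
#' The pocket radius is `max(half anchor separation, min(2 * L, 16))`
#' Angstrom for a loop of `L` residues.  If the radius exceeds 20 Angstrom,
#' pseudo-loop points are interpolated linearly between the anchors and
#' residues within 12 Angstrom of any point are kept.  Otherwise residues
#' whose centroid lies in the radius sphere form the initial pocket; a
#' larger sphere (radius + 12) adds candidates, of which those pointing in a
#' direction (from the midpoint) within `prune_angle` degrees of an
#' inner-sphere residue are pruned; finally residues within `augment_cutoff`
#' Angstrom of any selected residue are added.  Anchors are always included.
#'
#' @param structure a `protein_structure`.
#' @param spec a [loop_spec()].
#' @param prune_angle angular threshold in degrees for the direction-
#'   similarity pruning of outer-sphere residues.
#' @param augment_cutoff heavy-atom distance (Angstrom) for the final
#'   augmentation step (the midpoint of the 5-7 Angstrom band).
#' @return a `pocket_selection` with residue keys (`"chain:index"`), the
#'   anchor midpoint and the pocket radius.
#' @export
select_surface_pocket <- function(structure, spec, prune_angle = 15,
                                  augment_cutoff = 6) {
  ac <- anchor_coms(structure, spec)
  L <- spec$end - spec$start + 1L
  midpoint <- (ac$a1 + ac$a2) / 2
  sep <- vnorm(ac$a2 - ac$a1)
  radius <- max(sep / 2, min(2 * L, 16))
  nl_keys <- nonloop_residue_keys(structure, spec)
  coms <- t(vapply(nl_keys, function(k)
    residue_com(residue_by_key(structure, k)), numeric(3)))

  if (radius > 20) {
    frac <- seq_len(L) / (L + 1)
    pts <- outer(frac, ac$a2 - ac$a1) + matrix(ac$a1, L, 3L, byrow = TRUE)
    keep <- vapply(nl_keys, function(k) {
      X <- residue_atom_coords(residue_by_key(structure, k))
      dmin <- min(vapply(seq_len(nrow(pts)), function(i)
        min(sqrt(rowSums(sweep(X, 2L, pts[i, ])^2))), 0))
      dmin <= 12
    }, TRUE)
    selected <- nl_keys[keep]
  } else {
    d_mid <- sqrt(rowSums(sweep(coms, 2L, midpoint)^2))
    ss <- nl_keys[d_mid <= radius]
    bs_only <- nl_keys[d_mid > radius & d_mid <= radius + 12]
    if (length(bs_only) && length(ss)) {
      dirs <- sweep(coms, 2L, midpoint)
      dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
      ss_dirs <- dirs[match(ss, nl_keys), , drop = FALSE]
      cos_thr <- cos(prune_angle * pi / 180)
      pruned <- vapply(bs_only, function(k) {
        v <- dirs[match(k, nl_keys), ]
        any(ss_dirs %*% v >= cos_thr)
      }, TRUE)
      bs_only <- bs_only[!pruned]
    }
    selected <- c(ss, bs_only)
    # augmentation: residues close to the already selected pocket
    remaining <- setdiff(nl_keys, selected)
    if (length(remaining) && length(selected)) {
      sel_X <- do.call(rbind, lapply(selected, function(k)
        residue_atom_coords(residue_by_key(structure, k))))
      add <- vapply(remaining, function(k) {
        X <- residue_atom_coords(residue_by_key(structure, k))
        min(as.matrix(proxy_crossdist(X, sel_X))) <= augment_cutoff
      }, TRUE)
      selected <- c(selected, remaining[add])
    }
  }
  selected <- union(selected, anchor_keys(spec))
  new_pocket(selected, midpoint, radius)
}

# min-free cross distance matrix (avoids a package dependency)
proxy_crossdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(D2, 0))
}

#' Select the refinement pocket around an existing loop conformation
#'
#' Keeps every nonloop residue having any heavy atom within `cutoff`
#' Angstrom of any supplied loop atom.
#'
#' @param structure a `protein_structure`.
#' @param spec a [loop_spec()] identifying which residues are loop.
#' @param raw_loop_coords matrix of existing (possibly inaccurate) loop atom
#'   coordinates.
#' @param cutoff distance threshold in Angstrom (default 12).
#' @return a `pocket_selection`; empty pockets trigger a warning.
#' @export
select_refinement_pocket <- function(structure, spec, raw_loop_coords,
                                     cutoff = 12) {
  if (is.null(raw_loop_coords) || nrow(raw_loop_coords) == 0L) {
    stop("raw loop coordinates must be nonempty")
  }
  nl_keys <- nonloop_residue_keys(structure, spec)
  keep <- vapply(nl_keys, function(k) {
    X <- residue_atom_coords(residue_by_key(structure, k))
    min(proxy_crossdist(X, raw_loop_coords)) <= cutoff
  }, TRUE)
  selected <- nl_keys[keep]
  if (length(selected) == 0L) {
    warning("refinement pocket is empty: no residue within ", cutoff,
            " Angstrom of the supplied loop")
  }
  new_pocket(selected, colMeans(raw_loop_coords), 12)
}

loop_atom_counts <- function(structure, spec) {
  vapply(spec$start:spec$end, function(i) {
    length(structure$chains[[spec$chain_id]][[i + 1L]]$atoms)
  }, 0L)
}

#' Initialize loop coordinates for reconstruction
#'
#' Target centers for the loop residues divide the segment between the two
#' anchor centroids uniformly (residue i of L sits at fraction i/(L+1));
#' every atom of residue i is drawn independently from an isotropic Gaussian
#' with that center and per-axis standard deviation `sd`.
#'
#' @param structure a `protein_structure`.
#' @param spec a [loop_spec()].
#' @param sd per-axis standard deviation in Angstrom (default 1.75, the
#'   single-conformation setting).
#' @param seed integer seed.
#' @return a `loop_init` with `coords` (n_loop_atoms x 3), `mode`, `sd`,
#'   `seed`.
#' @export
init_loop_reconstruction <- function(structure, spec, sd = 1.75, seed = 0L) {
  if (sd <= 0) stop("sd must be positive")
  ac <- anchor_coms(structure, spec)
  L <- spec$end - spec$start + 1L
  counts <- loop_atom_counts(structure, spec)
  set.seed(seed)
  coords <- matrix(0, sum(counts), 3L)
  pos <- 0L
  for (i in seq_len(L)) {
    center <- ac$a1 + (i / (L + 1)) * (ac$a2 - ac$a1)
    n <- counts[i]
    coords[pos + seq_len(n), ] <-
      matrix(stats::rnorm(3L * n, sd = sd), n, 3L) +
      matrix(center, n, 3L, byrow = TRUE)
    pos <- pos + n
  }
  structure(list(coords = coords, mode = "reconstruction", sd = sd,
                 seed = as.integer(seed)), class = "loop_init")
}

#' Initialize loop coordinates for refinement
#'
#' Every loop atom is drawn from an isotropic Gaussian centered at the
#' overall centroid of the supplied raw loop with per-axis SD `sd`.
#'
#' @param raw_loop_coords matrix of existing loop atom coordinates.
#' @param sd per-axis standard deviation in Angstrom (default 4).
#' @param seed integer seed.
#' @export
init_loop_refinement <- function(raw_loop_coords, sd = 4, seed = 0L) {
  if (sd <= 0) stop("sd must be positive")
  if (is.null(raw_loop_coords) || nrow(raw_loop_coords) == 0L) {
    stop("raw loop coordinates must be nonempty")
  }
  com <- colMeans(raw_loop_coords)
  n <- nrow(raw_loop_coords)
  set.seed(seed)
  coords <- matrix(stats::rnorm(3L * n, sd = sd), n, 3L) +
    matrix(com, n, 3L, byrow = TRUE)
  structure(list(coords = coords, mode = "refinement", sd = sd,
                 seed = as.integer(seed)), class = "loop_init")
}

#' Independent initializations for multi-conformation generation
#'
#' @param structure,spec as in [init_loop_reconstruction()].
#' @param n number of conformations.
#' @param sd per-axis SD in Angstrom; 7 is the multi-conformation setting
#'   (versus 1.75 for single conformations).
#' @param seeds integer vector of distinct seeds, one per conformation.
#' @return list of `loop_init` objects (mode `"multiconf"`).
#' @export
init_multiconf <- function(structure, spec, n = 5L, sd = 7,
                           seeds = seq_len(n) - 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (length(seeds) != n) stop("need exactly one seed per conformation")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  lapply(seeds, function(s) {
    ini <- init_loop_reconstruction(structure, spec, sd = sd, seed = s)
    ini$mode <- "multiconf"
    ini
  })
}
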