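# The three graph levels.
#
# * atom graph: covalent bonds over pocket + loop atoms; purely topological
#   scalar features (the atom encoder never sees coordinates).
# * residue graph: directed K-nearest-neighbor graph over pocket residues
#   with rotation-invariant scalar features and rotation-equivariant
#   3-vector features.
# * interaction graph: loop atoms and pocket residues jointly, with all
#   loop-loop pairs, the inherited residue KNN topology, and a complete
#   bipartite loop-residue edge set.  Edge scalars carry a one-hot edge type
#   and a distance feature (-1 for loop-residue edges at construction, since
#   loop coordinates are still random there).

ELEMENTS <- c("C", "N", "O", "S")

one_hot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  ok <- !is.na(idx) & idx >= 1L & idx <= n
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

# residues kept for a task, ordered by (chain, index)
task_residue_keys <- function(structure, pocket, spec) {
  keys <- union(pocket$residue_ids, loop_residue_keys(spec))
  parts <- strsplit(keys, ":", fixed = TRUE)
  ord <- order(vapply(parts, `[`, "", 1L),
               as.integer(vapply(parts, `[`, "", 2L)))
  keys[ord]
}

#' Build the covalent atom graph over pocket and loop residues
#'
#' Node scalars concatenate an element one-hot (C, N, O, S, other), the
#' residue-type one-hot, a backbone flag and a covalent-degree one-hot.
#' Edge scalars are a bond-type one-hot (intra-residue vs peptide).  Every
#' covalent bond appears in both directions.
#'
#' @param structure a `protein_structure`.
#' @param pocket a `pocket_selection`.
#' @param spec a [loop_spec()].
#' @return an `atom_graph` list.
#' @export
build_atom_graph <- function(structure, pocket, spec) {
  keys <- task_residue_keys(structure, pocket, spec)
  tb <- atom_table(structure)
  tb_key <- res_key(tb$chain, tb$res_index)
  keep <- tb_key %in% keys
  keep_idx <- which(keep)
  sub <- tb[keep, , drop = FALSE]
  n <- nrow(sub)
  atom2res <- match(tb_key[keep], keys)
  if (anyNA(atom2res)) stop("atom without residue assignment")

  bonds <- derive_covalent_bonds(structure)
  bkeep <- bonds[, 1] %in% keep_idx & bonds[, 2] %in% keep_idx
  bonds <- bonds[bkeep, , drop = FALSE]
  b1 <- match(bonds[, 1], keep_idx)
  b2 <- match(bonds[, 2], keep_idx)
  src <- c(b1, b2)
  dst <- c(b2, b1)
  peptide <- atom2res[b1] != atom2res[b2]
  etype <- c(peptide, peptide)

  degree <- tabulate(c(b1, b2), nbins = n)
  elem_idx <- match(sub$element, ELEMENTS)
  elem_oh <- cbind(one_hot(elem_idx, 4L), as.numeric(is.na(elem_idx)))
  res_oh <- one_hot(match(sub$res_name, AA3), 20L)
  deg_oh <- one_hot(pmin(degree, 5L) + 1L, 6L)
  # atom-name one-hot and a sequence-position encoding: without them the
  # interior atoms of a long uniform segment have identical receptive
  # fields and collapse to one embedding, leaving loop atoms unaddressable
  name_oh <- one_hot(match(sub$atom, c("N", "CA", "C", "O", "CB")), 5L)
  name_oh <- cbind(name_oh, as.numeric(rowSums(name_oh) == 0))
  pos <- sub$res_index
  pos_enc <- cbind(sin(pos / 2), cos(pos / 2), sin(pos / 8), cos(pos / 8),
                   sin(pos / 32), cos(pos / 32))
  node_s <- cbind(elem_oh, res_oh, as.numeric(sub$is_backbone), deg_oh,
                  name_oh, pos_enc)
  edge_s <- cbind(1 - etype, as.numeric(etype))

  loop_atom <- sub$chain == spec$chain_id &
    sub$res_index >= spec$start & sub$res_index <= spec$end

  structure(list(
    node_s = node_s, src = src, dst = dst, edge_s = edge_s,
    coords = as.matrix(sub[, c("x", "y", "z")]),
    atom2res = atom2res, res_keys = keys, loop_atom = loop_atom,
    keep_idx = keep_idx, atoms = sub,
    elem_class = ifelse(is.na(elem_idx), 5L, elem_idx),
    bond_class = as.integer(etype) + 1L
  ), class = "atom_graph")
}

rbf_expand <- function(d, n = 16L, d_max = 20) {
  centers <- seq(0, d_max, length.out = n)
  sigma <- centers[2] - centers[1]
  exp(-((outer(d, centers, "-") / sigma)^2))
}

backbone_dihedrals <- function(structure, cid, idx) {
  res <- structure$chains[[cid]]
  getc <- function(i, nm) {
    if (i < 0L || i > length(res) - 1L) return(NULL)
    r <- res[[i + 1L]]
    for (a in r$atoms) if (a$name == nm) return(a$coords)
    NULL
  }
  phi <- psi <- omega <- NA_real_
  cN <- getc(idx, "N"); cCA <- getc(idx, "CA"); cC <- getc(idx, "C")
  pC <- getc(idx - 1L, "C")
  nN <- getc(idx + 1L, "N"); nCA <- getc(idx + 1L, "CA")
  if (!is.null(pC) && !is.null(cN) && !is.null(cCA) && !is.null(cC)) {
    phi <- dihedral_angle(pC, cN, cCA, cC)
  }
  if (!is.null(cN) && !is.null(cCA) && !is.null(cC) && !is.null(nN)) {
    psi <- dihedral_angle(cN, cCA, cC, nN)
  }
  if (!is.null(cCA) && !is.null(cC) && !is.null(nN) && !is.null(nCA)) {
    omega <- dihedral_angle(cCA, cC, nN, nCA)
  }
  c(phi = phi, psi = psi, omega = omega)
}

residue_ca <- function(residue) {
  for (a in residue$atoms) if (a$name == "CA") return(a$coords)
  stop("residue ", residue$chain_id, ":", residue$index, " has no CA atom")
}

#' Build the K-nearest-neighbor residue graph over the pocket
#'
#' Nodes are pocket residues positioned at their CA atoms.  Each node
#' receives directed edges from its `min(K, N - 1)` nearest neighbors by
#' CA-CA distance (ties broken by lower residue order).  Scalar node
#' features: residue one-hot plus sin/cos of the backbone dihedrals with
#' validity flags.  Vector node features: unit vectors to the next and
#' previous CA along the chain and to the side-chain centroid.  Scalar edge
#' features: a 16-bin radial basis expansion of the CA distance on
#' [0, 20] Angstrom plus a signed sequence-separation encoding.  Vector edge
#' features: the unit displacement from source to target CA.
#'
#' @param structure a `protein_structure`.
#' @param pocket a `pocket_selection`.
#' @param K neighbor count (default 30).
#' @return a `residue_graph` list.
#' @export
build_residue_graph <- function(structure, pocket, K = 30L) {
  if (K < 1L) stop("K must be >= 1")
  keys <- pocket$residue_ids
  parts <- strsplit(keys, ":", fixed = TRUE)
  cids <- vapply(parts, `[`, "", 1L)
  idxs <- as.integer(vapply(parts, `[`, "", 2L))
  ord <- order(cids, idxs)
  keys <- keys[ord]; cids <- cids[ord]; idxs <- idxs[ord]
  n <- length(keys)
  residues <- lapply(keys, function(k) residue_by_key(structure, k))
  ca <- t(vapply(residues, residue_ca, numeric(3)))

  # scalar node features
  res_oh <- one_hot(match(vapply(residues, function(r) r$name, ""), AA3), 20L)
  dihed <- t(vapply(seq_len(n), function(i)
    backbone_dihedrals(structure, cids[i], idxs[i]), numeric(3)))
  valid <- !is.na(dihed)
  rad <- dihed * pi / 180
  rad[!valid] <- 0
  node_s <- cbind(res_oh, sin(rad), cos(rad) * valid, valid * 1)

  # vector node features (3 channels): forward CA, backward CA, side chain
  node_v <- matrix(0, n, 9L)
  for (i in seq_len(n)) {
    chain <- structure$chains[[cids[i]]]
    if (idxs[i] + 1L <= length(chain) - 1L) {
      node_v[i, 1:3] <- vunit(residue_ca(chain[[idxs[i] + 2L]]) - ca[i, ])
    }
    if (idxs[i] - 1L >= 0L) {
      node_v[i, 4:6] <- vunit(residue_ca(chain[[idxs[i]]]) - ca[i, ])
    }
    sc <- Filter(function(a) !a$is_backbone, residues[[i]]$atoms)
    if (length(sc)) {
      cen <- colMeans(do.call(rbind, lapply(sc, function(a) a$coords)))
      node_v[i, 7:9] <- vunit(cen - ca[i, ])
    }
  }

  # KNN edges (directed: src is an in-neighbor of dst)
  D <- as.matrix(stats::dist(ca))
  k_eff <- min(K, n - 1L)
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ordN <- others[order(D[i, others], others)]
    nb <- ordN[seq_len(k_eff)]
    src <- c(src, nb)
    dst <- c(dst, rep(i, k_eff))
  }
  # canonical edge order (by target, then source): the KNN selection order
  # depends on floating-point distance ties, the feature tables must not
  ord_e <- order(dst, src)
  src <- src[ord_e]; dst <- dst[ord_e]
  d_edge <- D[cbind(src, dst)]
  sep <- ifelse(cids[src] == cids[dst], idxs[dst] - idxs[src], 0)
  same_chain <- as.numeric(cids[src] == cids[dst])
  edge_s <- cbind(rbf_expand(d_edge), tanh(sep / 10), same_chain)
  edge_v <- (ca[dst, , drop = FALSE] - ca[src, , drop = FALSE]) /
    pmax(d_edge, 1e-12)

  structure(list(
    node_s = node_s, node_v = node_v, seq_codes = match(
      vapply(residues, function(r) r$name, ""), AA3, nomatch = 21L),
    src = src, dst = dst, edge_s = edge_s, edge_v = edge_v,
    coords = ca, keys = keys, K = k_eff
  ), class = "residue_graph")
}

# edge topology of the interaction graph; features are (re)built by
# interaction_edge_features()
interaction_topology <- function(n_loop, n_res, knn_src, knn_dst,
                                 loop_coords = NULL, loop_k = Inf) {
  src <- integer(0); dst <- integer(0); type <- integer(0)
  if (n_loop > 1L) {
    if (is.finite(loop_k) && loop_k < n_loop - 1L) {
      D <- as.matrix(stats::dist(loop_coords))
      for (i in seq_len(n_loop)) {
        others <- setdiff(seq_len(n_loop), i)
        nb <- others[order(D[i, others], others)][seq_len(loop_k)]
        src <- c(src, nb); dst <- c(dst, rep(i, loop_k))
      }
    } else {
      pairs <- expand.grid(src = seq_len(n_loop), dst = seq_len(n_loop))
      pairs <- pairs[pairs$src != pairs$dst, ]
      src <- c(src, pairs$src); dst <- c(dst, pairs$dst)
    }
    type <- c(type, rep(1L, length(src)))
  }
  if (length(knn_src)) {
    src <- c(src, knn_src + n_loop); dst <- c(dst, knn_dst + n_loop)
    type <- c(type, rep(2L, length(knn_src)))
  }
  lr <- expand.grid(l = seq_len(n_loop), r = seq_len(n_res))
  src <- c(src, lr$l, lr$r + n_loop)
  dst <- c(dst, lr$r + n_loop, lr$l)
  type <- c(type, rep(3L, 2L * nrow(lr)))
  list(src = src, dst = dst, type = type)
}

# edge scalar features: one-hot type + distance; loop-residue distances are
# -1 unless refresh_cross is TRUE (recycling refresh)
interaction_edge_features <- function(ig, x, refresh_cross = FALSE) {
  xd <- ad_val(x)
  d <- sqrt(rowSums((xd[ig$dst, , drop = FALSE] -
                       xd[ig$src, , drop = FALSE])^2))
  if (!refresh_cross) d[ig$type == 3L] <- -1
  cbind(one_hot(ig$type, 3L), d)
}

#' Build the loop-atom / pocket-residue interaction graph
#'
#' Nodes are the loop atoms followed by the pocket residues; node embeddings
#' come from the encoder stage (graph-transformer rows for loop atoms,
#' merged hierarchical embeddings for residues).  Edges: all ordered
#' loop-loop pairs, the residue KNN topology, and a complete bipartite
#' loop-residue set whose distance feature is -1 at construction.
#'
#' @param loop_embeddings n_loop x d matrix (or ad node).
#' @param loop_init a `loop_init` providing initial loop coordinates.
#' @param residue_embeddings n_res x d matrix (or ad node).
#' @param residue_graph the pocket `residue_graph` (KNN topology + CA
#'   coordinates).
#' @return an `interaction_graph` list.
#' @export
build_interaction_graph <- function(loop_embeddings, loop_init,
                                    residue_embeddings, residue_graph,
                                    loop_k = Inf, topo = NULL) {
  n_loop <- nrow(ad_val(loop_embeddings))
  n_res <- nrow(ad_val(residue_embeddings))
  if (ncol(ad_val(loop_embeddings)) != ncol(ad_val(residue_embeddings))) {
    stop("embedding widths of loop atoms and residues must match")
  }
  if (nrow(loop_init$coords) != n_loop) {
    stop("loop_init coordinate count does not match loop embeddings")
  }
  if (is.null(topo)) {
    topo <- interaction_topology(n_loop, n_res,
                                 residue_graph$src, residue_graph$dst,
                                 loop_coords = loop_init$coords,
                                 loop_k = loop_k)
  }
  ig <- structure(list(
    n_loop = n_loop, n_res = n_res,
    src = topo$src, dst = topo$dst, type = topo$type,
    h0 = ad_rbind(loop_embeddings, residue_embeddings),
    x0 = rbind(loop_init$coords, residue_graph$coords),
    node_kind = rep(c("loop_atom", "residue"), c(n_loop, n_res))
  ), class = "interaction_graph")
  ig$e0 <- interaction_edge_features(ig, ig$x0, refresh_cross = FALSE)
  ig
}
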