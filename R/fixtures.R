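# Synthetic structure generation.
#
# Idealized full-backbone chains (N, CA, C, O plus CB, or a small leucine
# side chain) are built by sequential internal-coordinate placement so that
# every downstream stage can be exercised on structures with exactly known
# ground-truth loop coordinates.  Geometry uses standard bond lengths and
# idealized angles; helix and strand segments use canonical torsions and
# loop segments draw torsions uniformly from broadly allowed backbone
# ranges under the recipe seed.

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
BOND_CA_CB <- 1.521

ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
ANGLE_N_CA_CB <- 110.5

TORSION_HELIX <- c(phi = -57, psi = -47, omega = 180)
TORSION_STRAND <- c(phi = -139, psi = 135, omega = 180)

# allowed backbone ranges for random loop torsions (degrees)
LOOP_PHI_RANGE <- c(-160, -50)
LOOP_PSI_RANGE <- c(-60, 170)

#' Recipe for a synthetic chain
#'
#' @param segments list of segments, each `list(kind, length)` with kind one
#'   of `"helix"`, `"strand"`, `"loop"`, or `list(kind = "fixed", torsions =
#'   <length x 3 matrix>)` for explicit per-residue (phi, psi, omega).
#' @param residue_name 3-letter residue code used for every residue
#'   (`"ALA"`, `"GLY"` or `"LEU"`).
#' @param seed integer seed controlling random loop torsions.
#' @export
chain_recipe <- function(segments, residue_name = "ALA", seed = 0L) {
  for (sg in segments) {
    if (!sg$kind %in% c("helix", "strand", "loop", "fixed")) {
      stop("unknown segment kind: ", sg$kind)
    }
    if (sg$kind == "fixed") {
      if (any(sg$torsions <= -180 | sg$torsions > 180)) {
        stop("torsions must lie in (-180, 180]")
      }
    } else if (sg$length < 1L) stop("segment lengths must be >= 1")
  }
  if (!residue_name %in% names(SIDECHAIN_BONDS)) {
    stop("unsupported residue name: ", residue_name)
  }
  structure(list(segments = segments, residue_name = residue_name,
                 seed = as.integer(seed)), class = "chain_recipe")
}

recipe_torsions <- function(recipe) {
  rows <- list()
  set.seed(recipe$seed)
  for (sg in recipe$segments) {
    if (sg$kind == "fixed") {
      rows[[length(rows) + 1L]] <- sg$torsions
    } else if (sg$kind == "loop") {
      n <- sg$length
      phi <- stats::runif(n, LOOP_PHI_RANGE[1], LOOP_PHI_RANGE[2])
      psi <- stats::runif(n, LOOP_PSI_RANGE[1], LOOP_PSI_RANGE[2])
      rows[[length(rows) + 1L]] <- cbind(phi, psi, omega = rep(180, n))
    } else {
      t <- if (sg$kind == "helix") TORSION_HELIX else TORSION_STRAND
      rows[[length(rows) + 1L]] <-
        matrix(t, sg$length, 3L, byrow = TRUE,
               dimnames = list(NULL, c("phi", "psi", "omega")))
    }
  }
  do.call(rbind, rows)
}

# leucine side-chain internal coordinates beyond CB (built off CA-CB)
build_leu_sidechain <- function(n, ca, cb) {
  cg <- nerf_place(n, ca, cb, 1.530, 116.3, -60)
  cd1 <- nerf_place(ca, cb, cg, 1.521, 110.7, 175)
  cd2 <- nerf_place(ca, cb, cg, 1.521, 110.7, -65)
  list(CG = cg, CD1 = cd1, CD2 = cd2)
}

backbone_from_torsions <- function(tors) {
  n <- nrow(tors)
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  ang <- ANGLE_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANGLE_CA_C_N, tors[i - 1, "psi"])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANGLE_C_N_CA, tors[i - 1, "omega"])
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANGLE_N_CA_C, tors[i, "phi"])
  }
  list(N = N, CA = CA, C = C)
}

#' Build an idealized chain from a recipe
#'
#' @param recipe a [chain_recipe()].
#' @param chain_id chain identifier for the resulting structure.
#' @return a `protein_structure` with one chain.
#' @export
build_chain <- function(recipe, chain_id = "A") {
  tors <- recipe_torsions(recipe)
  n <- nrow(tors)
  bb <- backbone_from_torsions(tors)
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    atoms <- list(
      new_atom("N", "N", bb$N[i, ]),
      new_atom("CA", "C", bb$CA[i, ]),
      new_atom("C", "C", bb$C[i, ]))
    # carbonyl O anti to the next N (torsion psi + 180 about N-CA-C)
    atoms[[4L]] <- new_atom("O", "O", nerf_place(
      bb$N[i, ], bb$CA[i, ], bb$C[i, ],
      BOND_C_O, ANGLE_CA_C_O, tors[i, "psi"] + 180))
    if (recipe$residue_name != "GLY") {
      cb <- nerf_place(bb$N[i, ], bb$C[i, ], bb$CA[i, ],
                       BOND_CA_CB, ANGLE_N_CA_CB, 122.6)
      atoms[[length(atoms) + 1L]] <- new_atom("CB", "C", cb)
      if (recipe$residue_name == "LEU") {
        sc <- build_leu_sidechain(bb$N[i, ], bb$CA[i, ], cb)
        for (nm in names(sc)) {
          atoms[[length(atoms) + 1L]] <- new_atom(nm, "C", sc[[nm]])
        }
      }
    }
    residues[[i]] <- new_residue(i - 1L, recipe$residue_name, chain_id, atoms)
  }
  protein_structure(stats::setNames(list(residues), chain_id),
                    title = "synthetic chain")
}

# smallest heavy-atom distance between non-bonded atom pairs more than two
# residues apart; used to reject self-clashing loop conformations
min_nonlocal_distance <- function(structure) {
  tb <- atom_table(structure)
  X <- as.matrix(tb[, c("x", "y", "z")])
  sep <- abs(outer(tb$res_index, tb$res_index, "-"))
  D <- as.matrix(stats::dist(X))
  D[sep <= 2L] <- Inf
  min(D)
}

#' Generate a helix-loop-helix modeling task with known ground truth
#'
#' Builds a single-chain structure of two idealized helical flanks joined by
#' a random-torsion loop, together with the loop specification and the true
#' loop coordinates.  Loop torsions are resampled (up to `max_resample`
#' times) until no heavy-atom pair more than two residues apart comes closer
#' than 1.5 Angstrom.
#'
#' @param n_flank1,n_flank2 helix lengths in residues.
#' @param loop_len loop length in residues; must be at least 4, the minimum
#'   length at which a segment is treated as a loop.
#' @param seed integer seed.
#' @param residue_name residue type used throughout (default poly-alanine).
#' @return list with `structure`, `spec` (a [loop_spec()]), and `truth`
#'   (matrix of ground-truth loop atom coordinates in atom-table order).
#' @export
make_loop_task <- function(n_flank1, loop_len, n_flank2, seed = 0L,
                           residue_name = "ALA", max_resample = 100L) {
  if (loop_len < 4L) stop("loop_len must be >= 4")
  for (attempt in seq_len(max_resample)) {
    rec <- chain_recipe(list(
      list(kind = "helix", length = n_flank1),
      list(kind = "loop", length = loop_len),
      list(kind = "helix", length = n_flank2)),
      residue_name = residue_name,
      seed = as.integer(seed) + 100003L * (attempt - 1L))
    st <- build_chain(rec)
    if (min_nonlocal_distance(st) >= 1.5) break
    if (attempt == max_resample) {
      stop("could not sample a clash-free loop in ", max_resample, " tries")
    }
  }
  sp <- loop_spec("A", n_flank1, n_flank1 + loop_len - 1L)
  tb <- atom_table(st)
  mask <- loop_mask(st, sp)
  truth <- as.matrix(tb[mask, c("x", "y", "z")])
  dimnames(truth) <- NULL
  list(structure = st, spec = sp, truth = truth)
}
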