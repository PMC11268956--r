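# Protein structure container, PDB I/O, loop specification and covalent
# bond derivation.
#
# Structures are stored hierarchically (chains -> residues -> atoms) with a
# flat atom table cached for the graph-building stages.  Residues are indexed
# 0-based and contiguously within each chain; the original PDB numbering
# (including insertion codes) is kept in `auth_seq_id` for round-tripping.
# Hydrogens are dropped everywhere: "full-atom" here means all heavy atoms.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# intra-residue heavy-atom bond templates (backbone N-CA, CA-C, C-O are
# common to all residues and added separately)
SIDECHAIN_BONDS <- list(
  GLY = list(),
  ALA = list(c("CA", "CB")),
  SER = list(c("CA", "CB"), c("CB", "OG")),
  CYS = list(c("CA", "CB"), c("CB", "SG")),
  THR = list(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2")),
  VAL = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2")),
  LEU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  ILE = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  MET = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PRO = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  PHE = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  TYR = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
             c("CZ", "OH")),
  TRP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
             c("CD2", "CE3"), c("CE2", "CZ2"), c("CZ2", "CH2"),
             c("CH2", "CZ3"), c("CZ3", "CE3")),
  ASP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  ASN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  GLU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "OE2")),
  GLN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "NE2")),
  LYS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
             c("CE", "NZ")),
  ARG = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
             c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  HIS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"), c("ND1", "CE1"),
             c("CE1", "NE2"), c("NE2", "CD2"), c("CG", "CD2"))
)

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  if (nchar(nm) == 0L) return("X")
  first <- substr(nm, 1L, 1L)
  if (first %in% c("C", "N", "O", "S", "P", "H")) first else first
}

#' Construct an atom
#' @param name PDB atom name.
#' @param element element symbol.
#' @param coords length-3 numeric vector in Angstrom.
#' @export
new_atom <- function(name, element, coords) {
  list(name = name, element = element, coords = as.numeric(coords),
       is_backbone = name %in% BACKBONE_ATOMS)
}

#' Construct a residue
#' @param index 0-based position within the chain.
#' @param name 3-letter amino-acid code.
#' @param chain_id single-character chain id.
#' @param atoms ordered list of atoms from [new_atom()].
#' @param auth_seq_id original PDB residue number (defaults to `index + 1`).
#' @export
new_residue <- function(index, name, chain_id, atoms, auth_seq_id = NULL) {
  list(index = index, name = name, chain_id = chain_id, atoms = atoms,
       auth_seq_id = if (is.null(auth_seq_id)) as.character(index + 1L)
                     else auth_seq_id)
}

#' Construct a protein structure from chains of residues
#'
#' @param chains named list (by chain id) of lists of residues.
#' @param title free-text title.
#' @return an object of class `protein_structure`.
#' @export
protein_structure <- function(chains, title = "") {
  st <- list(chains = chains, title = title)
  class(st) <- "protein_structure"
  validate_structure(st)
  st
}

validate_structure <- function(st) {
  for (cid in names(st$chains)) {
    res <- st$chains[[cid]]
    idx <- vapply(res, function(r) r$index, 0L)
    if (length(idx) && !identical(as.integer(idx), seq_along(idx) - 1L)) {
      stop("residue indices in chain ", cid, " must be contiguous from 0")
    }
    for (r in res) {
      nms <- vapply(r$atoms, function(a) a$name, "")
      if (anyDuplicated(nms)) {
        stop("duplicate atom name in chain ", cid, " residue ", r$index)
      }
      for (a in r$atoms) {
        if (!all(is.finite(a$coords)) || length(a$coords) != 3L) {
          stop("non-finite atom coordinates in chain ", cid)
        }
      }
    }
  }
  invisible(st)
}

#' Flat atom table of a structure
#'
#' One row per heavy atom, in chain/residue/atom order.  This flat view is
#' what the masking, pocket and graph stages operate on.
#'
#' @param structure a `protein_structure`.
#' @return data.frame with chain, residue index/name, atom name, element,
#'   coordinates and backbone flag.
#' @export
atom_table <- function(structure) {
  rows <- list()
  k <- 0L
  for (cid in names(structure$chains)) {
    for (r in structure$chains[[cid]]) {
      for (a in r$atoms) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          chain = cid, res_index = r$index, res_name = r$name,
          auth_seq_id = r$auth_seq_id, atom = a$name, element = a$element,
          x = a$coords[1], y = a$coords[2], z = a$coords[3],
          is_backbone = a$is_backbone, stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(chain = character(), res_index = integer(),
                      res_name = character(), auth_seq_id = character(),
                      atom = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      is_backbone = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Coordinate matrix of all heavy atoms, in atom-table order
#' @param structure a `protein_structure`.
#' @export
atom_coords <- function(structure) {
  tb <- atom_table(structure)
  as.matrix(tb[, c("x", "y", "z")])
}

n_atoms <- function(structure) nrow(atom_table(structure))

#' Loop region specification
#'
#' @param chain_id chain containing the loop.
#' @param start 0-based index of the first loop residue.
#' @param end 0-based index of the last loop residue (inclusive).
#' @return a `loop_spec` with derived anchor indices (`start - 1`,
#'   `end + 1`), the nonloop residues immediately flanking the loop.
#' @export
loop_spec <- function(chain_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (end < start) stop("loop end must be >= start")
  sp <- list(chain_id = chain_id, start = start, end = end,
             anchors = c(start - 1L, end + 1L))
  class(sp) <- "loop_spec"
  sp
}

validate_loop_spec <- function(structure, spec) {
  if (!spec$chain_id %in% names(structure$chains)) {
    stop("chain ", spec$chain_id, " not present in structure")
  }
  n <- length(structure$chains[[spec$chain_id]])
  if (spec$anchors[1] < 0L || spec$anchors[2] > n - 1L) {
    stop("both anchor residues must exist: loop at a chain terminus is not ",
         "supported (anchors ", spec$anchors[1], ", ", spec$anchors[2],
         " for chain of length ", n, ")")
  }
  invisible(spec)
}

#' Boolean mask over all atoms selecting the loop region
#'
#' @param structure a `protein_structure`.
#' @param spec a `loop_spec`.
#' @return logical vector, one entry per row of [atom_table()].
#' @export
loop_mask <- function(structure, spec) {
  validate_loop_spec(structure, spec)
  tb <- atom_table(structure)
  tb$chain == spec$chain_id &
    tb$res_index >= spec$start & tb$res_index <= spec$end
}

# --- PDB parsing --------------------------------------------------------------

#' Parse a PDB-format string into a protein structure
#'
#' Reads ATOM records only; HETATM records, waters and hydrogens are
#' skipped.  Alternate locations are resolved to the highest-occupancy
#' conformer (first on ties).  Insertion codes are preserved in
#' `auth_seq_id`.
#'
#' @param text a single string or character vector of PDB lines.
#' @return a `protein_structure`.
#' @export
parse_pdb <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  title <- ""
  recs <- list()
  k <- 0L
  for (ln_i in seq_along(lines)) {
    ln <- lines[[ln_i]]
    tag <- substr(ln, 1L, 6L)
    if (startsWith(ln, "TITLE")) {
      title <- trimws(paste(title, trimws(substr(ln, 11L, nchar(ln)))))
      next
    }
    if (tag != "ATOM  ") next
    name <- trimws(substr(ln, 13L, 16L))
    altloc <- substr(ln, 17L, 17L)
    res_name <- trimws(substr(ln, 18L, 20L))
    chain <- substr(ln, 22L, 22L)
    seqnum <- trimws(substr(ln, 23L, 26L))
    icode <- trimws(substr(ln, 27L, 27L))
    xs <- trimws(substr(ln, 31L, 38L))
    ys <- trimws(substr(ln, 39L, 46L))
    zs <- trimws(substr(ln, 47L, 54L))
    occ <- suppressWarnings(as.numeric(trimws(substr(ln, 55L, 60L))))
    elem <- trimws(substr(ln, 77L, 78L))
    x <- suppressWarnings(as.numeric(xs))
    y <- suppressWarnings(as.numeric(ys))
    z <- suppressWarnings(as.numeric(zs))
    if (anyNA(c(x, y, z))) {
      stop("malformed coordinate field on line ", ln_i, ": ", ln)
    }
    if (res_name == "HOH") next
    if (elem == "") elem <- guess_element(name)
    if (toupper(elem) == "H" || toupper(elem) == "D") next
    if (is.na(occ)) occ <- 1
    k <- k + 1L
    recs[[k]] <- list(name = name, altloc = altloc, res_name = res_name,
                      chain = chain, auth = paste0(seqnum, icode),
                      coords = c(x, y, z), occ = occ, elem = toupper(elem))
  }
  chains <- list()
  if (k > 0L) {
    chain_ids <- unique(vapply(recs, function(r) r$chain, ""))
    for (cid in chain_ids) {
      crecs <- Filter(function(r) r$chain == cid, recs)
      auths <- unique(vapply(crecs, function(r) r$auth, ""))
      residues <- vector("list", length(auths))
      for (i in seq_along(auths)) {
        rrecs <- Filter(function(r) r$auth == auths[i], crecs)
        # altloc resolution: per atom name keep highest occupancy, first on tie
        atoms <- list()
        for (nm in unique(vapply(rrecs, function(r) r$name, ""))) {
          cand <- Filter(function(r) r$name == nm, rrecs)
          occ <- vapply(cand, function(r) r$occ, 0)
          best <- cand[[which.max(occ)]]
          atoms[[length(atoms) + 1L]] <-
            new_atom(best$name, best$elem, best$coords)
        }
        residues[[i]] <- new_residue(i - 1L, rrecs[[1]]$res_name, cid, atoms,
                                     auth_seq_id = auths[i])
      }
      chains[[cid]] <- residues
    }
  }
  protein_structure(chains, title = title)
}

# --- PDB writing --------------------------------------------------------------

#' Serialize a protein structure to a PDB-format string
#'
#' @param structure a `protein_structure`.
#' @return a single string of fixed-column ATOM/TER records.
#' @export
write_pdb <- function(structure) {
  out <- character()
  if (nzchar(structure$title)) {
    out <- c(out, sprintf("TITLE     %s", structure$title))
  }
  serial <- 0L
  for (cid in names(structure$chains)) {
    last_res <- NULL
    for (r in structure$chains[[cid]]) {
      auth <- r$auth_seq_id
      icode <- " "
      seqnum <- auth
      if (grepl("[A-Za-z]$", auth)) {
        icode <- substr(auth, nchar(auth), nchar(auth))
        seqnum <- substr(auth, 1L, nchar(auth) - 1L)
      }
      for (a in r$atoms) {
        if (any(abs(a$coords) >= 10000)) {
          stop("coordinate magnitude >= 10000 Angstrom cannot be formatted")
        }
        serial <- serial + 1L
        nm <- a$name
        # standard PDB atom-name justification
        nm_fmt <- if (nchar(nm) < 4L && nchar(a$element) == 1L) {
          formatC(paste0(" ", nm), width = -4L)
        } else {
          formatC(nm, width = -4L)
        }
        out <- c(out, sprintf(
          "ATOM  %5d %s%s%3s %s%4s%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, substr(nm_fmt, 1, 4), " ", r$name, cid,
          seqnum, icode, a$coords[1], a$coords[2], a$coords[3], 1, 0,
          a$element))
      }
      last_res <- r
    }
    if (!is.null(last_res)) {
      serial <- serial + 1L
      out <- c(out, sprintf("TER   %5d      %3s %s", serial %% 100000L,
                            last_res$name, cid))
    }
  }
  out <- c(out, "END")
  paste0(paste(out, collapse = "\n"), "\n")
}

# --- covalent bonds -----------------------------------------------------------

#' Derive the covalent bond list of a structure
#'
#' Bonds come from per-residue heavy-atom templates (backbone N-CA, CA-C,
#' C-O plus side-chain templates for the 20 canonical residues) and the
#' inter-residue peptide bond C(i)-N(i+1).  Atoms not covered by a template
#' (nonstandard names or residues) fall back to a 1.9 Angstrom distance rule,
#' which covers standard covalent bond lengths without bridging CA-CA pairs
#' (3.8 Angstrom).  Missing atoms simply yield no bond.
#'
#' @param structure a `protein_structure`.
#' @return integer matrix with two columns of atom indices (rows of
#'   [atom_table()]); each undirected bond appears once.
#' @export
derive_covalent_bonds <- function(structure) {
  tb <- atom_table(structure)
  if (nrow(tb) == 0L) return(matrix(integer(), 0L, 2L))
  key <- paste(tb$chain, tb$res_index, tb$atom, sep = "\r")
  lookup <- stats::setNames(seq_len(nrow(tb)), key)
  find_atom <- function(cid, ri, nm) {
    i <- lookup[paste(cid, ri, nm, sep = "\r")]
    if (is.na(i)) NA_integer_ else as.integer(i)
  }
  bonds <- list()
  add_bond <- function(i, j) {
    if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1L]] <<- c(i, j)
  }
  for (cid in names(structure$chains)) {
    res <- structure$chains[[cid]]
    for (r in res) {
      ri <- r$index
      add_bond(find_atom(cid, ri, "N"), find_atom(cid, ri, "CA"))
      add_bond(find_atom(cid, ri, "CA"), find_atom(cid, ri, "C"))
      add_bond(find_atom(cid, ri, "C"), find_atom(cid, ri, "O"))
      add_bond(find_atom(cid, ri, "C"), find_atom(cid, ri, "OXT"))
      tmpl <- SIDECHAIN_BONDS[[r$name]]
      covered <- c(BACKBONE_ATOMS, "OXT")
      if (!is.null(tmpl)) {
        for (b in tmpl) {
          add_bond(find_atom(cid, ri, b[1]), find_atom(cid, ri, b[2]))
          covered <- c(covered, b)
        }
      }
      # distance fallback for atoms not covered by any template entry
      extra <- vapply(r$atoms, function(a) !(a$name %in% covered), TRUE)
      if (any(extra)) {
        idx_all <- vapply(r$atoms, function(a)
          find_atom(cid, ri, a$name), 0L)
        coords <- do.call(rbind, lapply(r$atoms, function(a) a$coords))
        for (i in which(extra)) {
          for (j in seq_along(r$atoms)) {
            if (j == i) next
            if (vnorm(coords[i, ] - coords[j, ]) < 1.9) {
              add_bond(idx_all[i], idx_all[j])
            }
          }
        }
      }
      # peptide bond to the next residue in the chain
      if (ri < length(res) - 1L) {
        add_bond(find_atom(cid, ri, "C"), find_atom(cid, ri + 1L, "N"))
      }
    }
  }
  if (length(bonds) == 0L) return(matrix(integer(), 0L, 2L))
  bm <- do.call(rbind, bonds)
  bm <- t(apply(bm, 1L, sort))
  bm <- unique(bm)
  bm <- bm[bm[, 1] != bm[, 2], , drop = FALSE]
  storage.mode(bm) <- "integer"
  bm
}

# splice new loop coordinates (atom_table order within the loop) into a copy
# of the structure; all other atoms untouched
splice_loop_coords <- function(structure, spec, coords) {
  mask <- loop_mask(structure, spec)
  stopifnot(nrow(coords) == sum(mask))
  k <- 0L
  pos <- 0L
  for (cid in names(structure$chains)) {
    for (ri in seq_along(structure$chains[[cid]])) {
      r <- structure$chains[[cid]][[ri]]
      for (ai in seq_along(r$atoms)) {
        pos <- pos + 1L
        if (mask[pos]) {
          k <- k + 1L
          structure$chains[[cid]][[ri]]$atoms[[ai]]$coords <-
            as.numeric(coords[k, ])
        }
      }
    }
  }
  structure
}
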