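# End-to-end prediction: pocket selection -> loop initialization -> graph
# building -> encoders -> hierarchical merge -> interaction graph ->
# recycled EGNN generation -> confidence scoring.  The predicted loop
# coordinates are spliced into a copy of the input structure; all other
# atoms are untouched.

#' Predict loop conformations for a structure
#'
#' @param structure a `protein_structure` (or PDB text, parsed on the fly).
#' @param spec a [loop_spec()].
#' @param model a `loop_model` or a checkpoint path.
#' @param mode `"reconstruct"` (loop unknown: anchors define initialization
#'   and a surface pocket), `"refine"` (an inaccurate loop conformation is
#'   supplied: 12 Angstrom pocket, SD 4 initialization) or `"multiconf"`
#'   (`n_conformations` reconstruction-mode samples at SD 7).
#' @param n_conformations conformations to generate (multiconf mode).
#' @param seed integer seed for the loop initialization.
#' @param raw_loop_coords existing loop coordinates (refine mode).
#' @param sd initialization SD override in Angstrom.
#' @param recycles recycling override.
#' @return list of per-conformation results (`structure` with the predicted
#'   loop spliced in, `coords`, `score`) plus the `pocket` and a `scores`
#'   data.frame.
#' @export
predict_loops <- function(structure, spec, model,
                          mode = c("reconstruct", "refine", "multiconf"),
                          n_conformations = 1L, seed = 0L,
                          raw_loop_coords = NULL, sd = NULL,
                          recycles = NULL) {
  mode <- match.arg(mode)
  if (is.character(model) && length(model) == 1L) {
    model <- load_checkpoint(model)
  }
  if (is.character(structure)) structure <- parse_pdb(structure)
  validate_loop_spec(structure, spec)
  ad_set_training(FALSE)

  pocket <- if (mode == "refine") {
    if (is.null(raw_loop_coords)) {
      stop("refine mode requires raw_loop_coords")
    }
    select_refinement_pocket(structure, spec, raw_loop_coords)
  } else {
    select_surface_pocket(structure, spec)
  }
  if (length(pocket$residue_ids) == 0L) stop("empty pocket")

  inits <- switch(mode,
    reconstruct = list(init_loop_reconstruction(
      structure, spec, sd = if (is.null(sd)) 1.75 else sd, seed = seed)),
    refine = list(init_loop_refinement(
      raw_loop_coords, sd = if (is.null(sd)) 4 else sd, seed = seed)),
    multiconf = init_multiconf(
      structure, spec, n = n_conformations,
      sd = if (is.null(sd)) 7 else sd,
      seeds = seed + seq_len(n_conformations) - 1L))

  ag <- build_atom_graph(structure, pocket, spec)
  rg <- build_residue_graph(structure, pocket)
  atom2pocket <- match(ag$res_keys[ag$atom2res], rg$keys)
  gt <- encode_atoms_gt(ag, model)
  gv <- encode_residues_gvp(rg, model)
  merged <- merge_hierarchical(gv$s, gt$h, atom2pocket, length(rg$keys),
                               model)
  loop_h <- extract_loop_embeddings(gt$h, ag$loop_atom)
  res_coord_list <- lapply(rg$keys, function(k)
    residue_atom_coords(residue_by_key(structure, k)))

  results <- lapply(seq_along(inits), function(ci) {
    ig <- build_interaction_graph(loop_h, inits[[ci]], merged, rg,
                                  loop_k = model$config$loop_k)
    gen <- generate_conformation(ig, model, recycles = recycles)
    out <- mdn_head(loop_h, merged, model)
    d <- pair_min_distances(gen$coords, res_coord_list)
    list(structure = splice_loop_coords(structure, spec, gen$coords),
         coords = gen$coords,
         trajectory = gen$trajectory,
         score = mdn_score(out, d))
  })
  list(conformations = results, pocket = pocket,
       scores = data.frame(conformation = seq_along(results),
                           score = vapply(results, `[[`, 0, "score")))
}
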