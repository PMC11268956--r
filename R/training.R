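# Two-stage training.
#
# Stage 1 pretrains the encoders and the mixture-density head on the
# distance likelihood (plus two small cross-entropy auxiliaries on the atom
# encoder: element class per atom node, intra-residue vs peptide class per
# bond edge).  Stage 2 adds the generator and the coordinate loss with
# coefficient 1, starting from the stage-1 parameters.  Optimization is
# Adam with batch size 64, learning rate 1e-3 / 1e-4 and weight decay
# 1e-5 / 0 for stages 1 / 2; early stopping keeps the best-validation
# parameters with a default patience of 70 epochs.

#' Training configuration
#'
#' @param stage 1 (distance likelihood pretraining) or 2 (joint training
#'   with the coordinate loss).
#' @param batch_size tasks per optimizer step.
#' @param lr learning rate; defaults to 1e-3 for stage 1, 1e-4 for stage 2.
#' @param weight_decay defaults to 1e-5 for stage 1, 0 for stage 2.
#' @param epochs maximum epochs.
#' @param patience early-stop patience (epochs without validation
#'   improvement).
#' @param seed RNG seed for splits, loop initializations and dropout.
#' @param aux_coef coefficient of the auxiliary cross-entropies (0.001).
#' @param rmsd_coef coefficient of the coordinate loss in stage 2 (1).
#' @param mdn_cutoff training cutoff for pair distances (Angstrom).
#' @param init_sd SD of the reconstruction-mode loop initialization used as
#'   teacher forcing during stage-2 training (1.75, matching inference).
#' @param val_fraction validation fraction of the stratified split; with 0
#'   the training loss is monitored instead.
#' @param stop_loss optional target: stop once the monitored loss falls
#'   below this value (training-budget control for small overfit runs).
#' @param clip global gradient-norm clip; the unbounded coordinate updates
#'   of the generator make clipping necessary for stable optimization at
#'   practical learning rates.
#' @param teacher_forcing `"fixed"` (default) draws one reconstruction-mode
#'   initialization per task, deterministically from the seed, and reuses
#'   it every epoch; `"resample"` draws a fresh initialization per epoch.
#'   Fixed initializations give a stationary regression target and converge
#'   far faster at small scale; resampling trains a contraction of the
#'   whole initialization distribution.
#' @param lr_decay reduce-on-plateau factor (1 disables); whenever the
#'   monitored loss has not improved for `lr_patience` consecutive epochs
#'   the learning rate is multiplied by `lr_decay`.
#' @param lr_patience epochs without improvement before each decay step.
#' @export
train_config <- function(stage = 1L, batch_size = 64L, lr = NULL,
                         weight_decay = NULL, epochs = 200L, patience = 70L,
                         seed = 0L, aux_coef = 0.001, rmsd_coef = 1,
                         mdn_cutoff = 12, init_sd = 1.75,
                         val_fraction = 0.1, stop_loss = NULL, clip = 1,
                         teacher_forcing = c("fixed", "resample"),
                         lr_decay = 1, lr_patience = 25L) {
  teacher_forcing <- match.arg(teacher_forcing)
  stage <- as.integer(stage)
  if (!stage %in% c(1L, 2L)) stop("stage must be 1 or 2")
  if (patience < 1L) stop("patience must be >= 1")
  if (is.null(lr)) lr <- if (stage == 1L) 1e-3 else 1e-4
  if (is.null(weight_decay)) weight_decay <- if (stage == 1L) 1e-5 else 0
  if (lr <= 0) stop("learning rate must be positive")
  structure(list(stage = stage, batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed), aux_coef = aux_coef,
                 rmsd_coef = rmsd_coef, mdn_cutoff = mdn_cutoff,
                 init_sd = init_sd, val_fraction = val_fraction,
                 stop_loss = stop_loss, clip = clip,
                 teacher_forcing = teacher_forcing, lr_decay = lr_decay,
                 lr_patience = as.integer(lr_patience)),
            class = "train_config")
}

#' Auxiliary cross-entropy losses on the atom encoder
#'
#' Linear classification heads on the graph-transformer outputs predict the
#' element class of every atom node and the bond class (intra-residue vs
#' peptide) of every edge.
#'
#' @param atom_h atom embeddings, `bond_e` edge embeddings.
#' @param atom_labels,bond_labels integer class labels.
#' @param model a `loop_model` (uses `model$aux`).
#' @return list with `L_atom` and `L_bond` (mean cross-entropies).
#' @export
auxiliary_losses <- function(atom_h, bond_e, atom_labels, bond_labels,
                             model) {
  list(L_atom = cross_entropy(ad_lin(atom_h, model$aux$atom), atom_labels),
       L_bond = cross_entropy(ad_lin(bond_e, model$aux$bond), bond_labels))
}

#' Mean cross-entropy of logits against integer labels
#' @keywords internal
cross_entropy <- function(logits, labels) {
  lv <- ad_val(logits)
  if (nrow(lv) != length(labels)) stop("label/logit length mismatch")
  logp <- ad_sub(logits,
                 ad_matmul(ad_logsumexp_rows(logits),
                           matrix(1, 1L, ncol(lv))))
  M <- one_hot(as.integer(labels), ncol(lv))
  ad_scale(ad_scale(ad_sum_all(ad_mul(logp, M)), 1 / nrow(lv)), -1)
}

#' Coordinate loss: RMSD without superposition
#'
#' Square root of the mean over loop atoms of the squared coordinate error;
#' prediction and reference share the pocket frame, so no alignment is
#' applied.
#'
#' @param pred,truth n x 3 coordinate matrices (pred may be an ad node).
#' @export
rmsd_loss <- function(pred, truth) {
  pv <- ad_val(pred)
  if (!all(dim(pv) == dim(truth))) stop("coordinate shapes must match")
  res <- ad_sqrt(ad_scale(ad_sum_all(ad_square(ad_sub(pred, truth))),
                          1 / nrow(pv)))
  if (is_nd(res)) res else as.numeric(res)
}

#' Compose the stage total from its loss components
#'
#' Stage 1: `L_MDN + 0.001 L_atom + 0.001 L_bond`.
#' Stage 2: `L_rmsd + L_MDN + 0.001 L_atom + 0.001 L_bond`.
#'
#' @param parts list with `L_MDN`, `L_atom`, `L_bond` and (stage 2)
#'   `L_rmsd`; entries may be ad nodes.
#' @param config a [train_config()].
#' @return a `loss_report` list with all components and `total`.
#' @export
compute_losses <- function(parts, config) {
  total <- ad_add(parts$L_MDN,
                  ad_scale(ad_add(parts$L_atom, parts$L_bond),
                           config$aux_coef))
  if (config$stage == 2L) {
    if (is.null(parts$L_rmsd)) stop("stage 2 requires the coordinate loss")
    total <- ad_add(ad_scale(parts$L_rmsd, config$rmsd_coef), total)
  }
  rep <- list(L_MDN = as_scalar(parts$L_MDN),
              L_atom = as_scalar(parts$L_atom),
              L_bond = as_scalar(parts$L_bond),
              L_rmsd = if (is.null(parts$L_rmsd)) NA_real_
                       else as_scalar(parts$L_rmsd),
              total = total)
  class(rep) <- "loss_report"
  rep
}

# assemble graphs and lookups for one task; done once per task
prepare_task <- function(task, K = 30L) {
  st <- task$structure; sp <- task$spec
  pocket <- select_surface_pocket(st, sp)
  ag <- build_atom_graph(st, pocket, sp)
  rg <- build_residue_graph(st, pocket, K = K)
  atom2pocket <- match(ag$res_keys[ag$atom2res], rg$keys)
  res_coord_list <- lapply(rg$keys, function(k)
    residue_atom_coords(residue_by_key(st, k)))
  list(structure = st, spec = sp, pocket = pocket, agraph = ag, rgraph = rg,
       atom2pocket = atom2pocket, res_coord_list = res_coord_list,
       truth = task$truth,
       d_true = pair_min_distances(task$truth, res_coord_list),
       cache = new.env(parent = emptyenv()))
}

# forward pass producing the loss parts for one prepared task
task_loss_parts <- function(model, pt, config, loop_init = NULL) {
  gt <- encode_atoms_gt(pt$agraph, model)
  gv <- encode_residues_gvp(pt$rgraph, model)
  merged <- merge_hierarchical(gv$s, gt$h, pt$atom2pocket,
                               length(pt$rgraph$keys), model)
  loop_h <- extract_loop_embeddings(gt$h, pt$agraph$loop_atom)
  out <- mdn_head(loop_h, merged, model)
  parts <- list(L_MDN = mdn_nll(out, pt$d_true, cutoff = config$mdn_cutoff))
  aux <- auxiliary_losses(gt$h, gt$e, pt$agraph$elem_class,
                          pt$agraph$bond_class, model)
  parts$L_atom <- aux$L_atom
  parts$L_bond <- aux$L_bond
  if (config$stage == 2L) {
    if (is.null(loop_init)) stop("stage 2 requires a loop initialization")
    topo <- NULL
    if (!is.null(pt$cache)) {
      key <- paste0("topo:", loop_init$seed, ":", model$config$loop_k)
      topo <- pt$cache[[key]]
    }
    ig <- build_interaction_graph(loop_h, loop_init, merged, pt$rgraph,
                                  loop_k = model$config$loop_k, topo = topo)
    if (!is.null(pt$cache) && is.null(topo)) {
      pt$cache[[key]] <- ig[c("src", "dst", "type")]
    }
    gen <- generate_conformation(ig, model)
    pred <- ad_rows(gen$coords_node, seq_len(ig$n_loop))
    parts$L_rmsd <- rmsd_loss(pred, pt$truth)
  }
  parts
}

stratified_split <- function(tasks, val_fraction, seed) {
  lens <- vapply(tasks, function(t) t$spec$end - t$spec$start + 1L, 0L)
  set.seed(seed)
  val <- integer(0)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    n_val <- floor(val_fraction * length(idx))
    if (n_val > 0L) val <- c(val, sample(idx, n_val))
  }
  list(train = setdiff(seq_along(tasks), val), val = val)
}

#' Train the model
#'
#' @param tasks list of loop tasks as produced by [make_loop_task()] (each
#'   with `structure`, `spec`, `truth`).
#' @param config a [train_config()].
#' @param model starting parameters; required for stage 2 (the stage-1
#'   result), optional for stage 1.
#' @param model_config a [model_config()] used when `model` is NULL.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best-validation parameters), `log`
#'   (per-epoch data.frame) and `config`.
#' @export
train_model <- function(tasks, config, model = NULL, model_config = NULL,
                        verbose = FALSE) {
  if (length(tasks) == 0L) stop("empty dataset")
  if (config$stage == 2L && is.null(model)) {
    stop("stage 2 must start from a stage-1 model")
  }
  if (is.null(model)) {
    if (is.null(model_config)) model_config <- loopcraft::model_config()
    model <- init_model(model_config, seed = config$seed)
  }
  prepared <- lapply(tasks, prepare_task)
  split <- stratified_split(tasks, config$val_fraction, config$seed)
  monitor_idx <- if (length(split$val)) split$val else split$train

  params <- collect_params(model[c("gt", "gvp", "fmb", "mdn", "aux",
                                   if (config$stage == 2L) "egnn")])
  opt <- adam_new(params, lr = config$lr, weight_decay = config$weight_decay,
                  clip = config$clip)

  epoch_init <- function(epoch, i) {
    # deterministic teacher-forcing initialization: per task ("fixed") or
    # per (epoch, task) ("resample")
    s <- if (identical(config$teacher_forcing, "fixed")) {
      config$seed * 131L + 1000003L + i
    } else {
      config$seed * 131L + epoch * 17L + i
    }
    init_loop_reconstruction(prepared[[i]]$structure, prepared[[i]]$spec,
                             sd = config$init_sd,
                             seed = s %% .Machine$integer.max)
  }

  eval_monitor <- function(model, epoch) {
    ad_set_training(FALSE)
    tot <- 0
    rms <- 0
    for (i in monitor_idx) {
      ini <- if (config$stage == 2L) {
        if (identical(config$teacher_forcing, "fixed")) {
          epoch_init(0L, i)
        } else {
          init_loop_reconstruction(prepared[[i]]$structure,
                                   prepared[[i]]$spec, sd = config$init_sd,
                                   seed = 7919L + i)
        }
      }
      parts <- task_loss_parts(model, prepared[[i]], config, ini)
      rep <- compute_losses(parts, config)
      tot <- tot + as_scalar(rep$total)
      if (config$stage == 2L) rms <- rms + rep$L_rmsd
    }
    c(total = tot / length(monitor_idx), rmsd = rms / length(monitor_idx))
  }

  best <- list(loss = Inf, values = NULL, epoch = 0L)
  bad_epochs <- 0L
  log <- list()
  for (epoch in seq_len(config$epochs)) {
    ad_set_training(TRUE)
    set.seed(config$seed * 7L + epoch)
    order_idx <- sample(split$train)
    nb <- ceiling(length(order_idx) / config$batch_size)
    epoch_loss <- 0
    epoch_rmsd <- 0
    for (b in seq_len(nb)) {
      batch <- order_idx[((b - 1L) * config$batch_size + 1L):
                           min(b * config$batch_size, length(order_idx))]
      zero_grads(params)
      batch_loss <- 0
      batch_rmsd <- 0
      for (i in batch) {
        ini <- if (config$stage == 2L) epoch_init(epoch, i)
        tp <- ad_tape_begin()
        parts <- task_loss_parts(model, prepared[[i]], config, ini)
        rep <- compute_losses(parts, config)
        loss <- ad_scale(rep$total, 1 / length(batch))
        ad_tape_end()
        ad_backward(loss, tp)
        batch_loss <- batch_loss + as_scalar(rep$total)
        if (config$stage == 2L) batch_rmsd <- batch_rmsd + rep$L_rmsd
      }
      adam_step(opt)
      epoch_loss <- epoch_loss + batch_loss / length(batch)
      epoch_rmsd <- epoch_rmsd + batch_rmsd / length(batch)
    }
    ad_set_training(FALSE)
    # with a held-out set, monitor it; otherwise monitor the epoch's own
    # training loss to avoid a redundant forward pass
    mon <- if (length(split$val)) {
      eval_monitor(model, epoch)
    } else {
      c(total = epoch_loss / nb, rmsd = epoch_rmsd / nb)
    }
    log[[epoch]] <- data.frame(
      epoch = epoch, train_loss = epoch_loss / nb,
      train_rmsd = if (config$stage == 2L) epoch_rmsd / nb else NA_real_,
      monitor_loss = mon[["total"]],
      monitor_rmsd = if (config$stage == 2L) mon[["rmsd"]] else NA_real_)
    if (verbose) {
      message(sprintf("epoch %d train %.4f monitor %.4f", epoch,
                      epoch_loss / nb, mon[["total"]]))
    }
    if (mon[["total"]] < best$loss - 1e-8) {
      best <- list(loss = mon[["total"]],
                   values = params_to_values(model), epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
      # reduce-on-plateau learning-rate schedule
      if (config$lr_decay < 1 && bad_epochs %% config$lr_patience == 0L) {
        opt$lr <- opt$lr * config$lr_decay
      }
    }
    if (!is.null(config$stop_loss) && mon[["total"]] <= config$stop_loss) {
      break
    }
  }
  if (!is.null(best$values)) {
    restored <- values_to_params(best$values)
    for (nm in c("gt", "gvp", "fmb", "mdn", "aux", "egnn")) {
      model[[nm]] <- restored[[nm]]
    }
  }
  list(model = model, log = do.call(rbind, log), config = config,
       best_epoch = best$epoch)
}
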