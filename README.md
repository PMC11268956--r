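# loopcraft

Full-atom protein loop modeling with hierarchical graph neural networks,
in pure R.

Protein loops — the irregular segments connecting helices and strands —
are the most flexible and most frequently unresolved parts of experimental
structures, and the hardest part of protein modeling (antibody CDR H3
being the classic case).  `loopcraft` predicts the conformation of a loop
of at least four residues at full heavy-atom resolution (backbone N, CA,
C, O plus side-chain heavy atoms), given the surrounding structure, by
moving randomly initialized loop atoms inside a deterministically selected
pocket of context residues.

The method, end to end:

* a **graph transformer** encodes the covalent atom graph of pocket + loop
  (topology only, no coordinates): 6 layers of edge-featured multi-head
  attention with per-channel softmax over in-neighbors of
  `(q ⊙ k)/√d_k ⊙ e`;
* **geometric vector perceptrons** encode a K-nearest-neighbor residue
  graph (K = 30, CA positions) with an E(3)-invariant scalar track and a
  rotation-equivariant vector track;
* a **feature-merging block** sums each residue's atom embeddings into its
  residue embedding — atom detail at residue cost;
* an **attention-augmented E(n)-equivariant GNN** (8 layers, recycled with
  a gated re-injection of the raw embeddings) moves loop-atom coordinates
  along normalized difference vectors scaled by learned per-head scalars
  ("pseudo-forces"); residue coordinates are frozen context, so the whole
  pipeline is exactly translation-equivariant and rotation-equivariant to
  float precision;
* a **mixture density network** over every (loop atom, pocket residue)
  pair predicts a 10-component Gaussian mixture of their minimum
  heavy-atom distance `d`; training minimizes
  `L = L_rmsd + L_MDN + 0.001·L_atom + 0.001·L_bond`, where
  `L_MDN = −log Σ_c π_c N(d | μ_c, σ_c)` (stage 1 omits `L_rmsd`), and at
  inference `score = Σ_pairs log P(d | h_l, h_nl)` ranks conformations.

Training, the autodiff engine behind it (a small tape-based reverse-mode
engine in `R/autodiff.R`), synthetic helix–loop–helix fixture generation,
pocket selection, loop initialization and RMSD evaluation utilities are
all part of the package.  No pretrained weights are shipped; everything is
verified by property-based tests and a desk-scale overfit experiment.

## Worked example

Generate a synthetic loop task, train briefly at reduced width, and
predict:

```r
library(loopcraft)

tasks <- lapply(0:4, function(s) make_loop_task(6 + s, 6, 6 + s, seed = s))
cfg <- model_config(d = 32, heads = 2, gvp_s = 32, gvp_v = 4,
                    gvp_layers = 2, recycles = 2, mdn_width = 32,
                    dropout = 0, loop_k = 12)

s1 <- train_model(tasks, train_config(stage = 1, epochs = 30,
                                      batch_size = 5, val_fraction = 0),
                  model_config = cfg)
s2 <- train_model(tasks, train_config(stage = 2, epochs = 180, lr = 3e-3,
                                      batch_size = 1, val_fraction = 0,
                                      teacher_forcing = "fixed",
                                      patience = 10000),
                  model = s1$model)

task <- tasks[[1]]
res <- predict_loops(task$structure, task$spec, s2$model,
                     mode = "reconstruct", seed = 7)
loop_rmsd(res$conformations[[1]]$structure, task$structure, task$spec,
          align = "none")
res$conformations[[1]]$score
```

The untrained model (its coordinate-update heads start at zero) leaves the
1.75 Å-SD initialization untouched at roughly 4–6 Å loop RMSD.  A
`scripts/acceptance.R` run with `--seed 1` (which executes exactly this
protocol with a 300-epoch two-phase schedule) printed:

```
overfit_train_rmsd       1.54349  (n = 5)
trained_pred_rmsd        1.8953   (n = 5)
baseline_pred_rmsd       4.80158  (n = 5)
baseline_improvement     2.53342  (n = 5)
success_rate_at_2A       0.6      (n = 5)
equivariance_coord_err   5.2e-12  (n = 30)
```

i.e. training RMSD 1.5 Å, predictions on fresh initializations 1.9 Å
versus 4.8 Å for the untrained baseline (2.5× better, 3 of 5 loops within
2 Å), and end-to-end rigid-transform equivariance at float precision.
Longer schedules converge further (≈ 0.3 Å training RMSD at ≈ 1200
epochs); `predict_loops` returns the predicted structure with only loop
atoms changed plus its mixture-density confidence score.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/loopcraft-cli.R",
                                       package = "loopcraft"))')" \
  fixtures --flank1 8 --loop 6 --flank2 8 --seed 7 --out task.pdb
```

with `predict` (`--pdb in.pdb --loop A:9-14 --ckpt model.rds --mode
reconstruct|refine|multiconf --nconf 5 --seed 0 --out outdir/`, optional
`--posthook` command for external force-field minimization) and
`evaluate` subcommands.

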