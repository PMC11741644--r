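# laseg

Automatic configuration of a dense encoder-decoder segmentation CNN by a
team of learning automata, for neonatal brain tissue segmentation
(CSF / grey matter / white matter) in multimodal MRI.

Neonatal MRI has notoriously low grey/white-matter contrast, and the
segmentation quality of a convolutional network depends strongly on
per-layer hyperparameters.  `laseg` treats that configuration problem as
reinforcement learning: one **learning automaton** per configurable layer
holds a probability vector over that layer's discrete hyperparameter
actions.  Nineteen convolution automata each choose among
15 × 5 × 5 = 375 actions ⟨N, L, W⟩ (filter count 32–256 in steps of 16;
kernel length and width odd in 1–9) and two binary automata choose the
encoder pooling operators (max / average) — a genotype of 59 scalar
hyperparameters chosen by 21 automata.  Each search iteration, the joint
genotype is trained as a candidate network and scored by mean Dice over
the tissue classes; if the quality strictly beats the best seen so far,
every automaton applies the linear reward

    p_i <- p_i + a (1 - p_i),     p_j <- (1 - a) p_j   (j != i)

to its chosen action, otherwise the linear penalty

    p_i <- (1 - b) p_i,           p_j <- b/(K-1) + (1 - b) p_j

with K the automaton's action count (defaults a = b = 0.5, 30%
uniform exploration).  The search stops at the iteration budget T, after
K consecutive iterations without improvement, or at a quality ceiling;
defaults T = 200, K = 15.

The package contains everything needed to run and study the method at
desk scale on a CPU:

* the learning-automaton primitives (`la_new`, `la_select`, `la_reward`,
  `la_penalty`) and the action-space encoding (`conv_action_space`,
  `assemble_configuration`);
* the configurable CNN itself — six dense blocks of
  convolution → batch-norm → ReLU with in-block dense connectivity, two
  searchable pooling stages, nearest-neighbour decoder upsampling and a
  softmax head — with a self-contained CPU training engine
  (`build_model`, `train_candidate`, `predict_segmentation`) whose
  gradients are verified against finite differences;
* segmentation metrics: per-class Dice, surface extraction and average
  surface distance in mm (`dice_score`, `extract_surface`, `asd`,
  `mean_quality`);
* the search loop and environments (`run_search`, `check_termination`,
  `make_cnn_environment`, `make_oracle_table`);
* a multimodal tissue-phantom generator (`generate_phantom`,
  `generate_dataset`) emulating T1/T2-like contrast with low GM/WM
  separation;
* NIfTI volume I/O and a CLI (`read_volume`, `write_phantom`,
  `laseg_cli_path()`; subcommands `phantom`, `search`, `train`,
  `evaluate`).

## Worked example

The search loop is testable without any network training against a
deterministic oracle environment with a known optimum:

```r
library(laseg)

env  <- make_oracle_table(3, 4, structure = "single_peak", seed = 11)
team <- lapply(1:3, function(i) la_new(4))
res  <- run_search(env, team, T = 300, K = 300, seed = 1)
res
#> <search_state> 162 iterations, stopped: quality_ceiling
#>   best quality 1 at iteration 162
rbind(found = res$best_actions, optimum = env$known_optimum)
#>         [,1] [,2] [,3]
#> found      2    2    4
#> optimum    2    2    4
```

The three automata locate the unique optimal joint action (quality 1, so
the run stops at the quality ceiling after 162 iterations).  A phantom and
a configured model:

```r
ph <- generate_phantom(phantom_spec(), seed = 1)   # 32^3, 2 modalities
table(ph$labels$labels)
#>    0    1    2    3
#> 8192 6554 9830 8192        # background, CSF, GM, WM voxels

cfg <- assemble_configuration(rep(encode_conv_action(32, 3, 3), 19), c(0, 1))
build_model(cfg, n_modalities = 2, n_classes = 4, spatial_rank = 3)
#> <dense_seg_model> rank-3 encoder-decoder, 2 modalities -> 4 classes,
#> 947,172 parameters
```

An end-to-end desk-scale search over phantoms (reduced action subspace,
5-epoch candidate training — a few minutes on one CPU) runs from the
command line:

```sh
CLI=$(Rscript -e 'cat(laseg::laseg_cli_path())')
Rscript $CLI search --iterations 20 --stall 20 --seed 1 --out-dir run1
Rscript $CLI evaluate --pred pred.nii.gz --truth truth.nii.gz
```

`evaluate` prints the per-class + average Dice/ASD table; `search` writes
`best_configuration.json`, a JSONL per-iteration log and a reproducible
`manifest.json`.

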