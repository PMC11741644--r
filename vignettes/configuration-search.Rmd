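---
title: "Configuring a dense segmentation CNN with a team of learning automata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Configuring a dense segmentation CNN with a team of learning automata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laseg)
```

## The problem

Neonatal brain MRI is hard to segment: tissue contrast between grey matter
(GM) and white matter (WM) is low in the first months of life, while
cerebrospinal fluid (CSF) is comparatively easy to find (dark in T1-like
images, bright in T2-like images).  Convolutional networks segment such
images well, but their performance depends strongly on per-layer
hyperparameters — how many filters each convolution has, how large its
kernel is, which pooling operator the encoder uses.  `laseg` automates that
choice with a team of *learning automata* (LAs): simple reinforcement-
learning units that hold a probability vector over a finite action set and
adapt it from scalar feedback.

## The model being configured

The base network is an encoder-decoder of six *dense blocks*.  Each block
stacks three convolution → batch-normalisation → ReLU layers,

$$y_l = \mathrm{ReLU}(\mathrm{BatchNorm}(\mathrm{Conv}(x))),$$

with dense connectivity inside the block: layer $l$ receives the block
input concatenated with the outputs of all earlier layers in the block, so
the third layer of a block sees $C_{\mathrm{in}} + N_1 + N_2$ channels.
The encoder interleaves its three blocks with two searchable pooling stages
(window 2, stride 2; max or average); the decoder mirrors them with
nearest-neighbour upsampling, so the output grid equals the input grid.  A
19th configurable convolution feeds a fixed $1{\times}1({\times}1)$
projection to the class scores and a per-voxel softmax.

Each of the 19 convolutions chooses an action
$\langle N, L, W \rangle$: filter count $N \in \{32, 48, \dots, 256\}$
(15 values), filter length and width $L, W \in \{1, 3, 5, 7, 9\}$ (5 values
each) — $15 \times 5 \times 5 = 375$ actions per layer.  With the two
binary pooling choices the genotype carries $19 \times 3 + 2 = 59$ scalar
hyperparameters, selected by $19 + 2 = 21$ automata.

Two choices here were genuinely open and are our own:

* **Dense connectivity operator.** "Each layer receives the earlier
  outputs" is implemented as channel concatenation, the DenseNet
  convention; a block's output is its third layer's activation, which keeps
  channel counts bounded through the pooling stages.
* **The third kernel extent.** The action space specifies kernels by
  length and width only.  For 3-D inputs the through-plane extent is
  `min(L, 3)`: anisotropic kernels stay small in the third axis, which is
  both cheaper and the common practice for near-isotropic volumes.
* **Filter widths are odd.** Widths share the odd grid $\{1,3,5,7,9\}$
  with lengths, because odd kernels admit exact same-padding.

## The search

Every automaton starts uniform ($1/375$ per convolution action, $\{1/2,
1/2\}$ per pooling stage).  Each iteration:

1. every automaton selects an action — uniformly at random with
   probability 0.3 (exploration), otherwise from its probability vector;
2. the joint genotype is assembled, the candidate network is trained, and
   its validation quality is measured as the mean Dice over CSF, GM and WM;
3. the feedback is broadcast to the whole team.  If the quality strictly
   exceeds the best seen so far, every automaton applies the linear
   **reward** with coefficient $a$ to its chosen action $i$:
   $$p_i \leftarrow p_i + a(1 - p_i), \qquad p_j \leftarrow (1-a)\,p_j,$$
   and the configuration is saved; otherwise (ties included) every
   automaton applies the linear **penalty** with coefficient $b$,
   redistributing mass uniformly over the other $K-1$ actions:
   $$p_i \leftarrow (1-b)\,p_i, \qquad
     p_j \leftarrow \tfrac{b}{K-1} + (1-b)\,p_j.$$

Both maps conserve $\sum_j p_j = 1$ algebraically; the implementation
renormalises after every update so the invariant holds to $10^{-9}$ over
arbitrarily long runs.  Defaults are $a = b = 0.5$.  The search stops at
the iteration budget $T$ (default 200), after $K$ consecutive iterations
without improvement (default 15), or at the quality ceiling
`q_max` (default 1); the best configuration ever seen is returned, not the
last one.

Three semantics were open and are fixed as follows (each is tested):

* **Improvement is strict** against the *global* best, so ties are
  penalised and the first iteration is always rewarded and saved.
* **Exploration coins are per-automaton**, one independent draw per
  automaton per iteration — the weaker assumption, and it mixes the joint
  space faster than a single global coin.
* **The penalty's redistribution term is $b/(K-1)$.** Only this reading
  conserves probability mass; the alternative literal grouping does not
  sum to one, which is checked algebraically in the test suite.
* **Candidate training uses one fixed seed across the whole search**, so
  the environment's noise reflects configuration differences rather than
  initialisation luck.

```{r oracle-search}
# the loop is testable without any network: a deterministic oracle
# environment with a known optimum
env <- make_oracle_table(3, 4, structure = "single_peak", seed = 11)
team <- lapply(1:3, function(i) la_new(4))
res <- run_search(env, team, T = 300, K = 300, seed = 1)
c(found = res$best_quality, optimum = env$optimum_quality)
```

## Quality criteria

Candidate quality is the unweighted mean of per-class Dice scores,
$$\mathrm{DICE} = \frac{2\,|S \cap T|}{|S| + |T|},$$
over the tissue labels.  For boundary accuracy the package also implements
the average surface distance
$$\mathrm{ASD}(T, S) = \tfrac{1}{2}\Bigl(
  \mathrm{mean}_{x \in R_S} \min_{y \in R_T} d(x, y) +
  \mathrm{mean}_{y \in R_T} \min_{x \in R_S} d(x, y)\Bigr),$$
with $d$ the Euclidean distance in mm.  The surface of a region is the set
of its voxels with at least one face-adjacent neighbour outside the region
(grid edges count as outside) — the usual convention for surface-distance
metrics; the defining equation names region points, but boundary voxels are
what "surface distance" measures.  Nearest-neighbour distances are
computed exactly by blocked matrix algebra and are verified against a
brute-force double loop to $10^{-9}$.  Degenerate masks are handled
loudly: a label absent from *both* volumes scores Dice 1 (a vanished
structure absent from the truth is not an error), while ASD on an empty
mask raises an error, which the search maps to quality 0.

## The training engine

No deep-learning framework is involved: the network is a compact CPU
engine built on dense arrays in `(channels, H, W, D, batch)` layout, with
convolutions evaluated as sums of BLAS matrix products over kernel
offsets.  The backward pass is the exact adjoint of the forward pass; the
test suite verifies every parameter gradient against central finite
differences.  Training minimises voxel-wise cross-entropy plus a soft-Dice
loss over the tissue classes (targeting the selection criterion directly),
optimised with Adam (step size $10^{-3}$).  An epoch draws `batch_size`
random patches from the training volumes and takes one optimisation step —
the standard patch-wise regime for volumetric data; early stopping halts
after `patience_epochs` epochs without strict improvement of the batch
mean Dice, up to `max_epochs` (defaults 15 and 200).  A non-finite loss is
reported as a failure flag, which the search environment maps to
quality 0.

## The phantom generator

Desk-scale experiments need data with the statistical structure of the
real task but none of its bulk.  `generate_phantom()` builds nested tissue
bands — WM core, GM ribbon, CSF rim, background envelope — by thresholding
a radial field perturbed by a smoothed random field at its own quantiles
(volume fractions 25/30/20/25%, so no class is ever degenerate).  Each
modality is the per-voxel class mean plus class jitter and Gaussian noise,
standardised to mean 0 and variance 1.  The default means make CSF the
darkest tissue in modality 1 and the brightest in modality 2, and keep the
GM/WM separation (0.1) well below the CSF/GM separation (0.35–0.4) — the
low-contrast regime that motivates automatic configuration.

What the phantom does *not* emulate: anatomy (the bands are not
brain-shaped), bias fields, partial-volume mixtures, or acquisition
physics.  Tests passing on phantoms therefore demonstrate that the search
loop, the training engine and the metrics behave correctly and that the
pipeline can learn a separable segmentation task — not that any particular
Dice level transfers to clinical data.

```{r phantom}
ph <- generate_phantom(phantom_spec(), seed = 1)
table(ph$labels$labels)
```

## Desk-scale problem sizes

The full protocol (200 search iterations, each training a candidate to
convergence on 10 volumes of $144 \times 192 \times 256$ voxels) is a
GPU-cluster workload.  The package's own experiments — the ones its test
suite runs — use deliberately scaled-down sizes chosen so that a complete
end-to-end search is a coffee-break CPU job: 10 phantoms of $32^3$ voxels,
20 search iterations, 5-epoch candidate training on $8^3$ patches (batch
4), validation on $16^3$ centre crops, and a reduced convolution action
subspace (`conv_action_subspace()` with $N \in \{32, 48\}$,
$L, W \in \{1, 3\}$) for the 19 convolution automata.  The subspace only
shrinks each automaton's action set; the encoding, the network builder and
the update rules are identical to the full space.  At these sizes a
candidate evaluation takes a few seconds and a 20-iteration search a
couple of minutes.  Five optimisation steps barely begin to train a
network, so absolute qualities are low; the end-to-end check is therefore
comparative — the search's best must not lose to the median of uniformly
random genotypes trained identically — rather than an absolute accuracy
claim.

## Numerical choices and edge cases

* Probability vectors are renormalised after every update; selection needs
  no tie-breaking because sampling handles zero-mass actions naturally.
* Convolutions use same-padding; input extents must be divisible by the
  total downsampling factor 4, enforced with an explicit shape error.
* Max-pooling resolves ties by first-offset selection, making forward and
  backward passes deterministic.
* Batch normalisation uses batch statistics during training and running
  statistics (momentum 0.1) at inference.
* Labels are coded 0 = background, 1 = CSF, 2 = GM, 3 = WM; Dice/ASD
  reporting excludes background.  `n_classes` defaults to 4 because real
  volumes contain background even though only three tissues are scored.
* Voxel spacing defaults to 1 mm isotropic when a file header omits it,
  so ASD in voxel units equals ASD in mm at the default.

## Known limitations

* The linear reward-penalty scheme with $a = b = 0.5$ is aggressive; no
  convergence guarantee is claimed for the joint 21-automaton game, and
  the oracle-environment tests measure empirical success rates instead.
* Pure-R training is CPU-bound; the engine is meant for desk-scale
  experiments and method development, not for full-resolution clinical
  training runs.
* With few training epochs per candidate the environment separates
  configurations weakly; the search then behaves closer to best-of-budget
  random sampling than to a converged automaton policy.  Longer candidate
  training sharpens the signal at proportional cost.
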