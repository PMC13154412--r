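---
title: "Evolution-guided design of MHCII binding-core peptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution-guided design of MHCII binding-core peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcoev)
```

## The problem

MHC class II molecules present short exogenous peptides to helper T cells.
The presented peptide engages the binding groove through a linear 9-residue
*binding core*, one residue per pocket, with pockets P1, P4, P6 and P9
acting as anchors with strong residue preferences.  Because unbound short
peptides are structurally disordered, structure-based design is of little
use; what is available, per HLA allotype, is a large *aligned, gap-free*
set of known binding cores — effectively a multiple sequence alignment of
fixed length $L$ (default 9) over the 20 canonical amino acids.

`pepcoev` designs *artificial* binding-core sets that reproduce the
evolutionary statistics of such a native set: the per-position residue
frequencies (first order) and the pairwise joint frequencies / coupling
structure (second order).

## Statistics

For an alignment of $M$ sequences, with $f_{ia}$ the observed frequency of
residue $a$ at position $i$ and $q_a$ a background frequency:

* **Positional conservation** (nats):
  $C_i = \sum_a f_{ia}\,\ln(f_{ia}/q_a)$ — the KL divergence of position
  $i$ from background.  Anchor pockets appear as conservation peaks.
* **Positional weights**:
  $k_{ia} = \ln\!\big[f_{ia}(1-q_a)\big/ q_a(1-f_{ia})\big]$, the log-odds
  coefficient of residue $a$ at position $i$; $k_{ia}=0$ iff $f_{ia}=q_a$.
* **Coupling conservation**:
  $C_{ij} = \sum_{a,b} (k_{ia} k_{jb})^2\,(f^{ab}_{ij} - f_{ia} f_{jb})^2$,
  where $f^{ab}_{ij}$ is the joint frequency of the pair.  $C_{ij}$ is
  symmetric, non-negative, vanishes off-diagonal for independent columns
  as $M\to\infty$, and its diagonal is dominated by first-order
  conservation.

Agreement between two coupling matrices is summarized by the Pearson
correlation of their flattened upper triangles (`coupling_pcc`).  The
diagonal is included by default — it carries the strong first-order signal
and its convention is not fixed by the source material — and an
`include_diagonal = FALSE` switch restricts the correlation to genuine
pairwise coupling.

### Numerical choices

* **Pseudocount.** $k_{ia}$ and the logarithm in $C_i$ are undefined at
  $f\in\{0,1\}$, so all estimators share a uniform-mixture regularization
  $f \mapsto (1-\mathrm{pc})f + \mathrm{pc}/A$ (and $\mathrm{pc}/A^2$ for
  off-diagonal joint blocks), with $\mathrm{pc} = 10^{-3}$ by default and
  $\mathrm{pc}=0$ allowed wherever finite.  Diagonal joint blocks keep the
  $\delta_{ab}$ structure with the single-site regularization on their
  diagonal, so every block sums to 1 and marginalization is exact.
* **Background.** The source material never defines $q_a$.  The default is
  the *pooled* empirical composition of the input set (so $C_i$ measures
  deviation from the family's own composition, as in statistical coupling
  analysis); `uniform` ($1/20$) and user-supplied vectors are selectable.
  `compare_designs()` pools over the union of the two sets being compared,
  which makes the comparison exactly invariant under swapping their roles.
* **Logarithms** are natural throughout (units: nats).
* **Alphabet order** is fixed and documented: alphabetical one-letter codes
  (A, C, D, …, Y).  All flattened layouts (tokens $t = (i-1)\cdot 20 + a$)
  follow it.

## The three design routes

**FS (frequency sampling).** Each position of each designed sequence is
drawn independently from the native $f_{i\cdot}$ (regularized, so every
residue has support).  First-order statistics are preserved by
construction; off-diagonal coupling collapses to sampling noise.

**MCSA (MC1 / MC2).** A whole $M$-sequence design set is annealed to
minimize
$E = \sum_{i\ne j}(C^{\mathrm{design}}_{ij}-C^{\mathrm{native}}_{ij})^2
 + w_d \sum_i (\Delta C_{ii})^2$,
with the diagonal down-weighted to $w_d = 0.1$ because its strongly
conserved entries would otherwise dominate.  The design coupling matrix is
recomputed from the design set's *own* regularized statistics at every
step, sharing the native background and pseudocount so $E = 0$ is
attainable in principle.  Schedule defaults: 2000 temperature cycles
(geometric cooling $T_{k+1} = 0.99\,T_k$ from $T_0 = 15$) × 2000 inner
iterations; each (sequence, position) cell mutates with probability 8% per
iteration.  MC1 starts from uniform-random sequences and proposes uniform
replacements; MC2 starts from FS sequences and proposes
frequency-guided replacements (which may redraw the current residue).

*Acceptance granularity.* The description of one iteration — "each position
of the sequences mutated with 8% probability across all M sequences" — can
be read as one joint proposal or as per-sequence proposals.  We measured
the joint (whole-sweep) reading and found it cannot converge: near an
optimum a ~8%-of-all-cells joint move is almost surely uphill, and the
objective stalls at roughly 30% of its initial value even under complete
cooling.  The per-sequence reading (each mutated sequence retained or
reverted by its own Metropolis decision, one inner iteration = one pass
over all $M$ sequences) descends to the expected floor and is the default;
`acceptance = "sweep"` keeps the other reading available.  The inner loop
is compiled (Rcpp) and maintains single-site and pair-count tallies
incrementally, refreshing the coupling matrix only at touched positions; a
debug mode (`debug_check_every`) recomputes everything from scratch and
asserts agreement to $10^{-9}$.

*Objective scale and the reduced schedule.* With $T_0 = 15$ and decay 0.99
the full 2000-cycle schedule sweeps ten orders of magnitude of
temperature, so it anneals essentially any objective scale.  A 300-cycle
test schedule only cools to $T \approx 0.74$ and therefore only freezes
objectives whose per-move $\Delta E$ is of order 1 or larger — i.e.
strongly coupled targets (native off-diagonal $C_{ij}\sim 1$–$10$).  The
package's `strongly_coupled_spec()` (below) provides exactly that regime
and is the fixture for the reduced recovery tests; weakly coupled targets
simply need the longer printed schedule.

**Attention network (L1 / L2).** A small generative model maps one
allotype's statistics pair to per-position output probabilities $P_{ia}$:
the frequency matrix, flattened to a length-$180$ vector, passes through a
1-D convolution; the joint tensor, reshaped to $180\times180$, through a
2-D convolution; the per-token convolved features are concatenated,
linearly embedded (with a learned positional embedding) and processed by a
stack of pre-norm Transformer blocks with multi-head scaled dot-product
attention $\mathrm{softmax}(QK^\top/\sqrt{d_k})$; a 1-D convolutional head
produces one logit per (position, residue) token and a per-position
softmax yields $P_{ia}$.  Published essentials are defaults (12 blocks,
Adam lr $10^{-4}$, 2000 epochs, $\lambda = 65$); unpublished details are
exposed configuration with standard small-attention defaults ($H = 4$
heads, width $d = 128$, kernel 3, feed-forward $4d$).  A reduced preset
(2 blocks, $d = 64$) runs in minutes on one CPU and is what the test
suite trains.

Losses: `loss1` is the $(L\cdot20)^{-2}$-normalized MSE between predicted
and native joint frequencies, averaged over the allotype batch; `loss2`
adds the (un-normalized) per-position frequency MSE plus
$\lambda\cdot\mathrm{loss1}$.  Because the model outputs only per-position
distributions and sequences are sampled position-independently, the
predicted joint frequencies entering the loss are the *product surrogate*
$\hat f^{ab}_{ij} = P_{ia}P_{jb}$ ($i\ne j$; $\delta_{ab}P_{ia}$ on the
diagonal) — the unique construction consistent with independent sampling,
and differentiable.  Whether the original work used this surrogate or
statistics of sampled sequences is unstated; the choice is documented, not
asserted.

*Autodiff.* No deep-learning framework is assumed: the model runs on a
small in-package tape-based reverse-mode autodiff over BLAS matrix
primitives (matmul, row-softmax, layer norm, ReLU, gathers).  Every
primitive's gradient is verified against central finite differences in the
test suite (relative error $<10^{-5}$ on sampled parameters).

*Batching.* One training example is one allotype's statistics pair.  The
published batch composition is unstated; the default is `batch_size = 1`
(one Adam step per allotype per epoch, seeded shuffled order).  Full-batch
training at the printed learning rate takes too few optimizer steps in a
300-epoch reduced run to converge, which is why the spec-suggested
"all allotypes per step" default was not adopted.  Training is
bit-deterministic given the seed; `n_repeats` reruns with derived seeds to
measure run-to-run spread.

## Synthetic data: what it emulates, and what it does not

`synthetic_spec` defines a **mixture of profile models**: a sequence is
generated by picking component $k$ with probability $w_k$ and sampling
each position independently from that component's profile $p_k$.  This was
chosen over a Potts-style pairwise generator because both first- and
second-order statistics have closed forms —
$f_{ia} = \sum_k w_k\, p_{k,ia}$ and
$f^{ab}_{ij} = \sum_k w_k\, p_{k,ia} p_{k,jb}$ ($i \ne j$) — giving every
downstream estimator and design route an exact, independent oracle
(`exact_statistics`, enumerated exhaustively in tests at small alphabet).
Coupling strength is tuned by component contrast; $K = 1$ gives exactly
independent columns.

`make_benchmark_suite` builds three synthetic "allotypes" (M = 500 each,
L = 9, anchors at P1/P4/P6/P9 with peak profile mass 0.90/0.85/0.80 and
component contrasts 0.75/0.65/0.55, K = 3–4) emulating moderately coupled
native sets; all pass the ≥200-sequence allotype filter.
`strongly_coupled_spec` is the canonical maximal-coupling world: two equal
components sharing anchors but preferring disjoint residues (mass 0.9)
everywhere else.

What the generator does **not** emulate: real binding-core sets have
residue-class-structured anchor preferences (hydrophobic P1, charged P4,
…), position-dependent amino-acid usage beyond a global background,
phylogenetic and ascertainment correlations between sequences, and
prediction noise from the upstream binding-core assignment.  A green test
therefore establishes that the estimators and design algorithms recover
known statistical structure at realistic sizes — not that designed
peptides bind real MHCII molecules.  Affinity and structure validation
are export-only concerns here (`write_designed`, `export_bundle` produce
FASTA/CSV bundles for external predictors); no external service is
called.

## Degenerate inputs and tie-breaks

* `positional_weights` raises an explicit domain error naming the
  offending (position, residue) when $f\in\{0,1\}$ with zero pseudocount.
* `coupling_pcc` requires ≥3 included elements and nonzero variance in
  both matrices (self-comparison of a constant matrix is an error, not 1).
* Metropolis: $\Delta E \le 0$ is always accepted ($\exp(0)=1$ at the
  boundary); $T \le 0$ is an error; the zero-temperature limit is greedy
  descent.
* Uniform mutation proposals exclude the current residue (a "mutation"
  always changes the cell); frequency-guided proposals may redraw it, in
  which case no Metropolis decision is spent.
* `sample_fs` and all samplers take explicit seeds; identical seeds give
  bit-identical designs.

## Known limitations

* The attention model trains on CPU via R-level autodiff: fine at the
  reduced preset and workable at the full printed configuration, but not a
  GPU-scale implementation.
* With per-sequence acceptance the annealer's wall-clock cost is
  $O(M \cdot n_\mathrm{outer} \cdot n_\mathrm{inner})$ Metropolis
  decisions; the full printed schedule at M ≈ 200 runs in tens of minutes
  on one CPU.
* Only first- and second-order statistics are modelled; three-site and
  higher interactions are out of scope.
* The package never predicts binding cores from full-length peptides, nor
  affinity or structure; it consumes already-aligned cores and exports
  designs for external validators.
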