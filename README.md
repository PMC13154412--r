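# pepcoev — evolution-guided design of MHCII binding-core peptides

MHC class II molecules present short peptides to helper T cells through a
nine-pocket binding groove; the presented peptide's 9-residue **binding
core** carries essentially all of the interaction.  Designing artificial
binding cores for a given HLA allotype is hard for structure-based methods
because unbound short peptides are disordered — but per-allotype
collections of known binding cores form large, gap-free, fixed-length
alignments whose *evolutionary statistics* are highly informative.

`pepcoev` is for immunoinformaticians who have such per-allotype core sets
(or want realistic synthetic ones) and need designed peptide sets that
reproduce their statistics.  It extracts, for an alignment of M sequences
at L positions (default L = 9):

* site frequencies `f_ia` and positional conservation
  `C_i = Σ_a f_ia ln(f_ia/q_a)` (KL divergence from background, in nats) —
  anchor pockets P1/P4/P6/P9 show up as conservation peaks;
* positional log-odds weights `k_ia = ln[f_ia(1−q_a)/(q_a(1−f_ia))]`;
* pairwise joint frequencies `f_ij^ab` and the coupling matrix
  `C_ij = Σ_ab (k_ia k_jb)² (f_ij^ab − f_ia f_jb)²`.

and generates designed sets by three routes:

| route | what it matches | how |
|---|---|---|
| **FS** | first order | independent per-position sampling from `f_i·` |
| **MC1 / MC2** | coupling (MC2: + frequencies) | simulated annealing of a whole M-sequence set on `E = Σ_{i≠j} ΔC_ij² + 0.1·Σ_i ΔC_ii²` (T0 = 15, geometric decay 0.99, 2000×2000 schedule, 8% per-cell mutations, Metropolis acceptance; compiled inner loop) |
| **L1 / L2** | joint frequencies (L2: + frequencies) | small convolution + multi-head-attention generative model trained with MSE matching losses (`loss2 = freq-MSE + λ·joint-MSE`, λ = 65, Adam 1e-4) |

A mixture-of-profiles synthetic-data module provides alignments with
closed-form target statistics for testing and benchmarking, and an
evaluation module summarizes designed-vs-native agreement (frequency PCC,
coupling PCC, per-position KL) and exports FASTA/CSV bundles for external
affinity/structure validators.

## Worked example

```r
library(pepcoev)

# a strongly coupled synthetic "allotype": 200 native binding cores
spec   <- strongly_coupled_spec(L = 9, seed = 99)
native <- sample_msa(spec, 200, seed = 42)
st     <- evo_statistics(native)          # f, q, C_i, k, f_ij, C_ij
print(st)

# FS design: keeps first-order, loses coupling
fs <- sample_fs(st$frequencies, n = 200, seed = 13)
print(compare_designs(native, fs, strategy = "FS"))

# MC2 design at a reduced 300x300 schedule (other defaults as published)
res <- anneal(st, mcsa_preset("MC2", n_outer = 300, n_inner = 300,
                              M = 200, seed = 7))
print(res)
print(compare_designs(native, res$design, strategy = "MC2"))
```

Output (exactly as printed by the code above):

```
evo_statistics: L=9, alphabet=20, pseudocount=0.001, background=pooled
conservation C_i (nats):  1.899 1.813 1.794 1.552 1.752 1.807 1.341 1.344 1.409

design_report [FS]: first-order PCC 0.9989 | coupling PCC 0.6670 | mean KL 0.04187 nats

anneal_result: M=200, L=9 | E: 644.2 -> 13.25 (2.1% of initial) | accept rate 0.751

design_report [MC2]: first-order PCC 0.9977 | coupling PCC 0.9684 | mean KL 0.04681 nats
```

Reading it: both designs reproduce the native site frequencies (first-order
PCC ≈ 1), but only the annealed MC2 set also reproduces the coupling
structure (coupling PCC 0.97 vs 0.67 for FS) — frequency sampling cannot
carry second-order conservation, which is the point of the coupling-aware
routes.  The annealing objective fell to 2.3% of its initial value over the
reduced schedule.

The network route is analogous:

```r
suite <- make_benchmark_suite(1)                      # 3 synthetic allotypes
stats <- lapply(unclass(suite$dataset), evo_statistics)
tm  <- train_design_model(stats, reduced_model_config(),
                          training_config(epochs = 300, seed = 2))  # ~2 min CPU
des <- design_from_model(tm, stats[[1]], n = 5000, seed = 4)
```

(Final Loss2 is ~0.4% of the epoch-1 loss at this preset, and the designed
set's site-frequency PCC against native is ≈ 0.999 — the test suite and
acceptance script recompute both.)

## Command line

```sh
Rscript inst/cli/pepcoev.R synth       --out out/synth --seed 1
Rscript inst/cli/pepcoev.R stats       --input cores.txt --out out/stats
Rscript inst/cli/pepcoev.R design-mcsa --input cores.txt --variant MC2 --out out/mc2
Rscript inst/cli/pepcoev.R train       --input dataset.csv --preset reduced --out out/model
Rscript inst/cli/pepcoev.R design-nn   --model out/model/model.rds --input cores.txt --out out/l2
Rscript inst/cli/pepcoev.R evaluate    --native cores.txt --designed out/mc2/designed.fasta --out out/report
```

Every subcommand accepts `--config file` (flat `key: value` lines), takes an
explicit `--seed`, and writes the exact configuration used to
`run_config.txt` in its output directory.  Defaults mirror the published
parameters (L = 9, T0 = 15, decay 0.99, 2000×2000, 8% mutation, diagonal
weight 0.1, λ = 65, lr 1e-4, 2000 epochs, 12 blocks).

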