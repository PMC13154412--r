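# Shared fixtures, computed lazily once per test session.  The heavier
# objects (annealing runs, network trainings) are used by several files;
# memoizing them keeps the suite inside its time budget.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fx_bench <- function() fixture("bench", function() make_benchmark_suite(1))

fx_bench_stats <- function() fixture("bench_stats", function()
  lapply(unclass(fx_bench()$dataset), evo_statistics))

# strongly coupled recovery world: spec, native M = 200 alignment, stats
fx_strong <- function() fixture("strong", function() {
  spec <- strongly_coupled_spec(L = 9, seed = 99)
  native <- sample_msa(spec, 200, seed = 42)
  list(spec = spec, native = native, stats = evo_statistics(native))
})

# reduced-schedule annealing runs at the published defaults
fx_mc <- function(variant) fixture(paste0("mc_", variant), function() {
  st <- fx_strong()$stats
  cfg <- mcsa_preset(variant, n_outer = 300, n_inner = 300, M = 200,
                     seed = 7, trace_every = 10, debug_check_every = 20000)
  res <- anneal(st, cfg)
  dst <- evo_statistics(res$design, bg = st$background)
  list(res = res, stats = dst)
})

# reduced-preset network training on the 3-allotype benchmark
fx_nn <- function(lambda = 65) fixture(sprintf("nn_l%g", lambda), function() {
  train_design_model(fx_bench_stats(), reduced_model_config(),
                     training_config(lambda = lambda, epochs = 300, seed = 2))
})

# tiny world for fast unit tests of the network
fx_tiny_stats <- function() fixture("tiny_stats", function() {
  suite <- make_benchmark_suite(5, M = 60, L = 3, alphabet = aa_alphabet(4))
  lapply(unclass(suite$dataset), evo_statistics)
})

tiny_model_config <- function() {
  design_model_config(L = 3, alphabet_size = 4, n_blocks = 2, n_heads = 2,
                      d = 8, conv1d_channels = 3, conv2d_channels = 2)
}
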