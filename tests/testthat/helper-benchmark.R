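# Shared benchmark fixtures, built once per test run and memoised. The
# benchmark population is the package's desk-scale stand-in for a clinical
# cohort: 10 phantom patients x 8 repeats at 32x32x24 voxels (2 mm), the
# last 2 patients held out entirely.

.bench_cache <- new.env(parent = emptyenv())

bench_seed <- 20L

bench_population <- function() {
  if (is.null(.bench_cache$pop))
    .bench_cache$pop <- generate_population(10, 8, seed = bench_seed)
  .bench_cache$pop
}

bench_train_cases <- function() {
  Filter(function(cs) cs$split == "train", bench_population()$cases)
}

bench_test_cases <- function() {
  Filter(function(cs) cs$split == "test", bench_population()$cases)
}

# benchmark network: narrow towers keep the suite within its time budget;
# the architecture family (3 levels, GN, r + z conditioned generator) is
# unchanged
bench_network <- function(N) {
  network_config(N = N, conv_channels = 8L, gn_groups = 4L,
                 gen_head_channels = c(8L, 3L))
}

# training recipe of the benchmark checkpoints: batch size 1 and a
# deterministic warm-up (see the methods vignette); the N = 1 run is the
# cheaper companion for the latent-dimension trend
bench_train_config <- function(N) {
  loss <- loss_config(dice_weight = 50)
  if (N == 8L)
    train_config(epochs = 26L, batch_size = 1L, warmup_epochs = 12L,
                 seed = 7L, max_restarts = 1L, loss = loss,
                 network = bench_network(8L))
  else
    train_config(epochs = 12L, batch_size = 1L, warmup_epochs = 7L,
                 seed = 7L, max_restarts = 1L, loss = loss,
                 network = bench_network(N))
}

bench_model <- function(N) {
  key <- paste0("model_", N)
  if (is.null(.bench_cache[[key]])) {
    cfg <- bench_train_config(N)
    .bench_cache[[key]] <- train_model(bench_train_cases(), cfg)$model
  }
  .bench_cache[[key]]
}
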