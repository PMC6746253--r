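# Shared, lazily-built end-to-end benchmark artifacts. The detection
# benchmark (6 training + 4 held-out wild-type scenes, seed 1, default
# configuration) is expensive, so it is trained once per test run and
# reused by every test that needs a trained model or its predictions.

.bench_cache <- new.env(parent = emptyenv())

bench_run <- function() {
  if (is.null(.bench_cache$run)) {
    dir <- file.path(tempdir(), "starchseg-benchmark")
    .bench_cache$run <- suppressMessages(
      detection_benchmark(seed = 1, n_train = 6, n_test = 4, dir = dir))
  }
  .bench_cache$run
}
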