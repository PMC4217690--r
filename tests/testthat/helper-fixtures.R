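# Lazily built, memoised heavy fixtures shared across test files. The
# default benchmark bundle and its trained scorers take a few seconds to
# build; construct them once per test run.

.fixture_env <- new.env(parent = emptyenv())

default_benchmark <- function() {
  if (is.null(.fixture_env$bench)) {
    .fixture_env$bench <- build_benchmark(benchmark_spec(seed = 42))
  }
  .fixture_env$bench
}

benchmark_scorer <- function(kind) {
  key <- paste0("scorer_", kind)
  if (is.null(.fixture_env[[key]])) {
    b <- default_benchmark()
    .fixture_env[[key]] <- train_scorer(kind, b$training_crms,
                                        b$background)
  }
  .fixture_env[[key]]
}

benchmark_ranked <- function(kind = "mshexmcd") {
  key <- paste0("ranked_", kind)
  if (is.null(.fixture_env[[key]])) {
    b <- default_benchmark()
    prof <- scan_genome(benchmark_scorer(kind), b$genome)
    .fixture_env[[key]] <- assign_global_ranks(prof)
  }
  .fixture_env[[key]]
}
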