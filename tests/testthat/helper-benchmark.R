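# The end-to-end virtual-species benchmark is expensive (minutes), so one run
# is shared across all test blocks that examine it.
.benchmark_cache <- new.env(parent = emptyenv())

get_benchmark <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.benchmark_cache[[key]]))
    .benchmark_cache[[key]] <- suppressWarnings(synthetic_benchmark(seed))
  .benchmark_cache[[key]]
}
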