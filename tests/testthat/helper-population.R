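# One moderately sized Monte Carlo filter run shared across test files
# (computed lazily, once per test session).

.pop_cache <- new.env(parent = emptyenv())

population_fixture <- function(N = 150000, seed = 20240901) {
  key <- sprintf("pop_%d_%d", N, seed)
  if (is.null(.pop_cache[[key]]))
    .pop_cache[[key]] <- run_filter(N, seed = seed)
  .pop_cache[[key]]
}
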