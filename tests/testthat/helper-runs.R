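# Shared fixtures: one memoised standard run per variant so test files do not
# re-integrate the same diel cycle repeatedly.

.run_cache <- new.env(parent = emptyenv())

std_run <- function(variant = c("unified", "segregated"), ...) {
  variant <- match.arg(variant)
  key <- paste(variant, paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- integrate_diel(
      fixed_parameters(),
      default_optimized_parameters(variant),
      run_config(variant = variant, ...)
    )
  }
  .run_cache[[key]]
}

# coarse, fast settings for tests that exercise machinery rather than accuracy
fast_config <- function(...) {
  run_config(rtol = 1e-5, atol = 1e-8, dt_out = 600, ...)
}
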