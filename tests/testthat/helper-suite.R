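# The 12 reference scenarios (4 layouts x 3 haul-in procedures) at the
# desk-scale profile take a few minutes; they are run once and shared by
# every test that needs full-haul results.
.suite_cache <- new.env(parent = emptyenv())

reference_suite <- function() {
  if (is.null(.suite_cache$suite)) {
    .suite_cache$suite <- run_scenario_suite(seed = 1)
  }
  .suite_cache$suite
}
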