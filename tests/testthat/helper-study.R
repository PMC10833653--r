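# The full planted-cohort simulation study is expensive; run it once per
# session and share it across test blocks.
full_study_cached <- local({
  res <- NULL
  function() {
    if (is.null(res))
      res <<- run_simulation_study(seed = 1L, verbose = FALSE)
    res
  }
})
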