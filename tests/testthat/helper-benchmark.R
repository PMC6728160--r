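# The end-to-end phantom benchmark (cohort generation, training of both
# compact networks, corruption and both pipeline paths) is computed once and
# shared by the network, pipeline and acceptance tests.
cached_benchmark <- local({
  env <- new.env()
  function() {
    if (is.null(env$bm))
      env$bm <- run_phantom_benchmark(pipeline_config(rng_seed = 42L))
    env$bm
  }
})
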