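## The scaled-down study run shared by the trend tests: desk preset
## (4 loci x 2 kb, 50 individuals, 300 generations, mu = 0.001), fixed
## seed. Computed lazily once and cached for the session.

desk_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      t0 <- Sys.time()
      res <- run_pipeline(regevo_config("desk"), seed = 11)
      res$elapsed_min <- as.numeric(difftime(Sys.time(), t0,
                                             units = "mins"))
      cache <<- res
    }
    cache
  }
})
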