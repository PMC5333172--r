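## Small shared fixtures built in code. Everything is seeded; the tiny
## model configuration keeps expression simulations in the millisecond
## range.

fixture_pwms <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_pwm_set(default_tf_specs(), rng_seed = 101,
                             n_calib = 2e4)
    cache
  }
})

fixture_genotype <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_genotype(
        default_locus_specs(length = 600L, n_planted = 5L),
        fixture_pwms(), rng_seed = 202)
    cache
  }
})

tiny_params <- function(pwms = fixture_pwms(), ...) {
  model_params(pwms, dt = 0.01, t_end = 0.5, obs_times = c(0.25, 0.5),
               ...)
}

tiny_profiles <- function(n = 8) make_tf_profiles(n)

## hand-built annotation data.frame
ann_df <- function(tf, locus, start, length, strand = "+", E = 10) {
  data.frame(tf = tf, locus = locus, start = as.integer(start),
             length = as.integer(length),
             strand = rep_len(strand, base::length(tf)),
             E = rep_len(E, base::length(tf)), stringsAsFactors = FALSE)
}

## a minimal run object sufficient for the tracking / analysis functions:
## hand-specified tracked annotations per generation
fake_run <- function(anns, loci = c("hb", "Kr", "gt", "kni"),
                     loci_lengths = c(hb = 500, Kr = 500, gt = 500,
                                      kni = 500), bin_width = 100) {
  bins <- regevo:::make_bins(loci_lengths, bin_width)
  mats <- lapply(anns, regevo:::ann_df_to_matrix)
  founder_keys <- regevo:::site_keys(mats[[1]])
  records <- lapply(seq_along(mats), function(g) {
    st <- regevo:::generation_stats_(mats[g], founder_keys, bins,
                                     bin_width, 8L)
    list(gen = g - 1L, F_pop = rep(0.1 * g, 4), elite_F = rep(0.1 * g, 2),
         tracked_F = 0.1 * g, tracked_annotation = mats[[g]], stats = st)
  })
  structure(list(records = records, founder_annotation = mats[[1]],
                 loci = loci, tf_names = regevo:::REGEVO_TFS,
                 bins = bins, bin_width = bin_width),
            class = "regevo_run")
}
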