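#' Pipeline configuration
#'
#' Two presets: "desk" (4 loci x 2 kb, 30 nuclei, 50 individuals, 300
#' generations) keeps a full run in the minutes range; "full" mirrors
#' the full-scale study conditions (18 kb loci, 100 individuals, 3,350
#' generations) and is expressible but slow. Any field can be overridden
#' via `...` using nested lists, e.g.
#' `regevo_config("desk", evo = list(generations = 50))`.
#'
#' @param preset "desk" or "full"
#' @param ... named overrides merged over the preset (per section:
#'   loci, pwm, profiles, model, evo)
#' @return configuration list of class `regevo_config`
#' @export
regevo_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    loci = list(length = 2000L, accessible_fraction = 0.8,
                n_planted = 15L),
    pwm = list(info_content = 1.2, p_hit = 5e-4),
    profiles = list(n_nuclei = 30L, c_max = 1),
    model = list(dt = 0.01, t_end = 2, obs_times = c(0.5, 1, 1.5, 2),
                 beta = 0.3, omega = 1, coop_range = 50,
                 high_score_offset = 2),
    evo = list(population_size = 50L, mu = 0.001, generations = 300L,
               elite_size = 20L),
    analysis = list(bin_width = 180L, n_sets = 35L, burn_in = 100L))
  if (preset == "full") {
    cfg$loci$length <- 18000L
    cfg$evo$population_size <- 100L
    cfg$evo$generations <- 3350L
  }
  ov <- list(...)
  for (sec in names(ov)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (f in names(ov[[sec]])) cfg[[sec]][[f]] <- ov[[sec]][[f]]
  }
  structure(validate_config(cfg), class = "regevo_config")
}

#' Validate a configuration
#'
#' Checks presence and ranges of every required field; errors name the
#' offending field.
#'
#' @param cfg configuration list
#' @return the validated configuration (invisibly unchanged)
#' @export
validate_config <- function(cfg) {
  need <- list(
    loci = c("length", "accessible_fraction", "n_planted"),
    pwm = c("info_content", "p_hit"),
    profiles = c("n_nuclei", "c_max"),
    model = c("dt", "t_end", "obs_times", "beta", "omega", "coop_range",
              "high_score_offset"),
    evo = c("population_size", "mu", "generations", "elite_size"),
    analysis = c("bin_width", "n_sets", "burn_in"))
  for (sec in names(need)) {
    if (is.null(cfg[[sec]]))
      stop("config validation: missing section '", sec, "'")
    for (f in need[[sec]])
      if (is.null(cfg[[sec]][[f]]))
        stop("config validation: missing field '", sec, "$", f, "'")
  }
  with(cfg, {
    if (loci$length < 100) stop("config validation: loci$length too small")
    if (evo$mu < 0 || evo$mu > 1) stop("config validation: evo$mu outside [0,1]")
    if (evo$elite_size > evo$population_size)
      stop("config validation: evo$elite_size > evo$population_size")
    if (model$dt <= 0) stop("config validation: model$dt must be positive")
  })
  cfg
}

#' Read a YAML configuration file
#' @param path YAML file with the sections of [regevo_config()]
#' @return validated `regevo_config`
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "desk"
  y$preset <- NULL
  do.call(regevo_config, c(list(preset = preset), y))
}

#' Run the full pipeline
#'
#' Orchestrates generate -> evolve -> track -> analyze with fully derived
#' stage seeds, writes the standard-format outputs (FASTA loci, BED
#' interval sets and sites, PWM file, delimited result tables) and a
#' manifest with per-file checksums.
#'
#' @param config a `regevo_config` (or path to a YAML file)
#' @param seed global integer seed
#' @param out_dir output directory (created if missing); NULL skips all
#'   file output
#' @param keep_elite store full elite annotations in the run object
#' @param progress print stage progress
#' @param through_stage last stage to execute ("generate", "evolve",
#'   "track" or "analyze"); earlier stages always run since later ones
#'   consume their objects
#' @return list(run, tracks, manifest, summary) invisibly (components
#'   NULL for stages not executed)
#' @export
run_pipeline <- function(config = regevo_config(), seed = 1,
                         out_dir = NULL, keep_elite = FALSE,
                         progress = FALSE,
                         through_stage = c("analyze", "generate",
                                           "evolve", "track")) {
  through_stage <- match.arg(through_stage)
  stage_rank <- match(through_stage,
                      c("generate", "evolve", "track", "analyze"))
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "regevo_config")) config <- validate_config(config)
  stage_seeds <- c(pwm = derive_seed(seed, 101),
                   genotype = derive_seed(seed, 102),
                   evolve = derive_seed(seed, 103),
                   analysis = derive_seed(seed, 104))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- "ok"

  ## -- generate ---------------------------------------------------------
  if (progress) message("stage: generate")
  specs <- default_tf_specs(info_content = config$pwm$info_content)
  pwms <- make_pwm_set(specs, rng_seed = stage_seeds[["pwm"]],
                       p_hit = config$pwm$p_hit)
  loci <- default_locus_specs(
    length = config$loci$length,
    accessible_fraction = config$loci$accessible_fraction,
    n_planted = config$loci$n_planted)
  founder <- make_genotype(loci, pwms,
                           rng_seed = stage_seeds[["genotype"]])
  profiles <- make_tf_profiles(config$profiles$n_nuclei,
                               c_max = config$profiles$c_max)
  params <- model_params(pwms, dt = config$model$dt,
                         t_end = config$model$t_end,
                         obs_times = config$model$obs_times,
                         beta = config$model$beta,
                         omega = config$model$omega,
                         coop_range = config$model$coop_range)
  if (!is.null(out_dir)) {
    write_fasta_loci(founder, file.path(out_dir, "loci.fasta"))
    write_pwms(pwms, file.path(out_dir, "pwms.txt"))
    write_bed_intervals(founder$accessibility,
                        file.path(out_dir, "accessibility.bed"), "open")
    write_bed_intervals(founder$crms, file.path(out_dir, "crms.bed"),
                        "crm")
    write_bed_intervals(founder$footprints,
                        file.path(out_dir, "footprints.bed"), "footprint")
    pl <- founder$planted
    write.table(pl, file.path(out_dir, "planted_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (stage_rank < 2) {
    manifest <- if (!is.null(out_dir))
      write_manifest(out_dir, unclass(config), seed, stage_seeds, status)
    else NULL
    return(invisible(list(run = NULL, tracks = NULL,
                          manifest = manifest, summary = NULL,
                          pwms = pwms, founder = founder,
                          params = params, profiles = profiles)))
  }

  ## -- evolve -----------------------------------------------------------
  if (progress) message("stage: evolve")
  evo <- evo_config(population_size = config$evo$population_size,
                    mu = config$evo$mu,
                    generations = config$evo$generations,
                    elite_size = config$evo$elite_size,
                    seed = stage_seeds[["evolve"]])
  run <- evolve(founder, pwms, params, profiles, evo,
                keep_elite = keep_elite,
                bin_width = config$analysis$bin_width,
                high_score_offset = config$model$high_score_offset,
                progress = progress)
  if (!is.null(out_dir)) {
    ann0 <- ann_matrix_to_df(run$founder_annotation, run$tf_names,
                             run$loci)
    write_bed_sites(ann0, file.path(out_dir, "sites_wildtype.bed"))
    lastm <- run$records[[length(run$records)]]$tracked_annotation
    write_bed_sites(ann_matrix_to_df(lastm, run$tf_names, run$loci),
                    file.path(out_dir, "sites_final_tracked.bed"))
    Ftab <- do.call(rbind, lapply(run$records, function(r)
      data.frame(gen = r$gen, mean_F = mean(r$F_pop[is.finite(r$F_pop)]),
                 best_F = min(r$F_pop), elite_mean_F = mean(r$elite_F),
                 elite_sites = r$stats$n_sites,
                 new_sites = r$stats$n_new,
                 mean_E = r$stats$mean_E)))
    write.table(Ftab, file.path(out_dir, "generations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (stage_rank < 3) {
    manifest <- if (!is.null(out_dir))
      write_manifest(out_dir, unclass(config), seed, stage_seeds, status)
    else NULL
    return(invisible(list(run = run, tracks = NULL, manifest = manifest,
                          summary = NULL, pwms = pwms, founder = founder,
                          params = params, profiles = profiles)))
  }

  ## -- track ------------------------------------------------------------
  if (progress) message("stage: track")
  tracks <- track_sites(run)
  if (!is.null(out_dir))
    write.table(tracks$trajectories,
                file.path(out_dir, "trajectories.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (stage_rank < 4) {
    manifest <- if (!is.null(out_dir))
      write_manifest(out_dir, unclass(config), seed, stage_seeds, status)
    else NULL
    return(invisible(list(run = run, tracks = tracks,
                          manifest = manifest, summary = NULL,
                          pwms = pwms, founder = founder,
                          params = params, profiles = profiles)))
  }

  ## -- analyze ----------------------------------------------------------
  if (progress) message("stage: analyze")
  core <- core_sites(tracks)
  nb <- classify_neighbors(tracks,
                           coop_range = config$model$coop_range)
  lt <- lifetimes(tracks)
  summary <- list(
    n_sites_initial = run$records[[1]]$stats$n_sites,
    n_sites_final = run$records[[length(run$records)]]$stats$n_sites,
    n_core = nrow(core),
    n_cooperative = sum(nb$class == "cooperative"),
    n_overlapping = sum(nb$class == "overlapping"),
    overlap_fraction_initial = overlap_fractions(
      ann_matrix_to_df(run$founder_annotation, run$tf_names, run$loci)),
    founder_F = run$records[[1]]$elite_F[1])
  if (!is.null(out_dir)) {
    ed <- energy_dynamics(run, "all")
    write.table(ed, file.path(out_dir, "energy_dynamics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(lt, file.path(out_dir, "lifetimes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- if (!is.null(out_dir))
    write_manifest(out_dir, unclass(config), seed, stage_seeds, status)
  else NULL
  invisible(list(run = run, tracks = tracks, manifest = manifest,
                 summary = summary,
                 pwms = pwms, founder = founder, params = params,
                 profiles = profiles))
}
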