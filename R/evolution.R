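#' Configuration of the evolutionary simulation
#'
#' @param population_size number of haploid individuals
#' @param mu substitution rate per bp per generation
#' @param generations number of generations to simulate
#' @param elite_size truncation-selection rank cutoff: individuals at
#'   least as fit as the `elite_size`-th best (rms-score ties included)
#'   are eligible parents
#' @param seed integer RNG seed for the whole run
#' @return object of class `regevo_evo_config`
#' @export
evo_config <- function(population_size = 100L, mu = 0.001,
                       generations = 300L, elite_size = 20L, seed = 1L) {
  stopifnot(elite_size <= population_size, mu >= 0, mu <= 1,
            generations >= 1)
  structure(list(population_size = as.integer(population_size), mu = mu,
                 generations = as.integer(generations),
                 elite_size = as.integer(elite_size),
                 seed = as.integer(seed)),
            class = "regevo_evo_config")
}

## substitution mutation on an integer-coded sequence restricted to the
## given (1-based) mutable positions; draws from the current RNG stream
mutate_code_ <- function(code, mutable, mu) {
  if (mu <= 0 || length(mutable) == 0) return(code)
  k <- rbinom(1L, length(mutable), mu)
  if (k == 0) return(code)
  pos <- if (k == length(mutable)) mutable else sample(mutable, k)
  code[pos] <- ((code[pos] - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L
  code
}

#' Mutate a genotype
#'
#' Each accessible base pair is independently substituted with
#' probability `mu`, uniformly to one of the three other bases.
#' Substitutions only: sequence lengths and the coordinate system are
#' unchanged, which the site-tracking algorithm presupposes. The
#' represented (mutable) sequence is the union of accessibility
#' intervals.
#'
#' @param genotype a `regevo_genotype`
#' @param mu substitution probability per bp per generation
#' @param rng_seed optional seed; if NULL the current RNG stream is used
#' @return mutated `regevo_genotype`
#' @export
mutate_genotype <- function(genotype, mu, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  mutable <- accessible_positions(genotype)
  for (g in names(genotype$code))
    genotype$code[[g]] <- mutate_code_(genotype$code[[g]], mutable[[g]], mu)
  genotype
}

accessible_positions <- function(genotype) {
  lapply(names(genotype$code), function(g) {
    iv <- genotype$accessibility[[g]]
    if (nrow(iv) == 0) return(integer(0))
    unlist(lapply(seq_len(nrow(iv)), function(k)
      if (iv$end[k] > iv$start[k]) (iv$start[k] + 1L):iv$end[k]
      else integer(0)))
  }) |> setNames(names(genotype$code))
}

#' Truncation selection: draw a parent pair
#'
#' The eligible set contains every individual whose rms-score is at most
#' the `elite_size`-th smallest (ties at the boundary included). Both
#' parents are drawn uniformly from it, with replacement.
#'
#' @param F numeric vector of rms-scores (lower = fitter)
#' @param elite_size rank cutoff
#' @return integer vector of two parent indices
#' @export
select_parents <- function(F, elite_size) {
  eligible <- eligible_set(F, elite_size)
  eligible[sample.int(length(eligible), 2L, replace = TRUE)]
}

eligible_set <- function(F, elite_size) {
  cutoff <- sort(F)[elite_size]
  which(F <= cutoff)
}

#' Recombine two parental genotypes
#'
#' Free recombination between loci, none within: each of the four loci is
#' copied whole from parent A or parent B with probability 1/2,
#' independently.
#'
#' @param parent_a,parent_b genotypes with identical locus structure
#' @param rng_seed optional seed; if NULL the current RNG stream is used
#' @return child `regevo_genotype`
#' @export
recombine <- function(parent_a, parent_b, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  stopifnot(identical(names(parent_a$code), names(parent_b$code)))
  child <- parent_a
  from_b <- runif(length(child$code)) < 0.5
  for (k in which(from_b)) child$code[[k]] <- parent_b$code[[k]]
  child
}

## per-generation summary statistics over the elite annotations
generation_stats_ <- function(anns_elite, founder_keys, bins, bin_width,
                              n_tf) {
  pooled_E <- numeric(0)
  new_E <- numeric(0)
  n_sites <- 0L
  n_new <- 0L
  tf_counts <- numeric(n_tf)
  binsum <- numeric(bins$n_total)
  for (m in anns_elite) {
    n_sites <- n_sites + nrow(m)
    if (nrow(m) == 0) next
    pooled_E <- c(pooled_E, m[, "E"])
    key <- site_keys(m)
    isnew <- !(key %in% founder_keys)
    n_new <- n_new + sum(isnew)
    new_E <- c(new_E, m[isnew, "E"])
    tf_counts <- tf_counts + tabulate(m[, "tf"], n_tf)
    bi <- bins$offset[m[, "locus"]] + (m[, "start"] %/% bin_width) + 1L
    binsum <- binsum + unname(rowsum_vec(m[, "E"], bi, bins$n_total))
  }
  ne <- length(anns_elite)
  list(n_sites = n_sites / ne, n_new = n_new / ne,
       tf_counts = tf_counts / ne,
       mean_E = if (length(pooled_E)) mean(pooled_E) else NA_real_,
       sd_E = if (length(pooled_E) > 1) sd(pooled_E) else NA_real_,
       mean_E_new = if (length(new_E)) mean(new_E) else NA_real_,
       sd_E_new = if (length(new_E) > 1) sd(new_E) else NA_real_,
       bin_E = (binsum / ne) / bins$width)
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

## fixed-width bins tiling each locus (last bin may be shorter)
make_bins <- function(loci_lengths, bin_width) {
  n_per <- pmax(1L, as.integer(ceiling(loci_lengths / bin_width)))
  offset <- cumsum(c(0L, n_per[-length(n_per)]))
  width <- unlist(lapply(seq_along(n_per), function(k) {
    w <- rep(bin_width, n_per[k])
    w[n_per[k]] <- loci_lengths[k] - (n_per[k] - 1L) * bin_width
    w
  }))
  list(n_per = n_per, offset = offset, n_total = sum(n_per),
       width = width)
}

site_keys <- function(m) {
  ## unique key per (locus, tf, start, strand); lengths are per-TF fixed
  m[, "locus"] * 1e9 + m[, "tf"] * 1e7 + m[, "start"] * 4 + m[, "strand"]
}

#' Run the evolutionary simulation
#'
#' Seeds a population of identical wild-type genotypes, then per
#' generation: mutate every individual, annotate, simulate expression,
#' score against the wild-type reference (individuals whose integration
#' diverges get F = +Inf and are never selected), record the elite and
#' one uniformly drawn tracked individual, and breed the next generation
#' by truncation selection and free locus recombination. Fully
#' reproducible from `config$seed`.
#'
#' @param founder wild-type `regevo_genotype`
#' @param pwms PWM set
#' @param params [model_params()]
#' @param profiles external TF profiles
#' @param config [evo_config()]
#' @param U wild-type reference state; computed from the founder if NULL
#' @param keep_elite store every elite annotation per generation (memory
#'   heavy; summary statistics are always stored)
#' @param bin_width sequence bin width for the energy profile, bp
#' @param high_score_offset passed to the annotation stage
#' @param progress print a line every 50 generations
#' @return object of class `regevo_run`: per-generation records plus the
#'   founder annotation, reference state and configuration
#' @export
evolve <- function(founder, pwms, params, profiles, config,
                   U = NULL, keep_elite = FALSE, bin_width = 180L,
                   high_score_offset = 2, progress = FALSE) {
  stopifnot(inherits(config, "regevo_evo_config"))
  ctx <- make_annot_ctx(founder, pwms, high_score_offset)
  simctx <- make_sim_ctx(params, profiles)
  set.seed(config$seed)
  npop <- config$population_size
  nel <- config$elite_size
  mutable <- accessible_positions(founder)
  bins <- make_bins(founder$loci_lengths, bin_width)

  founder_ann <- annotate_code_(founder$code, ctx)
  if (is.null(U)) {
    res <- simulate_matrix_(founder_ann, params, simctx)
    if (res$blowup) stop("founder expression diverged; adjust params")
    U <- res$u
  } else if (inherits(U, "regevo_expression")) {
    U <- as.vector(U)
  }
  founder_keys <- site_keys(founder_ann)

  eval_F <- function(m) {
    res <- simulate_matrix_(m, params, simctx)
    if (res$blowup) Inf else sqrt(mean((res$u - U)^2))
  }

  pop <- rep(list(founder$code), npop)
  records <- vector("list", config$generations + 1L)
  g0_stats <- generation_stats_(list(founder_ann), founder_keys, bins,
                                bin_width, length(ctx$mats))
  records[[1]] <- list(gen = 0L, F_pop = rep(0, npop),
                       elite_F = rep(0, nel),
                       tracked_F = 0,
                       tracked_annotation = founder_ann,
                       stats = g0_stats,
                       elite_ann = if (keep_elite)
                         rep(list(founder_ann), nel) else NULL)

  for (gen in seq_len(config$generations)) {
    for (i in seq_len(npop))
      for (g in seq_along(pop[[i]]))
        pop[[i]][[g]] <- mutate_code_(pop[[i]][[g]], mutable[[g]],
                                      config$mu)
    anns <- lapply(pop, annotate_code_, ctx = ctx)
    F <- vapply(anns, eval_F, 0)
    ord <- order(F)
    elite_idx <- ord[seq_len(nel)]
    eligible <- eligible_set(F, nel)
    tracked <- elite_idx[sample.int(nel, 1L)]
    stats <- generation_stats_(anns[elite_idx], founder_keys, bins,
                               bin_width, length(ctx$mats))
    records[[gen + 1L]] <- list(
      gen = gen, F_pop = F, elite_F = F[elite_idx],
      tracked_F = F[tracked],
      tracked_annotation = anns[[tracked]],
      stats = stats,
      elite_ann = if (keep_elite) anns[elite_idx] else NULL)
    if (progress && gen %% 50 == 0)
      message("generation ", gen, ": best F = ",
              signif(F[elite_idx[1]], 4), ", elite sites = ",
              signif(stats$n_sites, 4))
    if (gen < config$generations) {
      newpop <- vector("list", npop)
      for (i in seq_len(npop)) {
        pr <- eligible[sample.int(length(eligible), 2L, replace = TRUE)]
        child <- pop[[pr[1]]]
        from_b <- runif(length(child)) < 0.5
        for (k in which(from_b)) child[[k]] <- pop[[pr[2]]][[k]]
        newpop[[i]] <- child
      }
      pop <- newpop
    }
  }

  structure(list(records = records, config = config,
                 founder = founder, founder_annotation = founder_ann,
                 U = U, params = params, profiles = profiles,
                 pwms = if (!is.null(names(pwms)) &&
                            all(REGEVO_TFS %in% names(pwms)))
                   pwms[REGEVO_TFS] else pwms,
                 bins = bins, bin_width = bin_width,
                 tf_names = ctx$tf_names, loci = ctx$loci),
            class = "regevo_run")
}

#' @export
print.regevo_run <- function(x, ...) {
  G <- length(x$records) - 1L
  cat("regevo run:", G, "generations,",
      x$config$population_size, "individuals, mu =", x$config$mu, "\n")
  last <- x$records[[G + 1L]]
  cat("  founder sites:", x$records[[1]]$stats$n_sites,
      "| final elite mean sites:", signif(last$stats$n_sites, 4), "\n")
  cat("  final best F:", signif(last$elite_F[1], 4), "\n")
  invisible(x)
}
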