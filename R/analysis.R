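#' Binding-energy profile of sequence bins
#'
#' Splits each locus into fixed-width bins and sums the binding energies
#' of the sites within each bin, normalised by the bin length (score
#' units per bp). A site straddling a bin boundary is assigned to the bin
#' containing its start. The result is invariant to the ordering of sites
#' in the annotation.
#'
#' @param annotation data.frame(tf, locus, start, length, strand, E)
#' @param loci_lengths named locus lengths, bp
#' @param bin_width bin width, bp (default 180)
#' @return data.frame(locus, bin, start, end, E_bin)
#' @export
bin_energy <- function(annotation, loci_lengths, bin_width = 180L) {
  stopifnot(bin_width >= 1)
  out <- lapply(names(loci_lengths), function(g) {
    len <- loci_lengths[[g]]
    nb <- max(1L, as.integer(ceiling(len / bin_width)))
    starts <- (seq_len(nb) - 1L) * bin_width
    ends <- pmin(starts + bin_width, len)
    Eb <- numeric(nb)
    sub <- annotation[annotation$locus == g, , drop = FALSE]
    if (nrow(sub)) {
      bi <- (sub$start %/% bin_width) + 1L
      s <- rowsum(sub$E, bi)
      Eb[as.integer(rownames(s))] <- s
    }
    data.frame(locus = g, bin = seq_len(nb), start = starts, end = ends,
               E_bin = Eb / (ends - starts), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## per-generation E samples of tracked trajectories restricted by origin
tracked_E_by_gen <- function(tracks, ids = NULL) {
  cc <- tracks$coords
  if (!is.null(ids)) cc <- cc[cc$id %in% ids, , drop = FALSE]
  split(cc$E, factor(cc$gen, levels = 0:tracks$G))
}

#' Mean binding energy and CV per generation for a site set
#'
#' Site sets: "all" and "new" are pooled across the elite individuals
#' (from the stored per-generation summaries); "tracked" uses the
#' initial-origin trajectories of the tracked individual that are alive
#' in each generation; "core" the core trajectories. CV = SD / mean of
#' the within-generation E sample.
#'
#' @param run a `regevo_run`
#' @param set one of "all", "new", "tracked", "core"
#' @param tracks precomputed [track_sites()] result (computed if needed)
#' @return data.frame(gen, n, mean_E, cv)
#' @export
energy_dynamics <- function(run, set = c("all", "new", "tracked", "core"),
                            tracks = NULL) {
  set <- match.arg(set)
  G <- length(run$records) - 1L
  if (set %in% c("all", "new")) {
    mk <- if (set == "all")
      c(n = "n_sites", m = "mean_E", s = "sd_E")
    else c(n = "n_new", m = "mean_E_new", s = "sd_E_new")
    df <- do.call(rbind, lapply(run$records, function(r)
      data.frame(gen = r$gen, n = r$stats[[mk["n"]]],
                 mean_E = r$stats[[mk["m"]]],
                 cv = r$stats[[mk["s"]]] / r$stats[[mk["m"]]])))
    return(df)
  }
  if (is.null(tracks)) tracks <- track_sites(run)
  ids <- if (set == "tracked")
    tracks$trajectories$id[tracks$trajectories$origin == "initial"]
  else core_sites(tracks)$id
  es <- tracked_E_by_gen(tracks, ids)
  data.frame(gen = 0:G,
             n = vapply(es, length, 0L),
             mean_E = vapply(es, function(x)
               if (length(x)) mean(x) else NA_real_, 0),
             cv = vapply(es, function(x)
               if (length(x) > 1) sd(x) / mean(x) else NA_real_, 0))
}

#' Ratio of low- to high-energy tracked sites per generation
#'
#' Sites of the tracked individual are split at `threshold`; the series
#' is the count below over the count at or above. Generations with an
#' empty high set give NA.
#'
#' @param run a `regevo_run`
#' @param threshold energy threshold (score units)
#' @param tracks precomputed tracks (optional)
#' @return data.frame(gen, n_low, n_high, ratio)
#' @export
low_high_ratio <- function(run, threshold = 4, tracks = NULL) {
  if (is.null(tracks)) tracks <- track_sites(run)
  cc <- tracks$coords
  gens <- 0:tracks$G
  lo <- vapply(gens, function(g) sum(cc$gen == g & cc$E < threshold), 0L)
  hi <- vapply(gens, function(g) sum(cc$gen == g & cc$E >= threshold), 0L)
  data.frame(gen = gens, n_low = lo, n_high = hi,
             ratio = ifelse(hi > 0, lo / hi, NA_real_))
}

#' Correlation matrix of affinity-ranked site sets
#'
#' Initial-origin tracked sites are ordered by wild-type energy and
#' partitioned into `n_sets` near-equal rank sets (the remainder spread
#' over the leading sets). For each generation the mean energy of each
#' set's alive members gives a time series; pairwise Pearson correlations
#' over jointly defined generations form the matrix.
#'
#' @param tracks a `regevo_tracks`
#' @param n_sets number of affinity sets
#' @return list(cor = n_sets x n_sets matrix, series = G+1 x n_sets
#'   matrix, sets = per-trajectory set index)
#' @export
affinity_set_correlation <- function(tracks, n_sets = 35) {
  tr <- tracks$trajectories
  ini <- tr[tr$origin == "initial", , drop = FALSE]
  if (nrow(ini) < n_sets)
    stop("fewer initial trajectories (", nrow(ini), ") than n_sets")
  o <- ini$id[order(ini$E_wt)]
  sizes <- rep(nrow(ini) %/% n_sets, n_sets)
  extra <- nrow(ini) %% n_sets
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  setidx <- rep(seq_len(n_sets), sizes)
  set_of <- setNames(setidx, o)     # trajectory id -> set
  cc <- tracks$coords
  cc <- cc[cc$id %in% o, , drop = FALSE]
  cc$set <- set_of[as.character(cc$id)]
  series <- matrix(NA_real_, tracks$G + 1L, n_sets)
  agg <- tapply(cc$E, list(cc$gen, cc$set), mean)
  series[as.integer(rownames(agg)) + 1L, as.integer(colnames(agg))] <- agg
  cmat <- suppressWarnings(cor(series, use = "pairwise.complete.obs"))
  ## a set correlates perfectly with itself wherever it is defined,
  ## including the zero-variance case of a constant series
  defined <- colSums(!is.na(series)) > 0
  diag(cmat)[defined] <- 1
  list(cor = cmat, series = series, sets = set_of)
}

#' Generation-by-generation correlation of the bin-energy profile
#'
#' Pearson correlation between the elite-averaged E_bin vectors of every
#' pair of generations.
#'
#' @param run a `regevo_run`
#' @return (G+1) x (G+1) correlation matrix
#' @export
generation_correlation <- function(run) {
  B <- vapply(run$records, function(r) r$stats$bin_E,
              numeric(run$bins$n_total))
  suppressWarnings(cor(B))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum distance between the empirical CDFs, evaluated at the jump
#' points with ties handled exactly.
#'
#' @param a,b numeric samples
#' @return statistic in [0, 1]
#' @export
ks_stat <- function(a, b) {
  n <- length(a); m <- length(b)
  w <- c(a, b)
  o <- order(w)
  z <- cumsum(ifelse(o <= n, 1 / n, -1 / m))
  ws <- w[o]
  last_of_run <- c(ws[-1] != ws[-length(ws)], TRUE)
  max(abs(z[last_of_run]))
}

#' Bootstrapped two-sample KS test
#'
#' The null distribution is formed by pooling both samples and resampling
#' two samples of the original sizes with replacement; the p-value uses
#' the +1 correction, p = (1 + #{boot >= observed}) / (n_boot + 1).
#'
#' @param a,b numeric samples
#' @param n_boot bootstrap replicates
#' @param rng_seed optional seed
#' @return list(statistic, p, n_boot) of class `regevo_ks`
#' @export
ks_bootstrap <- function(a, b, n_boot = 999, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  obs <- ks_stat(a, b)
  pool <- c(a, b)
  n <- length(a); m <- length(b)
  ge <- 0L
  for (k in seq_len(n_boot)) {
    idx <- sample.int(n + m, n + m, replace = TRUE)
    if (ks_stat(pool[idx[seq_len(n)]], pool[idx[(n + 1):(n + m)]]) >=
        obs - 1e-12) ge <- ge + 1L
  }
  structure(list(statistic = obs, p = (1 + ge) / (n_boot + 1),
                 n_boot = n_boot), class = "regevo_ks")
}

#' Correlation between mean rms-score and mean energy across generations
#'
#' The run is split into epochs (default thirds); within each epoch the
#' Pearson correlation across generations between the population mean
#' rms-score and the mean binding energy of the chosen site set is
#' reported. Constant series give NA (flagged by `defined`).
#'
#' @param run a `regevo_run`
#' @param set site set, as in [energy_dynamics()]
#' @param epochs number of equal epochs, or an explicit vector of epoch
#'   start generations
#' @param tracks optional precomputed tracks
#' @return data.frame(epoch, from, to, n, r, defined)
#' @export
rms_energy_correlation <- function(run, set = "all", epochs = 3,
                                   tracks = NULL) {
  G <- length(run$records) - 1L
  meanF <- vapply(run$records, function(r) mean(r$F_pop[is.finite(r$F_pop)]), 0)
  ed <- energy_dynamics(run, set, tracks)
  gens <- 0:G
  bounds <- if (length(epochs) == 1)
    unique(round(seq(0, G + 1, length.out = epochs + 1))) else
      c(epochs, G + 1)
  out <- lapply(seq_len(length(bounds) - 1), function(k) {
    sel <- gens >= bounds[k] & gens < bounds[k + 1]
    x <- meanF[sel]; y <- ed$mean_E[sel]
    ok <- is.finite(x) & is.finite(y)
    r <- if (sum(ok) > 2 && sd(x[ok]) > 0 && sd(y[ok]) > 0)
      cor(x[ok], y[ok]) else NA_real_
    data.frame(epoch = k, from = bounds[k], to = bounds[k + 1] - 1,
               n = sum(ok), r = r, defined = !is.na(r))
  })
  do.call(rbind, out)
}

#' Knockout-score distributions by site group
#'
#' Computes the regulatory rms-score of every wild-type site
#' ([site_knockout_score()]) and groups sites as core / non-core /
#' cooperative / overlapping (from the tracking classification) plus the
#' full set. KS comparisons between the core and non-core groups are
#' reported.
#'
#' @param run a `regevo_run`
#' @param tracks precomputed tracks (computed if NULL)
#' @param n_boot bootstrap replicates for the KS comparison
#' @param rng_seed seed for the bootstrap
#' @return list(scores = per-site data.frame with group columns,
#'   ks_core_vs_noncore = `regevo_ks`)
#' @export
knockout_score_distributions <- function(run, tracks = NULL,
                                         n_boot = 199, rng_seed = 1) {
  if (is.null(tracks)) tracks <- track_sites(run)
  ann <- ann_matrix_to_df(run$founder_annotation, run$tf_names, run$loci)
  U <- array(run$U, dim = c(2, 4, ncol(run$profiles),
                            length(run$params$obs_times)))
  scores <- vapply(seq_len(nrow(ann)), function(i)
    site_knockout_score(ann, i, run$params, run$profiles, U), 0)
  ## founder annotation row i is trajectory id i
  core_ids <- core_sites(tracks)$id
  nb <- classify_neighbors(tracks)
  cls <- setNames(nb$class, nb$id)
  idx <- seq_len(nrow(ann))
  grp <- ifelse(idx %in% core_ids, "core",
                ifelse(!is.na(cls[as.character(idx)]),
                       unname(cls[as.character(idx)]), "other"))
  df <- cbind(ann, score = scores, group = grp,
              core = idx %in% core_ids)
  ks <- if (sum(df$core) >= 3 && sum(!df$core) >= 3)
    ks_bootstrap(df$score[df$core], df$score[!df$core], n_boot,
                 rng_seed) else NULL
  list(scores = df, ks_core_vs_noncore = ks)
}
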