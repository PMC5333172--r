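#' Parameters of the gap-gene expression model
#'
#' The model maps a site annotation to spatiotemporal mRNA / protein
#' expression in two stages. (i) Thermodynamic activation: each site s of
#' TF f bound at energy E has occupancy phi = q/(1+q) with
#' q = K_f * c_f(i,t) * exp(beta * (E - E_ref_f)); same-TF sites within
#' `coop_range` bp (edge-to-edge) receive a single-pass cooperative boost
#' q' = q * (1 + omega * sum of neighbour occupancies); the activation
#' probability of gene a is the logistic of the signed occupancy sum,
#' P_on = logistic(sum_s T[f(s), a] * phi_s + theta_a). (ii) Dynamics:
#' explicit-Euler reaction-diffusion with nearest-neighbour coupling and
#' zero-flux boundaries,
#' dm/dt = R * P_on - lambda * m + D * lap(m),
#' dp/dt = r * m - rho * p + D' * lap(p).
#'
#' The four gap TFs (Hb, Gt, Kr, Kni) take their concentrations from the
#' protein state at the current step; Bcd, Cad, Tll, Hkb are external
#' profiles. E_ref per TF defaults to the PWM threshold, so the weakest
#' callable site has q = K_f * c.
#'
#' @param pwms optional PWM set; supplies per-TF E_ref (= thresholds)
#' @param R,lambda,D,r,rho,Dp,theta per-gene rate parameters (recycled
#'   across the four genes): max mRNA synthesis, mRNA decay, mRNA
#'   diffusion, translation, protein decay, protein diffusion, and the
#'   basal activation bias
#' @param K per-TF concentration scale (recycled to 8)
#' @param Tmat 8 x 4 signed regulatory weight matrix (TFs x genes);
#'   defaults to [default_t_matrix()]
#' @param omega cooperativity strength (>= 0)
#' @param coop_range cooperativity range, bp
#' @param beta energy scale (1 / score units)
#' @param E_ref per-TF reference energies (overrides `pwms`)
#' @param dt Euler time step
#' @param t_end end of integration
#' @param obs_times observation times at which the state is recorded
#' @return object of class `regevo_params`
#' @export
model_params <- function(pwms = NULL, R = 2, lambda = 1.5, D = 0.2,
                         r = 1.5, rho = 1.5, Dp = 0.2, theta = -3,
                         K = 1, Tmat = default_t_matrix(), omega = 1,
                         coop_range = 50, beta = 0.3, E_ref = NULL,
                         dt = 0.01, t_end = 2,
                         obs_times = c(0.5, 1, 1.5, 2)) {
  rec4 <- function(x) setNames(rep_len(x, 4), REGEVO_GENES)
  if (is.null(E_ref))
    E_ref <- if (!is.null(pwms))
      vapply(pwms, `[[`, 0, "threshold")[REGEVO_TFS] else
      setNames(rep(0, 8), REGEVO_TFS)
  stopifnot(all(REGEVO_TFS %in% names(E_ref)))
  p <- list(R = rec4(R), lambda = rec4(lambda), D = rec4(D),
            r = rec4(r), rho = rec4(rho), Dp = rec4(Dp),
            theta = rec4(theta),
            K = setNames(rep_len(K, 8), REGEVO_TFS),
            Tmat = Tmat, omega = omega, coop_range = coop_range,
            beta = beta, E_ref = E_ref[REGEVO_TFS],
            dt = dt, t_end = t_end, obs_times = obs_times)
  if (any(c(p$R, p$lambda, p$D, p$r, p$rho, p$Dp) < 0))
    stop("rate parameters must be non-negative")
  stab <- max(p$lambda + 4 * p$D, p$rho + 4 * p$Dp)
  if (dt * stab >= 2)
    stop("dt = ", dt, " exceeds the Euler stability bound 2/",
         format(stab))
  structure(p, class = "regevo_params")
}

#' Default signed regulatory weight matrix
#'
#' Qualitative gap-gene network wiring: Bcd activates all four genes with
#' anterior weighting, Cad with posterior weighting; the classical
#' mutually exclusive pairs (Hb-Kni, Gt-Kr) repress each other strongly;
#' remaining gap-gap inputs are weakly repressive with mild
#' self-activation; Tll and Hkb act as terminal repressors (Tll weakly
#' activates hb). Magnitudes are per-site weights: with tens of sites per
#' locus the summed input stays in the responsive range of the logistic.
#'
#' @return 8 x 4 numeric matrix, rows TFs, columns genes
#' @export
default_t_matrix <- function() {
  m <- rbind(
    Bcd = c(0.20,  0.15,  0.12,  0.08),
    Cad = c(0.04,  0.08,  0.15,  0.18),
    Hb  = c(0.10,  0.08, -0.15, -0.20),
    Gt  = c(-0.06, -0.18,  0.08, -0.04),
    Kr  = c(-0.05,  0.10, -0.18, -0.10),
    Kni = c(-0.18, -0.08, -0.05,  0.08),
    Tll = c(0.06, -0.12, -0.10, -0.12),
    Hkb = c(-0.10, -0.08, -0.08, -0.10))
  colnames(m) <- REGEVO_GENES
  m
}

#' Thermodynamic occupancy of a single site
#'
#' phi = q / (1 + q) with q = K_f * conc * exp(beta * (E - E_ref_f)).
#' Monotone increasing in both the concentration and the binding energy.
#'
#' @param E binding energy (PWM score units)
#' @param conc TF concentration (>= 0)
#' @param tf TF name
#' @param params [model_params()]
#' @return occupancy in [0, 1]; vectorised over E / conc
#' @export
site_occupancy <- function(E, conc, tf, params) {
  stopifnot(all(conc >= 0))
  q <- params$K[[tf]] * conc * exp(params$beta * (E - params$E_ref[[tf]]))
  q / (1 + q)
}

## cooperative pairs among sites of one locus: directed (i, j) pairs of
## same-TF sites with edge-to-edge distance <= coop_range
coop_pairs <- function(tf, start, len, coop_range) {
  pi <- integer(0); pj <- integer(0)
  for (f in unique(tf)) {
    idx <- which(tf == f)
    if (length(idx) < 2) next
    o <- idx[order(start[idx])]
    s <- start[o]; e <- s + len[o]
    for (a in seq_along(o)) {
      b <- a + 1L
      while (b <= length(o) && s[b] - e[a] <= coop_range) {
        pi <- c(pi, o[a], o[b]); pj <- c(pj, o[b], o[a])
        b <- b + 1L
      }
    }
  }
  list(pi = pi, pj = pj)
}

#' Activation probability of one gene in one nucleus
#'
#' Reference implementation of the thermodynamic stage used by the
#' integrator: occupancies with a single-pass cooperative boost computed
#' from the unboosted neighbour occupancies, then the logistic of the
#' signed sum. Useful for tests and for inspecting single states; the
#' time integration uses the compiled equivalent.
#'
#' @param sites data.frame(tf, start, length, E) of the gene's locus
#' @param gene gene name
#' @param conc named concentration vector covering all eight TFs
#' @param params [model_params()]
#' @return P_on in (0, 1)
#' @export
activation_probability <- function(sites, gene, conc, params) {
  if (!all(REGEVO_TFS %in% names(conc)))
    stop("missing TF concentration(s): ",
         paste(setdiff(REGEVO_TFS, names(conc)), collapse = ", "))
  if (nrow(sites) == 0) return(plogis(params$theta[[gene]]))
  q <- params$K[sites$tf] * conc[sites$tf] *
    exp(params$beta * (sites$E - params$E_ref[sites$tf]))
  phi <- q / (1 + q)
  if (params$omega > 0) {
    cp <- coop_pairs(sites$tf, sites$start, sites$length,
                     params$coop_range)
    if (length(cp$pi) > 0) {
      boost <- numeric(nrow(sites))
      for (k in seq_along(cp$pi))
        boost[cp$pi[k]] <- boost[cp$pi[k]] + phi[cp$pj[k]]
      bs <- which(boost > 0)
      q2 <- q[bs] * (1 + params$omega * boost[bs])
      phi[bs] <- q2 / (1 + q2)
    }
  }
  unname(plogis(sum(params$Tmat[cbind(sites$tf, gene)] * phi) +
                  params$theta[[gene]]))
}

## Build the per-gene site lists consumed by simulate_cpp from an
## internal annotation matrix. Locus k regulates gene k.
sim_sites_from_matrix <- function(m, params) {
  lapply(seq_along(REGEVO_GENES), function(g) {
    rows <- which(m[, "locus"] == g)
    if (length(rows) == 0)
      return(list(qcoef = numeric(0), tf0 = integer(0), Tv = numeric(0),
                  pi = integer(0), pj = integer(0)))
    tf <- m[rows, "tf"]
    E <- m[rows, "E"]
    qcoef <- params$K[tf] * exp(params$beta * (E - params$E_ref[tf]))
    cp <- coop_pairs(tf, m[rows, "start"], m[rows, "len"],
                     params$coop_range)
    list(qcoef = unname(qcoef), tf0 = as.integer(tf - 1L),
         Tv = unname(params$Tmat[cbind(tf, g)]),
         pi = as.integer(cp$pi - 1L), pj = as.integer(cp$pj - 1L))
  })
}

make_sim_ctx <- function(params, profiles) {
  n <- ncol(profiles)
  ext <- matrix(0, 8, n, dimnames = list(REGEVO_TFS, NULL))
  ext[rownames(profiles), ] <- profiles
  n_steps <- as.integer(round(params$t_end / params$dt))
  obs <- as.integer(round(params$obs_times / params$dt))
  if (any(obs < 0 | obs > n_steps))
    stop("obs_times outside [0, t_end]")
  list(n = n, ext = ext,
       gene_rows = as.integer(match(GAP_TF_OF_GENE[REGEVO_GENES],
                                    REGEVO_TFS) - 1L),
       n_steps = n_steps, obs = obs)
}

simulate_matrix_ <- function(m, params, simctx, init = NULL) {
  sites <- sim_sites_from_matrix(m, params)
  z <- matrix(0, 4, simctx$n)
  m0 <- if (is.null(init)) z else init$m
  p0 <- if (is.null(init)) z else init$p
  simulate_cpp(simctx$n, params$dt, simctx$n_steps, simctx$obs,
               simctx$ext, simctx$gene_rows,
               params$R, params$lambda, params$D, params$r, params$rho,
               params$Dp, params$theta, params$omega, sites, m0, p0)
}

#' Simulate gap-gene expression for an annotated genotype
#'
#' Integrates the reaction-diffusion system described in
#' [model_params()] and samples the state at the observation times.
#'
#' @param annotation data.frame(tf, locus, start, length, strand, E)
#' @param params [model_params()]
#' @param profiles external TF profiles, 4 x n_nuclei
#'   ([make_tf_profiles()])
#' @param init optional initial state, list(m, p) of 4 x n matrices;
#'   default zero (expression onset)
#' @return numeric array with dim (2, 4, n_nuclei, n_obs) and dimnames
#'   (product, gene, nucleus, time); class `regevo_expression`
#' @export
simulate_expression <- function(annotation, params, profiles,
                                init = NULL) {
  stopifnot(ncol(profiles) >= 3)
  simctx <- make_sim_ctx(params, profiles)
  m <- if (is.matrix(annotation)) annotation else
    ann_df_to_matrix(annotation)
  res <- simulate_matrix_(m, params, simctx, init)
  if (res$blowup)
    stop("expression integration diverged at step ", res$blow_step,
         " (dt = ", params$dt, "); reduce dt or rates")
  u <- array(res$u, dim = c(2, 4, simctx$n, length(simctx$obs)),
             dimnames = list(product = c("mRNA", "protein"),
                             gene = REGEVO_GENES,
                             nucleus = NULL,
                             time = format(params$obs_times)))
  structure(u, times = params$obs_times, class = "regevo_expression")
}

#' Root-mean-square score between two expression states
#'
#' F = sqrt( (1/N) * sum over (product, gene, nucleus, time) of
#' (u - U)^2 ), with N the full observation grid. F = 0 iff the states
#' coincide; adding a constant offset d everywhere gives F = |d|.
#'
#' @param u,U expression states of identical shape
#' @return non-negative scalar
#' @export
rms_score <- function(u, U) {
  stopifnot(all(dim(u) == dim(U)))
  sqrt(mean((u - U)^2))
}

#' Regulatory rms-score of a single site
#'
#' Recomputes expression with one site removed from the annotation (the
#' sequence itself is unchanged) and returns the rms-score against the
#' wild-type reference: the site's functional importance.
#'
#' @param annotation wild-type site annotation
#' @param site row index of the site to delete
#' @param params,profiles as for [simulate_expression()]
#' @param U wild-type reference state
#' @return non-negative scalar
#' @export
site_knockout_score <- function(annotation, site, params, profiles, U) {
  stopifnot(site >= 1, site <= nrow(annotation))
  u <- simulate_expression(annotation[-site, , drop = FALSE], params,
                           profiles)
  rms_score(u, U)
}

#' Expression state as a long-format table
#' @param x `regevo_expression`
#' @param ... unused
#' @return data.frame(product, gene, nucleus, time, value)
#' @export
as.data.frame.regevo_expression <- function(x, ...) {
  d <- dim(x)
  g <- expand.grid(product = c("mRNA", "protein"), gene = REGEVO_GENES,
                   nucleus = seq_len(d[3]),
                   time = attr(x, "times"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$value <- as.vector(x)
  g
}
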