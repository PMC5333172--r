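test_that("site occupancy follows the closed form and is monotone", {
  par <- tiny_params()
  expect_identical(site_occupancy(10, 0, "Bcd", par), 0)
  ## q = 1 at c = exp(-beta (E - E_ref)) / K  ->  phi = 0.5
  E <- par$E_ref[["Bcd"]] + 3
  c_half <- exp(-par$beta * 3) / par$K[["Bcd"]]
  expect_equal(site_occupancy(E, c_half, "Bcd", par), 0.5,
               tolerance = 1e-12)
  ## monotone in E and in c over a grid
  for (cc in c(0.1, 0.5, 2)) {
    phis <- site_occupancy(seq(2, 14, by = 0.5), cc, "Kr", par)
    expect_true(all(diff(phis) > 0))
  }
  phis <- site_occupancy(8, seq(0, 3, by = 0.1), "Kr", par)
  expect_true(all(diff(phis) > 0))
})

test_that("activation probability: empty annotation, omega = 0, and cooperative distance", {
  par <- tiny_params()
  conc <- setNames(rep(0.5, 8), regevo:::REGEVO_TFS)
  empty <- ann_df(character(0), character(0), integer(0), integer(0))
  expect_equal(activation_probability(empty, "hb", conc, par),
               plogis(par$theta[["hb"]]), tolerance = 1e-12)
  ## omega = 0: P_on independent of inter-site distance
  par0 <- tiny_params(omega = 0)
  near <- ann_df(rep("Bcd", 2), "hb", c(100, 140), 8, E = 10)
  far <- ann_df(rep("Bcd", 2), "hb", c(100, 200), 8, E = 10)
  expect_equal(activation_probability(near, "hb", conc, par0),
               activation_probability(far, "hb", conc, par0),
               tolerance = 1e-12)
  ## omega > 0: activator pair 40 bp apart beats 60 bp apart
  ## (edge-to-edge: 32 vs 52 <= 50-bp range only for the first)
  expect_gt(activation_probability(near, "hb", conc, par),
            activation_probability(far, "hb", conc, par))
  ## missing TF concentration errors
  expect_error(activation_probability(near, "hb", conc[-1], par),
               "missing TF concentration")
})

test_that("compiled activation matches the R reference implementation", {
  par <- tiny_params()
  prof <- tiny_profiles(6)
  set.seed(31)
  ann <- random_annotation(25, loci_lengths = c(hb = 500, Kr = 500,
                                                gt = 500, kni = 500),
                           tfs = regevo:::REGEVO_TFS)
  ## one Euler step from zero state: recorded mRNA = dt * R * P_on
  p1 <- model_params(fixture_pwms(), dt = 0.01, t_end = 0.01,
                     obs_times = 0.01)
  u <- simulate_expression(ann, p1, prof)
  for (gene in regevo:::REGEVO_GENES) {
    sub <- ann[ann$locus == gene, , drop = FALSE]
    for (i in c(1, 4, 6)) {
      conc <- setNames(numeric(8), regevo:::REGEVO_TFS)
      conc[rownames(prof)] <- prof[, i]
      want <- p1$dt * p1$R[[gene]] *
        activation_probability(sub, gene, conc, p1)
      expect_equal(unname(u["mRNA", gene, i, 1]), want,
                   tolerance = 1e-12)
    }
  }
})

test_that("with no diffusion and constant drive, mRNA follows the exponential relaxation", {
  ## no sites: P_on = plogis(theta), D = 0 -> per-nucleus ODE with
  ## closed form m(t) = (R P / lambda)(1 - exp(-lambda t))
  prof <- tiny_profiles(4)
  par <- model_params(fixture_pwms(), D = 0, Dp = 0, dt = 1e-6,
                      t_end = 0.2, obs_times = c(0.1, 0.2),
                      R = 2, lambda = 1.5, theta = -1)
  empty <- ann_df(character(0), character(0), integer(0), integer(0))
  u <- simulate_expression(empty, par, prof)
  P <- plogis(-1)
  for (ti in 1:2) {
    t <- c(0.1, 0.2)[ti]
    want <- (2 * P / 1.5) * (1 - exp(-1.5 * t))
    expect_equal(unname(u["mRNA", , , ti]),
                 matrix(want, 4, 4), tolerance = 1e-6)
  }
})

test_that("zero synthesis from a zero state stays identically zero", {
  prof <- tiny_profiles(5)
  par <- model_params(fixture_pwms(), R = 0, dt = 0.01, t_end = 0.5,
                      obs_times = 0.5)
  empty <- ann_df(character(0), character(0), integer(0), integer(0))
  u <- simulate_expression(empty, par, prof)
  expect_true(all(u == 0))
})

test_that("zero-flux diffusion conserves mass when decay is off", {
  ## lambda = rho = 0, r = 0: total mRNA grows exactly by
  ## n * R * mean(P_on) per unit time; diffusion redistributes only
  prof <- tiny_profiles(7)
  par <- model_params(fixture_pwms(), lambda = 0, rho = 0, r = 0,
                      D = 0.3, Dp = 0.3, dt = 1e-4, t_end = 0.5,
                      obs_times = c(0.25, 0.5), theta = -1)
  set.seed(8)
  ann <- random_annotation(12, loci_lengths = c(hb = 400, Kr = 400,
                                                gt = 400, kni = 400),
                           tfs = c("Bcd", "Cad", "Tll"))
  u <- simulate_expression(ann, par, prof)
  ## P_on is constant in time here (only external, static TFs bind)
  for (gene in regevo:::REGEVO_GENES) {
    sub <- ann[ann$locus == gene, , drop = FALSE]
    Pbar <- mean(vapply(seq_len(7), function(i) {
      conc <- setNames(numeric(8), regevo:::REGEVO_TFS)
      conc[rownames(prof)] <- prof[, i]
      activation_probability(sub, gene, conc, par)
    }, 0))
    for (ti in 1:2) {
      t <- c(0.25, 0.5)[ti]
      expect_equal(sum(u["mRNA", gene, , ti]),
                   7 * par$R[[gene]] * Pbar * t, tolerance = 1e-3)
    }
  }
})

test_that("rms score matches its oracle and the constant-offset identity", {
  set.seed(12)
  for (rep in 1:30) {
    u <- array(runif(2 * 4 * 5 * 3), dim = c(2, 4, 5, 3))
    U <- array(runif(2 * 4 * 5 * 3), dim = c(2, 4, 5, 3))
    expect_equal(rms_score(u, U), oracle_rms(u, U), tolerance = 1e-12)
  }
  U <- array(runif(2 * 4 * 5 * 3), dim = c(2, 4, 5, 3))
  expect_identical(rms_score(U, U), 0)
  expect_equal(rms_score(U + 0.37, U), 0.37, tolerance = 1e-12)
})

test_that("halving the time step barely changes the rms-score (convergence)", {
  g <- fixture_genotype()
  pwms <- fixture_pwms()
  prof <- tiny_profiles()
  ann <- annotate_genotype(g, pwms)
  mut <- ann[-c(2, 5, 9), , drop = FALSE]    # a perturbed annotation
  F_at <- function(dt) {
    par <- model_params(pwms, dt = dt, t_end = 1, obs_times = c(0.5, 1))
    U <- simulate_expression(ann, par, prof)
    u <- simulate_expression(mut, par, prof)
    rms_score(u, U)
  }
  expect_lt(abs(F_at(2e-3) - F_at(1e-3)), 1e-4)
})

test_that("site knockout is an involution and zero-weight sites score zero", {
  pwms <- fixture_pwms()
  prof <- tiny_profiles()
  g <- fixture_genotype()
  ann <- annotate_genotype(g, pwms)
  ## a TF with all-zero role weights contributes nothing
  Tz <- default_t_matrix()
  Tz["Cad", ] <- 0
  par <- tiny_params(Tmat = Tz)
  U <- simulate_expression(ann, par, prof)
  cad_site <- which(ann$tf == "Cad")[1]
  expect_false(is.na(cad_site))
  expect_identical(site_knockout_score(ann, cad_site, par, prof, U), 0)
  ## removing then restoring returns the original annotation and score
  par2 <- tiny_params()
  U2 <- simulate_expression(ann, par2, prof)
  restored <- rbind(ann[-3, , drop = FALSE], ann[3, , drop = FALSE])
  restored <- restored[order(match(restored$locus, regevo:::REGEVO_GENES),
                             restored$start, restored$tf), ]
  u <- simulate_expression(restored, par2, prof)
  expect_equal(rms_score(u, U2), 0, tolerance = 1e-14)
})

test_that("activation stays inside (0,1) and responds with the role sign", {
  par <- tiny_params()
  conc <- setNames(rep(0.4, 8), regevo:::REGEVO_TFS)
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(0:30, 1)
    ann <- if (n == 0)
      ann_df(character(0), character(0), integer(0), integer(0))
    else random_annotation(n, loci_lengths = c(hb = 400),
                           tfs = regevo:::REGEVO_TFS)
    p <- activation_probability(ann, "hb", conc, par)
    expect_gt(p, 0); expect_lt(p, 1)
  }
  ## activator concentration up -> P_on up; repressor up -> P_on down
  ann <- ann_df(c("Bcd", "Kni"), "hb", c(50, 200), 8, E = 10)
  base <- activation_probability(ann, "hb", conc, par)
  up_act <- conc; up_act["Bcd"] <- 1.5
  up_rep <- conc; up_rep["Kni"] <- 1.5
  expect_gt(activation_probability(ann, "hb", up_act, par), base)
  expect_lt(activation_probability(ann, "hb", up_rep, par), base)
})
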