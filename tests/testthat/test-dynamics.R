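# Brownian propagator: free diffusion, equipartition, Boltzmann sampling of
# analytic potentials, MSD estimation, scaling-rule insensitivity.

free_particle_system <- function(L = 20) {
  topo <- topology(strands = list(0L), native_pairs = matrix(integer(0), ncol = 2))
  conf <- configuration(pos = matrix(c(1, 1, 1), 1),
                        e1 = matrix(c(1, 0, 0), 1),
                        e3 = matrix(c(0, 0, 1), 1),
                        L_box = L, cpos = matrix(L / 2, 1, 3), r_c = 0.85)
  list(topology = topo, configuration = conf)
}

test_that("free-particle MSD follows the Einstein relation 6 D t", {
  sys <- free_particle_system()
  dyn <- dynamics_params(temperature = 310, dt = 0.01, seed = 1)
  # replicate short tracks; slope at the first few lags
  m1 <- vapply(1:12, function(s) {
    tr <- integrate_bd(sys$configuration, sys$topology, dyn = dyn,
                       n_steps = 6000, sample_every = 20, track_crowder = 1,
                       seed = s)
    msd(tr)$msd[1]
  }, numeric(1))
  lag1 <- 0.01 * 20
  expected <- 6 * 0.24 * lag1
  se <- sd(m1) / sqrt(length(m1))
  expect_lt(abs(mean(m1) - expected), 3 * se)
})

test_that("the measured diffusion coefficient of an isolated crowder is within 5%", {
  sys <- free_particle_system()
  # slow the lone nucleotide so the crowder track is genuinely isolated
  dyn <- dynamics_params(temperature = 310, dt = 0.01, seed = 1,
                         D_nt = 0.001, D_crowder = 0.24)
  curves <- sapply(1:40, function(s) {
    tr <- integrate_bd(sys$configuration, sys$topology, dyn = dyn,
                       n_steps = 8000, sample_every = 20, track_crowder = 1,
                       seed = 100 + s)
    msd(tr)$msd
  })
  m1 <- msd(integrate_bd(sys$configuration, sys$topology, dyn = dyn,
                         n_steps = 8000, sample_every = 20,
                         track_crowder = 1, seed = 100))
  avg <- tibble::tibble(lag = m1$lag, msd = rowMeans(curves))
  D <- diffusion_from_msd(avg, window = c(0, 0.08))$D
  expect_lt(abs(D - 0.24) / 0.24, 0.05)
})

test_that("harmonic-well sampling satisfies equipartition", {
  k <- 4; beta <- 1
  xs <- cpp_bd1d(1L, k, 0, 1, 5e-3, beta, 2e5, 10L, 7L)
  v_expected <- 1 / (beta * k)
  n_eff <- length(xs) / 10  # crude correlation allowance
  se <- v_expected * sqrt(2 / n_eff)
  expect_lt(abs(var(xs) - v_expected), 3 * se)
})

test_that("double-well sampling reproduces its Boltzmann distribution", {
  h <- 2; beta <- 1
  xs <- cpp_bd1d(2L, h, -1, 1, 5e-3, beta, 4e5, 20L, 11L)
  # analytic marginal on a grid
  grid <- seq(-2, 2, length.out = 41)
  dens <- exp(-beta * h * (grid^2 - 1)^2)
  dens <- dens / sum(dens)
  hist_counts <- table(cut(xs, breaks = c(-Inf, (grid[-1] + grid[-41]) / 2, Inf)))
  emp <- as.numeric(hist_counts) / length(xs)
  # coarse agreement: total variation distance small
  expect_lt(sum(abs(emp - dens)) / 2, 0.05)
  # symmetric wells equally occupied
  expect_lt(abs(mean(xs > 0) - 0.5), 0.1)
})

test_that("msd flags ballistic input as nonlinear and recovers known D", {
  # deterministic ballistic track x = v t
  tvec <- seq(0, 10, by = 0.1)
  track <- cbind(2 * tvec, 0, 0)
  m <- msd(track, dt_sample = 0.1)
  d <- diffusion_from_msd(m)
  expect_true(d$nonlinear)
  # Brownian synthetic track with known D (1D steps in 3 dims)
  set.seed(31)
  Dtrue <- 0.5; dt <- 0.1
  est <- vapply(1:10, function(r) {
    steps <- matrix(rnorm(3 * 4000, 0, sqrt(2 * Dtrue * dt)), ncol = 3)
    track <- apply(steps, 2, cumsum)
    diffusion_from_msd(msd(track, dt_sample = dt), window = c(0, 0.25))$D
  }, numeric(1))
  se <- sd(est) / sqrt(10)
  expect_lt(abs(mean(est) - Dtrue), 3 * se)
  # wrapped input refused; short input refused
  expect_error(msd(track, dt_sample = dt, wrapped = TRUE), "unwrapped")
  expect_error(msd(track[1:2, ], dt_sample = dt), "origins")
})

test_that("ssDNA diffusion in crowders is Brownian and insensitive to crowder D", {
  # 8-nt single strand in phi = 0.1 crowders: MSD linear at long times, and
  # tripling the crowder diffusion coefficient leaves ssDNA diffusion
  # unchanged within error (masses never enter the overdamped propagator)
  topo <- topology(strands = list(0:7), native_pairs = matrix(integer(0), ncol = 2))
  fx <- build_fixture("duplex8", "unbound", seed = 1, phi = 0.1, r_c = 0.85)
  # keep only strand 1 as an 8-nt ssDNA
  conf <- fx$configuration
  conf$pos <- conf$pos[1:8, ]; conf$e1 <- conf$e1[1:8, ]; conf$e3 <- conf$e3[1:8, ]
  run_one <- function(Dc, seed) {
    dyn <- dynamics_params(temperature = 310, dt = 0.005, D_crowder = Dc,
                           seed = seed)
    tr <- integrate_bd(conf, topo, dyn = dyn, n_steps = 20000,
                       sample_every = 40, track_strand = 1, seed = seed)
    d <- diffusion_from_msd(msd(tr), window = c(0, 0.3))
    d
  }
  base <- vapply(1:5, function(s) run_one(0.24, s)$D, numeric(1))
  fast <- vapply(1:5, function(s) run_one(0.72, 50 + s)$D, numeric(1))
  # Brownian: the MSD fit is linear
  expect_false(run_one(0.24, 99)$nonlinear)
  se <- sqrt(var(base) / 5 + var(fast) / 5)
  expect_lt(abs(mean(base) - mean(fast)), 3 * se + 0.01)
})

test_that("timestep stability pre-check refuses oversized steps", {
  expect_error(dynamics_params(dt = 5), class = "crowdna_dt_unstable")
  expect_silent(dynamics_params(dt = 0.003))
})

test_that("stop predicates terminate propagation with the right status", {
  p <- interaction_params(eps_hb = 6)
  tb <- build_two_bead("bound")
  dyn <- dynamics_params(temperature = 340, dt = 0.005, seed = 3)
  fail <- list(ffs_clause("n_bp", "eq", 0), ffs_clause("d_min", "ge", 1.5))
  tr <- integrate_bd(tb$configuration, tb$topology, p, dyn, n_steps = 3e5,
                     sample_every = 0, stop_success = fail, seed = 8)
  expect_identical(tr$status, "success")
  expect_lt(tr$steps, 3e5)
  # determinism of the propagator
  tr2 <- integrate_bd(tb$configuration, tb$topology, p, dyn, n_steps = 3e5,
                      sample_every = 0, stop_success = fail, seed = 8)
  expect_identical(tr$steps, tr2$steps)
  expect_identical(tr$final$pos, tr2$final$pos)
})
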