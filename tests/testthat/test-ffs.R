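# Forward flux sampling: interface definitions, rate composition, the k_off
# relation, and FFS-vs-direct equivalence on the two-bead bonding toy.
# (The 1D double-well exactness check lives in the acceptance suite.)

test_that("standard interface sets match the staged definitions", {
  d <- standard_interfaces("duplex8")
  expect_length(d$interfaces, 3)
  expect_equal(d$interfaces$lambda0[[1]]$value, 0.85)
  expect_identical(d$interfaces$lambda0[[1]]$metric, "d_min")
  expect_equal(d$interfaces$lambda2[[1]]$value, 8)
  h <- standard_interfaces("hairpin_loop10")
  expect_equal(h$interfaces$lambda2[[1]]$value, 6)  # full stem
  s <- standard_interfaces("displacement")
  expect_length(s$interfaces, 4)
  expect_identical(s$interfaces$lambda0[[1]]$subset, "toehold")
  expect_equal(s$interfaces$lambda2[[1]]$value, 6)      # toehold fully paired
  # full displacement: incumbent off AND invader fully paired
  l3 <- s$interfaces$lambda3
  expect_length(l3, 2)
  expect_equal(l3[[1]]$value, 0); expect_identical(l3[[1]]$subset, "incumbent")
  expect_equal(l3[[2]]$value, 16); expect_identical(l3[[2]]$subset, "invader_all")
  # failure predicate: unbound and beyond the basin distance
  expect_equal(d$fail[[2]]$value, 2.5)
  expect_error(standard_interfaces("unknown"), "arg")
})

test_that("compose_rate multiplies flux and probabilities with propagated error", {
  expect_equal(compose_rate(2, c(0.5, 0.1))$k, 0.1)
  expect_equal(compose_rate(2, c(0.5, 0, 0.4))$k, 0)
  k <- compose_rate(1, c(0.5, 0.5), flux_se = 0.1, p_se = c(0.05, 0.05))
  expect_equal(k$k, 0.25)
  expect_equal(k$se, 0.25 * sqrt(0.1^2 + 0.1^2 + 0.1^2), tolerance = 1e-12)
  # error propagation cross-checked against a bootstrap over replicates
  set.seed(2)
  B <- 4000
  reps <- rnorm(B, 1, 0.1) * rnorm(B, 0.5, 0.05) * rnorm(B, 0.5, 0.05)
  expect_lt(abs(sd(reps) - k$se), 0.1 * k$se + 0.002)
  expect_error(relative_rate(1, 0), "zero")
  rr <- relative_rate(2, 4, se = 0.2, se_ref = 0.4)
  expect_equal(rr$ratio, 0.5)
})

test_that("k_off_from_kon has the stated closed forms", {
  expect_equal(k_off_from_kon(3, 0), 3)
  expect_equal(k_off_from_kon(1e6, -log(10)), 1e5, tolerance = 1e-9)
  # kT0 units convert through the temperature
  expect_equal(k_off_from_kon(1, 1, temperature = 300, units = "kT0"),
               exp(1), tolerance = 1e-12)
  expect_equal(k_off_from_kon(1, 1, temperature = 600, units = "kT0"),
               exp(0.5), tolerance = 1e-12)
})

two_bead_interfaces <- function() {
  structure(list(kind = "two_bead",
                 interfaces = list(
                   lambda0 = list(ffs_clause("d_min", "le", 0.85)),
                   lambda1 = list(ffs_clause("n_bp", "ge", 1))),
                 fail = list(ffs_clause("n_bp", "eq", 0),
                             ffs_clause("d_min", "ge", 1.5))),
            class = "ffs_interfaces")
}

test_that("transition probability is 1 when the next interface is already met", {
  p <- interaction_params(eps_hb = 6)
  dyn <- dynamics_params(temperature = 310, dt = 0.005, seed = 1)
  tb <- build_two_bead("bound")
  ifs <- two_bead_interfaces()
  # a bound configuration already satisfies n_bp >= 1
  st <- transition_probability(list(tb$configuration),
                               ifs$interfaces$lambda1, ifs$fail,
                               tb$topology, p, dyn, n_trials = 10,
                               max_steps = 50, seed = 3)
  expect_equal(st$p, 1)
  expect_identical(st$successes, 10L)
})

test_that("zero successes give P = 0 with a one-sided bound and a flag", {
  p <- interaction_params(eps_hb = 6)
  dyn <- dynamics_params(temperature = 310, dt = 0.005, seed = 1)
  tb <- build_two_bead("unbound")
  ifs <- two_bead_interfaces()
  # from deep in the basin with a tiny budget, reaching contact never happens
  expect_warning(
    st <- transition_probability(list(tb$configuration),
                                 ifs$interfaces$lambda0, ifs$fail,
                                 tb$topology, p, dyn, n_trials = 15,
                                 max_steps = 10, seed = 4),
    "unresolved|zero successes")
  expect_equal(st$p, 0)
  expect_gt(st$ci_hi, 0)   # one-sided upper bound remains positive
})

test_that("FFS on the two-bead toy matches the direct association rate", {
  p <- interaction_params(eps_hb = 6)
  dyn <- dynamics_params(temperature = 310, dt = 0.005, seed = 1)
  tb <- build_two_bead("unbound")
  ifs <- two_bead_interfaces()
  ff <- run_ffs(tb$configuration, tb$topology, p, dyn, ifs,
                n_steps_max = 3e5, target_crossings = 60, n_trials = 300,
                max_steps_trial = 5000, seed = 2)
  times <- vapply(1:35, function(s) {
    tr <- integrate_bd(tb$configuration, tb$topology, p, dyn, n_steps = 2e5,
                       sample_every = 0,
                       stop_success = ifs$interfaces$lambda1,
                       check_every = 5, seed = 100 + s)
    if (tr$status == "success") tr$time else NA_real_
  }, numeric(1))
  expect_gt(sum(is.finite(times)), 30)
  k_direct <- 1 / mean(times, na.rm = TRUE)
  ratio <- ff$k / k_direct
  expect_gt(ratio, 1 / 1.2)
  expect_lt(ratio, 1.2)
})

test_that("inserting an intermediate interface leaves the composed rate invariant", {
  p <- interaction_params(eps_hb = 6)
  dyn <- dynamics_params(temperature = 310, dt = 0.005, seed = 1)
  tb <- build_two_bead("unbound")
  ifs2 <- two_bead_interfaces()
  ifs3 <- ifs2
  ifs3$interfaces <- list(lambda0 = list(ffs_clause("d_min", "le", 0.85)),
                          lambda0b = list(ffs_clause("d_min", "le", 0.6)),
                          lambda1 = list(ffs_clause("n_bp", "ge", 1)))
  f2 <- run_ffs(tb$configuration, tb$topology, p, dyn, ifs2,
                n_steps_max = 3e5, target_crossings = 60, n_trials = 300,
                max_steps_trial = 5000, seed = 5)
  f3 <- run_ffs(tb$configuration, tb$topology, p, dyn, ifs3,
                n_steps_max = 3e5, target_crossings = 60, n_trials = 300,
                max_steps_trial = 5000, seed = 6)
  z <- abs(f2$k - f3$k) / sqrt(f2$k_se^2 + f3$k_se^2)
  expect_lt(z, 3)
})

test_that("flux measurement flags a first interface inside the basin", {
  p <- interaction_params(eps_hb = 6)
  dyn <- dynamics_params(temperature = 310, dt = 0.005, seed = 1)
  tb <- build_two_bead("unbound")
  ifs <- two_bead_interfaces()
  # threshold so large the start already satisfies it
  ifs$interfaces$lambda0 <- list(ffs_clause("d_min", "le", 3.5))
  expect_warning(
    try(initial_flux(tb$configuration, tb$topology, p, dyn, ifs,
                     n_steps_max = 2000, seed = 1), silent = TRUE),
    "already satisfied")
})

test_that("flux estimates from independent seeds agree within combined error", {
  p <- interaction_params(eps_hb = 6)
  dyn <- dynamics_params(temperature = 310, dt = 0.005, seed = 1)
  tb <- build_two_bead("unbound")
  ifs <- two_bead_interfaces()
  f1 <- initial_flux(tb$configuration, tb$topology, p, dyn, ifs,
                     n_steps_max = 4e5, target_crossings = 80, seed = 21)
  f2 <- initial_flux(tb$configuration, tb$topology, p, dyn, ifs,
                     n_steps_max = 4e5, target_crossings = 80, seed = 22)
  se1 <- f1$flux / sqrt(f1$n_crossings)
  se2 <- f2$flux / sqrt(f2$n_crossings)
  expect_lt(abs(f1$flux - f2$flux) / sqrt(se1^2 + se2^2), 3.5)
})
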