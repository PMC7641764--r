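# Sampling machinery: toy-chain oracles, detailed balance, unbiasing,
# reweighting, melting temperatures, bulk extrapolation, van't Hoff.

toy_E <- c(0, 1.2, 0.4, 2.0, 0.8)   # enumerable 5-state Hamiltonian (kB T0)

test_that("toy chain sampling matches exact Boltzmann within multinomial error", {
  res <- toy_chain_mc(toy_E, temperature = 300, n_sweeps = 3e5, seed = 1)
  p_exact <- boltzmann_exact(toy_E, 300)
  n <- sum(res$counts)
  # inflate the binomial sigma for chain autocorrelation
  act <- est_act(rep(0:4, res$counts)[order(stats::runif(n))])
  for (k in seq_along(toy_E)) {
    sig <- sqrt(p_exact[k] * (1 - p_exact[k]) / n) * 6
    expect_lt(abs(res$counts[k] / n - p_exact[k]), 3 * sig + 0.005)
  }
})

test_that("umbrella weights reweight the stationary distribution as prescribed", {
  w <- c(1, 1, 2, 1, 1)
  res <- toy_chain_mc(toy_E, weights = w, temperature = 300,
                      n_sweeps = 3e5, seed = 2)
  p_b <- boltzmann_exact(toy_E, 300, weights = w)
  n <- sum(res$counts)
  for (k in seq_along(toy_E))
    expect_lt(abs(res$counts[k] / n - p_b[k]), 0.01)
})

test_that("the sampler is bit-reproducible for a fixed seed", {
  a <- toy_chain_mc(toy_E, temperature = 320, n_sweeps = 5e3, seed = 9,
                    n_keep = 200)
  b <- toy_chain_mc(toy_E, temperature = 320, n_sweeps = 5e3, seed = 9,
                    n_keep = 200)
  expect_identical(a$head, b$head)
  expect_identical(a$counts, b$counts)
  fx <- build_fixture("duplex4", "bound")
  r1 <- run_mc(fx$configuration, fx$topology, temperature = 330,
               n_sweeps = 300, seed = 4)
  r2 <- run_mc(fx$configuration, fx$topology, temperature = 330,
               n_sweeps = 300, seed = 4)
  expect_identical(r1$samples, r2$samples)
})

test_that("detailed balance holds for the estimated toy transition matrix", {
  res <- toy_chain_mc(toy_E, temperature = 300, n_sweeps = 4e5, seed = 3)
  trans <- res$trans
  pi_est <- rowSums(trans) / sum(trans)
  for (i in 1:4) {
    j <- i + 1
    f_ij <- pi_est[i] * trans[i, j] / max(rowSums(trans)[i], 1)
    f_ji <- pi_est[j] * trans[j, i] / max(rowSums(trans)[j], 1)
    # flux balance within counting error
    n_ij <- trans[i, j]; n_ji <- trans[j, i]
    expect_lt(abs(n_ij - n_ji) / sqrt(n_ij + n_ji + 1), 4)
  }
})

test_that("unbias has the stated closed forms and matches enumeration", {
  # flat weights: identity on the raw log-histogram
  s <- tibble::tibble(n_bp = c(rep(0, 80), rep(1, 20)), weight = 1)
  pr <- unbias(s, n_states = 2, temperature = 300, n_boot = 0)
  expect_equal(pr$G[1] - pr$G[2], -log(80 / 20), tolerance = 1e-12)
  expect_equal(pr$G[2], 0)   # reference G(1) = 0
  # two-state with bias w(bound) = 2 and P(bound) = 0.8: dG = -ln 2
  s2 <- tibble::tibble(n_bp = c(rep(0, 20), rep(1, 80)),
                       weight = c(rep(1, 20), rep(2, 80)))
  pr2 <- unbias(s2, n_states = 2, temperature = 300, n_boot = 0)
  expect_equal(delta_G0(pr2), -log((80 / 2) / 20), tolerance = 1e-12)
  expect_equal(delta_G0(pr2), -log(2), tolerance = 1e-12)
  # toy chain: profile matches exact enumeration
  res <- toy_chain_mc(toy_E, temperature = 300, n_sweeps = 4e5, seed = 5)
  pr3 <- unbias(res$samples, n_states = 5, temperature = 300, n_boot = 0)
  G_exact <- -log(boltzmann_exact(toy_E, 300))
  G_exact <- G_exact - G_exact[2]
  expect_lt(max(abs(pr3$G - G_exact)), 0.05)
  # unvisited state is an explicit error naming the state
  s3 <- tibble::tibble(n_bp = rep(1, 10), weight = 1)
  expect_error(unbias(s3, n_states = 3, temperature = 300),
               class = "crowdna_incomplete_sampling")
  expect_error(unbias(s3, n_states = 3, temperature = 300), "0, 2")
})

test_that("delta_G0 matches the direct Boltzmann sum", {
  pr <- structure(tibble::tibble(n_bp = 0:3, G = c(0, -1, 0.5, -2), se = 0),
                  class = c("fe_profile", "tbl_df", "tbl", "data.frame"),
                  temperature = 300)
  direct <- -log(sum(exp(-c(-1, 0.5, -2))) / exp(0))
  expect_equal(delta_G0(pr), direct, tolerance = 1e-12)
  # equal bound and unbound weight -> 0
  pr2 <- structure(tibble::tibble(n_bp = 0:1, G = c(0, 0), se = 0),
                   class = class(pr), temperature = 300)
  expect_equal(delta_G0(pr2), 0)
  # single bound state at -2 kT -> -2 kT
  pr3 <- structure(tibble::tibble(n_bp = 0:1, G = c(0, -2), se = 0),
                   class = class(pr), temperature = 300)
  expect_equal(delta_G0(pr3), -2)
})

test_that("temperature reweighting is exact on the enumerable toy", {
  res <- toy_chain_mc(toy_E, temperature = 320, n_sweeps = 4e5, seed = 6)
  run <- structure(list(samples = res$samples, temperature = 320,
                        weights = rep(1, 5)), class = "mc_run")
  # identity at the sampling temperature
  y0 <- reweight_to_temperature(run, 320)
  expect_equal(y0$yield, sum(res$counts[-1]) / sum(res$counts),
               tolerance = 1e-12)
  # reweighted yield matches exact enumeration at T2
  for (t2 in c(305, 335)) {
    y <- reweight_to_temperature(run, t2)
    p2 <- boltzmann_exact(toy_E, t2)
    exact <- sum(p2[-1])
    expect_lt(abs(y$yield - exact), 0.02)
  }
  # effective-sample-size floor refuses wild extrapolation
  expect_error(reweight_to_temperature(run, 320, ess_floor = 1e9),
               class = "crowdna_ess_error")
})

test_that("reweighted molecular yields agree with direct sampling at T2", {
  # two-bead system: reweight 310 -> 325 and compare with direct MC at 325
  p <- interaction_params(eps_hb = 8)
  tb <- build_two_bead("bound")
  y_rw <- vapply(1:4, function(s) {
    run <- run_mc(tb$configuration, tb$topology, p, 310, n_sweeps = 20000,
                  sample_every = 5, seed = s)
    lv <- -(beta_reduced(325) - beta_reduced(310)) * run$samples$energy
    v <- exp(lv - max(lv))
    sum(v[run$samples$n_bp >= 1]) / sum(v)
  }, numeric(1))
  y_dir <- vapply(5:8, function(s) {
    run <- run_mc(tb$configuration, tb$topology, p, 325, n_sweeps = 20000,
                  sample_every = 5, seed = s)
    mean(run$samples$n_bp >= 1)
  }, numeric(1))
  se <- sqrt(var(y_rw) / 4 + var(y_dir) / 4)
  expect_lt(abs(mean(y_rw) - mean(y_dir)), 3 * se + 0.01)
})

test_that("bulk extrapolation solves mass action and matches enumeration", {
  # closed form: in-box 2/3 corresponds to bulk 1/2
  expect_equal(bulk_yield(2 / 3), 0.5, tolerance = 1e-12)
  expect_equal(bulk_yield(0), 0)
  expect_equal(bulk_yield(1), 1)
  # exact many-pair partition-function oracle: M strand pairs in volume M*V
  # with the same single-pair bond factor q = p/(1-p)
  M <- 6
  p_box <- 0.7
  q <- p_box / (1 - p_box)
  # Z = sum_n C(M,n)^2 n! (q/M)^n ; yield = <n>/M
  n <- 0:M
  w <- choose(M, n)^2 * factorial(n) * (q / M)^n
  yield_many <- sum(n * w) / (M * sum(w))
  expect_lt(abs(bulk_yield(p_box) - yield_many), 0.04) # finite-M correction
  # and the agreement improves with M
  M2 <- 40
  n2 <- 0:M2
  w2 <- exp(2 * lchoose(M2, n2) + lfactorial(n2) + n2 * log(q / M2))
  yield_many2 <- sum(n2 * w2) / (M2 * sum(w2))
  expect_lt(abs(bulk_yield(p_box) - yield_many2),
            abs(bulk_yield(p_box) - yield_many))
})

test_that("melting temperature interpolates at 50% and refuses non-bracketing", {
  # synthetic two-state curve with T* = 330 K (unimolecular)
  Ts <- seq(300, 360, by = 5)
  dH <- 60
  yy <- 1 / (1 + exp(dH * (1 / 330 - 1 / Ts) * 300))
  cv <- melting_curve(Ts, yy, kind = "hairpin")
  tm <- melting_temperature(cv)
  expect_equal(tm$tm, 330, tolerance = 1e-6)
  # linear two-point interpolation: {320: 0.8, 340: 0.2} -> 330
  cv2 <- melting_curve(c(320, 340), c(0.8, 0.2), kind = "hairpin")
  expect_equal(melting_temperature(cv2)$tm, 330, tolerance = 1e-9)
  # no bracketing -> refuse
  cv3 <- melting_curve(c(320, 340), c(0.9, 0.8), kind = "hairpin")
  expect_error(melting_temperature(cv3), class = "crowdna_no_bracket")
  # duplex curves are bulk-extrapolated before interpolation
  cv4 <- melting_curve(c(320, 340), c(0.9, 0.4), kind = "duplex")
  expect_equal(cv4$yield_bulk, bulk_yield(c(0.9, 0.4)))
  tm4 <- melting_temperature(cv4)
  expect_gt(tm4$tm, 320); expect_lt(tm4$tm, 340)
})

test_that("van't Hoff fits recover exact and noisy parameters", {
  kB <- 1 / 300
  dH <- -50; dS <- -0.14
  Ts <- c(310, 320, 330, 340, 350)
  lnK <- -dH / (kB * Ts) + dS / kB
  fit <- vant_hoff(tibble::tibble(temperature = Ts, lnK = lnK))
  expect_equal(fit$dH, dH, tolerance = 1e-9)
  expect_equal(fit$dS, dS, tolerance = 1e-9)
  expect_lt(fit$residual_rms, 1e-9)
  # unbiased recovery under iid noise (simulation study, scaled down)
  set.seed(42)
  est <- vapply(1:300, function(b) {
    fitb <- vant_hoff(tibble::tibble(temperature = Ts,
                                     lnK = lnK + rnorm(5, 0, 0.3)))
    c(fitb$dH, fitb$dS)
  }, numeric(2))
  se_dH <- sd(est[1, ]) / sqrt(300)
  expect_lt(abs(mean(est[1, ]) - dH), 3 * se_dH)
  se_dS <- sd(est[2, ]) / sqrt(300)
  expect_lt(abs(mean(est[2, ]) - dS), 3 * se_dS)
  # degenerate inputs refused
  expect_error(vant_hoff(tibble::tibble(temperature = 330, lnK = 1)),
               "at least 3")
  expect_error(vant_hoff(tibble::tibble(temperature = c(330, 330, 330),
                                        lnK = c(1, 2, 3))), "distinct")
  # tidiers
  expect_named(glance(fit), c("dH", "dS", "residual_rms", "r_squared"))
  expect_identical(nrow(tidy(fit)), 2L)
})

test_that("windowed profiles are consistent between seeds and with reweighting", {
  p <- interaction_params()
  a <- sample_thermo("duplex4", phi = 0, temperature = 330, n_sweeps = 4000,
                     seed = 1, params = p)
  b <- sample_thermo("duplex4", phi = 0, temperature = 330, n_sweeps = 4000,
                     seed = 2, params = p)
  expect_lt(abs(a$dG0 - b$dG0), 3 * sqrt(sum(a$profile$se^2 + b$profile$se^2)) + 0.3)
  # identity reweighting returns the sampling-temperature yield
  y <- yield_curve(a, c(330), ess_floor = 20)
  p330 <- exp(-a$profile$G)
  expect_equal(y$yield, sum(p330[-1]) / sum(p330), tolerance = 1e-9)
})
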