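# Crowder counts, packing, and the crowder pair potential.

test_that("crowders_for_phi reproduces direct arithmetic and round-trips", {
  expect_identical(crowders_for_phi(0, 0.85, 20)$count, 0L)
  # 0.1 * 8000 / ((4/3) pi 0.85^3) = 311.05 -> 311
  res <- crowders_for_phi(0.1, 0.85, 20)
  expect_identical(res$count, 311L)
  expect_equal(res$phi_achieved, 311 * 4 / 3 * pi * 0.85^3 / 8000,
               tolerance = 1e-12)
  # achieved phi within one crowder quantum of the request
  grid <- expand.grid(phi = c(0.1, 0.25, 0.4), r_c = c(0.85, 1.7, 2.56))
  for (i in seq_len(nrow(grid))) {
    r <- crowders_for_phi(grid$phi[i], grid$r_c[i], 15)
    quantum <- 4 / 3 * pi * grid$r_c[i]^3 / 15^3
    expect_lte(abs(r$phi_achieved - grid$phi[i]), quantum / 2 + 1e-12)
  }
  expect_error(crowders_for_phi(0.6, 0.85, 20), "0.55")
  expect_error(crowders_for_phi(0.1, 0.85, 1), "diameter")
})

test_that("crowder number density scales as r_c^-3 at fixed phi", {
  small <- crowders_for_phi(0.2, 0.85, 20)$count
  large <- crowders_for_phi(0.2, 2.56, 20)$count
  # (2.56/0.85)^3 = 27.36; assert within integer rounding
  expect_equal(small / large, (2.56 / 0.85)^3, tolerance = 0.05)
})

test_that("packing never violates the overlap criterion (all-pairs oracle)", {
  for (seed in c(3, 7, 11)) {
    pos <- pack_crowders(60, r_c = 1, L_box = 12, seed = seed)
    n <- nrow(pos)
    expect_identical(n, 60L)
    dmin <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      dmin <- min(dmin, dist_pbc(pos[i, ], pos[j, ], 12))
    expect_gte(dmin, 2 * (1 - 1e-6))
  }
})

test_that("packing honours clearance from existing sites and is deterministic", {
  sites <- matrix(5, nrow = 1, ncol = 3)
  pos1 <- pack_crowders(40, r_c = 0.85, L_box = 10, seed = 5,
                        existing_sites = sites, clearance = 2)
  d <- apply(pos1, 1, function(x) dist_pbc(x, sites[1, ], 10))
  expect_gte(min(d), 2)
  pos2 <- pack_crowders(40, r_c = 0.85, L_box = 10, seed = 5,
                        existing_sites = sites, clearance = 2)
  expect_identical(pos1, pos2)
  expect_error(pack_crowders(4000, r_c = 1, L_box = 8, seed = 1),
               class = "crowdna_packing_error")
})

test_that("crowder pair energy has the WCA closed form and monotonicity", {
  sig <- 1.7; eps <- 2
  cutoff <- sig * 2^(1 / 6)
  expect_equal(crowder_pair_energy(cutoff, sig, eps), 0)
  expect_equal(crowder_pair_energy(cutoff + 0.5, sig, eps), 0)
  # LJ is zero at d = sigma, so the shifted value is exactly eps
  expect_equal(crowder_pair_energy(sig, sig, eps), eps, tolerance = 1e-12)
  d <- seq(0.4, 2.5, by = 0.01)
  v <- crowder_pair_energy(d, sig, eps)
  expect_true(all(diff(v) <= 1e-12))   # monotone non-increasing
  expect_true(all(v >= 0))             # purely repulsive
  expect_error(crowder_pair_energy(0, sig, eps),
               class = "crowdna_overlap_error")
})

test_that("crowder mass and diffusion follow the stated scaling rules", {
  expect_equal(crowder_mass(0.85), 1)
  expect_equal(crowder_mass(1.70), 8)
  expect_equal(crowder_mass(2.56), (2.56 / 0.85)^3)
  expect_equal(crowder_diffusion(0.85), 0.24)
  expect_equal(crowder_diffusion(1.70), 0.12)
  expect_equal(crowder_diffusion(2.56), 0.24 * 0.85 / 2.56)
  expect_equal(0.24 * 0.85 / 2.56, 0.0796875)
  expect_error(crowder_spec(phi = 0.6), "0.55")
  expect_error(crowder_spec(r_c = -1), "positive")
})
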