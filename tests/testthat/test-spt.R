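# Scaled particle theory: limits, monotonicity, the Widom-insertion oracle,
# stability shifts, effective-radius fitting, end-to-end radii.

test_that("sphere insertion work has the exact SPT limits", {
  expect_equal(spt_work_sphere(1.3, 1, 0), 0)            # empty fluid
  expect_equal(spt_work_sphere(0, 1, 0.3), -log(0.7))    # point probe
  expect_equal(spt_work_sphere(1e-9, 2, 0.3), -log(0.7), tolerance = 1e-6)
  expect_error(spt_work_sphere(1, 1, 0.6), "0.55")
  expect_error(spt_work_sphere(1, -1, 0.2), "positive")
})

test_that("insertion work is strictly increasing in probe size and packing", {
  Rg <- seq(0.05, 3, by = 0.05)
  for (phi in c(0.05, 0.2, 0.4)) {
    w <- spt_work_sphere(Rg, 1, phi)
    expect_true(all(diff(w) > 0))
  }
  for (R in c(0.3, 1, 2)) {
    w <- vapply(seq(0.02, 0.5, by = 0.02), function(ph)
      spt_work_sphere(R, 1, ph), numeric(1))
    expect_true(all(diff(w) > 0))
  }
  # spherocylinder grows with its length
  wl <- vapply(seq(0, 4, by = 0.5), function(l)
    spt_work_spherocylinder(0.8, l, 1, 0.25), numeric(1))
  expect_true(all(diff(wl) > 0))
})

test_that("the spherocylinder reduces exactly to the sphere at zero length", {
  for (phi in c(0.1, 0.3)) for (r in c(0.5, 1.3))
    expect_equal(spt_work_spherocylinder(r, 0, 1, phi),
                 spt_work_sphere(r, 1, phi), tolerance = 1e-12)
  expect_equal(spt_work_spherocylinder(1, 2, 1, 0), 0)
})

test_that("SPT matches Widom insertion within 0.1 kT in its regime of validity", {
  # moderate sizes at phi = 0.1 and 0.15 (the acceptance suite covers the
  # full grid at higher statistics)
  fl <- hs_fluid(0.1, r_c = 1, L = 14, seed = 1)
  for (R in c(0.5, 1)) {
    w <- widom_insertion(fl, "sphere", R = R, n_insert = 2e5, seed = 2)
    expect_lt(abs(w$bW - spt_work_sphere(R, 1, fl$phi)), 0.1)
  }
  w <- widom_insertion(fl, "spherocylinder", R = 0.8, L_sc = 1.6,
                       n_insert = 2e5, seed = 3)
  expect_lt(abs(w$bW - spt_work_spherocylinder(0.8, 1.6, 1, fl$phi)), 0.1)
})

test_that("stability shifts have the trivial zeros and the crowding trends", {
  g0 <- spt_geometry(r_u = 1.2, r_f = 1.2, r_c = 0.85, phi = 0.3)
  expect_equal(ddg_hairpin(g0), 0)                       # no shape change
  g1 <- spt_geometry(r_u = 1.2, r_f = 0.8, r_sc = 1.0, r_c = 0.85, phi = 0)
  expect_equal(ddg_hairpin(g1), 0)                       # no crowders
  expect_equal(ddg_duplex(g1), 0)
  # more negative at higher packing and for smaller crowders
  tab <- ddg_grid(spt_geometry(r_u = 1.2, r_f = 0.8),
                  phi = c(0.1, 0.3), r_c = c(0.85, 2.56), kind = "hairpin")
  expect_true(all(tab$ddg < 0))
  d85 <- tab$ddg[tab$r_c == 0.85]
  expect_lt(d85[tab$phi[tab$r_c == 0.85] == 0.3][1], d85[1])
  at03 <- tab[tab$phi == 0.3, ]
  expect_lt(at03$ddg[at03$r_c == 0.85], at03$ddg[at03$r_c == 2.56])
})

test_that("effective radii are recovered exactly from a noise-free table", {
  geom <- spt_geometry(r_u = 1.15, r_f = 0.72)
  tab <- ddg_grid(geom, phi = c(0.1, 0.2, 0.3, 0.4),
                  r_c = c(0.85, 1.27, 1.7, 2.13, 2.56), kind = "hairpin")
  fit <- fit_effective_radii(tab, "hairpin", start = c(r_u = 0.9, r_f = 0.5))
  expect_lt(fit$rss, 1e-8)
  expect_equal(fit$parameters$estimate, c(1.15, 0.72), tolerance = 1e-3)
  gd <- spt_geometry(r_u = 1.3, r_sc = 0.95)
  tabd <- ddg_grid(gd, phi = c(0.1, 0.25, 0.4), r_c = c(0.85, 1.7, 2.56),
                   kind = "duplex")
  fd <- fit_effective_radii(tabd, "duplex", start = c(r_u = 1.0, r_sc = 1.2))
  expect_lt(fd$rss, 1e-8)
  expect_equal(fd$parameters$estimate, c(1.3, 0.95), tolerance = 1e-3)
  expect_error(fit_effective_radii(tab[1:2, ], "hairpin"), "at least 3")
})

test_that("noisy tables recover the radii within their confidence intervals", {
  geom <- spt_geometry(r_u = 1.15, r_f = 0.72)
  tab0 <- ddg_grid(geom, phi = c(0.1, 0.2, 0.3, 0.4),
                   r_c = c(0.85, 1.27, 1.7, 2.13, 2.56), kind = "hairpin")
  set.seed(7)
  hits <- 0; B <- 40
  noise_sd <- 0.05 * mean(abs(tab0$ddg))
  for (b in seq_len(B)) {
    tab <- tab0
    tab$ddg <- tab$ddg + rnorm(nrow(tab), 0, noise_sd)
    fit <- suppressWarnings(
      fit_effective_radii(tab, "hairpin", start = c(r_u = 0.9, r_f = 0.5)))
    ok <- all(fit$parameters$ci_lo <= c(1.15, 0.72) &
              fit$parameters$ci_hi >= c(1.15, 0.72), na.rm = TRUE)
    hits <- hits + ok
  }
  expect_gt(hits / B, 0.75)   # nominal 95% intervals, small-sample slack
})

test_that("boundary-pinned fits are flagged", {
  geom <- spt_geometry(r_u = 1.15, r_f = 0.72)
  tab <- ddg_grid(geom, phi = c(0.1, 0.3), r_c = c(0.85, 1.7), kind = "hairpin")
  expect_warning(fit_effective_radii(tab, "hairpin",
                                     start = c(r_u = 0.9, r_f = 0.5),
                                     upper = c(r_u = 1.0, r_f = 0.8)),
                 "bounds")
})

test_that("end-to-end radius has the rigid-rod limit and honest errors", {
  # a rigid rod of length 4 nm: R_ee = 4 exactly, radius 2 by convention
  rod <- rep(4, 500)
  est <- end_to_end_radius(rod, n_boot = 0)
  expect_equal(est$mean_ree, 4)
  expect_equal(est$radius, 2)
  # ideal-chain synthetic trajectory: unbiased within 3 standard errors
  set.seed(11)
  nseg <- 12; b <- 0.64
  ree <- vapply(1:4000, function(i) {
    steps <- matrix(rnorm(3 * nseg, 0, b / sqrt(3)), ncol = 3)
    sqrt(sum(colSums(steps)^2))
  }, numeric(1))
  truth <- mean(ree)   # large-sample reference from the same generator
  est2 <- end_to_end_radius(ree[1:800], n_boot = 200)
  expect_lt(abs(est2$radius - 0.5 * truth), 3 * est2$se_radius + 0.02)
  # bootstrap errors shrink roughly as 1/sqrt(blocks)
  est_small <- end_to_end_radius(ree[1:200], n_boot = 200)
  expect_gt(est_small$se_radius, est2$se_radius)
})

test_that("bound-state trajectories are refused for the end-to-end radius", {
  p <- interaction_params()
  tb <- build_two_bead("bound")
  run <- run_mc(tb$configuration, tb$topology, p, 300, n_sweeps = 2000,
                sample_every = 5, seed = 1, ree_strand = 1L)
  expect_error(end_to_end_radius(run), class = "crowdna_bound_trajectory")
})

test_that("measured end-to-end radii feed the SPT geometry sensibly", {
  # unbound 8-mer strand: radius should be positive and below the contour
  run <- sample_ree("duplex8", n_sweeps = 3000, seed = 2)
  est <- end_to_end_radius(run)
  expect_gt(est$radius, 0.2)
  expect_lt(est$radius, 8 * 0.64)
})
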