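# Core model: energies, base-pair counting, order parameters, fixtures.

test_that("total energy matches the independent brute-force oracle", {
  p <- interaction_params()
  for (seed in 1:6) {
    sys <- random_system(seed, n = 4, n_crowders = if (seed > 3) 8 else 0)
    e_cpp <- tryCatch(total_energy(sys$configuration, sys$topology, p),
                      crowdna_overstretch = function(e) Inf)
    e_r <- oracle_energy(sys$configuration, sys$topology, p)
    if (is.finite(e_r)) {
      expect_equal(e_cpp, e_r, tolerance = 1e-10)
    } else {
      expect_error(total_energy(sys$configuration, sys$topology, p),
                   class = "crowdna_overstretch")
    }
  }
  # larger crowded duplex
  fx <- build_fixture("duplex8", "bound", seed = 3, phi = 0.2, r_c = 0.85)
  expect_equal(total_energy(fx$configuration, fx$topology, p),
               oracle_energy(fx$configuration, fx$topology, p),
               tolerance = 1e-10)
})

test_that("energy decomposes into its terms and is invariant under periodic shifts", {
  p <- interaction_params()
  fx <- build_fixture("duplex8", "partial", seed = 2, phi = 0.1)
  tt <- total_energy(fx$configuration, fx$topology, p, terms = TRUE)
  expect_equal(tt$total,
               tt$fene + tt$stacking + tt$hbond + tt$excluded + tt$crowder,
               tolerance = 1e-10)
  # rigid translation by a full box vector leaves the energy unchanged
  conf2 <- fx$configuration
  conf2$pos[, 1] <- conf2$pos[, 1] + conf2$L
  if (nrow(conf2$cpos) > 0) conf2$cpos[, 1] <- conf2$cpos[, 1] + conf2$L
  expect_equal(total_energy(conf2, fx$topology, p), tt$total, tolerance = 1e-10)
  # and by a partial shift with wrapping
  conf3 <- fx$configuration
  conf3$pos <- conf3$pos + 1.234
  conf3$cpos <- conf3$cpos + 1.234
  conf3 <- wrap_configuration(conf3)
  expect_equal(total_energy(conf3, fx$topology, p), tt$total, tolerance = 1e-8)
})

test_that("a pair at the hydrogen-bond optimum contributes exactly -eps_hb", {
  p <- interaction_params(eps_st = 0)
  tb <- build_two_bead("bound")
  tt <- total_energy(tb$configuration, tb$topology, p, terms = TRUE)
  expect_equal(tt$hbond, -p$eps_hb, tolerance = 1e-10)
})

test_that("non-native pairs never contribute hydrogen-bond energy", {
  p <- interaction_params()
  # two complementary beads declared WITHOUT a native pair: same geometry,
  # no HB term
  topo <- topology(strands = list(0L, 1L),
                   native_pairs = matrix(integer(0), ncol = 2))
  tb <- build_two_bead("bound")
  tt <- total_energy(tb$configuration, topo, p, terms = TRUE)
  expect_identical(tt$hbond, 0)
  # base-base excluded volume now applies instead
  expect_gte(tt$excluded, 0)
})

test_that("count_native_bp matches construction for bound/unbound/partial fixtures", {
  p <- interaction_params()
  fx <- build_fixture("duplex8", "bound")
  expect_identical(count_native_bp(fx$configuration, fx$topology, p), 8L)
  fx <- build_fixture("duplex8", "unbound")
  expect_identical(count_native_bp(fx$configuration, fx$topology, p), 0L)
  fx <- build_fixture("duplex8", "partial", bound_pairs = 3L)
  expect_identical(count_native_bp(fx$configuration, fx$topology, p), 3L)
  # verified against direct per-pair energies
  hb <- hb_energies(fx$configuration, fx$topology, p)
  expect_identical(sum(hb$formed), 3L)
  expect_true(all(hb$energy[hb$formed] < -p$bp_frac * p$eps_hb))
})

test_that("count_native_bp decreases monotonically as a formed pair is pulled apart", {
  p <- interaction_params()
  fx <- build_fixture("duplex8", "bound")
  conf <- fx$configuration
  counts <- vapply(seq(0, 3, by = 0.25), function(dx) {
    c2 <- conf
    # move the partner of pair 1 outward along the pair axis (+x)
    j <- fx$topology$native_pairs[1, 2] + 1
    c2$pos[j, 1] <- conf$pos[j, 1] + dx
    as.numeric(count_native_bp(c2, fx$topology, p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], 8)
  expect_identical(counts[length(counts)], 7)
})

test_that("min_native_distance uses the minimum image and matches the 27-image oracle", {
  p <- interaction_params()
  # pair placed across the periodic boundary
  L <- 10
  topo <- topology(strands = list(0L, 1L), native_pairs = cbind(0L, 1L))
  conf <- configuration(pos = rbind(c(0.1 - p$d_base, 5, 5),
                                    c(L - 0.1 + p$d_base, 5, 5)),
                        e1 = rbind(c(1, 0, 0), c(-1, 0, 0)),
                        e3 = rbind(c(0, 0, 1), c(0, 0, 1)), L_box = L)
  expect_equal(min_native_distance(conf, topo, params = p), 0.2,
               tolerance = 1e-10)
  # exact separation
  conf2 <- configuration(pos = rbind(c(2 - p$d_base, 5, 5),
                                     c(2.85 - p$d_base, 5, 5)),
                         e1 = rbind(c(1, 0, 0), c(1, 0, 0)),
                         e3 = rbind(c(0, 0, 1), c(0, 0, 1)), L_box = L)
  expect_equal(min_native_distance(conf2, topo, params = p), 0.85,
               tolerance = 1e-10)
  # random systems vs the explicit 27-image enumeration
  for (seed in 1:5) {
    sys <- random_system(seed)
    rows <- seq_len(nrow(sys$topology$native_pairs))
    expect_equal(min_native_distance(sys$configuration, sys$topology,
                                     params = p),
                 oracle_min_dist(sys$configuration, sys$topology, p, rows),
                 tolerance = 1e-10)
  }
  expect_error(min_native_distance(conf, topo, subset = integer(0)),
               "non-empty")
})

test_that("fixtures are valid for every kind and state", {
  p <- interaction_params()
  for (kind in c("duplex8", "duplex4", "hairpin_loop10", "hairpin_loop4",
                 "displacement")) {
    for (state in c("bound", "unbound", "partial")) {
      fx <- build_fixture(kind, state, seed = 1)
      expect_silent(validate_configuration(fx$configuration))
      e <- total_energy(fx$configuration, fx$topology, p, terms = TRUE)
      expect_false(e$overstretch)
      expect_lt(e$excluded, 5) # no serious clashes in any built state
    }
  }
})

test_that("fixture pair counts match the designed systems", {
  p <- interaction_params()
  hp <- build_fixture("hairpin_loop10", "bound")
  expect_identical(n_nucleotides(hp$topology), 22L)    # 6 + 10 + 6
  expect_identical(nrow(hp$topology$native_pairs), 6L)
  expect_identical(count_native_bp(hp$configuration, hp$topology, p), 6L)

  dp <- build_fixture("displacement", "bound")
  hb <- hb_energies(dp$configuration, dp$topology, p)
  inc <- dp$topology$subsets$incumbent
  toe <- dp$topology$subsets$toehold
  expect_identical(sum(hb$formed[inc]), 10L)  # incumbent fully paired
  expect_identical(sum(hb$formed[toe]), 0L)   # toehold open
  expect_gt(min_native_distance(dp$configuration, dp$topology, "toehold", p),
            2.5)

  ub <- build_fixture("duplex8", "unbound")
  expect_gt(min_native_distance(ub$configuration, ub$topology, params = p),
            0.85)
})

test_that("topology invariants are enforced", {
  expect_error(topology(strands = list(0:2, 4:5),
                        native_pairs = matrix(integer(0), ncol = 2)),
               "contiguous")
  expect_error(topology(strands = list(0:3),
                        native_pairs = rbind(c(0L, 3L), c(0L, 2L))),
               "more than one native pair")
  # competing pairs allowed only when requested (displacement)
  expect_silent(topology(strands = list(0:3),
                         native_pairs = rbind(c(0L, 3L), c(0L, 2L)),
                         allow_competing = TRUE))
  expect_error(build_fixture("nonsense"), "arg")
})

test_that("configuration validation rejects broken frames and coordinates", {
  ok <- build_two_bead("bound")$configuration
  bad <- ok; bad$e1[1, ] <- c(1, 1e-3, 0)
  expect_error(validate_configuration(bad), "orthonormal")
  bad2 <- ok; bad2$pos[1, 1] <- NaN
  expect_error(validate_configuration(bad2), "finite")
})

test_that("overstretched backbones raise an explicit condition", {
  p <- interaction_params()
  fx <- build_fixture("duplex4", "bound")
  conf <- fx$configuration
  conf$pos[2, ] <- conf$pos[1, ] + c(3, 0, 0) # break the backbone
  expect_error(total_energy(conf, fx$topology, p),
               class = "crowdna_overstretch")
  # terms = TRUE reports instead of failing
  tt <- total_energy(conf, fx$topology, p, terms = TRUE)
  expect_true(tt$overstretch)
})
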