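# Forward flux sampling: interface definitions, initial flux, staged
# transition probabilities, rate composition, and k_off via the
# detailed-balance relation with the sampled binding free energy.

#' An interface clause on the order-parameter state
#'
#' An interface is a conjunction of clauses, each a threshold on the minimum
#' native-pair distance (`d_min`, nm) or the formed-pair count (`n_bp`)
#' evaluated over a native-pair subset.
#'
#' @param metric `"d_min"` or `"n_bp"`.
#' @param op `"le"`, `"ge"` or `"eq"`.
#' @param value threshold.
#' @param subset native-pair subset name (resolved against the topology) or
#'   1-based pair rows; `NULL` means all native pairs.
#' @return a clause (named list).
#' @export
ffs_clause <- function(metric = c("d_min", "n_bp"), op = c("le", "ge", "eq"),
                       value, subset = NULL) {
  metric <- match.arg(metric); op <- match.arg(op)
  list(metric = metric, op = op, value = value, subset = subset)
}

# internal: clause list -> compiled-core representation (0-based subsets)
clauses_cpp <- function(clauses, topo) {
  lapply(clauses, function(cl) {
    rows <- resolve_subset(topo, cl$subset)
    list(metric = match(cl$metric, c("d_min", "n_bp")) - 1L,
         op = match(cl$op, c("le", "ge", "eq")) - 1L,
         value = as.numeric(cl$value),
         subset = as.integer(rows - 1L))
  })
}

#' Standard interface sets for the study systems
#'
#' Duplexes and hairpins use three staged interfaces: complementary bases
#' within 0.85 nm, the first base pair formed, and the fully formed duplex
#' or stem. Strand displacement uses four: toehold contact (0.85 nm),
#' first toehold base pair, toehold fully paired (6 bp), and full
#' displacement (incumbent at 0 bp with the invader fully paired at 16 bp).
#' The failure interface (return to the unbound basin) is zero formed pairs
#' with the pair distance beyond 2.5 nm, on the same pair subset.
#'
#' @param kind `"duplex8"`, `"duplex4"`, `"hairpin_loop10"`,
#'   `"hairpin_loop4"` or `"displacement"`.
#' @param contact_cutoff first-interface distance threshold (nm).
#' @param basin_distance return-to-basin distance threshold (nm).
#' @return object of class `ffs_interfaces`: named list of interfaces (each
#'   a list of clauses) plus the failure predicate.
#' @export
standard_interfaces <- function(kind = c("duplex8", "duplex4",
                                         "hairpin_loop10", "hairpin_loop4",
                                         "displacement"),
                                contact_cutoff = 0.85, basin_distance = 2.5) {
  kind <- match.arg(kind)
  if (kind == "displacement") {
    ifs <- list(
      lambda0 = list(ffs_clause("d_min", "le", contact_cutoff, "toehold")),
      lambda1 = list(ffs_clause("n_bp", "ge", 1, "toehold")),
      lambda2 = list(ffs_clause("n_bp", "ge", 6, "toehold")),
      lambda3 = list(ffs_clause("n_bp", "eq", 0, "incumbent"),
                     ffs_clause("n_bp", "ge", 16, "invader_all")))
    fail <- list(ffs_clause("n_bp", "eq", 0, "toehold"),
                 ffs_clause("d_min", "ge", basin_distance, "toehold"))
  } else {
    full <- switch(kind, duplex8 = 8, duplex4 = 4, 6)
    ifs <- list(
      lambda0 = list(ffs_clause("d_min", "le", contact_cutoff)),
      lambda1 = list(ffs_clause("n_bp", "ge", 1)),
      lambda2 = list(ffs_clause("n_bp", "ge", full)))
    fail <- list(ffs_clause("n_bp", "eq", 0),
                 ffs_clause("d_min", "ge", basin_distance))
  }
  structure(list(kind = kind, interfaces = ifs, fail = fail),
            class = "ffs_interfaces")
}

#' @export
print.ffs_interfaces <- function(x, ...) {
  cat(sprintf("<ffs_interfaces> %s: %d staged interfaces + failure predicate\n",
              x$kind, length(x$interfaces)))
  for (nm in names(x$interfaces)) {
    cl <- x$interfaces[[nm]]
    txt <- vapply(cl, function(c0) sprintf("%s %s %.2f [%s]", c0$metric, c0$op,
                                           c0$value,
                                           if (is.null(c0$subset)) "all" else paste(c0$subset, collapse = ",")),
                  character(1))
    cat("  ", nm, ": ", paste(txt, collapse = " & "), "\n", sep = "")
  }
  invisible(x)
}

#' Initial flux through the first interface
#'
#' Runs Brownian dynamics from the unbound basin and counts effective
#' positive crossings of the first interface: a crossing is counted only if
#' the trajectory has visited the basin since the previous crossing. The
#' flux is crossings per unit basin time; crossing configurations are
#' stored for the staged trial runs.
#'
#' @param conf,topo,params system definition (must start in the basin).
#' @param dyn a [dynamics_params()].
#' @param interfaces an `ffs_interfaces`.
#' @param n_steps_max maximum propagation steps.
#' @param target_crossings stop after this many crossings (0 = run out the
#'   clock).
#' @param check_every predicate check stride (steps).
#' @param seed RNG seed.
#' @return object of class `ffs_flux`: `flux` (1/ps), `n_crossings`,
#'   `basin_time`, `total_time`, stored `configs`, `seed`.
#' @export
initial_flux <- function(conf, topo, params = interaction_params(), dyn,
                         interfaces, n_steps_max, target_crossings = 25L,
                         check_every = 5L, seed = 1L) {
  stopifnot(inherits(interfaces, "ffs_interfaces"))
  l0 <- clauses_cpp(interfaces$interfaces[[1]], topo)
  ba <- clauses_cpp(interfaces$fail, topo)
  sys <- sys_list(conf, topo)
  # degenerate placement diagnostic: lambda0 must not hold in the start state
  d0 <- interfaces$interfaces[[1]][[1]]
  if (min_native_distance(conf, topo, d0$subset, params) <= d0$value)
    warn("first interface already satisfied by the starting configuration; flux will measure the basin correlation time, not a crossing flux")
  Dc <- crowder_D_for(dyn, conf)
  res <- cpp_ffs_flux(sys, params, dyn$temperature, dyn$D_nt, Dc, dyn$D_rot,
                      dyn$dt, as.integer(n_steps_max), as.integer(check_every),
                      as.integer(target_crossings), l0, ba, as.integer(seed))
  if (res$n_crossings == 0)
    abort("no interface crossings observed within the step budget: increase n_steps_max or re-place the first interface",
          class = "crowdna_undersampled")
  configs <- lapply(res$configs, conf_from_sys, template = conf)
  structure(list(flux = res$n_crossings / res$basin_time,
                 n_crossings = res$n_crossings,
                 basin_time = res$basin_time, total_time = res$total_time,
                 cross_times = res$cross_times,
                 configs = configs, seed = seed),
            class = "ffs_flux")
}

#' @export
print.ffs_flux <- function(x, ...) {
  cat(sprintf("<ffs_flux> %.3g crossings/ps (%d crossings over %.0f ps basin time)\n",
              x$flux, x$n_crossings, x$basin_time))
  invisible(x)
}

#' Staged transition probability between interfaces
#'
#' Fires trial trajectories from stored crossing configurations (drawn
#' uniformly with replacement, each with fresh noise) and scores the
#' fraction that reach the next interface before falling back to the
#' failure interface. The estimate is conditional on the stored crossing
#' ensemble; Wilson binomial confidence bounds are reported.
#'
#' @param crossings list of crossing configurations (from [initial_flux()]
#'   or a previous stage).
#' @param lambda_next clause list for the next interface.
#' @param lambda_fail clause list for the failure interface.
#' @param topo,params,dyn system definition and dynamics.
#' @param n_trials number of trial trajectories.
#' @param max_steps step budget per trial (unresolved trials count as
#'   failures and are reported).
#' @param seed RNG seed.
#' @return object of class `ffs_stage`: `p`, `successes`, `trials`,
#'   `ci_lo`, `ci_hi`, `unresolved`, stored success `configs`.
#' @export
transition_probability <- function(crossings, lambda_next, lambda_fail,
                                   topo, params = interaction_params(), dyn,
                                   n_trials = 100L, max_steps = 20000L,
                                   seed = 1L) {
  stopifnot(length(crossings) >= 1, n_trials >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  starts <- sample.int(length(crossings), n_trials, replace = TRUE)
  succ <- 0L; unresolved <- 0L
  kept <- list()
  for (t in seq_len(n_trials)) {
    tr <- integrate_bd(crossings[[starts[t]]], topo, params, dyn,
                       n_steps = max_steps, sample_every = 0L,
                       stop_success = lambda_next, stop_fail = lambda_fail,
                       check_every = 5L, seed = seed * 1000L + t)
    if (tr$status == "success") {
      succ <- succ + 1L
      kept[[length(kept) + 1L]] <- tr$final
    } else if (tr$status == "ran") unresolved <- unresolved + 1L
  }
  if (unresolved > 0)
    warn(sprintf("%d of %d trials unresolved within the step budget (counted as failures)",
                 unresolved, n_trials))
  p <- succ / n_trials
  ci <- wilson_ci(succ, n_trials)
  if (succ == 0)
    warn("zero successes: probability estimate is 0 with a one-sided confidence bound")
  structure(list(p = p, successes = succ, trials = as.integer(n_trials),
                 ci_lo = ci[1], ci_hi = ci[2], unresolved = unresolved,
                 configs = kept, seed = seed),
            class = "ffs_stage")
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, z = 1.96) {
  p <- x / n
  den <- 1 + z^2 / n
  cen <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, cen - hw), min(1, cen + hw))
}

#' Compose a rate from flux and staged probabilities
#'
#' `k = flux * prod(P)`, with the relative error combined across stages
#' under the documented independence assumption.
#'
#' @param flux initial flux (or an `ffs_flux`).
#' @param probabilities vector of stage probabilities (or list of
#'   `ffs_stage`).
#' @param flux_se,p_se optional standard errors (binomial errors are used
#'   for `ffs_stage` input).
#' @return tibble with columns `k` and `se`.
#' @export
compose_rate <- function(flux, probabilities, flux_se = 0, p_se = NULL) {
  if (inherits(flux, "ffs_flux")) {
    # Poisson counting error on the crossing count
    flux_se <- flux$flux / sqrt(flux$n_crossings)
    flux <- flux$flux
  }
  if (is.list(probabilities) && all(vapply(probabilities, inherits, logical(1), "ffs_stage"))) {
    p_se <- vapply(probabilities, function(s) sqrt(s$p * (1 - s$p) / s$trials), numeric(1))
    probabilities <- vapply(probabilities, `[[`, numeric(1), "p")
  }
  if (is.null(p_se)) p_se <- rep(0, length(probabilities))
  k <- flux * prod(probabilities)
  if (k == 0) return(tibble(k = 0, se = 0))
  rel2 <- (flux_se / flux)^2 + sum((p_se / probabilities)^2)
  tibble(k = k, se = k * sqrt(rel2))
}

#' Rate relative to a reference (crowder-free) rate
#'
#' @param k,k_ref rates (same units).
#' @param se,se_ref standard errors.
#' @return tibble with columns `ratio` and `se`.
#' @export
relative_rate <- function(k, k_ref, se = 0, se_ref = 0) {
  if (k_ref == 0) abort("reference rate is zero")
  r <- k / k_ref
  tibble(ratio = r, se = r * sqrt((se / max(k, .Machine$double.xmin))^2 * (k > 0) +
                                  (se_ref / k_ref)^2))
}

#' Dissociation rate from the association rate and binding free energy
#'
#' `k_off = k_on * exp(dG0 / kB T)`: detailed balance between association
#' and dissociation, with the binding free energy taken from equilibrium
#' sampling under the same crowding conditions.
#'
#' @param k_on association rate.
#' @param dG0 standard binding free energy. By default in kB T units at its
#'   sampling temperature (the [delta_G0()] convention), in which case it is
#'   used directly; with `units = "kT0"` it is converted using
#'   `temperature`.
#' @param temperature temperature (K), needed only for `units = "kT0"`.
#' @param units `"kT"` (default) or `"kT0"`.
#' @return `k_off` in the units of `k_on`.
#' @export
k_off_from_kon <- function(k_on, dG0, temperature = NULL,
                           units = c("kT", "kT0")) {
  units <- match.arg(units)
  stopifnot(is.finite(k_on), is.finite(dG0))
  ex <- if (units == "kT") dG0 else {
    stopifnot(!is.null(temperature), temperature > 0)
    dG0 * beta_reduced(temperature)
  }
  k_on * exp(ex)
}

#' Full staged FFS run
#'
#' Measures the initial flux, then walks the interface ladder, estimating
#' each conditional crossing probability from the previous stage's stored
#' configurations, and composes the rate.
#'
#' @inheritParams initial_flux
#' @param n_trials trials per stage (vector recycled over stages).
#' @param max_steps_trial step budget per trial (vector recycled).
#' @return object of class `ffs_result`: `flux` (an `ffs_flux`), `stages`
#'   tibble, `k`, `k_se`, `kind`, `seed`.
#' @export
run_ffs <- function(conf, topo, params = interaction_params(), dyn,
                    interfaces, n_steps_max = 2e5, target_crossings = 25L,
                    n_trials = 100L, max_steps_trial = 20000L, seed = 1L) {
  fl <- initial_flux(conf, topo, params, dyn, interfaces,
                     n_steps_max = n_steps_max,
                     target_crossings = target_crossings, seed = seed)
  ifs <- interfaces$interfaces
  n_stage <- length(ifs) - 1
  n_trials <- rep(as.integer(n_trials), length.out = n_stage)
  max_steps_trial <- rep(as.integer(max_steps_trial), length.out = n_stage)
  stages <- list()
  pool <- fl$configs
  for (i in seq_along(ifs)[-1]) {
    st <- transition_probability(pool, ifs[[i]], interfaces$fail, topo,
                                 params, dyn, n_trials = n_trials[i - 1],
                                 max_steps = max_steps_trial[i - 1],
                                 seed = seed + 17L * i)
    stages[[length(stages) + 1L]] <- st
    if (st$successes == 0) break
    pool <- st$configs
  }
  ktab <- compose_rate(fl, stages)
  stage_tbl <- tibble(
    stage = seq_along(stages),
    from = names(ifs)[seq_along(stages)],
    to = names(ifs)[seq_along(stages) + 1],
    p = vapply(stages, `[[`, numeric(1), "p"),
    ci_lo = vapply(stages, `[[`, numeric(1), "ci_lo"),
    ci_hi = vapply(stages, `[[`, numeric(1), "ci_hi"),
    successes = vapply(stages, `[[`, integer(1), "successes"),
    trials = vapply(stages, `[[`, integer(1), "trials"))
  structure(list(flux = fl, stages = stage_tbl, stage_objects = stages,
                 k = ktab$k, k_se = ktab$se, kind = interfaces$kind,
                 seed = seed, incomplete = length(stages) < length(ifs) - 1),
            class = "ffs_result")
}

#' @export
print.ffs_result <- function(x, ...) {
  cat(sprintf("<ffs_result> %s: flux %.3g /ps, k = %.3g +/- %.2g /ps\n",
              x$kind, x$flux$flux, x$k, x$k_se))
  print(x$stages)
  invisible(x)
}

# ---------------------------------------------------------------------------
# analytically tractable 1D double-well toy (FFS exactness checks)

#' Direct mean-first-passage rate in the 1D double well
#'
#' Brownian propagation of `V(x) = h (x^2 - 1)^2` from the left minimum
#' until `x_target` is reached; the rate is the inverse mean first-passage
#' time over replicates.
#'
#' @param h barrier height (energy units; `beta` multiplies it).
#' @param D diffusion coefficient.
#' @param dt timestep.
#' @param beta inverse temperature.
#' @param n_rep replicates.
#' @param x_target absorbing threshold.
#' @param max_steps per-replicate step budget.
#' @param seed RNG seed.
#' @return tibble with columns `rate`, `se`, `n`.
#' @export
double_well_direct_rate <- function(h, D = 1, dt = 1e-3, beta = 1,
                                    n_rep = 200L, x_target = 0.9,
                                    max_steps = 2e6, seed = 1L) {
  times <- vapply(seq_len(n_rep), function(r) {
    res <- cpp_bd1d_until(2L, h, -1, D, dt, beta, -1e9, x_target,
                          as.integer(max_steps), as.integer(seed + r))
    if (res$status != 1) return(NA_real_)
    res$steps * dt
  }, numeric(1))
  times <- times[is.finite(times)]
  if (length(times) < 2) abort("first-passage sampling failed: raise max_steps")
  m <- mean(times)
  tibble(rate = 1 / m, se = sd(times) / sqrt(length(times)) / m^2,
         n = length(times))
}

#' Staged FFS rate in the 1D double well
#'
#' Effective-positive-flux measurement through the first interface followed
#' by staged trial runs to successive interfaces; the composed rate is
#' `flux * prod(P)`. Adding intermediate interfaces leaves the composed
#' rate invariant within statistical error (FFS exactness).
#'
#' @inheritParams double_well_direct_rate
#' @param lambdas increasing interface positions; the last is the target
#'   state. The first is `lambda0`.
#' @param basin_x basin (re-arming / failure) threshold.
#' @param n_flux_steps step budget for the flux stage.
#' @param n_trials trials per stage.
#' @return tibble with columns `k`, `se`, `flux`, plus one `p_i` column per
#'   stage.
#' @export
double_well_ffs <- function(h, lambdas = c(-0.5, 0, 0.9), basin_x = -0.9,
                            D = 1, dt = 1e-3, beta = 1, n_flux_steps = 5e5,
                            n_trials = 300L, max_steps = 2e5, seed = 1L) {
  fl <- cpp_bd1d_flux(2L, h, -1, D, dt, beta, lambdas[1], basin_x,
                      as.integer(n_flux_steps), 0L, as.integer(seed))
  if (fl$n_crossings == 0) abort("no crossings in the double-well flux stage",
                                 class = "crowdna_undersampled")
  flux <- fl$n_crossings / fl$basin_time
  flux_se <- flux / sqrt(fl$n_crossings)
  pool <- fl$states
  ps <- numeric(0); pse <- numeric(0)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (i in seq_along(lambdas)[-1]) {
    starts <- sample(pool, n_trials, replace = TRUE)
    res <- vapply(seq_len(n_trials), function(t) {
      r <- cpp_bd1d_until(2L, h, starts[t], D, dt, beta, basin_x, lambdas[i],
                          as.integer(max_steps), as.integer(seed + 7919L * i + t))
      c(r$status, r$x)
    }, numeric(2))
    succ <- sum(res[1, ] == 1)
    ps <- c(ps, succ / n_trials)
    pse <- c(pse, sqrt(ps[length(ps)] * (1 - ps[length(ps)]) / n_trials))
    if (succ == 0) break
    pool <- res[2, res[1, ] == 1]
  }
  kt <- compose_rate(flux, ps, flux_se, pse)
  out <- tibble(k = kt$k, se = kt$se, flux = flux)
  for (i in seq_along(ps)) out[[paste0("p", i)]] <- ps[i]
  out
}
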