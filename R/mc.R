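# Equilibrium Monte Carlo with umbrella biasing on the number of native
# base pairs; unbiasing, single-histogram temperature reweighting, melting
# temperatures with bulk extrapolation, van't Hoff analysis.

#' Umbrella-biased Monte Carlo sampling
#'
#' Metropolis Monte Carlo satisfying detailed balance with respect to the
#' biased Boltzmann distribution `exp(-E/kBT) * w(n_bp)`. The move set is
#' single-nucleotide translations/rotations, crowder translations, and
#' rigid whole-strand translations/rotations (a symmetric-proposal cluster
#' move for strongly bound systems). Deterministic for a given seed.
#'
#' @param conf a `cg_configuration`.
#' @param topo a `cg_topology`.
#' @param params interaction parameters.
#' @param temperature temperature in kelvin.
#' @param n_sweeps number of MC sweeps (one attempted move per mobile entity
#'   per sweep).
#' @param weights umbrella weights, one positive value per `n_bp` state
#'   `0..n_pairs`; `NULL` for unbiased sampling.
#' @param sample_every record one sample per this many sweeps.
#' @param seed RNG seed.
#' @param ree_strand if positive, also record the end-to-end distance
#'   between the terminal base sites of this strand.
#' @param moves optional list overriding move amplitudes (`dx_nt`,
#'   `dang_nt`, `dx_c`, `dx_s`, `dang_s`, pivot `dang_p`) or enabling
#'   Wang-Landau refinement (`wl_f`).
#' @param window optional two integers restricting sampling to
#'   `n_bp in [window[1], window[2]]` (overlapping-window estimator);
#'   proposals leaving the window are rejected.
#' @return an object of class `mc_run`: samples tibble (`sweep`, `n_bp`,
#'   `d_min`, `energy`, `weight`, `ree`), final configuration, acceptance
#'   rate, visit histogram, and full metadata (temperature, weights, seed,
#'   base-pair criterion).
#' @examples
#' \donttest{
#' fx <- build_fixture("duplex4", "bound")
#' run <- run_mc(fx$configuration, fx$topology, temperature = 320,
#'               n_sweeps = 200, seed = 1)
#' head(run$samples)
#' }
#' @export
run_mc <- function(conf, topo, params = interaction_params(), temperature,
                   n_sweeps, weights = NULL, sample_every = 10L, seed = 1L,
                   ree_strand = 0L, moves = list(), window = NULL) {
  stopifnot(n_sweeps > 0, temperature > 0)
  if (is.null(window)) window <- c(-1L, -1L)
  npairs <- nrow(topo$native_pairs)
  if (is.null(weights)) weights <- rep(1, npairs + 1)
  if (length(weights) != npairs + 1 || any(!is.finite(weights)) || any(weights <= 0))
    abort("weights must be positive and cover every n_bp state 0..n_pairs")
  mv <- modifyList(list(dx_nt = 0.12, dang_nt = 0.25, dx_c = 0.25,
                        dx_s = 0.20, dang_s = 0.15, wl_f = 0,
                        dang_p = 0.60), moves)
  res <- cpp_run_mc(sys_list(conf, topo), params, temperature,
                    as.numeric(weights), as.integer(n_sweeps),
                    as.integer(sample_every), as.integer(seed),
                    mv$dx_nt, mv$dang_nt, mv$dx_c, mv$dx_s, mv$dang_s,
                    500L, as.integer(ree_strand), mv$wl_f, mv$dang_p,
                    as.integer(window[1]), as.integer(window[2]))
  samples <- as_tibble(setNames(as.data.frame(res$samples),
                                c("sweep", "n_bp", "d_min", "energy",
                                  "weight", "ree")))
  structure(list(samples = samples,
                 final = conf_from_sys(res$final, conf),
                 acceptance = res$acceptance,
                 hist = res$hist,
                 weights_out = as.numeric(res$weights_out),
                 weights = as.numeric(weights),
                 temperature = temperature,
                 seed = seed,
                 params = params,
                 bp_criterion = sprintf("pair formed iff HB energy < -%.2g * eps_hb",
                                        params$bp_frac)),
            class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("<mc_run> %d samples at T = %.1f K, acceptance %.2f\n",
              nrow(x$samples), x$temperature, x$acceptance))
  cat("  visit histogram over n_bp:", paste(x$hist, collapse = " "), "\n")
  invisible(x)
}

#' Adapt umbrella weights by iterative histogram flattening
#'
#' Short biased pre-runs refine the weights towards the inverse of the
#' stationary distribution of `n_bp` (Wang-Landau-style), after which the
#' weights are frozen for production. The adapted weights are returned with
#' the visit history attached.
#'
#' @inheritParams run_mc
#' @param n_iter number of refinement iterations.
#' @param sweeps_per_iter sweeps per iteration.
#' @return numeric weight vector (normalised to weight 1 at `n_bp = 0`),
#'   with attribute `history` (visit counts per iteration).
#' @export
adapt_umbrella_weights <- function(conf, topo, params = interaction_params(),
                                   temperature, n_iter = 8L,
                                   sweeps_per_iter = 1500L, seed = 1L) {
  # one continuous Wang-Landau run: per-visit penalties with the refinement
  # amplitude halved whenever the running histogram flattens
  run <- run_mc(conf, topo, params, temperature,
                n_sweeps = n_iter * sweeps_per_iter,
                weights = NULL, sample_every = sweeps_per_iter,
                seed = seed, moves = list(wl_f = 0.05))
  w <- pmax(run$weights_out / max(run$weights_out), 1e-12)
  w <- w / w[1]
  attr(w, "history") <- run$hist
  attr(w, "final_conf") <- run$final
  w
}

# integrated autocorrelation time (in samples) of a series, crude windowed sum
est_act <- function(x) {
  n <- length(x)
  if (n < 20 || sd(x) == 0) return(1)
  m <- min(n %/% 4, 200)
  ac <- stats::acf(x, lag.max = m, plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  if (length(pos) > 0) ac <- ac[seq_len(pos[1])]
  max(1, 1 + 2 * sum(ac))
}

#' Unbias umbrella-sampled data into a free-energy profile
#'
#' The unbiased population of each `n_bp` state is the bias-corrected visit
#' count `sum(1/w)` over its samples; the free energy is its negative log,
#' shifted so that `G(1) = 0` (matching the convention used for duplex and
#' hairpin profiles). Errors are estimated by block bootstrap with block
#' length at least ten times the measured autocorrelation time.
#'
#' @param x an `mc_run`, or a samples tibble with columns `n_bp`, `weight`.
#' @param n_states number of order-parameter states (`n_pairs + 1`);
#'   inferred from an `mc_run`.
#' @param temperature profile temperature (K); inferred from an `mc_run`.
#' @param n_boot bootstrap replicates.
#' @return an object of class `fe_profile`: tibble with columns `n_bp`,
#'   `G` (units of kB T at `temperature`), `se`; attributes `temperature`,
#'   `reference`.
#' @export
unbias <- function(x, n_states = NULL, temperature = NULL, n_boot = 50L) {
  if (inherits(x, "mc_run")) {
    samples <- x$samples
    if (is.null(n_states)) n_states <- length(x$weights)
    if (is.null(temperature)) temperature <- x$temperature
  } else samples <- x
  if (is.null(n_states)) n_states <- max(samples$n_bp) + 1
  v <- samples$n_bp
  invw <- 1 / samples$weight
  pop <- vapply(0:(n_states - 1), function(s) sum(invw[v == s]), numeric(1))
  if (any(pop == 0))
    abort(paste0("incomplete sampling: no samples at n_bp = ",
                 paste(which(pop == 0) - 1, collapse = ", ")),
          class = "crowdna_incomplete_sampling")
  G <- -log(pop)
  ref <- if (n_states >= 2) G[2] else G[1]
  G <- G - ref
  # block bootstrap
  n <- length(v)
  blk <- max(20L, ceiling(10 * est_act(v)))
  nblk <- max(1L, n %/% blk)
  se <- rep(0, n_states)
  if (nblk >= 2 && n_boot > 0) {
    starts <- (seq_len(nblk) - 1) * blk + 1
    boots <- matrix(NA_real_, n_boot, n_states)
    for (b in seq_len(n_boot)) {
      pick <- sample(starts, nblk, replace = TRUE)
      idx <- unlist(lapply(pick, function(s) s:min(s + blk - 1, n)))
      pb <- vapply(0:(n_states - 1), function(s) sum(invw[idx][v[idx] == s]),
                   numeric(1))
      pb[pb == 0] <- NA
      Gb <- -log(pb)
      boots[b, ] <- Gb - (if (n_states >= 2) Gb[2] else Gb[1])
    }
    se <- apply(boots, 2, sd, na.rm = TRUE)
    se[is.na(se)] <- 0
  }
  out <- tibble(n_bp = 0:(n_states - 1), G = G, se = se)
  structure(out, class = c("fe_profile", class(out)),
            temperature = temperature, reference = "G(n_bp = 1) = 0",
            block_length = blk)
}

#' Standard binding free energy from a profile
#'
#' `dG0 = -kBT ln( sum_{n>=1} exp(-G(n)) / exp(-G(0)) )`, the free-energy
#' difference between the bound ensemble (at least one base pair) and the
#' unbound state, in units of kB T at the profile temperature. Negative
#' favours the bound state.
#'
#' @param profile an `fe_profile` (must cover `n_bp = 0` and at least one
#'   bound state).
#' @return scalar free-energy difference (kB T units).
#' @export
delta_G0 <- function(profile) {
  stopifnot(inherits(profile, "fe_profile"))
  G <- profile$G[order(profile$n_bp)]
  if (length(G) < 2) abort("profile must cover n_bp = 0 and at least one bound state")
  -(log(sum(exp(-G[-1]))) - log(exp(-G[1])))
}

#' Reweight sampled yields to a nearby temperature
#'
#' Single-histogram Boltzmann reweighting: each sample is weighted by
#' `exp(-E (1/kBT2 - 1/kBT1)) / w`, and the bound-state yield (fraction
#' with `n_bp >= 1`) is the weighted average. The effective sample size is
#' reported and the extrapolation is refused when it falls below the floor.
#'
#' @param run an `mc_run` (samples carry energies in kB T0 units).
#' @param t_new temperature(s) to reweight to (K).
#' @param ess_floor minimum effective sample size.
#' @return tibble with columns `temperature`, `yield`, `ess`.
#' @export
reweight_to_temperature <- function(run, t_new, ess_floor = 100) {
  stopifnot(inherits(run, "mc_run"))
  s <- run$samples
  b1 <- beta_reduced(run$temperature)
  out <- purrr::map(t_new, function(t2) {
    lv <- -(beta_reduced(t2) - b1) * s$energy - log(s$weight)
    lv <- lv - max(lv)
    vwt <- exp(lv)
    ess <- sum(vwt)^2 / sum(vwt^2)
    if (ess < ess_floor)
      abort(sprintf("effective sample size %.1f below floor %.0f when reweighting %.1f K -> %.1f K; sample closer to the target temperature",
                    ess, ess_floor, run$temperature, t2),
            class = "crowdna_ess_error")
    tibble(temperature = t2, yield = sum(vwt[s$n_bp >= 1]) / sum(vwt), ess = ess)
  })
  bind_rows(out)
}

#' Bulk-extrapolated yield for a two-strand simulation box
#'
#' A single pair of complementary strands in a periodic box over-estimates
#' the bound fraction relative to a bulk solution at the same strand
#' concentration. With in-box bound probability `p`, mass action at equal
#' total strand concentrations gives the bulk bound fraction `x` solving
#' `x / (1-x)^2 = p / (1-p)`; in particular the bulk melting point
#' (`x = 1/2`) corresponds to an in-box yield of 2/3.
#'
#' @param p in-box bound probability (vectorised).
#' @return bulk bound fraction.
#' @export
bulk_yield <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- p / (1 - p)
  x <- ifelse(q == 0, 0, (2 * q + 1 - sqrt(4 * q + 1)) / (2 * q))
  ifelse(p == 1, 1, x)
}

#' Assemble a melting curve
#'
#' @param temperatures temperatures (K).
#' @param yield in-box bound yields at those temperatures.
#' @param se optional standard errors on the yields.
#' @param kind `"duplex"` (bimolecular: the yield is bulk-extrapolated
#'   before locating the melting temperature) or `"hairpin"`
#'   (unimolecular: raw yields are used).
#' @return object of class `melting_curve` (a tibble with columns
#'   `temperature`, `yield`, `yield_bulk`, `se`).
#' @export
melting_curve <- function(temperatures, yield, se = NULL,
                          kind = c("hairpin", "duplex")) {
  kind <- match.arg(kind)
  if (is.null(se)) se <- rep(0, length(yield))
  out <- tibble(temperature = temperatures, yield = yield,
                yield_bulk = if (kind == "duplex") bulk_yield(yield) else yield,
                se = se)
  out <- arrange(out, .data$temperature)
  structure(out, class = c("melting_curve", class(out)), kind = kind)
}

#' Melting temperature from a yield curve
#'
#' The temperature at which the bound yield is 50%, by monotone linear
#' interpolation of the (bulk-extrapolated, for bimolecular duplexes) yield
#' curve. Refuses to extrapolate when the yields do not bracket one half.
#' When the curve carries yield standard errors, a parametric bootstrap
#' gives the error on Tm.
#'
#' @param curve a `melting_curve`.
#' @param n_boot bootstrap replicates for the Tm error.
#' @return tibble with columns `tm` (K) and `tm_se`.
#' @export
melting_temperature <- function(curve, n_boot = 200L) {
  stopifnot(inherits(curve, "melting_curve"))
  interp <- function(y) {
    if (min(y) > 0.5 || max(y) < 0.5)
      abort("yields do not bracket 0.5: refusing to extrapolate the melting temperature",
            class = "crowdna_no_bracket")
    # yield decreases with T; interpolate T as a function of yield
    ord <- order(y)
    approx(y[ord], curve$temperature[ord], xout = 0.5, ties = "mean")$y
  }
  tm <- interp(curve$yield_bulk)
  tm_se <- NA_real_
  if (any(curve$se > 0) && n_boot > 0) {
    kind <- attr(curve, "kind")
    tms <- vapply(seq_len(n_boot), function(b) {
      y <- pmin(pmax(curve$yield + rnorm(nrow(curve), 0, curve$se), 1e-6), 1 - 1e-6)
      yb <- if (kind == "duplex") bulk_yield(y) else y
      if (min(yb) > 0.5 || max(yb) < 0.5) return(NA_real_)
      ord <- order(yb)
      approx(yb[ord], curve$temperature[ord], xout = 0.5, ties = "mean")$y
    }, numeric(1))
    tm_se <- sd(tms, na.rm = TRUE)
  }
  tibble(tm = tm, tm_se = tm_se)
}

#' Van't Hoff analysis of equilibrium constants
#'
#' Least-squares line of `ln K` against `1/T`: the slope is `-dH/kB` and
#' the intercept `dS/kB`. With energies in kB T0 units (T0 = 300 K),
#' `kB = 1/300` per kelvin, so `dH` is returned in kB T0 units and `dS` in
#' kB T0 per kelvin.
#'
#' @param data data frame with columns `temperature` (K) and `lnK`.
#' @return object of class `vant_hoff_fit` with elements `dH`, `dS`,
#'   `fit` (the `lm`), `residual_rms`.
#' @examples
#' d <- tibble::tibble(temperature = c(300, 320, 340),
#'                     lnK = 50 / (1/300) * (1 / c(300, 320, 340)) - 140)
#' vant_hoff(d)
#' @export
vant_hoff <- function(data) {
  stopifnot(all(c("temperature", "lnK") %in% names(data)))
  if (nrow(data) < 3) abort("van't Hoff analysis needs at least 3 temperatures")
  if (length(unique(data$temperature)) < 2)
    abort("degenerate input: fewer than 2 distinct temperatures")
  kB <- 1 / 300
  fit <- lm(lnK ~ I(1 / temperature), data = data)
  co <- coef(fit)
  structure(list(dH = -kB * unname(co[2]), dS = kB * unname(co[1]),
                 fit = fit,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2))),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("<vant_hoff_fit> dH = %.3g kB T0, dS = %.3g kB T0 / K (residual RMS %.2g)\n",
              x$dH, x$dS, x$residual_rms))
  invisible(x)
}

# ---------------------------------------------------------------------------
# enumerable toy chain (correctness oracles for the sampling machinery)

#' Metropolis sampling of an enumerable discrete-state chain
#'
#' A nearest-neighbour Metropolis chain over `K` states with prescribed
#' energies and umbrella weights, sharing the acceptance rule of the
#' molecular sampler. Used to validate sampling, unbiasing and reweighting
#' against exact enumeration.
#'
#' @param energies state energies (kB T0 units).
#' @param weights umbrella weights (positive), default flat.
#' @param temperature temperature in kelvin.
#' @param n_sweeps chain length.
#' @param seed RNG seed.
#' @param n_keep number of initial states to return verbatim.
#' @return list with `counts` (visits per state), `trans` (transition count
#'   matrix), `head` (first `n_keep` states), and `samples` (a tibble with
#'   `n_bp`, `weight`, `energy` usable by [unbias()]).
#' @export
toy_chain_mc <- function(energies, weights = NULL, temperature = 300,
                         n_sweeps = 1e5, seed = 1L, n_keep = 0L) {
  K <- length(energies)
  if (is.null(weights)) weights <- rep(1, K)
  stopifnot(length(weights) == K, all(weights > 0))
  res <- cpp_mc_toy(as.numeric(energies), as.numeric(weights),
                    beta_reduced(temperature), as.integer(n_sweeps),
                    as.integer(seed), as.integer(n_keep))
  counts <- as.numeric(res$counts)
  samples <- tibble(n_bp = rep(0:(K - 1), counts),
                    weight = rep(weights, counts),
                    energy = rep(energies, counts))
  list(counts = counts, trans = res$trans, head = as.integer(res$head),
       samples = samples)
}

#' Exact Boltzmann distribution of a discrete-state system
#'
#' @inheritParams toy_chain_mc
#' @return probability vector.
#' @export
boltzmann_exact <- function(energies, temperature = 300, weights = NULL) {
  b <- beta_reduced(temperature)
  w <- if (is.null(weights)) rep(1, length(energies)) else weights
  p <- w * exp(-b * (energies - min(energies)))
  p / sum(p)
}
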