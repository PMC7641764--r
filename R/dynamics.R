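# Brownian (overdamped) dynamics with the crowder mass and diffusion
# scaling rules, plus MSD / diffusion-coefficient diagnostics.

#' Crowder mass under the constant-density rule
#'
#' Crowders keep the mass density of the reference sphere:
#' `m = m_0 (r_c / r_0)^3`. Masses are metadata in the overdamped
#' propagator (kinetics are insensitive to them); they are kept for
#' completeness and for the mass-insensitivity diagnostics.
#'
#' @param r_c crowder radius (nm), vectorised.
#' @param spec a [crowder_spec()].
#' @return mass in units of `m_0`.
#' @examples
#' crowder_mass(1.70) # 8 m0
#' @export
crowder_mass <- function(r_c, spec = crowder_spec()) {
  stopifnot(all(r_c > 0))
  spec$m_0 * (r_c / spec$r_0)^3
}

#' Crowder diffusion coefficient under the Stokes-like scaling rule
#'
#' `D = D_0 r_0 / r_c`, with `D_0` the diffusion coefficient of a single
#' nucleotide (0.24 nm^2/ps by default, deliberately fast to accelerate
#' sampling; rates are therefore reported in simulation-time units and as
#' crowder-free-normalised ratios).
#'
#' @inheritParams crowder_mass
#' @return diffusion coefficient (nm^2/ps).
#' @examples
#' crowder_diffusion(0.85) # 0.24
#' @export
crowder_diffusion <- function(r_c, spec = crowder_spec()) {
  stopifnot(all(r_c > 0))
  spec$D_0 * spec$r_0 / r_c
}

#' Dynamics parameters
#'
#' Parameters of the overdamped Brownian propagator: per-species diffusion
#' coefficients, rotational diffusion tied to translational diffusion by a
#' stored length scale, timestep and temperature. A stability pre-check
#' refuses timesteps whose free-flight displacement exceeds a fraction of
#' the smallest excluded-volume core.
#'
#' @param temperature temperature (K).
#' @param dt timestep (ps).
#' @param D_nt nucleotide translational diffusion coefficient (nm^2/ps).
#' @param D_crowder crowder diffusion coefficient; default from the scaling
#'   rule once the system's crowder radius is known (see [integrate_bd()]).
#' @param l_rot length scale tying rotational to translational diffusion:
#'   `D_rot = D_nt / l_rot^2` (rad^2/ps).
#' @param seed RNG seed.
#' @param max_step_frac maximum allowed ratio of the RMS trial step to the
#'   smallest WCA core diameter.
#' @param params interaction parameters used by the stability check.
#' @return object of class `dynamics_params`.
#' @export
dynamics_params <- function(temperature = 310, dt = 0.003, D_nt = 0.24,
                            D_crowder = NULL, l_rot = 0.5, seed = 1L,
                            max_step_frac = 0.25,
                            params = interaction_params()) {
  stopifnot(dt > 0, D_nt > 0, temperature > 0, l_rot > 0)
  rms_step <- sqrt(2 * D_nt * dt)
  core <- min(params$sig_ss, params$sig_bs, params$sig_bb)
  if (rms_step > max_step_frac * core)
    abort(sprintf("unstable timestep: RMS step %.3f nm exceeds %.2f of the smallest core %.2f nm",
                  rms_step, max_step_frac, core), class = "crowdna_dt_unstable")
  structure(list(temperature = temperature, dt = dt, D_nt = D_nt,
                 D_crowder = D_crowder, D_rot = D_nt / l_rot^2,
                 l_rot = l_rot, seed = seed),
            class = "dynamics_params")
}

# internal: resolve the crowder diffusion coefficient for a configuration
crowder_D_for <- function(dyn, conf, spec = crowder_spec()) {
  if (!is.null(dyn$D_crowder)) return(dyn$D_crowder)
  if (nrow(conf$cpos) == 0) return(0.24)
  crowder_diffusion(conf$rc, spec)
}

#' Integrate Brownian dynamics
#'
#' Overdamped propagation: every entity takes Gaussian free-diffusion trial
#' displacements of per-axis variance `2 D dt` (and rotations of variance
#' `4 D_rot dt` about a random axis), filtered by a Metropolis acceptance on
#' the potential energy. The scheme is exactly Boltzmann-stationary and
#' reduces to free diffusion (MSD = 6 D t) away from interactions; it
#' converges to overdamped Langevin dynamics as `dt -> 0`.
#'
#' @param conf,topo,params system definition.
#' @param dyn a [dynamics_params()].
#' @param n_steps number of timesteps.
#' @param sample_every record order parameters every this many steps (0 to
#'   disable).
#' @param track_strand if positive, record the unwrapped centre-of-mass
#'   track of this strand (for MSD analysis).
#' @param track_crowder if positive, record the unwrapped track of this
#'   crowder.
#' @param stop_success,stop_fail optional interface predicates (see
#'   [standard_interfaces()]); propagation stops when one is satisfied.
#' @param check_every predicate check stride (steps).
#' @param seed RNG seed (overrides `dyn$seed` when given).
#' @return object of class `bd_trajectory`: samples tibble (`time`, `n_bp`,
#'   `d_min`, `energy`), optional `com_track` / `crowder_track` matrices
#'   (unwrapped, one row per sample), `status` (`"ran"`, `"success"`,
#'   `"fail"`), steps, elapsed time (ps), acceptance, final configuration.
#' @export
integrate_bd <- function(conf, topo, params = interaction_params(), dyn,
                         n_steps, sample_every = 100L, track_strand = 0L,
                         track_crowder = 0L, stop_success = NULL,
                         stop_fail = NULL, check_every = 10L, seed = NULL) {
  stopifnot(inherits(dyn, "dynamics_params"), n_steps > 0)
  if (is.null(seed)) seed <- dyn$seed
  Dc <- crowder_D_for(dyn, conf)
  sA <- if (!is.null(stop_success)) clauses_cpp(stop_success, topo) else NULL
  sB <- if (!is.null(stop_fail)) clauses_cpp(stop_fail, topo) else NULL
  res <- cpp_run_bd(sys_list(conf, topo), params, dyn$temperature,
                    dyn$D_nt, Dc, dyn$D_rot, dyn$dt, as.integer(n_steps),
                    as.integer(sample_every), as.integer(seed),
                    sA, sB, as.integer(check_every),
                    as.integer(track_strand), as.integer(track_crowder))
  ns <- res$n_samples
  samp <- as.data.frame(res$samples)[seq_len(max(ns, 0)), , drop = FALSE]
  samples <- as_tibble(setNames(samp, c("time", "n_bp", "d_min", "energy")))
  out <- list(samples = samples,
              status = c("ran", "success", "fail")[res$status + 1],
              steps = res$steps, time = res$time,
              acceptance = res$acceptance,
              final = conf_from_sys(res$final, conf),
              dt = dyn$dt, sample_every = sample_every)
  if (track_strand > 0)
    out$com_track <- res$com_track[seq_len(max(ns, 0)), , drop = FALSE]
  if (track_crowder > 0)
    out$crowder_track <- res$crowder_track[seq_len(max(ns, 0)), , drop = FALSE]
  structure(out, class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("<bd_trajectory> %d steps (%.1f ps), status '%s', acceptance %.2f\n",
              x$steps, x$time, x$status, x$acceptance))
  invisible(x)
}

#' Time-origin-averaged mean-square displacement
#'
#' @param track an n x 3 matrix of unwrapped coordinates sampled at a fixed
#'   stride (e.g. `com_track` or `crowder_track` from [integrate_bd()]), or
#'   a `bd_trajectory` with a recorded track.
#' @param dt_sample time between consecutive rows (ps); inferred from a
#'   `bd_trajectory`.
#' @param max_lag_frac largest lag as a fraction of the track length.
#' @param wrapped set `TRUE` if the coordinates were wrapped into the box;
#'   wrapped input is refused since it corrupts displacements.
#' @return tibble with columns `lag` (ps) and `msd` (nm^2).
#' @export
msd <- function(track, dt_sample = NULL, max_lag_frac = 0.25,
                wrapped = FALSE) {
  if (inherits(track, "bd_trajectory")) {
    dt_sample <- track$dt * track$sample_every
    track <- if (!is.null(track$com_track)) track$com_track else track$crowder_track
    if (is.null(track)) abort("trajectory has no recorded track; rerun with track_strand/track_crowder")
  }
  if (isTRUE(wrapped)) abort("wrapped coordinates refused: MSD needs unwrapped tracks")
  track <- as.matrix(track)
  n <- nrow(track)
  if (n < 3) abort("need at least 2 time origins")
  lags <- seq_len(max(2L, floor(n * max_lag_frac)))
  ms <- vapply(lags, function(k) {
    d <- track[(k + 1):n, , drop = FALSE] - track[1:(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  tibble(lag = lags * dt_sample, msd = ms)
}

#' Diffusion coefficient from an MSD curve
#'
#' Linear fit `MSD = 2 d D t` over a window of the curve; the fit window,
#' R^2 and a nonlinearity flag (raised when a quadratic in `t` fits the
#' window substantially better, as for ballistic motion) are reported.
#'
#' @param msd_curve tibble from [msd()].
#' @param dim spatial dimension (3 for molecules in the box).
#' @param window fraction range of lags used for the fit.
#' @return tibble with columns `D`, `r_squared`, `nonlinear`, `window_lo`,
#'   `window_hi`.
#' @export
diffusion_from_msd <- function(msd_curve, dim = 3, window = c(0.1, 0.9)) {
  m <- msd_curve[msd_curve$lag >= quantile(msd_curve$lag, window[1]) &
                 msd_curve$lag <= quantile(msd_curve$lag, window[2]), ]
  fit <- lm(msd ~ lag, data = m)
  fit2 <- lm(msd ~ lag + I(lag^2), data = m)
  r2 <- summary(fit)$r.squared
  # ballistic / strongly curved input: quadratic term dominates
  ss1 <- sum(stats::residuals(fit)^2)
  ss2 <- sum(stats::residuals(fit2)^2)
  nonlinear <- is.finite(ss1) && ss1 > 0 && (ss2 < 0.1 * ss1 || r2 < 0.9)
  tibble(D = unname(coef(fit)[2]) / (2 * dim), r_squared = r2,
         nonlinear = nonlinear,
         window_lo = min(m$lag), window_hi = max(m$lag))
}
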