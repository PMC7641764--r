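# Study-level orchestration: one call from fixture to free-energy profile,
# melting curve or van't Hoff line under given crowding conditions.

# push a configuration down to n_bp <= target with a strongly biased short
# run (handoff between adjacent windows)
drive_down <- function(conf, topo, params, temperature, target, seed) {
  K1 <- nrow(topo$native_pairs) + 1
  for (try in 1:20) {
    n <- count_native_bp(conf, topo, params)
    if (n <= target) return(conf)
    w <- exp(-4 * pmax(0:(K1 - 1) - target, 0))
    run <- run_mc(conf, topo, params, temperature, n_sweeps = 300L,
                  weights = w, sample_every = 300L, seed = seed + try,
                  window = c(target, n))
    conf <- run$final
  }
  abort("could not relax the configuration into the next sampling window",
        class = "crowdna_incomplete_sampling")
}

# probe + production run in one two-state window; returns the visit-count
# ratio pi(k+1)/pi(k), its bootstrap error, and the samples for reweighting
window_ratio <- function(conf, topo, params, temperature, k, n_sweeps,
                         probe_sweeps, sample_every, seed, ree_strand = 0L) {
  K1 <- nrow(topo$native_pairs) + 1
  win <- c(k, k + 1)
  conf <- drive_down(conf, topo, params, temperature, k + 1, seed + 7000L)
  probe <- run_mc(conf, topo, params, temperature, n_sweeps = probe_sweeps,
                  weights = NULL, sample_every = 10L, seed = seed,
                  window = win)
  h <- probe$hist[win + 1]
  # balance the window: umbrella weight on the upper state. The probe ratio
  # is clamped to a moderate band: short probes can be grossly kinetics-
  # limited, and an extreme weight would empty one state entirely.
  w_hi <- min(max((h[1] + 1) / (h[2] + 1), 1e-2), 1e2)
  start <- probe$final
  for (attempt in 1:3) {
    weights <- rep(1, K1)
    weights[k + 2] <- w_hi
    run <- run_mc(start, topo, params, temperature, n_sweeps = n_sweeps,
                  weights = weights, sample_every = sample_every,
                  seed = seed + attempt, ree_strand = ree_strand,
                  window = win)
    s <- run$samples
    up <- s$n_bp == k + 1
    num <- sum(1 / s$weight[up]); den <- sum(1 / s$weight[!up])
    if (num > 0 && den > 0) break
    # one state unvisited: shift the balance towards it and retry
    w_hi <- if (num == 0) w_hi * 30 else w_hi / 30
    start <- run$final
  }
  if (num == 0 || den == 0)
    abort(sprintf("incomplete sampling: window (%d, %d) never visited state %d",
                  k, k + 1, if (num == 0) k + 1 else k),
          class = "crowdna_incomplete_sampling")
  # block bootstrap on the log-ratio
  n <- nrow(s)
  blk <- max(20L, ceiling(10 * est_act(s$n_bp)))
  nblk <- max(1L, n %/% blk)
  se <- 0
  if (nblk >= 2) {
    starts <- (seq_len(nblk) - 1) * blk + 1
    lr <- vapply(seq_len(60L), function(b) {
      idx <- unlist(lapply(sample(starts, nblk, replace = TRUE),
                           function(x) x:min(x + blk - 1, n)))
      nu <- sum(1 / s$weight[idx][s$n_bp[idx] == k + 1])
      de <- sum(1 / s$weight[idx][s$n_bp[idx] == k])
      if (nu == 0 || de == 0) return(NA_real_)
      log(nu / de)
    }, numeric(1))
    se <- sd(lr, na.rm = TRUE)
  }
  list(ln_ratio = log(num / den), se = se, run = run,
       samples = s[, c("sweep", "n_bp", "energy", "weight", "ree")])
}

#' Equilibrium thermodynamics of one system under one crowding condition
#'
#' Free-energy profile over the number of formed native base pairs by the
#' overlapping-window estimator: sampling is restricted to one pair of
#' adjacent `n_bp` states at a time (with a short probe run setting a
#' balancing umbrella weight inside each window), the population ratio of
#' each window is measured as the bias-corrected time spent in each state,
#' and the profile is stitched from the log-ratios. Windows are walked from
#' the fully bound fixture downwards, so every window starts from an
#' equilibrated configuration of its upper state.
#'
#' @param kind fixture kind (see [build_fixture()]).
#' @param phi crowder excluded volume fraction.
#' @param r_c crowder radius (nm).
#' @param temperature temperature (K).
#' @param n_sweeps production sweeps per window.
#' @param seed RNG seed.
#' @param L_box box edge (nm) or `NULL` for the default.
#' @param params interaction parameters.
#' @param probe_sweeps probe sweeps per window (sets the window umbrella).
#' @param sample_every sampling stride (sweeps).
#' @param ree_strand strand whose end-to-end distance is recorded in the
#'   lowest (unbound) window (0 = none).
#' @return list with elements `profile` (`fe_profile`), `dG0` (kB T),
#'   `windows` (per-window samples and log-ratios), and the condition
#'   metadata.
#' @export
sample_thermo <- function(kind, phi = 0, r_c = 0.85, temperature = 330,
                          n_sweeps = 8000, seed = 1L, L_box = NULL,
                          params = interaction_params(),
                          probe_sweeps = 1500L, sample_every = 5L,
                          ree_strand = 0L) {
  fx <- build_fixture(kind, "bound", seed = seed, phi = phi, r_c = r_c,
                      L_box = L_box, params = params)
  topo <- fx$topology
  K <- nrow(topo$native_pairs)
  conf <- fx$configuration
  wins <- vector("list", K)
  lnr <- se <- numeric(K)
  for (k in (K - 1):0) {
    wr <- window_ratio(conf, topo, params, temperature, k, n_sweeps,
                       probe_sweeps, sample_every, seed + 131L * k,
                       ree_strand = if (k == 0) ree_strand else 0L)
    wins[[k + 1]] <- wr
    lnr[k + 1] <- wr$ln_ratio
    se[k + 1] <- wr$se
    conf <- wr$run$final
  }
  G <- c(0, cumsum(-lnr))       # G(k) relative to G(0)
  G <- G - G[2]                 # reference: G(1) = 0
  gse <- sqrt(c(se[1]^2, c(0, cumsum(se[-1]^2))))  # error relative to state 1
  gse[2] <- 0
  prof <- tibble(n_bp = 0:K, G = G, se = gse)
  prof <- structure(prof, class = c("fe_profile", class(prof)),
                    temperature = temperature,
                    reference = "G(n_bp = 1) = 0")
  list(kind = kind, phi = phi, r_c = r_c, temperature = temperature,
       seed = seed, profile = prof, dG0 = delta_G0(prof), windows = wins,
       topology = topo)
}

# reweight the windowed profile to another temperature; returns the profile
# G(T2) (same reference) and the smallest per-window effective sample size
reweight_profile <- function(thermo, t_new) {
  b1 <- beta_reduced(thermo$temperature)
  b2 <- beta_reduced(t_new)
  K <- length(thermo$windows)
  lnr <- numeric(K); ess <- Inf
  for (k in seq_len(K)) {
    s <- thermo$windows[[k]]$samples
    lv <- -(b2 - b1) * s$energy - log(s$weight)
    lv <- lv - max(lv)
    v <- exp(lv)
    ess <- min(ess, sum(v)^2 / sum(v^2))
    up <- s$n_bp == k       # window k covers states (k-1, k)
    num <- sum(v[up]); den <- sum(v[!up])
    if (num == 0 || den == 0) return(NULL)
    lnr[k] <- log(num / den)
  }
  G <- c(0, cumsum(-lnr))
  list(G = G - G[2], ess = ess)
}

#' In-box yield over a temperature grid by single-histogram reweighting
#'
#' Each two-state window is reweighted with Boltzmann factors
#' `exp(-E (1/kBT2 - 1/kBT1))`, the profile re-stitched at the target
#' temperature, and the bound yield computed as the Boltzmann-weighted
#' fraction of states with at least one formed pair. The smallest
#' per-window effective sample size is reported and enforced.
#'
#' @param thermo result of [sample_thermo()].
#' @param temperatures target temperatures (K).
#' @param ess_floor minimum effective sample size in any window.
#' @return tibble with `temperature`, `yield`, `ess`.
#' @export
yield_curve <- function(thermo, temperatures, ess_floor = 100) {
  rows <- purrr::map(temperatures, function(t2) {
    rp <- reweight_profile(thermo, t2)
    if (is.null(rp))
      abort(sprintf("reweighting %.1f -> %.1f K lost all samples in a window",
                    thermo$temperature, t2), class = "crowdna_ess_error")
    if (rp$ess < ess_floor)
      abort(sprintf("effective sample size %.1f below floor %.0f when reweighting %.1f K -> %.1f K",
                    rp$ess, ess_floor, thermo$temperature, t2),
            class = "crowdna_ess_error")
    p <- exp(-rp$G)
    tibble(temperature = t2, yield = sum(p[-1]) / sum(p), ess = rp$ess)
  })
  bind_rows(rows)
}

#' Melting temperature of one system under one crowding condition
#'
#' Runs [sample_thermo()] at each anchor temperature, reweights to a fine
#' grid around it, assembles the (bulk-extrapolated, for duplexes) melting
#' curve and interpolates the 50% point.
#'
#' @inheritParams sample_thermo
#' @param anchors anchor temperatures (K) bracketing the melting point.
#' @param spread reweighting half-width around each anchor (K).
#' @param points reweighting grid points per anchor.
#' @param ess_floor minimum effective sample size for the reweighting.
#' @param ... passed to [sample_thermo()].
#' @return list with `curve` (a `melting_curve`) and `tm` (tibble from
#'   [melting_temperature()]).
#' @export
measure_tm <- function(kind, phi = 0, r_c = 0.85, anchors = c(320, 340),
                       spread = 8, points = 5, seed = 1L, ess_floor = 50,
                       ...) {
  kind_class <- if (grepl("duplex", kind)) "duplex" else "hairpin"
  rows <- list()
  for (i in seq_along(anchors)) {
    th <- sample_thermo(kind, phi = phi, r_c = r_c,
                        temperature = anchors[i], seed = seed + 97L * i, ...)
    grid <- seq(anchors[i] - spread, anchors[i] + spread, length.out = points)
    yc <- yield_curve(th, grid, ess_floor = ess_floor)
    # crude per-point error from the effective number of samples
    yc$se <- sqrt(pmax(yc$yield * (1 - yc$yield), 1e-6) / pmax(yc$ess, 1))
    rows[[i]] <- yc
  }
  tab <- bind_rows(rows)
  tab <- tab[order(tab$temperature), ]
  tab <- tab[!duplicated(round(tab$temperature, 6)), ]
  curve <- melting_curve(tab$temperature, tab$yield, se = tab$se,
                         kind = kind_class)
  tm <- melting_temperature(curve)
  list(curve = curve, tm = tm)
}

#' Van't Hoff line of a system under one crowding condition
#'
#' Reweights one windowed profile across a temperature grid, converts
#' yields to equilibrium constants `K = p / (1 - p)` and fits the van't
#' Hoff line.
#'
#' @inheritParams sample_thermo
#' @param temperatures temperature grid (K), at least 3 points.
#' @param ... passed to [sample_thermo()].
#' @return list with `data` (temperature, lnK), `fit` (a `vant_hoff_fit`)
#'   and the underlying `thermo` result.
#' @export
measure_vant_hoff <- function(kind, phi = 0, r_c = 0.85,
                              temperatures = c(320, 330, 340), seed = 1L,
                              ess_floor = 50, ...) {
  anchor <- stats::median(temperatures)
  th <- sample_thermo(kind, phi = phi, r_c = r_c, temperature = anchor,
                      seed = seed, ...)
  yc <- yield_curve(th, temperatures, ess_floor = ess_floor)
  d <- tibble(temperature = yc$temperature,
              lnK = log(yc$yield / (1 - yc$yield)))
  list(data = d, fit = vant_hoff(d), thermo = th)
}

#' End-to-end distance samples of an unbound strand
#'
#' Unbiased Monte Carlo of the unbound fixture restricted to `n_bp = 0`,
#' recording the end-to-end distance between the terminal bases of one
#' strand (the input of the effective-radius convention used by the
#' scaled-particle analysis).
#'
#' @inheritParams sample_thermo
#' @param strand strand index (1-based).
#' @return an `mc_run` whose samples carry `ree`.
#' @export
sample_ree <- function(kind, phi = 0, r_c = 0.85, temperature = 330,
                       n_sweeps = 10000, seed = 1L, L_box = NULL,
                       params = interaction_params(), strand = 1L) {
  fx <- build_fixture(kind, "unbound", seed = seed, phi = phi, r_c = r_c,
                      L_box = L_box, params = params)
  run_mc(fx$configuration, fx$topology, params, temperature,
         n_sweeps = n_sweeps, sample_every = 5L, seed = seed,
         ree_strand = strand, window = c(0L, 0L))
}
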