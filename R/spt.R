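# Scaled particle theory: insertion work of hard convex probes in a
# hard-sphere crowder fluid, crowding-induced stability shifts for hairpin
# and duplex formation, effective-radius fitting, and the Widom-insertion
# Monte Carlo oracle.

# SPT pressure of the hard-sphere fluid (compressibility route):
# beta P v_c = phi (1 + phi + phi^2) / (1 - phi)^3
spt_pressure_term <- function(phi) phi * (1 + phi + phi^2) / (1 - phi)^3

#' SPT insertion work for a hard sphere
#'
#' Reversible work (in kB T) to insert a hard sphere of radius `R` into a
#' hard-sphere fluid of radius `r_c` at packing fraction `phi`: the classic
#' scaled-particle cubic in `s = R/r_c`,
#' `bW = -ln(1-phi) + 3y s + (3y + 9y^2/2) s^2 + bP v_c s^3` with
#' `y = phi/(1-phi)` and the SPT pressure for the volume term. The
#' point-probe limit is `-ln(1-phi)` and the work is strictly increasing in
#' both `R` and `phi`.
#'
#' @param R probe radius (nm); vectorised.
#' @param r_c crowder radius (nm).
#' @param phi crowder packing fraction in `[0, 0.55)`.
#' @return insertion work in kB T.
#' @examples
#' spt_work_sphere(0, 1, 0.3)   # -log(0.7)
#' spt_work_sphere(1, 1, 0.2)
#' @export
spt_work_sphere <- function(R, r_c, phi) {
  check_spt_args(R, r_c, phi)
  s <- R / r_c
  y <- phi / (1 - phi)
  -log(1 - phi) + 3 * y * s + (3 * y + 4.5 * y^2) * s^2 +
    spt_pressure_term(phi) * s^3
}

#' SPT insertion work for a hard spherocylinder
#'
#' Convex-body extension of the scaled-particle sphere result via the
#' Steiner functionals (volume `V`, surface `S`, integral mean curvature
#' `M`): writing the sphere cubic as a linear form in `M/4pi`, `S/4pi` and
#' `3V/4pi` (which for a sphere are `R`, `R^2`, `R^3`), the same
#' coefficients applied to the spherocylinder give its insertion work.
#' For a spherocylinder of radius `r` and cylinder length `L`:
#' `V = pi r^2 L + 4/3 pi r^3`, `S = 2 pi r L + 4 pi r^2`,
#' `M = 4 pi r + pi L`. The expression reduces exactly to
#' [spt_work_sphere()] at `L = 0`.
#'
#' @param r_sc spherocylinder radius (nm).
#' @param L_sc cylinder length (nm, `>= 0`).
#' @param r_c crowder radius (nm).
#' @param phi crowder packing fraction.
#' @return insertion work in kB T.
#' @export
spt_work_spherocylinder <- function(r_sc, L_sc, r_c, phi) {
  check_spt_args(r_sc, r_c, phi)
  stopifnot(all(L_sc >= 0))
  V <- pi * r_sc^2 * L_sc + 4 / 3 * pi * r_sc^3
  S <- 2 * pi * r_sc * L_sc + 4 * pi * r_sc^2
  M <- 4 * pi * r_sc + pi * L_sc
  y <- phi / (1 - phi)
  c1 <- 3 * y / r_c
  c2 <- (3 * y + 4.5 * y^2) / r_c^2
  c3 <- spt_pressure_term(phi) / r_c^3
  -log(1 - phi) + c1 * (M / (4 * pi)) + c2 * (S / (4 * pi)) +
    c3 * (3 * V / (4 * pi))
}

check_spt_args <- function(R, r_c, phi) {
  if (any(R < 0)) abort("probe radius must be non-negative")
  if (any(r_c <= 0)) abort("crowder radius must be positive")
  if (any(phi < 0 | phi >= 0.55))
    abort("phi must lie in [0, 0.55): scaled particle theory is not evaluated beyond packing feasibility")
  invisible(TRUE)
}

#' SPT geometry for the folding/hybridisation transitions
#'
#' @param r_u unfolded-state effective sphere radius (nm).
#' @param r_f folded-hairpin effective sphere radius (nm; stabilisation
#'   requires `r_f < r_u`).
#' @param r_sc duplex spherocylinder radius (nm).
#' @param L_sc duplex cylinder length; the default `2 r_sc` realises the
#'   two-adjacent-spheres picture of the bound duplex.
#' @param r_c crowder radius (nm).
#' @param phi crowder packing fraction.
#' @return object of class `spt_geometry`.
#' @export
spt_geometry <- function(r_u, r_f = NULL, r_sc = NULL, L_sc = NULL,
                         r_c = 0.85, phi = 0.3) {
  stopifnot(r_u > 0)
  if (!is.null(r_f)) stopifnot(r_f > 0)
  if (!is.null(r_sc)) {
    stopifnot(r_sc > 0)
    if (is.null(L_sc)) L_sc <- 2 * r_sc
  }
  check_spt_args(r_u, r_c, phi)
  structure(list(r_u = r_u, r_f = r_f, r_sc = r_sc, L_sc = L_sc,
                 r_c = r_c, phi = phi), class = "spt_geometry")
}

#' Crowding-induced stability shift of hairpin folding
#'
#' `ddG = bW(r_f) - bW(r_u)`: the change in the folding free energy caused
#' by the crowders (kB T). Negative means the folded (compact) state is
#' stabilised in the crowded environment.
#'
#' @param geom an [spt_geometry()] with `r_f` set, or the individual
#'   arguments.
#' @return ddG in kB T (vectorised over `phi`/`r_c` when given directly).
#' @export
ddg_hairpin <- function(geom) {
  stopifnot(inherits(geom, "spt_geometry"), !is.null(geom$r_f))
  spt_work_sphere(geom$r_f, geom$r_c, geom$phi) -
    spt_work_sphere(geom$r_u, geom$r_c, geom$phi)
}

#' Crowding-induced stability shift of duplex formation
#'
#' `ddG = bW_spherocylinder(r_sc, L_sc) - 2 bW(r_u)`: two unfolded coils
#' are replaced by one bound spherocylinder.
#'
#' @inheritParams ddg_hairpin
#' @return ddG in kB T.
#' @export
ddg_duplex <- function(geom) {
  stopifnot(inherits(geom, "spt_geometry"), !is.null(geom$r_sc))
  spt_work_spherocylinder(geom$r_sc, geom$L_sc, geom$r_c, geom$phi) -
    2 * spt_work_sphere(geom$r_u, geom$r_c, geom$phi)
}

#' SPT stability-shift table over a crowding grid
#'
#' @param geom an [spt_geometry()] (its `phi`, `r_c` are ignored).
#' @param phi,r_c grids of packing fractions and crowder radii.
#' @param kind `"hairpin"` or `"duplex"`.
#' @return tibble with columns `phi`, `r_c`, `ddg`.
#' @export
ddg_grid <- function(geom, phi, r_c, kind = c("hairpin", "duplex")) {
  kind <- match.arg(kind)
  grid <- tidyr::expand_grid(phi = phi, r_c = r_c)
  f <- if (kind == "hairpin") ddg_hairpin else ddg_duplex
  grid$ddg <- purrr::map2_dbl(grid$phi, grid$r_c, function(p, rc) {
    g <- geom; g$phi <- p; g$r_c <- rc
    f(g)
  })
  grid
}

#' Fit effective radii to a measured stability-shift table
#'
#' Least-squares fit of the SPT geometry parameters (hairpin: `r_u`, `r_f`;
#' duplex: `r_u`, `r_sc` with `L_sc = 2 r_sc`) to measured `ddG(phi, r_c)`
#' values, within physical bounds. Parameter confidence intervals come from
#' the curvature of the objective at the optimum; parameters pinned at
#' their bounds are flagged.
#'
#' @param ddg_table tibble with columns `phi`, `r_c`, `ddg` (kB T); at
#'   least 3 rows.
#' @param kind `"hairpin"` or `"duplex"`.
#' @param start,lower,upper named starting values and box bounds for the
#'   two radii.
#' @return object of class `spt_fit`: fitted `geometry`, `parameters`
#'   tibble (estimate, se, ci, at_bound), `residuals`, `rss`, `converged`.
#' @export
fit_effective_radii <- function(ddg_table, kind = c("hairpin", "duplex"),
                                start = NULL, lower = NULL, upper = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(c("phi", "r_c", "ddg") %in% names(ddg_table)))
  if (nrow(ddg_table) < 3) abort("need at least 3 (phi, r_c) points to fit")
  pnames <- if (kind == "hairpin") c("r_u", "r_f") else c("r_u", "r_sc")
  if (is.null(start)) start <- setNames(c(1.2, 0.8), pnames)
  if (is.null(lower)) lower <- setNames(c(0.05, 0.05), pnames)
  if (is.null(upper)) upper <- setNames(c(5, 5), pnames)
  predfun <- function(par, phi, r_c) {
    if (kind == "hairpin") {
      spt_work_sphere(par[2], r_c, phi) - spt_work_sphere(par[1], r_c, phi)
    } else {
      spt_work_spherocylinder(par[2], 2 * par[2], r_c, phi) -
        2 * spt_work_sphere(par[1], r_c, phi)
    }
  }
  obj <- function(par) {
    pr <- purrr::map2_dbl(ddg_table$phi, ddg_table$r_c,
                          function(p, rc) predfun(par, p, rc))
    sum((pr - ddg_table$ddg)^2)
  }
  # multi-start box-constrained least squares (the surface can be multimodal)
  starts <- list(unname(start[pnames]), c(0.6, 0.4), c(1.5, 1.0), c(2.5, 1.8))
  opt <- NULL
  for (s0 in starts) {
    o <- stats::nlminb(s0, obj, lower = unname(lower[pnames]),
                       upper = unname(upper[pnames]),
                       control = list(iter.max = 500, abs.tol = 1e-14))
    if (is.null(opt) || o$objective < opt$objective) opt <- o
  }
  if (!opt$convergence %in% c(0, 1))
    abort(paste("effective-radius fit did not converge:", opt$message))
  opt$value <- opt$objective
  opt$hessian <- stats::optimHess(opt$par, obj)
  par <- setNames(opt$par, pnames)
  n <- nrow(ddg_table); k <- length(par)
  sigma2 <- opt$value / max(n - k, 1)
  se <- rep(NA_real_, k)
  covm <- try(solve(opt$hessian / 2) * sigma2, silent = TRUE)
  if (!inherits(covm, "try-error")) {
    dg <- diag(covm); dg[dg < 0] <- NA
    se <- sqrt(dg)
  }
  at_bound <- par <= lower[pnames] + 1e-6 | par >= upper[pnames] - 1e-6
  if (any(at_bound))
    warn(paste("fitted parameter(s) pinned at bounds:",
               paste(pnames[at_bound], collapse = ", ")))
  pred <- purrr::map2_dbl(ddg_table$phi, ddg_table$r_c,
                          function(p, rc) predfun(par, p, rc))
  geom <- if (kind == "hairpin")
    spt_geometry(r_u = par[1], r_f = par[2]) else
    spt_geometry(r_u = par[1], r_sc = par[2])
  structure(list(geometry = geom, kind = kind,
                 parameters = tibble(term = pnames, estimate = unname(par),
                                     se = unname(se),
                                     ci_lo = unname(par - 1.96 * se),
                                     ci_hi = unname(par + 1.96 * se),
                                     at_bound = unname(at_bound)),
                 residuals = ddg_table$ddg - pred, rss = opt$value,
                 fitted = pred, data = ddg_table, converged = TRUE),
            class = "spt_fit")
}

#' @export
print.spt_fit <- function(x, ...) {
  cat(sprintf("<spt_fit> %s: RSS %.3g over %d points\n", x$kind, x$rss,
              nrow(x$data)))
  print(x$parameters)
  invisible(x)
}

#' Effective sphere radius from end-to-end distances
#'
#' The effective radius of an unfolded strand is taken from the mean
#' end-to-end distance between its terminal bases: `radius =
#' convention * mean(R_ee)` with the documented default convention 1/2.
#' Bound-state trajectories are refused (the estimator is defined for the
#' unbound/unfolded ensemble). Errors come from a block bootstrap.
#'
#' @param x a numeric vector of end-to-end distances (nm), or an `mc_run`
#'   sampled with `ree_strand` set.
#' @param convention multiplier from mean end-to-end distance to radius.
#' @param max_bound_frac maximum tolerated fraction of frames with
#'   `n_bp > 0` for `mc_run` input.
#' @param n_boot bootstrap replicates.
#' @return tibble with columns `mean_ree`, `radius`, `se_radius`, `n`.
#' @export
end_to_end_radius <- function(x, convention = 0.5, max_bound_frac = 0.05,
                              n_boot = 100L) {
  if (inherits(x, "mc_run")) {
    frac_bound <- mean(x$samples$n_bp > 0)
    if (frac_bound > max_bound_frac)
      abort(sprintf("trajectory is bound in %.0f%% of frames: the end-to-end radius is defined for the unbound ensemble",
                    100 * frac_bound), class = "crowdna_bound_trajectory")
    x <- x$samples$ree
  }
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) abort("need at least 2 end-to-end samples")
  blk <- max(10L, ceiling(10 * est_act(x)))
  nblk <- max(1L, n %/% blk)
  se <- NA_real_
  if (nblk >= 2 && n_boot > 0) {
    starts <- (seq_len(nblk) - 1) * blk + 1
    ms <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(starts, nblk, replace = TRUE)
      idx <- unlist(lapply(pick, function(s) s:min(s + blk - 1, n)))
      mean(x[idx])
    }, numeric(1))
    se <- sd(ms) * convention
  }
  tibble(mean_ree = mean(x), radius = convention * mean(x),
         se_radius = se, n = n)
}

# ---------------------------------------------------------------------------
# Widom-insertion oracle

#' Equilibrated hard-sphere fluid
#'
#' Builds a periodic hard-sphere fluid at packing fraction `phi` by random
#' sequential addition followed by Monte Carlo relaxation.
#'
#' @param phi packing fraction.
#' @param r_c sphere radius (nm).
#' @param L box edge (nm).
#' @param equil_sweeps relaxation sweeps.
#' @param seed RNG seed.
#' @return object of class `hs_fluid`: positions, `r_c`, `L`, `phi`
#'   achieved.
#' @export
hs_fluid <- function(phi, r_c = 1, L = 12, equil_sweeps = 400L, seed = 1L) {
  cnt <- crowders_for_phi(phi, r_c, L)
  pos <- pack_crowders(cnt$count, r_c, L, seed = seed,
                       existing_sites = matrix(numeric(0), ncol = 3),
                       clearance = 0)
  pos <- cpp_hs_relax(pos, L, r_c, as.integer(equil_sweeps), 0.3 * r_c,
                      as.integer(seed + 1L))
  structure(list(pos = pos, r_c = r_c, L = L, n = cnt$count,
                 phi = cnt$phi_achieved, seed = seed), class = "hs_fluid")
}

#' Widom insertion estimate of the insertion work
#'
#' Monte Carlo test-particle insertion into an equilibrated hard-sphere
#' fluid: the insertion work is `-ln <exp(-bDU)>` with `DU` either 0 (no
#' overlap) or infinite, i.e. `-ln(acceptance fraction)`. Fresh fluid
#' snapshots are interleaved with insertion batches to decorrelate the
#' estimate.
#'
#' @param fluid an [hs_fluid()].
#' @param probe `"sphere"` or `"spherocylinder"`.
#' @param R probe radius (nm).
#' @param L_sc cylinder length for the spherocylinder probe.
#' @param n_insert total insertions.
#' @param n_batches fluid re-equilibration batches.
#' @param resample_sweeps relaxation sweeps between batches.
#' @param seed RNG seed.
#' @return tibble with columns `bW`, `se`, `frac`, `n_insert`.
#' @export
widom_insertion <- function(fluid, probe = c("sphere", "spherocylinder"),
                            R, L_sc = 0, n_insert = 2e5, n_batches = 8L,
                            resample_sweeps = 40L, seed = 1L) {
  probe <- match.arg(probe)
  stopifnot(inherits(fluid, "hs_fluid"))
  if (probe == "spherocylinder" && fluid$L < L_sc + 2 * (R + fluid$r_c))
    abort("box too small for the spherocylinder probe under minimum image")
  per <- ceiling(n_insert / n_batches)
  pos <- fluid$pos
  fracs <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    res <- cpp_widom(pos, fluid$L, fluid$r_c,
                     if (probe == "sphere") 0L else 1L, R, L_sc,
                     as.integer(per), as.integer(seed + 31L * b))
    fracs[b] <- res$frac
    pos <- cpp_hs_relax(pos, fluid$L, fluid$r_c, as.integer(resample_sweeps),
                        0.3 * fluid$r_c, as.integer(seed + 31L * b + 7L))
  }
  frac <- mean(fracs)
  if (frac == 0) abort("no successful insertions: probe too large for this fluid/budget",
                       class = "crowdna_undersampled")
  se_frac <- sd(fracs) / sqrt(n_batches)
  tibble(bW = -log(frac), se = se_frac / frac, frac = frac,
         n_insert = per * n_batches)
}
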