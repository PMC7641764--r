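# Miniature end-to-end study driver: runs the thermodynamic and kinetic
# pipeline over a crowding grid and assembles the report tables.

#' Run a study end-to-end and assemble its report
#'
#' For every job in the configured (phi, r_c) grid this measures the
#' free-energy profile and binding free energy, reweights a small melting
#' curve and a van't Hoff line, optionally runs staged FFS for the
#' association rate, fits the scaled-particle effective radii to the
#' measured stability shifts, and writes the report sections as TSV tables
#' plus a JSON summary into the output directory. Every table carries the
#' seeds and parameters needed to re-run it.
#'
#' @param config a [run_config()].
#' @param thermo_sweeps production sweeps per window.
#' @param ffs run the kinetics stage (staged FFS per job).
#' @param ffs_budget list of FFS budgets (`n_steps_max`, `target_crossings`,
#'   `n_trials`, `max_steps_trial`).
#' @param plots also write ggplot figures (regenerable; failures to open a
#'   graphics device are ignored).
#' @return (invisibly) a list with the assembled tables: `thermo`,
#'   `profiles`, `melting`, `vanthoff`, `ffs`, `spt`, and the `manifest`.
#' @export
study_report <- function(config, thermo_sweeps = 3000, ffs = TRUE,
                         ffs_budget = list(n_steps_max = 1.5e5,
                                           target_crossings = 15,
                                           n_trials = c(50, 30),
                                           max_steps_trial = c(8000, 30000)),
                         plots = FALSE) {
  stopifnot(inherits(config, "run_config"))
  manifest <- generate_study(config)
  out <- config$out_dir
  anchor <- stats::median(config$temperatures)
  kind_class <- if (grepl("duplex", config$system)) "duplex" else "hairpin"

  thermo_rows <- list(); prof_rows <- list(); melt_rows <- list()
  vh_rows <- list(); ffs_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    jb <- manifest[i, ]
    th <- sample_thermo(config$system, phi = jb$phi, r_c = jb$r_c,
                        temperature = anchor, n_sweeps = thermo_sweeps,
                        seed = jb$seed, L_box = config$L_box)
    thermo_rows[[i]] <- tibble(job = jb$job, phi = jb$phi, r_c = jb$r_c,
                               temperature = anchor, dG0 = th$dG0,
                               seed = jb$seed)
    prof_rows[[i]] <- mutate(tidy(th$profile), job = jb$job, phi = jb$phi,
                             r_c = jb$r_c)
    grid <- seq(anchor - 10, anchor + 10, length.out = 5)
    yc <- tryCatch(yield_curve(th, grid, ess_floor = 30),
                   crowdna_ess_error = function(e) NULL)
    if (!is.null(yc)) {
      melt_rows[[i]] <- mutate(yc, job = jb$job, phi = jb$phi,
                               r_c = jb$r_c,
                               yield_bulk = if (kind_class == "duplex")
                                 bulk_yield(.data$yield) else .data$yield)
      d <- tibble(temperature = yc$temperature,
                  lnK = log(pmin(pmax(yc$yield, 1e-9), 1 - 1e-9) /
                            pmax(1 - yc$yield, 1e-9)))
      fit <- vant_hoff(d)
      vh_rows[[i]] <- tibble(job = jb$job, phi = jb$phi, r_c = jb$r_c,
                             dH = fit$dH, dS = fit$dS,
                             residual_rms = fit$residual_rms)
    }
    if (ffs) {
      fx <- build_fixture(config$system, "unbound", seed = jb$seed,
                          phi = jb$phi, r_c = jb$r_c, L_box = config$L_box)
      dyn <- dynamics_params(temperature = anchor, dt = 0.005,
                             seed = jb$seed)
      ff <- tryCatch(
        run_ffs(fx$configuration, fx$topology, dyn = dyn,
                interfaces = standard_interfaces(config$system),
                n_steps_max = ffs_budget$n_steps_max,
                target_crossings = ffs_budget$target_crossings,
                n_trials = ffs_budget$n_trials,
                max_steps_trial = ffs_budget$max_steps_trial,
                seed = jb$seed),
        crowdna_undersampled = function(e) NULL)
      if (!is.null(ff))
        ffs_rows[[i]] <- mutate(glance(ff), job = jb$job, phi = jb$phi,
                                r_c = jb$r_c, k_se = ff$k_se)
    }
  }
  thermo <- bind_rows(thermo_rows)
  profiles <- bind_rows(prof_rows)
  melting <- bind_rows(melt_rows)
  vanthoff <- bind_rows(vh_rows)
  ffs_tab <- bind_rows(ffs_rows)

  # normalise rates to the crowder-free reference
  if (nrow(ffs_tab) > 0 && any(ffs_tab$phi == 0)) {
    k0 <- ffs_tab$k[ffs_tab$phi == 0][1]
    if (k0 > 0) ffs_tab$k_relative <- ffs_tab$k / k0
  }

  # SPT comparison: measured stability shifts against the crowder-free job
  spt_tab <- tibble()
  if (any(thermo$phi == 0) && sum(thermo$phi > 0) >= 1) {
    dg0_ref <- thermo$dG0[thermo$phi == 0][1]
    spt_tab <- filter(thermo, .data$phi > 0)
    spt_tab <- mutate(spt_tab, ddg = .data$dG0 - dg0_ref)
    if (nrow(spt_tab) >= 3) {
      fit <- tryCatch(fit_effective_radii(spt_tab, kind_class),
                      error = function(e) NULL)
      if (!is.null(fit))
        spt_tab$ddg_spt <- fit$fitted
    }
  }

  wr <- function(tab, name) {
    utils::write.table(tab, file.path(out, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(thermo, "thermo"); wr(profiles, "profiles"); wr(melting, "melting")
  wr(vanthoff, "vanthoff"); wr(ffs_tab, "ffs"); wr(spt_tab, "spt")
  jsonlite::write_json(
    list(system = config$system, seed = config$seed,
         temperature_anchor = anchor, n_jobs = nrow(manifest),
         sections = c("thermo", "profiles", "melting", "vanthoff", "ffs",
                      "spt")),
    file.path(out, "summary.json"), auto_unbox = TRUE)
  if (plots) {
    try({
      grDevices::pdf(file.path(out, "report.pdf"), width = 6, height = 4)
      on.exit(grDevices::dev.off(), add = TRUE)
      print(ggplot(profiles, aes(x = .data$n_bp, y = .data$G,
                                 colour = factor(.data$phi))) +
              geom_line() + geom_point() + theme_bw() +
              labs(x = "native base pairs", y = "G (kBT)", colour = "phi"))
    }, silent = TRUE)
  }
  invisible(list(manifest = manifest, thermo = thermo, profiles = profiles,
                 melting = melting, vanthoff = vanthoff, ffs = ffs_tab,
                 spt = spt_tab, out_dir = out))
}
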