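# Plain-text file dialects (topology / configuration, following the layout
# of the oxDNA text formats with versioned headers and inline crowder
# records), YAML run configuration, and study generation.

TOP_HEADER <- "# crowdna-top 1"
CONF_HEADER <- "# crowdna-conf 1"

#' Write a topology file
#'
#' Dialect: a versioned header, a count line `n_nucleotides n_strands`, one
#' line per nucleotide (`strand_id base prev next`, 0-based indices, -1 for
#' chain ends), one `pair i j` line per native pair, optional named
#' `subset` lines, and `competing` / `kind` metadata. Documented in the
#' package README; round-trips field-exactly.
#'
#' @param topo a `cg_topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  stopifnot(inherits(topo, "cg_topology"))
  n <- n_nucleotides(topo)
  lines <- c(TOP_HEADER,
             sprintf("%d %d", n, length(topo$strands)),
             sprintf("%d %s %d %d", topo$strand_id, topo$bases,
                     topo$prev, topo$nxt))
  if (nrow(topo$native_pairs) > 0)
    lines <- c(lines, sprintf("pair %d %d", topo$native_pairs[, 1],
                              topo$native_pairs[, 2]))
  for (nm in names(topo$subsets))
    lines <- c(lines, sprintf("subset %s %s", nm,
                              paste(topo$subsets[[nm]], collapse = ",")))
  lines <- c(lines, sprintf("competing %d", as.integer(topo$allow_competing)))
  if (!is.null(topo$kind)) lines <- c(lines, paste("kind", topo$kind))
  writeLines(lines, path)
  invisible(path)
}

parse_fail <- function(path, lineno, why) {
  abort(sprintf("%s:%d: %s", path, lineno, why), class = "crowdna_parse_error")
}

#' Read a topology file
#'
#' @param path file written by [write_topology()].
#' @return a `cg_topology`.
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) parse_fail(path, length(lines), "truncated file")
  if (!identical(lines[1], TOP_HEADER))
    parse_fail(path, 1, paste("unsupported topology version; expected", TOP_HEADER))
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]]))
  if (length(hdr) != 2 || any(is.na(hdr)))
    parse_fail(path, 2, "count line must be 'n_nucleotides n_strands'")
  n <- hdr[1]; ns <- hdr[2]
  if (length(lines) < 2 + n) parse_fail(path, length(lines), "truncated file: missing nucleotide records")
  strand_id <- integer(n); bases <- character(n)
  prv <- integer(n); nxt <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[2 + i]), "\\s+")[[1]]
    if (length(f) != 4) parse_fail(path, 2 + i, "nucleotide record must have 4 fields")
    strand_id[i] <- as.integer(f[1]); bases[i] <- f[2]
    prv[i] <- as.integer(f[3]); nxt[i] <- as.integer(f[4])
    if (is.na(strand_id[i]) || is.na(prv[i]) || is.na(nxt[i]))
      parse_fail(path, 2 + i, "malformed nucleotide record")
  }
  if (!setequal(unique(strand_id), seq_len(ns)))
    parse_fail(path, 2, "strand ids inconsistent with declared strand count")
  pairs <- matrix(integer(0), ncol = 2)
  subsets <- list(); competing <- FALSE; kind <- NULL
  for (ln in seq_along(lines)[-seq_len(2 + n)]) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) == 0 || f[1] == "") next
    if (f[1] == "pair") {
      ij <- suppressWarnings(as.integer(f[2:3]))
      if (length(f) != 3 || any(is.na(ij))) parse_fail(path, ln, "malformed pair record")
      pairs <- rbind(pairs, ij)
    } else if (f[1] == "subset") {
      if (length(f) != 3) parse_fail(path, ln, "malformed subset record")
      subsets[[f[2]]] <- as.integer(strsplit(f[3], ",")[[1]])
    } else if (f[1] == "competing") {
      competing <- as.integer(f[2]) == 1L
    } else if (f[1] == "kind") {
      kind <- f[2]
    } else parse_fail(path, ln, paste("unknown record type", f[1]))
  }
  # rebuild strands from ids and neighbour chains
  strands <- lapply(seq_len(ns), function(s) {
    ix <- which(strand_id == s) - 1L
    first <- ix[prv[ix + 1] == -1L]
    if (length(first) != 1) parse_fail(path, 2, "inconsistent chain structure")
    ordered <- integer(0); cur <- first
    while (cur != -1L) { ordered <- c(ordered, cur); cur <- nxt[cur + 1] }
    ordered
  })
  topology(strands = strands, native_pairs = pairs, bases = bases,
           subsets = if (length(subsets)) subsets else NULL,
           allow_competing = competing, kind = kind)
}

#' Write a configuration file
#'
#' Dialect: versioned header, then `t = 0`, `b = L L L`, `E = 0 0 0`
#' header lines, a `crowders = n r_c phi seed` record, one 9-column line
#' per nucleotide (position at fixed 6 decimals, base vector and base
#' normal at fixed 9 decimals so orthonormality survives the round trip)
#' and one `c x y z` line per crowder. Bit-stable on write/read/write.
#'
#' @param conf a `cg_configuration`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_configuration <- function(conf, path) {
  stopifnot(inherits(conf, "cg_configuration"))
  num <- function(x) sprintf("%.6f", x)
  ori <- function(x) sprintf("%.9f", x)
  hdr <- c(CONF_HEADER, "t = 0",
           paste("b =", num(conf$L), num(conf$L), num(conf$L)),
           "E = 0 0 0",
           sprintf("crowders = %d %s %s %s", nrow(conf$cpos), num(conf$rc),
                   if (is.null(conf$phi)) "NA" else num(conf$phi),
                   if (is.null(conf$seed)) "NA" else as.character(conf$seed)))
  nt <- vapply(seq_len(nrow(conf$pos)), function(i)
    paste(c(num(conf$pos[i, ]), ori(conf$e1[i, ]), ori(conf$e3[i, ])),
          collapse = " "), character(1))
  cr <- if (nrow(conf$cpos) > 0)
    apply(conf$cpos, 1, function(r) paste("c", paste(num(r), collapse = " ")))
  else character(0)
  writeLines(c(hdr, nt, cr), path)
  invisible(path)
}

#' Read a configuration file
#'
#' @param path file written by [write_configuration()].
#' @return a `cg_configuration`.
#' @export
read_configuration <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5) parse_fail(path, length(lines), "truncated file")
  if (!identical(lines[1], CONF_HEADER))
    parse_fail(path, 1, paste("unsupported configuration version; expected", CONF_HEADER))
  bf <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(bf) != 5 || bf[1] != "b")
    parse_fail(path, 3, "expected box record 'b = L L L'")
  L <- as.numeric(bf[3])
  cf <- strsplit(trimws(lines[5]), "\\s+")[[1]]
  if (length(cf) != 6 || cf[1] != "crowders")
    parse_fail(path, 5, "expected crowder record 'crowders = n r_c phi seed'")
  ncr <- as.integer(cf[3]); rc <- as.numeric(cf[4])
  phi <- suppressWarnings(as.numeric(cf[5])); if (is.na(phi)) phi <- NULL
  seed <- suppressWarnings(as.integer(cf[6])); if (is.na(seed)) seed <- NULL
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  is_cr <- startsWith(trimws(body), "c ")
  nt_lines <- body[!is_cr]; cr_lines <- body[is_cr]
  if (length(cr_lines) != ncr)
    parse_fail(path, length(lines),
               sprintf("inconsistent counts: header declares %d crowders, found %d", ncr, length(cr_lines)))
  if (length(nt_lines) == 0) parse_fail(path, 6, "no nucleotide records")
  nt <- matrix(NA_real_, length(nt_lines), 9)
  for (i in seq_along(nt_lines)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(nt_lines[i]), "\\s+")[[1]]))
    if (length(v) != 9 || any(is.na(v)))
      parse_fail(path, 5 + i, "nucleotide record must have 9 numeric fields")
    nt[i, ] <- v
  }
  cpos <- matrix(numeric(0), ncol = 3)
  if (ncr > 0) {
    cpos <- matrix(NA_real_, ncr, 3)
    for (i in seq_along(cr_lines)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(cr_lines[i]), "\\s+")[[1]][-1]))
      if (length(v) != 3 || any(is.na(v)))
        parse_fail(path, 5 + length(nt_lines) + i, "crowder record must be 'c x y z'")
      cpos[i, ] <- v
    }
  }
  configuration(pos = nt[, 1:3, drop = FALSE], e1 = nt[, 4:6, drop = FALSE],
                e3 = nt[, 7:9, drop = FALSE], L_box = L, cpos = cpos,
                r_c = rc, phi = phi, seed = seed)
}

# ---------------------------------------------------------------------------
# run configuration (YAML)

RUN_CONFIG_KEYS <- c("system", "phi", "r_c", "L_box", "temperatures",
                     "n_sweeps", "sample_every", "seed", "out_dir",
                     "dynamics", "ffs", "mc")

#' Run configuration
#'
#' Assembles and validates the configuration of a study: system kind, the
#' crowding grid, temperatures, sampling lengths, and the master seed from
#' which every per-job seed is derived. Unknown keys are rejected.
#'
#' @param system fixture kind (see [build_fixture()]).
#' @param phi vector of excluded volume fractions.
#' @param r_c vector of crowder radii (nm).
#' @param L_box box edge (nm) or `NULL` for the per-kind default.
#' @param temperatures temperatures (K).
#' @param n_sweeps MC sweeps per job.
#' @param sample_every sampling stride.
#' @param seed master seed; per-job seeds are derived from it.
#' @param out_dir output directory for [generate_study()].
#' @param dynamics,ffs,mc optional module parameter blocks (named lists).
#' @return object of class `run_config`.
#' @export
run_config <- function(system = "duplex8", phi = c(0, 0.3), r_c = 0.85,
                       L_box = NULL, temperatures = 330, n_sweeps = 20000,
                       sample_every = 10, seed = 1L, out_dir = tempdir(),
                       dynamics = list(), ffs = list(), mc = list()) {
  cfg <- list(system = system, phi = phi, r_c = r_c, L_box = L_box,
              temperatures = temperatures, n_sweeps = n_sweeps,
              sample_every = sample_every, seed = seed, out_dir = out_dir,
              dynamics = dynamics, ffs = ffs, mc = mc)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0)
    abort(paste("unknown run-config keys:", paste(unknown, collapse = ", ")),
          class = "crowdna_config_error")
  kinds <- c("duplex8", "duplex4", "hairpin_loop10", "hairpin_loop4",
             "displacement")
  if (!cfg$system %in% kinds)
    abort(paste("unknown system kind", cfg$system), class = "crowdna_config_error")
  if (any(cfg$phi < 0 | cfg$phi >= 0.55))
    abort("phi values must lie in [0, 0.55)", class = "crowdna_config_error")
  if (any(cfg$r_c <= 0)) abort("r_c must be positive", class = "crowdna_config_error")
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    abort("a master seed is required", class = "crowdna_config_error")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the keys of [run_config()].
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- run_config()
  merged <- modifyList(unclass(base), cfg)
  validate_run_config(merged)
}

# deterministic per-job seed derived from the master seed (kept below 2^31)
derive_seed <- function(master, idx) {
  as.integer((as.numeric(master) * 1009 + idx * 9176) %% 2147483647)
}

#' Enumerate and materialise a study grid
#'
#' Expands the (phi, r_c) grid for the configured system (phi = 0 collapses
#' to a single crowder-free reference job), builds each fixture with its
#' crowder packing, writes topology/configuration files into the output
#' directory, and returns the job manifest. Infeasible packings are skipped
#' with a warning. The manifest file is byte-identical for a fixed master
#' seed.
#'
#' @param config a `run_config`.
#' @return tibble manifest (one row per runnable job), invisibly; also
#'   written as `manifest.tsv` in `out_dir`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- tidyr::expand_grid(phi = sort(unique(config$phi)),
                             r_c = sort(unique(config$r_c)))
  grid <- grid[!(grid$phi == 0 & duplicated(grid$phi)), ]
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    phi <- grid$phi[i]; rc <- grid$r_c[i]
    job_seed <- derive_seed(config$seed, i)
    fx <- tryCatch(
      build_fixture(config$system, "unbound", seed = job_seed, phi = phi,
                    r_c = rc, L_box = config$L_box),
      crowdna_packing_error = function(e) {
        warn(sprintf("skipping infeasible packing phi=%.2f r_c=%.2f: %s",
                     phi, rc, conditionMessage(e)))
        NULL
      })
    if (is.null(fx)) next
    tag <- sprintf("%s_phi%03d_rc%03d", config$system,
                   round(100 * phi), round(100 * rc))
    top <- file.path(config$out_dir, paste0(tag, ".top"))
    cnf <- file.path(config$out_dir, paste0(tag, ".conf"))
    write_topology(fx$topology, top)
    write_configuration(fx$configuration, cnf)
    rows[[length(rows) + 1]] <- tibble(
      job = tag, system = config$system, phi = phi, r_c = rc,
      seed = job_seed, topology = basename(top), configuration = basename(cnf),
      temperatures = paste(config$temperatures, collapse = ","),
      n_sweeps = config$n_sweeps)
  }
  manifest <- bind_rows(rows)
  mpath <- file.path(config$out_dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(manifest)
}
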