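# Synthetic test-system generators: every system studied by the package can
# be built programmatically (no external data). Geometries are idealised
# ladders (duplexes, hairpin stems) and circular-arc loops that satisfy the
# FENE backbone constraint exactly.

# distance between consecutive backbone sites in built fixtures (= FENE r0)
RISE <- 0.64
# centre-to-centre separation of paired columns in a built ladder; places
# paired base sites exactly at the HB well minimum (d0_hb = 0.4 nm)
LADDER_SEP <- 1.2

# circle radius such that (n_seg) chords of length `rise` plus one closing
# chord of length `chord` tile the full circle (loop construction)
solve_loop_radius <- function(n_seg, rise = RISE, chord = 2.0) {
  f <- function(R) n_seg * 2 * asin(rise / (2 * R)) + 2 * asin(chord / (2 * R)) - 2 * pi
  lo <- max(rise, chord) / 2 + 1e-4
  uniroot(f, c(lo, 20))$root
}

# ladder columns for a duplex of n pairs; strand A along +z at x = 0,
# partner column at x = LADDER_SEP, antiparallel
ladder_positions <- function(n) {
  a_pos <- cbind(0, 0, RISE * (seq_len(n) - 1))
  b_pos <- cbind(LADDER_SEP, 0, RISE * (seq_len(n) - 1))
  list(a = a_pos, b = b_pos)
}

rep_row <- function(v, n) matrix(rep(v, each = n), nrow = n)

random_bases <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

complement <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

build_duplex <- function(n, state, L_box, bound_pairs = 3L) {
  strands <- list(0:(n - 1), n:(2 * n - 1))
  pairs <- cbind(0:(n - 1), (2 * n - 1):n)
  pos <- matrix(0, 2 * n, 3)
  e1 <- matrix(0, 2 * n, 3); e3 <- matrix(0, 2 * n, 3)
  lad <- ladder_positions(n)
  pos[1:n, ] <- lad$a
  e1[1:n, ] <- rep_row(c(1, 0, 0), n); e3[1:n, ] <- rep_row(c(0, 0, 1), n)
  # strand B nucleotide n + j (0-based) partners A_(n-1-j): descending z
  bz <- RISE * ((n - 1):0)
  pos[(n + 1):(2 * n), ] <- cbind(LADDER_SEP, 0, bz)
  e1[(n + 1):(2 * n), ] <- rep_row(c(-1, 0, 0), n)
  e3[(n + 1):(2 * n), ] <- rep_row(c(0, 0, -1), n)
  if (state == "unbound") {
    pos[(n + 1):(2 * n), 2] <- L_box / 2
  } else if (state == "partial") {
    # pairs bound_pairs..(n-1) opened by sliding their B nucleotides out +x
    for (i in bound_pairs:(n - 1)) {
      j <- 2 * n - 1 - i  # 0-based B index paired with A_i
      pos[j + 1, 1] <- pos[j + 1, 1] + 0.5 * (i - bound_pairs + 1)
    }
  }
  list(strands = strands, pairs = pairs, pos = pos, e1 = e1, e3 = e3)
}

build_hairpin <- function(loop_len, state, L_box) {
  stem <- 6L
  n <- 2L * stem + loop_len
  strands <- list(0:(n - 1))
  pairs <- cbind(0:(stem - 1), (n - 1):(n - stem))
  pos <- matrix(0, n, 3); e1 <- matrix(0, n, 3); e3 <- matrix(0, n, 3)
  # stem columns
  for (i in 0:(stem - 1)) {
    pos[i + 1, ] <- c(0, 0, RISE * i)
    e1[i + 1, ] <- c(1, 0, 0); e3[i + 1, ] <- c(0, 0, 1)
    j <- n - 1 - i
    pos[j + 1, ] <- c(LADDER_SEP, 0, RISE * i)
    e1[j + 1, ] <- c(-1, 0, 0); e3[j + 1, ] <- c(0, 0, -1)
  }
  # loop on a circular arc joining the two top backbone sites
  ztop <- RISE * (stem - 1)
  p1 <- c(-0.4, 0, ztop)            # backbone site of nucleotide stem-1
  p2 <- c(LADDER_SEP + 0.4, 0, ztop) # backbone site of nucleotide n-stem
  R <- solve_loop_radius(loop_len + 1, chord = sqrt(sum((p2 - p1)^2)))
  cen <- c((p1[1] + p2[1]) / 2, 0, ztop + sqrt(R^2 - sum((p2 - p1)^2) / 4))
  a1 <- atan2(p1[3] - cen[3], p1[1] - cen[1])
  dth <- 2 * asin(RISE / (2 * R))
  for (k in seq_len(loop_len)) {
    th <- a1 - k * dth  # long way round, over the top of the circle
    bb <- cen + c(R * cos(th), 0, R * sin(th))
    out <- c(cos(th), 0, sin(th))   # outward radial
    idx <- stem + k - 1              # 0-based nucleotide index stem..stem+loop-1
    pos[idx + 1, ] <- bb + 0.4 * out
    e1[idx + 1, ] <- out
    e3[idx + 1, ] <- c(0, 1, 0)
  }
  if (state == "unbound") {
    # open coil: backbone sites on a compact helix whose chords equal the
    # FENE rest length; all native pairs end up > 2.5 nm apart
    Rh <- 0.7; h <- 0.28
    alpha <- 2 * asin(sqrt(RISE^2 - h^2) / (2 * Rh))
    for (i in 0:(n - 1)) {
      th <- i * alpha
      out <- c(cos(th), sin(th), 0)
      bb <- c(Rh * cos(th), Rh * sin(th), h * i)
      pos[i + 1, ] <- bb + 0.4 * out
      e1[i + 1, ] <- out
      e3[i + 1, ] <- c(0, 0, 1)
    }
  }
  list(strands = strands, pairs = pairs, pos = pos, e1 = e1, e3 = e3)
}

build_displacement <- function(state, L_box) {
  toe <- 6L; bm <- 10L
  ns <- toe + bm                 # substrate 0..15
  ni <- bm                       # incumbent 16..25
  nv <- toe + bm                 # invader 26..41
  strands <- list(0:(ns - 1), ns:(ns + ni - 1), (ns + ni):(ns + ni + nv - 1))
  inv0 <- ns + ni
  # invader pairs cover the whole substrate; incumbent pairs cover the
  # branch-migration domain (substrate 6..15)
  pairs_inv <- cbind(0:(ns - 1), inv0 + (ns - 1):0)
  pairs_inc <- cbind(toe:(ns - 1), ns + (bm - 1):0)
  pairs <- rbind(pairs_inv, pairs_inc)
  subsets <- list(toehold = 1:toe, invader_all = 1:ns,
                  incumbent = ns + 1:bm, all = 1:(ns + bm))
  n <- ns + ni + nv
  pos <- matrix(0, n, 3); e1 <- matrix(0, n, 3); e3 <- matrix(0, n, 3)
  # substrate column
  for (s in 0:(ns - 1)) {
    pos[s + 1, ] <- c(0, 0, RISE * s)
    e1[s + 1, ] <- c(1, 0, 0); e3[s + 1, ] <- c(0, 0, 1)
  }
  # incumbent ladder-paired to substrate 6..15
  for (m in 0:(bm - 1)) {
    s <- ns - 1 - m
    idx <- ns + m
    pos[idx + 1, ] <- c(LADDER_SEP, 0, RISE * s)
    e1[idx + 1, ] <- c(-1, 0, 0); e3[idx + 1, ] <- c(0, 0, -1)
  }
  if (state %in% c("bound", "unbound")) {
    # invader free in solution, beyond the basin threshold
    for (j in 0:(nv - 1)) {
      s <- ns - 1 - j  # its eventual substrate partner
      pos[inv0 + j + 1, ] <- c(0.8, L_box / 2, RISE * s)
      e1[inv0 + j + 1, ] <- c(-1, 0, 0); e3[inv0 + j + 1, ] <- c(0, 0, -1)
    }
  } else { # partial: toehold fully paired, branch-migration domain dangling
    for (j in 0:(nv - 1)) {
      s <- ns - 1 - j
      idx <- inv0 + j
      if (s < toe) { # toehold partner: ladder position
        pos[idx + 1, ] <- c(LADDER_SEP, 0, RISE * s)
        e1[idx + 1, ] <- c(-1, 0, 0); e3[idx + 1, ] <- c(0, 0, -1)
      } else {       # dangle +x from the junction, bases turned aside (+y)
        bbx <- LADDER_SEP + 0.4 + RISE * (s - toe + 1)
        pos[idx + 1, ] <- c(bbx, 0.4, RISE * (toe - 1))
        e1[idx + 1, ] <- c(0, 1, 0); e3[idx + 1, ] <- c(0, 0, -1)
      }
    }
  }
  list(strands = strands, pairs = pairs, pos = pos, e1 = e1, e3 = e3,
       subsets = subsets)
}

#' Two-bead bonding toy
#'
#' Two single-nucleotide strands joined by one native pair: the smallest
#' system exhibiting association/dissociation. Used as an analytically
#' tractable oracle (its bound probability follows from one radial
#' quadrature) for sampling, reweighting, FFS and the k_off relation.
#'
#' @param state `"bound"` (pair at the hydrogen-bond optimum) or
#'   `"unbound"` (beads half a box apart).
#' @param L_box box edge (nm).
#' @param r_c crowder radius (nm) metadata.
#' @return list with `topology` and `configuration`.
#' @export
build_two_bead <- function(state = c("bound", "unbound"), L_box = 4,
                           r_c = 0.85) {
  state <- match.arg(state)
  topo <- topology(strands = list(0L, 1L), native_pairs = cbind(0L, 1L),
                   bases = c("A", "T"), subsets = list(all = 1L),
                   kind = "two_bead")
  cA <- c(L_box / 2 - 0.6, L_box / 2, L_box / 2)
  cB <- c(L_box / 2 + 0.6, L_box / 2, L_box / 2)
  if (state == "unbound") cB[2] <- cB[2] + L_box / 2
  conf <- configuration(pos = rbind(cA, cB),
                        e1 = rbind(c(1, 0, 0), c(-1, 0, 0)),
                        e3 = rbind(c(0, 0, 1), c(0, 0, -1)),
                        L_box = L_box, r_c = r_c)
  list(topology = topo, configuration = wrap_configuration(conf),
       kind = "two_bead", state = state)
}

#' Build a synthetic test system
#'
#' Constructs topology and configuration for the standard study systems: the
#' 8-mer duplex (plus a 4-mer used for miniature end-to-end studies), the
#' 6-bp-stem hairpins with 10-nt and 4-nt loops, and the strand-displacement
#' system with a 6-nt toehold and a 10-nt branch-migration domain. Bound
#' states have all native pairs formed at the hydrogen-bond optimum; unbound
#' states place the strands so that every native pair is separated beyond the
#' first forward-flux interface (and beyond the return-to-basin threshold).
#'
#' @param kind one of `"duplex8"`, `"duplex4"`, `"hairpin_loop10"`,
#'   `"hairpin_loop4"`, `"displacement"`.
#' @param state `"bound"`, `"unbound"` or `"partial"`. For the duplex,
#'   `"partial"` leaves the first `bound_pairs` pairs formed; for the
#'   displacement system, `"bound"` is the pre-displacement state (incumbent
#'   duplexed, toehold open, invader free) and `"partial"` has the toehold
#'   fully paired.
#' @param seed RNG seed (base identities and crowder packing).
#' @param phi crowder excluded volume fraction; 0 for none.
#' @param r_c crowder radius (nm).
#' @param L_box box edge (nm); a per-kind default is used when `NULL`.
#' @param bound_pairs number of formed pairs in a `"partial"` duplex.
#' @param params interaction parameters (used for crowder clearance).
#' @return a list with elements `topology` and `configuration`.
#' @examples
#' fx <- build_fixture("duplex8", "bound", seed = 1)
#' count_native_bp(fx$configuration, fx$topology)
#' @export
build_fixture <- function(kind = c("duplex8", "duplex4", "hairpin_loop10",
                                   "hairpin_loop4", "displacement"),
                          state = c("bound", "unbound", "partial"),
                          seed = 1L, phi = 0, r_c = 0.85, L_box = NULL,
                          bound_pairs = 3L, params = interaction_params()) {
  kind <- match.arg(kind)
  state <- match.arg(state)
  defaults <- c(duplex8 = 6, duplex4 = 5, hairpin_loop10 = 7,
                hairpin_loop4 = 6, displacement = 12)
  if (is.null(L_box)) L_box <- unname(defaults[kind])
  g <- switch(kind,
    duplex8 = build_duplex(8L, state, L_box, bound_pairs),
    duplex4 = build_duplex(4L, state, L_box, min(bound_pairs, 2L)),
    hairpin_loop10 = build_hairpin(10L, state, L_box),
    hairpin_loop4 = build_hairpin(4L, state, L_box),
    displacement = build_displacement(state, L_box))
  n <- nrow(g$pos)
  bases <- random_bases(n, seed)
  # complementary identities across native pairs (informational only)
  for (r in seq_len(nrow(g$pairs)))
    bases[g$pairs[r, 2] + 1] <- unname(complement(bases[g$pairs[r, 1] + 1]))
  subsets <- if (!is.null(g$subsets)) g$subsets else
    list(all = seq_len(nrow(g$pairs)))
  topo <- topology(strands = g$strands, native_pairs = g$pairs, bases = bases,
                   subsets = subsets,
                   allow_competing = identical(kind, "displacement"),
                   kind = kind)
  # centre the assembly in the box
  shift <- L_box / 2 - colMeans(g$pos)
  pos <- sweep(g$pos, 2, shift, "+")
  conf <- configuration(pos = pos, e1 = g$e1, e3 = g$e3, L_box = L_box,
                        r_c = r_c)
  conf <- wrap_configuration(conf)
  if (phi > 0) {
    conf <- add_crowders(conf, topo, phi = phi, r_c = r_c, seed = seed,
                         params = params)
  }
  validate_configuration(conf)
  list(topology = topo, configuration = conf, kind = kind, state = state)
}
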