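# Shared fixtures and an independent R-language energy oracle used to check
# the compiled evaluator. The oracle re-implements the potential from the
# documented formulas with plain vector arithmetic; it shares no code with
# the compiled path.

min_image <- function(d, L) d - L * round(d / L)

dist_pbc <- function(a, b, L) sqrt(sum(min_image(a - b, L)^2))

r_wca <- function(d, sig, eps) {
  if (d >= sig * 2^(1 / 6)) return(0)
  s6 <- (sig / d)^6
  4 * eps * (s6^2 - s6) + eps
}

r_morse <- function(d, eps, a, d0, rc) {
  if (d >= rc) return(0)
  m <- (1 - exp(-a * (d - d0)))^2 - 1
  mc <- (1 - exp(-a * (rc - d0)))^2 - 1
  eps * (m - mc) / (1 + mc)
}

r_fene <- function(d, p) {
  arg <- (d - p$fene_r0) / p$fene_dr
  if (abs(arg) >= 1) return(Inf)
  -0.5 * p$fene_k * p$fene_dr^2 * log(1 - arg^2)
}

# brute-force total energy: O(N^2) double loop over all sites and crowders
oracle_energy <- function(conf, topo, p) {
  n <- nrow(conf$pos)
  L <- conf$L
  back <- conf$pos - p$d_back * conf$e1
  base <- conf$pos + p$d_base * conf$e1
  pairs <- topo$native_pairs
  is_pair <- matrix(FALSE, n, n)
  if (nrow(pairs) > 0)
    for (r in seq_len(nrow(pairs))) {
      is_pair[pairs[r, 1] + 1, pairs[r, 2] + 1] <- TRUE
      is_pair[pairs[r, 2] + 1, pairs[r, 1] + 1] <- TRUE
    }
  e <- 0
  for (i in seq_len(n)) {
    j <- topo$nxt[i]
    if (j >= 0) {
      e <- e + r_fene(dist_pbc(back[i, ], back[j + 1, ], L), p)
      a3 <- sum(conf$e3[i, ] * conf$e3[j + 1, ])
      e <- e + r_morse(dist_pbc(base[i, ], base[j + 1, ], L),
                       p$eps_st, p$a_st, p$d0_st, p$rc_st) * a3^2
    }
  }
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1] + 1; j <- pairs[r, 2] + 1
      a3 <- -sum(conf$e3[i, ] * conf$e3[j, ])
      if (a3 > 0)
        e <- e + r_morse(dist_pbc(base[i, ], base[j, ], L),
                         p$eps_hb, p$a_hb, p$d0_hb, p$rc_hb) * a3^2
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    bonded <- (topo$nxt[i] == j - 1) || (topo$prev[i] == j - 1)
    if (!bonded) e <- e + r_wca(dist_pbc(back[i, ], back[j, ], L), p$sig_bb, p$eps_exc)
    e <- e + r_wca(dist_pbc(back[i, ], base[j, ], L), p$sig_bs, p$eps_exc)
    e <- e + r_wca(dist_pbc(base[i, ], back[j, ], L), p$sig_bs, p$eps_exc)
    if (!is_pair[i, j]) e <- e + r_wca(dist_pbc(base[i, ], base[j, ], L), p$sig_ss, p$eps_exc)
  }
  nc <- nrow(conf$cpos)
  if (nc > 0) {
    sigc <- conf$rc + p$r_site
    for (c in seq_len(nc)) {
      for (i in seq_len(n)) {
        e <- e + r_wca(dist_pbc(conf$cpos[c, ], back[i, ], L), sigc, p$eps_crowd)
        e <- e + r_wca(dist_pbc(conf$cpos[c, ], base[i, ], L), sigc, p$eps_crowd)
      }
      if (c < nc) for (c2 in (c + 1):nc)
        e <- e + r_wca(dist_pbc(conf$cpos[c, ], conf$cpos[c2, ], L),
                       2 * conf$rc, p$eps_crowd)
    }
  }
  e
}

# minimum native-pair distance by explicit enumeration of all 27 images
oracle_min_dist <- function(conf, topo, p, rows) {
  base <- conf$pos + p$d_base * conf$e1
  L <- conf$L
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * L
  dmin <- Inf
  for (r in rows) {
    i <- topo$native_pairs[r, 1] + 1; j <- topo$native_pairs[r, 2] + 1
    for (s in seq_len(nrow(shifts))) {
      d <- sqrt(sum((base[i, ] - base[j, ] - shifts[s, ])^2))
      dmin <- min(dmin, d)
    }
  }
  dmin
}

# a small random-but-valid two-strand system for property tests
random_system <- function(seed, n = 4, L = 10, n_crowders = 0, r_c = 0.85,
                          spread = 2.5) {
  set.seed(seed)
  topo <- topology(strands = list(0:(n - 1), n:(2 * n - 1)),
                   native_pairs = cbind(0:(n - 1), (2 * n - 1):n))
  pos <- matrix(NA_real_, 2 * n, 3)
  for (s in 0:1) {
    start <- c(runif(2, 2, L - 2), runif(1, 2, L - 2)) + c(s * spread, 0, 0)
    pos[s * n + 1, ] <- start
    for (k in 2:n) {
      step <- rnorm(3); step <- step / sqrt(sum(step^2)) * 0.64
      pos[s * n + k, ] <- pos[s * n + k - 1, ] + step
    }
  }
  e1 <- matrix(rnorm(6 * n), ncol = 3)
  e1 <- e1 / sqrt(rowSums(e1^2))
  ref <- matrix(rnorm(6 * n), ncol = 3)
  e3 <- ref - rowSums(ref * e1) * e1
  e3 <- e3 / sqrt(rowSums(e3^2))
  cpos <- NULL
  if (n_crowders > 0)
    cpos <- matrix(runif(3 * n_crowders, 0, L), ncol = 3)
  conf <- configuration(pos = pos %% L, e1 = e1, e3 = e3, L_box = L,
                        cpos = cpos, r_c = r_c)
  list(topology = topo, configuration = conf)
}
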