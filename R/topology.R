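#' DNA system topology
#'
#' A topology records the strand structure (ordered 0-based nucleotide
#' indices per strand), the per-nucleotide base identity (informational only
#' under the averaged-strength model) and the whitelist of native base pairs:
#' only pairs on this list are allowed to hydrogen-bond, so no mismatched or
#' alternative secondary structure can form.
#'
#' For strand-displacement systems the substrate bases in the branch
#' migration domain are native-paired to both the incumbent and the invader;
#' set `allow_competing = TRUE` for those, otherwise each nucleotide may
#' appear in at most one native pair.
#'
#' @param strands list of integer vectors, the 0-based nucleotide indices of
#'   each strand in 5'->3' order. Indices must be contiguous over the whole
#'   system, starting at 0.
#' @param native_pairs two-column integer matrix of 0-based nucleotide index
#'   pairs permitted to hydrogen-bond.
#' @param bases optional character vector of base identities (A/C/G/T).
#' @param subsets optional named list of native-pair row subsets (1-based row
#'   indices into `native_pairs`), e.g. toehold-only pairs.
#' @param allow_competing allow a nucleotide to appear in more than one
#'   native pair (strand displacement only).
#' @param kind optional system kind label.
#' @return an object of class `cg_topology`.
#' @examples
#' duo <- topology(strands = list(0:1, 2:3),
#'                 native_pairs = rbind(c(0, 3), c(1, 2)))
#' n_nucleotides(duo)
#' @export
topology <- function(strands, native_pairs, bases = NULL, subsets = NULL,
                     allow_competing = FALSE, kind = NULL) {
  stopifnot(is.list(strands), length(strands) >= 1)
  idx <- unlist(strands)
  n <- length(idx)
  if (!setequal(idx, 0:(n - 1)) || anyDuplicated(idx))
    abort("nucleotide indices must be 0-based, contiguous, and each belong to exactly one strand")
  native_pairs <- matrix(as.integer(native_pairs), ncol = 2)
  if (nrow(native_pairs) > 0) {
    if (any(native_pairs < 0) || any(native_pairs >= n))
      abort("native pair indices out of range")
    if (any(native_pairs[, 1] == native_pairs[, 2]))
      abort("a nucleotide cannot pair with itself")
    if (!allow_competing && anyDuplicated(as.vector(native_pairs)))
      abort("no nucleotide may appear in more than one native pair (use allow_competing for displacement systems)")
  }
  if (is.null(bases)) bases <- rep("N", n)
  if (length(bases) != n) abort("bases must have one entry per nucleotide")
  strand_id <- integer(n)
  prv <- nxt <- rep(-1L, n)
  for (s in seq_along(strands)) {
    ix <- strands[[s]]
    strand_id[ix + 1] <- s
    if (length(ix) > 1) {
      prv[ix[-1] + 1] <- ix[-length(ix)]
      nxt[ix[-length(ix)] + 1] <- ix[-1]
    }
  }
  structure(list(strands = strands, bases = bases,
                 native_pairs = native_pairs, strand_id = strand_id,
                 prev = prv, nxt = nxt, subsets = subsets,
                 allow_competing = allow_competing, kind = kind,
                 circular = rep(FALSE, length(strands))),
            class = "cg_topology")
}

#' Number of nucleotides in a topology
#' @param topo a `cg_topology`.
#' @return integer count.
#' @export
n_nucleotides <- function(topo) {
  stopifnot(inherits(topo, "cg_topology"))
  length(topo$bases)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology> %d nucleotides in %d strand(s), %d native pair(s)\n",
              n_nucleotides(x), length(x$strands), nrow(x$native_pairs)))
  if (!is.null(x$kind)) cat("  kind:", x$kind, "\n")
  if (!is.null(x$subsets)) cat("  subsets:", paste(names(x$subsets), collapse = ", "), "\n")
  invisible(x)
}

#' System configuration: coordinates, orientations, crowders, box
#'
#' Positions are nucleotide centres (nm); each nucleotide carries an
#' orthonormal orientation frame given by two unit vectors: `e1`, the base
#' direction (the base interaction site lies at `pos + d_base * e1`, the
#' backbone site at `pos - d_back * e1`), and `e3`, the base normal. The
#' third axis is implied by right-handedness. Crowders are points with a
#' common radius `r_c`. The box is cubic with periodic boundaries.
#'
#' @param pos n x 3 matrix of nucleotide centres (nm).
#' @param e1,e3 n x 3 matrices of unit vectors; frames must be orthonormal
#'   to within 1e-8.
#' @param L_box cubic box edge length (nm).
#' @param cpos crowder centres, m x 3 matrix (may have zero rows).
#' @param r_c crowder radius (nm).
#' @param phi,seed optional metadata recording the requested crowder volume
#'   fraction and the packing seed.
#' @return an object of class `cg_configuration`.
#' @export
configuration <- function(pos, e1, e3, L_box, cpos = NULL, r_c = 0.85,
                          phi = NULL, seed = NULL) {
  pos <- as.matrix(pos); e1 <- as.matrix(e1); e3 <- as.matrix(e3)
  if (is.null(cpos)) cpos <- matrix(numeric(0), ncol = 3)
  cpos <- as.matrix(cpos)
  conf <- structure(list(pos = pos, e1 = e1, e3 = e3, cpos = cpos,
                         L = L_box, rc = r_c, phi = phi, seed = seed),
                    class = "cg_configuration")
  validate_configuration(conf)
  conf
}

#' Validate a configuration
#'
#' Checks finiteness of all coordinates, box positivity, and orthonormality
#' of the orientation frames to within 1e-8.
#'
#' @param conf a `cg_configuration`.
#' @param tol orthonormality tolerance.
#' @return `conf`, invisibly; aborts on violation.
#' @export
validate_configuration <- function(conf, tol = 1e-8) {
  stopifnot(inherits(conf, "cg_configuration"))
  if (!all(is.finite(conf$pos)) || !all(is.finite(conf$cpos)))
    abort("all coordinates must be finite")
  if (!is.finite(conf$L) || conf$L <= 0) abort("box edge must be positive")
  if (nrow(conf$pos) > 0) {
    n1 <- rowSums(conf$e1^2); n3 <- rowSums(conf$e3^2)
    d13 <- rowSums(conf$e1 * conf$e3)
    if (max(abs(n1 - 1), abs(n3 - 1), abs(d13)) > tol)
      abort("orientation frames must be orthonormal to within 1e-8")
  }
  invisible(conf)
}

#' @export
print.cg_configuration <- function(x, ...) {
  cat(sprintf("<cg_configuration> %d nucleotide(s), %d crowder(s) (r_c = %.2f nm), box L = %.2f nm\n",
              nrow(x$pos), nrow(x$cpos), x$rc, x$L))
  invisible(x)
}

# internal: merge topology + configuration into the list consumed by the
# compiled core (0-based indices throughout)
sys_list <- function(conf, topo) {
  stopifnot(inherits(conf, "cg_configuration"), inherits(topo, "cg_topology"))
  if (nrow(conf$pos) != n_nucleotides(topo))
    abort("configuration and topology disagree on the number of nucleotides")
  list(pos = conf$pos, e1 = conf$e1, e3 = conf$e3, cpos = conf$cpos,
       L = conf$L, rc = conf$rc,
       strand = as.integer(topo$strand_id),
       prev = as.integer(topo$prev), next_ = NULL,
       "next" = as.integer(topo$nxt),
       pairs = matrix(as.integer(topo$native_pairs), ncol = 2))
}

# internal: rebuild a cg_configuration from the list returned by C++
conf_from_sys <- function(sys, template) {
  out <- template
  out$pos <- sys$pos; out$e1 <- sys$e1; out$e3 <- sys$e3; out$cpos <- sys$cpos
  out
}

#' Wrap coordinates into the primary periodic image
#'
#' @param conf a `cg_configuration`.
#' @return the configuration with all coordinates wrapped into `[0, L)`.
#' @export
wrap_configuration <- function(conf) {
  stopifnot(inherits(conf, "cg_configuration"))
  w <- function(m) m - conf$L * floor(m / conf$L)
  conf$pos <- w(conf$pos)
  if (nrow(conf$cpos) > 0) conf$cpos <- w(conf$cpos)
  conf
}
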