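# Collective variables biased by the protocol: funnel-axis projection z,
# orientation cosine, water-coordination numbers with a rational switching
# function, and torsions. These operate on n x 3 coordinate matrices; the
# toy engine biases bare coordinates directly (a point guest on a canonical
# funnel axis makes z literally the third coordinate).

#' Coordination-number parameters
#'
#' Parameters of the rational switching function and its neighbor list. The
#' shipped defaults are the protocol's printed values (r0 = 2.5 A, d_max =
#' 0.8 A, r_nl = 1.5 A, stride 20, ligand exponents n = 6, m = 10). Note the
#' printed lengths are mutually inconsistent (d_max < r0 and r_nl < d_max
#' would make the CV vanish and the neighbor list lossy); they are kept
#' verbatim but every field is overridable, and the toy tests override them
#' with self-consistent values. `validate = TRUE` errors on the inconsistency
#' instead of storing it.
#'
#' @param r0 switching characteristic distance (same length unit as the
#'   coordinates it is applied to)
#' @param d_max distance at which the switching function reaches exactly zero
#' @param r_nl neighbor-list cutoff radius
#' @param n,m rational exponents, n < m
#' @param nl_update_stride neighbor-list refresh stride in integration steps
#' @param validate error when `r_nl < d_max` (kept off: mirrors the printed
#'   protocol values)
#' @return object of class `coordination_params`
#' @export
coordination_params <- function(r0 = 0.25, d_max = 0.08, r_nl = 0.15,
                                n = 6L, m = 10L, nl_update_stride = 20L,
                                validate = FALSE) {
  stopifnot(r0 > 0, d_max > 0, n < m, n >= 1, nl_update_stride >= 1)
  if (validate && r_nl < d_max)
    stop("neighbor-list cutoff r_nl is smaller than d_max")
  structure(list(r0 = r0, d_max = d_max, r_nl = r_nl, n = as.integer(n),
                 m = as.integer(m),
                 nl_update_stride = as.integer(nl_update_stride)),
            class = "coordination_params")
}

#' Rational switching function, stretched so s(0)=1 and s(d_max)=0 exactly
#'
#' Raw form \eqn{s_0(r) = (1-(r/r_0)^n)/(1-(r/r_0)^m)} (with the n/m limit at
#' r = r0), then stretched and shifted:
#' \eqn{s(r) = (s_0(r) - s_0(d_{max}))/(s_0(0) - s_0(d_{max}))}, clamped to 0
#' beyond d_max. This is the PLUMED dialect's convention and makes the
#' statement "smoothly goes to zero at d_max" literally true.
#'
#' @param r distances (vectorized)
#' @param p a [coordination_params()]
#' @param stretch apply the stretch-and-shift (default TRUE)
#' @return switching values in [0, 1]
#' @export
switching_rational <- function(r, p, stretch = TRUE) {
  raw <- function(r) {
    t <- r / p$r0
    num <- 1 - t^p$n
    den <- 1 - t^p$m
    out <- ifelse(abs(den) < 1e-12, p$n / p$m, num / den)
    # exact limit n/m at t == 1 (L'Hopital); the ifelse guard handles it
    out
  }
  if (!stretch) return(raw(r))
  sdm <- raw(p$d_max)
  s <- (raw(r) - sdm) / (1 - sdm)
  ifelse(r >= p$d_max, 0, pmax(s, 0))
}

#' CV specification
#'
#' @param kind one of `"z_projection"`, `"cos_orientation"`,
#'   `"coordination_WL"`, `"coordination_WH"`, `"torsion"`, or
#'   `"coordinate"` (toy engine: bias a bare coordinate by index)
#' @param atom_selector integer indices (a torsion takes exactly 4)
#' @param params a [coordination_params()] where applicable
#' @param label unique label
#' @param period CV period for kernel wrapping (2*pi for torsions, 0 else)
#' @param point fixed virtual point (3-vector, nm): the WH "virtual atom in
#'   the vicinity of the host" is a configured fixed point on the funnel axis
#' @return object of class `cv_spec`
#' @export
cv_spec <- function(kind, atom_selector = integer(0), params = NULL,
                    label = kind, period = if (kind == "torsion") 2 * pi else 0,
                    point = NULL) {
  kinds <- c("z_projection", "cos_orientation", "coordination_WL",
             "coordination_WH", "torsion", "coordinate")
  kind <- match.arg(kind, kinds)
  if (kind == "torsion" && length(atom_selector) != 4)
    stop("a torsion selector must have exactly 4 atoms")
  if (kind %in% c("coordination_WL", "coordination_WH") && is.null(params))
    params <- coordination_params(
      n = if (kind == "coordination_WL") 6L else 2L,
      m = if (kind == "coordination_WL") 10L else 6L)
  structure(list(kind = kind, atom_selector = as.integer(atom_selector),
                 params = params, label = label, period = period,
                 point = if (!is.null(point)) as.numeric(point)),
            class = "cv_spec")
}

#' Funnel-axis projection of the ligand center of mass
#'
#' Signed scalar projection of the (unweighted, toy particles are unit-mass)
#' ligand center onto the funnel axis, relative to the funnel origin.
#'
#' @param coords n x 3 coordinate matrix
#' @param ligand_indices row indices of the ligand atoms (non-empty)
#' @param geom a [funnel_geometry()]
#' @return z in nm
#' @export
cv_z_projection <- function(coords, ligand_indices, geom) {
  if (length(ligand_indices) == 0) stop("empty ligand selection")
  com <- colMeans(coords[ligand_indices, , drop = FALSE])
  sum((com - geom$origin) * geom$axis)
}

#' Cosine of the ligand-axis / funnel-axis angle
#'
#' @param coords n x 3 coordinate matrix
#' @param axis_pair two distinct ligand atom indices defining the ligand axis
#' @param geom a [funnel_geometry()]
#' @return cosine in [-1, 1]
#' @export
cv_cos_orientation <- function(coords, axis_pair, geom) {
  stopifnot(length(axis_pair) == 2)
  if (axis_pair[1] == axis_pair[2]) stop("degenerate geometry: same atom twice")
  v <- coords[axis_pair[2], ] - coords[axis_pair[1], ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-10) stop("degenerate geometry: coincident atoms")
  sum(v * geom$axis) / nv
}

#' Water-coordination number around a center
#'
#' \eqn{CV = \sum_j s(r_{ij})} over solvent (water-oxygen) positions j, with
#' the stretched rational switching function [switching_rational()]. With a
#' `neighbor_list`, only listed tracers are summed; the result equals the
#' brute-force all-pairs sum whenever no particle moved more than
#' `r_nl - d_max` since the list was built.
#'
#' @param center 3-vector (a ligand atom for WL, a fixed virtual point near
#'   the host for WH)
#' @param solvent n x 3 tracer coordinates
#' @param p a [coordination_params()]
#' @param neighbor_list optional integer indices from [coord_neighbor_list()]
#' @return coordination number (>= 0, <= number of tracers)
#' @export
coordination_number <- function(center, solvent, p, neighbor_list = NULL) {
  stopifnot(inherits(p, "coordination_params"))
  if (nrow(solvent) == 0) return(0)
  if (!is.null(neighbor_list)) {
    solvent <- solvent[neighbor_list, , drop = FALSE]
    if (nrow(solvent) == 0) return(0)
  }
  d <- sqrt(rowSums(sweep(solvent, 2, center)^2))
  sum(switching_rational(d, p))
}

#' Build a coordination neighbor list
#'
#' @inheritParams coordination_number
#' @return integer indices of tracers within `p$r_nl` of `center`
#' @export
coord_neighbor_list <- function(center, solvent, p) {
  if (nrow(solvent) == 0) return(integer(0))
  d2 <- rowSums(sweep(solvent, 2, center)^2)
  which(d2 <= p$r_nl^2)
}

#' Dihedral (torsion) angle of four atoms
#'
#' Standard two-plane convention via the atan2 formula; returns radians in
#' (-pi, pi]. Flagged periodic for kernel placement.
#'
#' @param coords n x 3 coordinate matrix
#' @param four_atoms index quadruple (distinct, no three collinear)
#' @return angle in radians
#' @export
torsion_angle <- function(coords, four_atoms) {
  stopifnot(length(four_atoms) == 4)
  if (anyDuplicated(four_atoms)) stop("torsion atoms must be distinct")
  p <- coords[four_atoms, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry: collinear atom triple")
  m <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  b2n <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m * b2) / b2n  # sign: IUPAC convention (matches MDAnalysis)
  ang <- atan2(y, x)
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}
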