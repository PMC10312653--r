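# Ideal C-alpha helix geometry used to build initial structures and to
# derive the equilibrium values of the bonded terms.

#' Ideal alpha-helix builder parameters
#'
#' @param rise rise per residue along the helix axis, nm (default 0.15)
#' @param twist twist per residue, degrees (default 100)
#' @param radius C-alpha radius of the helix, nm (default 0.23)
#' @export
helix_geometry <- function(rise = 0.15, twist = 100, radius = 0.23) {
  stopifnot(rise > 0, twist > 0, radius > 0)
  list(rise = rise, twist = twist, radius = radius)
}

#' Coordinates of an ideal C-alpha helix
#'
#' Bead `i` (1-based) sits at angle `(i-1) * twist` around the z axis at
#' the helix radius, and height `(i-1) * rise`.
#'
#' @param n number of beads
#' @param helix see [helix_geometry()]
#' @return n x 3 coordinate matrix in nm, axis along z
#' @export
ideal_helix_coords <- function(n, helix = helix_geometry()) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  th <- i * helix$twist * pi / 180
  cbind(helix$radius * cos(th), helix$radius * sin(th), i * helix$rise)
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Internal coordinates of the ideal helix
#'
#' The pseudo-bond length, pseudo-angle and pseudo-torsion of four
#' consecutive beads on the ideal helix; these are the equilibrium values
#' of the default bonded terms.
#'
#' @param helix see [helix_geometry()]
#' @return named vector `c(bond, angle, torsion)` in nm / deg / deg
#' @export
helix_internal_geometry <- function(helix = helix_geometry()) {
  x <- ideal_helix_coords(4, helix)
  c(bond = sqrt(sum((x[2, ] - x[1, ])^2)),
    angle = .angle_deg(x[1, ], x[2, ], x[3, ]),
    torsion = .dihedral_deg(x[1, ], x[2, ], x[3, ], x[4, ]))
}
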