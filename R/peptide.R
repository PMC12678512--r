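# Backbone construction from internal coordinates (natural-extension
# reference frame). Used to build ideal helices for secondary-structure
# validation and the segments of the synthetic hinge protein.

# ideal backbone internal coordinates (Engh-Huber-like values)
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7
)

deg2rad <- function(x) x * pi / 180

# place atom D given positions A, B, C and internal coordinates:
# |C-D| = bond, angle(B,C,D) = angle (deg), torsion(A,B,C,D) = torsion (deg)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build a backbone peptide from phi/psi torsions
#'
#' Constructs N, CA, C, O positions for each residue from ideal bond
#' lengths and angles with the supplied backbone torsions (omega fixed at
#' 180 degrees). Carbonyl oxygens are placed in the peptide plane opposite
#' the next residue's nitrogen.
#'
#' @param phi,psi numeric vectors of backbone torsions in degrees, one per
#'   residue (`phi[1]` is unused, as is `psi[n]`).
#' @param sequence optional one-letter sequence (length must match);
#'   defaults to poly-alanine.
#' @param start_residue 1-based index of the first residue (for numbering).
#' @return list with `topology` ([topology()]) and `frame` ([frame()]).
#' @export
build_peptide <- function(phi, psi, sequence = NULL, start_residue = 1L) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1L)
  res3 <- if (is.null(sequence)) rep("ALA", n) else aa1to3(sequence)
  stopifnot(length(res3) == n)
  g <- .bb_geom
  xyz <- matrix(NA_real_, 4L * n, 3L)
  rn <- function(i, atom) (i - 1L) * 4L + match(atom, c("N", "CA", "C", "O"))
  # seed residue 1 in a canonical frame
  xyz[rn(1, "N"), ] <- c(0, 0, 0)
  xyz[rn(1, "CA"), ] <- c(g$b_n_ca, 0, 0)
  xyz[rn(1, "C"), ] <- xyz[rn(1, "CA"), ] +
    g$b_ca_c * c(-cos(deg2rad(g$a_n_ca_c)), sin(deg2rad(g$a_n_ca_c)), 0)
  if (n > 1L) for (i in 2:n) {
    xyz[rn(i, "N"), ] <- place_atom(xyz[rn(i - 1, "N"), ], xyz[rn(i - 1, "CA"), ],
                                    xyz[rn(i - 1, "C"), ],
                                    g$b_c_n, g$a_ca_c_n, psi[i - 1])
    xyz[rn(i, "CA"), ] <- place_atom(xyz[rn(i - 1, "CA"), ], xyz[rn(i - 1, "C"), ],
                                     xyz[rn(i, "N"), ],
                                     g$b_n_ca, g$a_c_n_ca, 180)
    xyz[rn(i, "C"), ] <- place_atom(xyz[rn(i - 1, "C"), ], xyz[rn(i, "N"), ],
                                    xyz[rn(i, "CA"), ],
                                    g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  # carbonyl oxygens: bisect away from CA and next N; terminal O in-plane
  for (i in seq_len(n)) {
    cpos <- xyz[rn(i, "C"), ]; capos <- xyz[rn(i, "CA"), ]
    ref <- if (i < n) xyz[rn(i + 1, "N"), ] else xyz[rn(i, "N"), ]
    u <- (cpos - capos) / sqrt(sum((cpos - capos)^2)) +
         (cpos - ref) / sqrt(sum((cpos - ref)^2))
    xyz[rn(i, "O"), ] <- cpos + g$b_c_o * u / sqrt(sum(u^2))
  }
  atoms <- data.frame(
    name = rep(c("N", "CA", "C", "O"), n),
    residue_index = rep(seq.int(start_residue, length.out = n), each = 4L),
    residue_name = rep(res3, each = 4L),
    stringsAsFactors = FALSE)
  list(topology = topology(atoms), frame = frame(xyz))
}

#' Build an ideal alpha-helical peptide
#'
#' @param n number of residues (>= 2).
#' @param phi,psi helical torsions in degrees (defaults -57/-47, ideal
#'   alpha helix).
#' @param sequence optional one-letter sequence.
#' @return list with `topology` and `frame`, as [build_peptide()].
#' @export
build_ideal_helix <- function(n, phi = -57, psi = -47, sequence = NULL) {
  build_peptide(rep(phi, n), rep(psi, n), sequence = sequence)
}
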