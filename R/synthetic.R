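# Synthetic two-flap hinge-protein generator. Emulates the statistical
# structure the analysis pipeline assumes: a saposin-like fold whose two
# flaps (helices 1+4 carrying the disulfide-tied termini, helices 2+3) sit
# at state-dependent diagnostic separations, two-state Markov switching
# between open and closed basins, isotropic Gaussian thermal noise, and
# uniform single-site solvent in a periodic cubic box. Provides exact
# ground truth (state sequence, stationary occupancy, reference
# geometries) for recovery tests of every pipeline stage.

#' Parameters of the synthetic hinge-protein model
#'
#' Defaults are the study conditions of the saposin-fold analysis: a
#' 79-residue chain with helical segments at residues 9-19, 27-33, 46-61
#' and 69-72, closed-basin diagnostic separations (15, 14) A and open-basin
#' (25, 27) A — inside the closed 12-17 A and open 20-40 A class ranges —
#' 0.5 A per-coordinate thermal noise, and symmetric per-frame switching
#' rates. The default 4000 frames at 0.25 ns spacing emulate a 1000-ns
#' production run sampled at a typical snapshot cadence.
#'
#' @param n_residues chain length (>= 12).
#' @param closed_geometry,open_geometry target (d1, d2) separations (A).
#' @param noise_sigma per-coordinate Gaussian thermal noise s.d. (A).
#' @param rate_open_to_closed,rate_closed_to_open per-frame switch
#'   probabilities in `[0, 1]`.
#' @param n_frames number of frames to simulate.
#' @param timestep frame spacing (ns).
#' @param start_state initial basin, `"closed"` or `"open"`.
#' @param seed integer seed; all generator randomness flows from it.
#' @param sequence one-letter sequence; defaults to the mature SP-B chain
#'   for 79 residues, poly-alanine otherwise.
#' @param disulfides list of cysteine residue-index pairs to tie with SG
#'   pseudo-atoms (defaults to the saposin 8-77, 11-71, 35-46 pattern when
#'   the sequence has cysteines at those positions).
#' @return list of class `hinge_params`.
#' @export
hinge_params <- function(n_residues = 79L,
                         closed_geometry = c(15, 14),
                         open_geometry = c(25, 27),
                         noise_sigma = 0.5,
                         rate_open_to_closed = 0.02,
                         rate_closed_to_open = 0.02,
                         n_frames = 4000L,
                         timestep = 0.25,
                         start_state = "closed",
                         seed = 1L,
                         sequence = NULL,
                         disulfides = NULL) {
  if (n_residues < 12L) stop("n_residues must be at least 12")
  stopifnot(rate_open_to_closed >= 0, rate_open_to_closed <= 1,
            rate_closed_to_open >= 0, rate_closed_to_open <= 1,
            noise_sigma >= 0, n_frames >= 1)
  chk <- function(g, lo, hi, what)
    if (any(g < lo) || any(g > hi))
      stop(sprintf("%s geometry must lie in the %g-%g A class range", what, lo, hi))
  chk(closed_geometry, 12, 17, "closed"); chk(open_geometry, 20, 40, "open")
  if (is.null(sequence))
    sequence <- if (n_residues == 79L) spb_mature_sequence()
                else paste(rep("A", n_residues), collapse = "")
  if (nchar(sequence) != n_residues) stop("sequence length must equal n_residues")
  if (is.null(disulfides)) {
    cys <- which(strsplit(sequence, "")[[1]] == "C")
    want <- list(c(8L, 77L), c(11L, 71L), c(35L, 46L))
    disulfides <- Filter(function(p) all(p %in% cys), want)
  }
  structure(list(n_residues = as.integer(n_residues),
                 closed_geometry = closed_geometry, open_geometry = open_geometry,
                 noise_sigma = noise_sigma,
                 rate_open_to_closed = rate_open_to_closed,
                 rate_closed_to_open = rate_closed_to_open,
                 n_frames = as.integer(n_frames), timestep = timestep,
                 start_state = match.arg(start_state, c("closed", "open")),
                 seed = as.integer(seed), sequence = sequence,
                 disulfides = disulfides),
            class = "hinge_params")
}

# proportional rescaling of the canonical 79-residue landmarks
.scale_idx <- function(i, n) pmax(1L, pmin(n, as.integer(round(i * n / 79))))

# landmark residues and segment boundaries for a chain of length n
.hinge_layout <- function(n) {
  list(helix1 = .scale_idx(c(9, 19), n), helix2 = .scale_idx(c(27, 33), n),
       helix3 = .scale_idx(c(46, 61), n), helix4 = .scale_idx(c(69, 72), n),
       flapA1_end = .scale_idx(24, n),       # helix-1 arm of the fixed flap
       flapB = .scale_idx(c(25, 62), n),     # mobile flap: helices 2+3
       anchors = list(d1 = .scale_idx(c(7, 34), n),
                      d2 = .scale_idx(c(45, 70), n),
                      d_cys = .scale_idx(c(8, 35), n)))
}

# torsions for residues first..last: helical inside any [start, end] of
# `helices`, extended elsewhere, alpha-turn values at `turn` residues
.segment_torsions <- function(first, last, helices, turn = integer(0)) {
  idx <- first:last
  phi <- rep(-140, length(idx)); psi <- rep(135, length(idx))
  for (h in helices) {
    in_h <- idx >= h[1] & idx <= h[2]
    phi[in_h] <- -57; psi[in_h] <- -47
  }
  phi[idx %in% turn] <- -60; psi[idx %in% turn] <- -30
  list(phi = phi, psi = psi)
}

# rotation taking unit vector a to unit vector b
.rot_a_to_b <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- pracma_cross(a, b); c_ <- sum(a * b)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (c_ > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- pracma_cross(a, p); v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

.rot_z <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
.rot_x <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)

# build one chain segment and rigidly place it: first CA at `origin`,
# first->last CA direction along `dir`
.place_chain <- function(first, last, helices, turn, origin, dir) {
  tor <- .segment_torsions(first, last, helices, turn)
  bp <- build_peptide(tor$phi, tor$psi, start_residue = first)
  xyz <- bp$frame$coordinates
  ca <- xyz[bp$topology$atoms$name == "CA", , drop = FALSE]
  axis <- ca[nrow(ca), ] - ca[1, ]
  R <- .rot_a_to_b(axis, dir)
  xyz <- sweep(xyz, 2, ca[1, ]) %*% t(R)
  xyz <- sweep(xyz, 2, origin, "+")
  list(topology = bp$topology, xyz = xyz)
}

# mass-weighted backbone center (N, CA, C, O) of a residue in an atom table
.res_center <- function(xyz, residx, r) {
  rows <- which(residx == r)
  w <- c(14.007, 12.011, 12.011, 15.999)[seq_along(rows)]
  colSums(xyz[rows, , drop = FALSE] * w) / sum(w)
}

#' Build the two-flap hinge protein
#'
#' Constructs a backbone-only (N, CA, C, O, plus cysteine SG pseudo-atoms)
#' model with four ideal helical segments joined by extended linkers,
#' arranged as two flaps: helices 1 and 4 (the disulfide-tied N/C-terminal
#' flap) and helices 2 and 3 (the mobile flap). The mobile flap is placed
#' by numerical optimization of a rigid transform so that the measured
#' diagnostic separations match `closed_geometry` and `open_geometry`
#' within 0.5 A; unreachable targets raise an error.
#'
#' @param params a [hinge_params()] list.
#' @return list with `topology`, `closed` ([frame()]), `open` ([frame()])
#'   and `anchors` (diagnostic residue pairs used by the layout).
#' @export
build_hinge_protein <- function(params = hinge_params()) {
  n <- params$n_residues
  lay <- .hinge_layout(n)

  # fixed flap: helix-1 arm along +x from the origin, helix-4 arm
  # antiparallel alongside it
  a1 <- .place_chain(1L, lay$flapA1_end, list(lay$helix1), integer(0),
                     c(0, 0, 0), c(1, 0, 0))
  a2_first <- lay$flapB[2] + 1L
  a2 <- .place_chain(a2_first, n, list(lay$helix4), integer(0),
                     c(28, 7, 0), c(-1, 0, 0))
  # mobile flap built in a local frame: helix-2 arm out, tight turn,
  # helix-3 arm back (hairpin)
  bfirst <- lay$flapB[1]; blast <- lay$flapB[2]
  mid <- .scale_idx(c(38, 41), n)
  b <- .place_chain(bfirst, blast, list(lay$helix2, lay$helix3), mid[1]:mid[2],
                    c(0, 0, 0), c(1, 0, 0))

  resA <- c(a1$topology$atoms$residue_index, a2$topology$atoms$residue_index)
  xyzA <- rbind(a1$xyz, a2$xyz)
  resB <- b$topology$atoms$residue_index

  anch <- lay$anchors
  pA7 <- .res_center(xyzA, resA, anch$d1[1])
  pA70 <- .res_center(xyzA, resA, anch$d2[2])

  # rigid placement of the mobile flap: rotation about z and x through the
  # flap centroid plus free translation, solved against the (d1, d2) targets
  place_b <- function(par) {
    ctr <- colMeans(b$xyz)
    R <- .rot_z(par[1]) %*% .rot_x(par[2])
    sweep(sweep(b$xyz, 2, ctr) %*% t(R), 2, ctr + par[3:5], "+")
  }
  solve_flap <- function(target) {
    obj <- function(par) {
      xb <- place_b(par)
      d1 <- sqrt(sum((pA7 - .res_center(xb, resB, anch$d1[2]))^2))
      d2 <- sqrt(sum((pA70 - .res_center(xb, resB, anch$d2[1]))^2))
      (d1 - target[1])^2 + (d2 - target[2])^2
    }
    best <- NULL
    for (s in seq_len(12)) {
      p0 <- c(stats::runif(1, -pi, pi), stats::runif(1, -pi, pi),
              stats::runif(3, -12, 12) + c(10, 10, 8 * (s %% 3 - 1)))
      fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value < 1e-6) break
    }
    if (sqrt(best$value) > 0.5)
      stop(sprintf("hinge geometry targets (%.1f, %.1f) A are unreachable (residual %.2f A)",
                   target[1], target[2], sqrt(best$value)))
    place_b(best$par)
  }
  xb_closed <- with_local_seed(params$seed, solve_flap(params$closed_geometry))
  xb_open <- with_local_seed(params$seed + 1L, solve_flap(params$open_geometry))

  # assemble atoms in residue order, adding SG pseudo-atoms at cysteines
  seq1 <- strsplit(params$sequence, "")[[1]]
  res3 <- aa1to3(params$sequence)
  all_res <- c(resA, resB)
  coords_for <- function(xb) {
    xyz_all <- rbind(xyzA, xb)
    ord <- order(all_res, seq_along(all_res))
    list(res = all_res[ord], xyz = xyz_all[ord, , drop = FALSE])
  }
  paired <- unlist(params$disulfides)
  build_conf <- function(xb) {
    cf <- coords_for(xb)
    names_v <- character(0); res_v <- integer(0); xyz_l <- list()
    base_names <- c("N", "CA", "C", "O")
    for (r in seq_len(n)) {
      rows <- which(cf$res == r)
      names_v <- c(names_v, base_names)
      res_v <- c(res_v, rep(r, 4L))
      xyz_l[[length(xyz_l) + 1L]] <- cf$xyz[rows, , drop = FALSE]
      if (seq1[r] == "C") {
        ca <- cf$xyz[rows[2], ]
        pair <- Find(function(p) r %in% p, params$disulfides)
        sg <- if (!is.null(pair)) {
          other <- setdiff(pair, r)
          rows_o <- which(cf$res == other)
          ca_o <- cf$xyz[rows_o[2], ]
          mid_ <- (ca + ca_o) / 2
          axis <- pracma_cross(ca_o - ca, c(0, 0, 1))
          if (sqrt(sum(axis^2)) < 1e-9) axis <- c(0, 1, 0)
          axis <- axis / sqrt(sum(axis^2))
          mid_ + 1.025 * axis * (if (r == min(pair)) 1 else -1)
        } else ca + c(0, 0, 1.8)
        names_v <- c(names_v, "SG"); res_v <- c(res_v, r)
        xyz_l[[length(xyz_l) + 1L]] <- matrix(sg, 1, 3)
      }
    }
    list(atoms = data.frame(name = names_v, residue_index = res_v,
                            residue_name = res3[res_v], stringsAsFactors = FALSE),
         xyz = do.call(rbind, xyz_l))
  }
  closed <- build_conf(xb_closed)
  open <- build_conf(xb_open)
  top <- topology(closed$atoms)
  list(topology = top, closed = frame(closed$xyz), open = frame(open$xyz),
       anchors = anch)
}

#' Simulate a two-state Markov hinge trajectory
#'
#' Per frame, a two-state Markov chain selects the basin (open/closed);
#' coordinates are the basin reference geometry plus independent Gaussian
#' noise of `noise_sigma` per coordinate. Fully reproducible from
#' `params$seed`; the global RNG state is left untouched.
#'
#' The analytic stationary occupancy follows the two-state balance
#' `pi_open = r_co / (r_co + r_oc)`; when both rates are zero the chain is
#' frozen in its start state.
#'
#' @param params a [hinge_params()] list.
#' @return list with `trajectory` ([trajectory()]) and `ground_truth`
#'   (list: `state_sequence`, `stationary_occupancy` named c(open, closed),
#'   `reference_geometries` list of frames, `anchors`).
#' @export
simulate_hinge_trajectory <- function(params = hinge_params()) {
  model <- build_hinge_protein(params)
  nf <- params$n_frames
  na <- n_atoms(model$topology)
  r_oc <- params$rate_open_to_closed; r_co <- params$rate_closed_to_open
  out <- with_local_seed(params$seed + 2L, {
    states <- character(nf)
    states[1] <- params$start_state
    if (nf > 1L) for (i in 2:nf) {
      u <- stats::runif(1)
      states[i] <- if (states[i - 1] == "open") {
        if (u < r_oc) "closed" else "open"
      } else {
        if (u < r_co) "open" else "closed"
      }
    }
    coords <- array(NA_real_, c(nf, na, 3))
    for (i in seq_len(nf)) {
      base <- if (states[i] == "open") model$open else model$closed
      coords[i, , ] <- base$coordinates +
        matrix(stats::rnorm(na * 3, sd = params$noise_sigma), na, 3)
    }
    list(states = states, coords = coords)
  })
  pi_open <- if (r_co + r_oc > 0) r_co / (r_co + r_oc)
             else as.numeric(params$start_state == "open")
  traj <- trajectory(model$topology, out$coords, timestep = params$timestep)
  list(trajectory = traj,
       ground_truth = list(
         state_sequence = out$states,
         stationary_occupancy = c(open = pi_open, closed = 1 - pi_open),
         reference_geometries = list(closed = model$closed, open = model$open),
         anchors = model$anchors))
}

#' Add uniform single-site solvent around a protein frame
#'
#' The protein is translated to the center of a cubic periodic box of edge
#' `box_edge`; `n_solvent` single-site solvent molecules are placed
#' uniformly at random in the box, rejecting positions closer than
#' `exclusion_radius` to any protein atom. Water-like solvent is tagged
#' `WAT` with an `O` site, chloroform-like `CL3` with a `C1` site.
#'
#' @param frame a protein [frame()].
#' @param topology matching [topology()].
#' @param box_edge cubic box edge length (A).
#' @param n_solvent number of solvent molecules.
#' @param exclusion_radius minimum site-protein distance (A).
#' @param solvent_kind `"water"` or `"chloroform"`.
#' @param seed integer seed.
#' @param max_tries rejection-sampling attempt budget per molecule.
#' @return list with `frame` (protein + solvent, periodic box set) and
#'   `topology` (solvent residues appended).
#' @export
add_uniform_solvent <- function(frame, topology, box_edge, n_solvent,
                                exclusion_radius = 2.5,
                                solvent_kind = c("water", "chloroform"),
                                seed = 1L, max_tries = 200L) {
  solvent_kind <- match.arg(solvent_kind)
  stopifnot(box_edge > 0, n_solvent >= 0, exclusion_radius >= 0)
  prot <- frame$coordinates
  shift <- rep(box_edge / 2, 3) - colMeans(prot)
  prot <- sweep(prot, 2, shift, "+")
  if (n_solvent == 0)
    return(list(frame = frame(prot, box = rep(box_edge, 3)), topology = topology))
  sites <- with_local_seed(seed, {
    acc <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(acc) < n_solvent) {
      if (tries >= max_tries) stop("solvent placement unsatisfiable: free volume too small")
      m <- matrix(stats::runif(3 * n_solvent * 2, 0, box_edge), ncol = 3)
      if (exclusion_radius > 0) {
        keep <- vapply(seq_len(nrow(m)), function(i) {
          min(sqrt(rowSums(sweep(prot, 2, m[i, ])^2))) >= exclusion_radius
        }, logical(1))
        m <- m[keep, , drop = FALSE]
      }
      acc <- rbind(acc, m)
      tries <- tries + 1L
    }
    acc[seq_len(n_solvent), , drop = FALSE]
  })
  resname <- if (solvent_kind == "water") "WAT" else "CL3"
  aname <- if (solvent_kind == "water") "O" else "C1"
  r0 <- max(topology$atoms$residue_index)
  atoms <- rbind(topology$atoms[, c("name", "residue_index", "residue_name")],
                 data.frame(name = aname, residue_index = r0 + seq_len(n_solvent),
                            residue_name = resname, stringsAsFactors = FALSE))
  list(frame = frame(rbind(prot, sites), box = rep(box_edge, 3)),
       topology = topology(atoms, chain_id = topology$chain_id))
}

#' Solvate every frame of a trajectory with fresh uniform solvent
#'
#' Convenience wrapper around [add_uniform_solvent()] drawing independent
#' solvent positions per frame (seed advanced by frame index), e.g. to
#' emulate an equilibrated uniform solvent for radial-distribution tests.
#'
#' @inheritParams add_uniform_solvent
#' @param traj a protein [trajectory()].
#' @return a [trajectory()] with solvent appended and a periodic box.
#' @export
solvate_trajectory <- function(traj, box_edge, n_solvent, exclusion_radius = 2.5,
                               solvent_kind = "water", seed = 1L) {
  nf <- n_frames(traj)
  frames <- vector("list", nf)
  top <- NULL
  for (i in seq_len(nf)) {
    s <- add_uniform_solvent(get_frame(traj, i), traj$topology, box_edge,
                             n_solvent, exclusion_radius, solvent_kind,
                             seed = seed + i - 1L)
    frames[[i]] <- s$frame
    top <- s$topology
  }
  trajectory(top, frames, timestep = traj$timestep)
}
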