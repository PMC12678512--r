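# Rigid-body superposition (Kabsch) and the fluctuation statistics built
# on it: RMSD time series, iterative average structures, mass-weighted
# per-residue RMSF and high-flexibility region detection.

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' mass-weighted) RMSD between two paired coordinate sets. Reflections are
#' excluded by forcing the rotation determinant to +1.
#'
#' @param mobile,reference numeric n x 3 matrices, paired atoms.
#' @param weights optional per-atom weights (e.g. masses); uniform when `NULL`.
#' @return object of class `superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (length 3) and `rmsd` (A). The transform maps
#'   mobile coordinates onto the reference: `x %*% t(R) + t`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("mobile and reference must have equal atom counts")
  if (n < 3L) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) stop("invalid weights")
  w <- weights / sum(weights)
  mc <- colSums(mobile * w); rc <- colSums(reference * w)
  P <- sweep(mobile, 2, mc); Q <- sweep(reference, 2, rc)
  if (qr(P)$rank < 2L || qr(Q)$rank < 2L)
    stop("degenerate geometry: points are collinear")
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = as.numeric(rc - R %*% mc),
                 rmsd = rmsd), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param sp a `superposition`.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

# resolve an atom-name selection against a topology, erroring when empty
.resolve_selection <- function(top, selection) {
  idx <- select_atoms(top, names = selection)
  if (length(idx) == 0L)
    stop("selection matches no atoms: ", paste(selection, collapse = ", "))
  idx
}

#' RMSD time series against a reference frame
#'
#' Each frame is independently superposed onto the reference over the
#' selected atoms (default peptide backbone N, CA, C) and its minimized
#' mass-weighted RMSD reported.
#'
#' @param traj a [trajectory()].
#' @param reference a [frame()] with the same atom layout (e.g. the
#'   minimized starting structure).
#' @param selection character vector of atom names.
#' @return numeric vector, one RMSD (A) per frame.
#' @export
rmsd_series <- function(traj, reference, selection = c("N", "CA", "C")) {
  idx <- .resolve_selection(traj$topology, selection)
  w <- traj$topology$atoms$mass[idx]
  ref <- reference$coordinates[idx, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(i) {
    kabsch_superpose(traj$coords[i, idx, , drop = TRUE], ref, weights = w)$rmsd
  }, numeric(1))
}

#' Iterative average structure of a trajectory
#'
#' Repeatedly aligns every frame to the current average over the selected
#' atoms and recomputes the mean of all atoms, until the average moves less
#' than `tol` (RMS over atoms) or `max_iter` is reached.
#'
#' @param traj a [trajectory()].
#' @param selection atom names used for the alignment.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance in A.
#' @return a [frame()] holding the converged average coordinates.
#' @export
average_structure <- function(traj, selection = c("N", "CA", "C"),
                              max_iter = 10L, tol = 1e-4) {
  idx <- .resolve_selection(traj$topology, selection)
  w <- traj$topology$atoms$mass[idx]
  nf <- n_frames(traj)
  avg <- traj$coords[1, , , drop = TRUE]
  if (nf == 1L) return(frame(avg))
  for (iter in seq_len(max_iter)) {
    acc <- matrix(0, nrow(avg), 3L)
    for (i in seq_len(nf)) {
      sp <- kabsch_superpose(traj$coords[i, idx, , drop = TRUE],
                             avg[idx, , drop = FALSE], weights = w)
      acc <- acc + apply_superposition(traj$coords[i, , , drop = TRUE], sp)
    }
    newavg <- acc / nf
    shift <- sqrt(mean(rowSums((newavg - avg)^2)))
    avg <- newavg
    if (shift < tol) break
  }
  frame(avg)
}

#' Align all frames of a trajectory to a reference frame
#'
#' @param traj a [trajectory()].
#' @param reference a [frame()]; defaults to the iterative average.
#' @param selection atom names for the fit.
#' @return a [trajectory()] with every frame superposed.
#' @export
align_trajectory <- function(traj, reference = NULL, selection = c("N", "CA", "C")) {
  if (is.null(reference)) reference <- average_structure(traj, selection)
  idx <- .resolve_selection(traj$topology, selection)
  w <- traj$topology$atoms$mass[idx]
  ref <- reference$coordinates[idx, , drop = FALSE]
  out <- traj$coords
  for (i in seq_len(n_frames(traj))) {
    sp <- kabsch_superpose(traj$coords[i, idx, , drop = TRUE], ref, weights = w)
    out[i, , ] <- apply_superposition(traj$coords[i, , , drop = TRUE], sp)
  }
  trajectory(traj$topology, out, box = traj$box, timestep = traj$timestep)
}

#' Mass-weighted per-residue RMSF profile
#'
#' By default the trajectory is first aligned to the supplied (or computed)
#' average structure over the selected atoms — the two-pass scheme: average,
#' align to average, then fluctuations about the per-atom mean. For each
#' residue, RMSF is the mass-weighted RMS of atomic deviations from the
#' per-atom time averages over that residue's selected atoms.
#'
#' @param traj a [trajectory()].
#' @param average optional [frame()] to align to; computed when `NULL`.
#' @param selection atom names entering the profile (default backbone).
#' @param align logical; disable to measure raw fluctuations (useful for
#'   closed-form noise checks, where i.i.d. noise of s.d. sigma per
#'   coordinate gives RMSF = sigma * sqrt(3)).
#' @return object of class `flexibility_profile`: list with `residue`
#'   (indices), `rmsf` (A, `NA` where a residue has no selected atoms, with
#'   those residues listed in `missing_residues`), `mean`, `sd`,
#'   `threshold` (= mean + sd) and `peak_regions` (data.frame start/end).
#' @export
rmsf_per_residue <- function(traj, average = NULL, selection = c("N", "CA", "C"),
                             align = TRUE) {
  top <- traj$topology
  idx <- .resolve_selection(top, selection)
  if (align) {
    if (is.null(average)) average <- average_structure(traj, selection)
    traj <- align_trajectory(traj, average, selection)
  }
  prot_res <- top$residues$index[!(top$residues$name %in% c(.solvent_resnames, .ion_resnames))]
  mean_xyz <- apply(traj$coords[, idx, , drop = FALSE], c(2, 3), mean)
  # per-atom mean squared fluctuation
  dev2 <- rep(0, length(idx))
  for (i in seq_len(n_frames(traj)))
    dev2 <- dev2 + rowSums((traj$coords[i, idx, , drop = TRUE] - mean_xyz)^2)
  dev2 <- dev2 / n_frames(traj)
  m <- top$atoms$mass[idx]
  resi <- top$atoms$residue_index[idx]
  rmsf <- vapply(prot_res, function(r) {
    a <- resi == r
    if (!any(a)) return(NA_real_)
    sqrt(sum(m[a] * dev2[a]) / sum(m[a]))
  }, numeric(1))
  prof <- structure(list(residue = prot_res, rmsf = rmsf,
                         mean = mean(rmsf, na.rm = TRUE),
                         sd = stats::sd(rmsf, na.rm = TRUE),
                         missing_residues = prot_res[is.na(rmsf)]),
                    class = "flexibility_profile")
  prof$threshold <- prof$mean + prof$sd
  prof$peak_regions <- find_flexible_regions(prof)
  prof
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat(sprintf("<flexibility_profile> %d residues, mean %.2f A, sd %.2f A, threshold %.2f A\n",
              length(x$residue), x$mean, x$sd, x$threshold))
  if (nrow(x$peak_regions))
    cat("  peaks:", paste(sprintf("%d-%d", x$peak_regions$start, x$peak_regions$end),
                          collapse = ", "), "\n")
  invisible(x)
}

#' High-flexibility regions of an RMSF profile
#'
#' Maximal contiguous runs of residues whose RMSF strictly exceeds the
#' profile threshold (mean + one standard deviation); no gap tolerance.
#'
#' @param profile a `flexibility_profile`.
#' @return data.frame with columns `start`, `end` (residue indices).
#' @export
find_flexible_regions <- function(profile) {
  above <- !is.na(profile$rmsf) & profile$rmsf > profile$threshold
  if (!any(above)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = profile$residue[starts[keep]],
             end = profile$residue[ends[keep]])
}
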