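# Kabsch-Sander (DSSP) secondary-structure assignment from backbone
# hydrogen-bond patterns, helical binarization, and replicate-averaged
# helicity occupancy maps.
#
# The electrostatic H-bond model: E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH
# - 1/rCN) kcal/mol, bond declared when E < -0.5 kcal/mol. Amide hydrogens
# absent from the file are reconstructed 1.0 A from N along the preceding
# residue's O->C bond direction (trans peptide geometry), the convention of
# reference DSSP implementations.

.HBOND_CUTOFF <- -0.5   # kcal/mol
.CHAIN_BREAK <- 4.5     # A, CA-CA distance splitting the chain
.ENERGY_CLAMP <- -9.9   # kcal/mol, overlapping-atom clamp (r < 0.5 A)

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' @param n_pos,h_pos donor backbone N and amide H positions (length-3).
#' @param c_pos,o_pos acceptor backbone C and carbonyl O positions.
#' @return energy in kcal/mol, with attribute `flagged = TRUE` when any
#'   interatomic distance is below 0.5 A (energy clamped to -9.9).
#' @export
backbone_hbond_energy <- function(n_pos, h_pos, c_pos, o_pos) {
  stopifnot(all(is.finite(c(n_pos, h_pos, c_pos, o_pos))))
  d <- function(a, b) sqrt(sum((a - b)^2))
  r_on <- d(o_pos, n_pos); r_ch <- d(c_pos, h_pos)
  r_oh <- d(o_pos, h_pos); r_cn <- d(c_pos, n_pos)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5)
    return(structure(.ENERGY_CLAMP, flagged = TRUE))
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# per-residue backbone atom row indices, computed once per topology
.backbone_index <- function(topology) {
  at <- topology$atoms
  prot <- !(at$residue_name %in% c(.solvent_resnames, .ion_resnames))
  res <- sort(unique(at$residue_index[prot]))
  idx <- function(nm) vapply(res, function(r) {
    i <- which(at$residue_index == r & at$name %in% nm)[1]
    if (is.na(i)) NA_integer_ else i
  }, integer(1))
  list(residue = res,
       resname = at$residue_name[match(res, at$residue_index)],
       N = idx("N"), CA = idx("CA"), C = idx("C"), O = idx("O"),
       H = idx(c("H", "HN", "H1")))
}

# backbone table for one frame: per protein residue the N/CA/C/O/H positions
.backbone_table <- function(frame, topology, bbidx = NULL) {
  if (is.null(bbidx)) bbidx <- .backbone_index(topology)
  pick <- function(i) if (is.na(i)) NULL else frame$coordinates[i, ]
  lapply(seq_along(bbidx$residue), function(k) {
    list(residue = bbidx$residue[k], resname = bbidx$resname[k],
         N = pick(bbidx$N[k]), CA = pick(bbidx$CA[k]), C = pick(bbidx$C[k]),
         O = pick(bbidx$O[k]), H = pick(bbidx$H[k]))
  })
}

#' Assign per-residue secondary structure (DSSP classes)
#'
#' Implements the Kabsch-Sander assignment from backbone H-bond patterns:
#' n-turns (n = 3, 4, 5) yield 3-10/alpha/pi helices (G/H/I, two
#' consecutive turns required), bridge patterns yield strand/bridge (E/B),
#' remaining turns yield T and backbone bends (CA pseudo-angle > 70 deg)
#' yield S. Per-residue priority on overlap: H, B/E, G, I, T, S. Chains are
#' split where consecutive CA atoms are further than 4.5 A apart or
#' backbone atoms are missing; proline and chain-start residues donate no
#' H-bond.
#'
#' @param frame a [frame()].
#' @param topology matching [topology()].
#' @param bbidx precomputed backbone index (internal; computed when `NULL`).
#' @return character vector of classes from `{H,G,I,E,B,T,S,-}`, one per
#'   protein residue, named by residue index.
#' @export
assign_secstruct <- function(frame, topology, bbidx = NULL) {
  bb <- .backbone_table(frame, topology, bbidx)
  n <- length(bb)
  labels <- rep("-", n)
  names(labels) <- vapply(bb, function(x) as.character(x$residue), character(1))
  if (n < 3L) return(labels)
  complete <- vapply(bb, function(x)
    !is.null(x$N) && !is.null(x$CA) && !is.null(x$C) && !is.null(x$O), logical(1))

  # chain breaks: missing backbone or CA-CA > 4.5 A
  break_after <- logical(n)
  for (i in seq_len(n - 1L)) {
    if (!complete[i] || !complete[i + 1L]) { break_after[i] <- TRUE; next }
    if (sqrt(sum((bb[[i + 1L]]$CA - bb[[i]]$CA)^2)) > .CHAIN_BREAK)
      break_after[i] <- TRUE
  }
  seg_start <- c(TRUE, break_after[-n])

  # donor H positions (explicit, else reconstructed); none for PRO or
  # chain starts (no preceding carbonyl). Reconstruction follows the
  # original Kabsch-Sander convention: H sits 1.0 A from N along the
  # preceding residue's O -> C bond direction (trans peptide geometry).
  Hpos <- vector("list", n)
  for (i in seq_len(n)) {
    if (!complete[i] || bb[[i]]$resname == "PRO" || seg_start[i]) next
    if (!is.null(bb[[i]]$H)) { Hpos[[i]] <- bb[[i]]$H; next }
    u <- bb[[i - 1L]]$C - bb[[i - 1L]]$O
    Hpos[[i]] <- bb[[i]]$N + u / sqrt(sum(u^2))
  }

  # H-bond matrix: hb[i, j] <=> C=O(i) accepts from N-H(j); vectorized
  # Kabsch-Sander energies over all acceptor/donor pairs within 9 A CA-CA
  getm <- function(key) t(vapply(bb, function(x)
    if (is.null(x[[key]])) rep(NA_real_, 3) else x[[key]], numeric(3)))
  Cm <- getm("C"); Om <- getm("O"); Nm <- getm("N"); CAm <- getm("CA")
  Hm <- t(vapply(Hpos, function(h) if (is.null(h)) rep(NA_real_, 3) else h,
                 numeric(3)))
  pdist <- function(A, B) {
    d2 <- outer(rowSums(A^2), rep(1, n)) + outer(rep(1, n), rowSums(B^2)) -
      2 * A %*% t(B)
    sqrt(pmax(d2, 0))
  }
  r_on <- pdist(Om, Nm); r_ch <- pdist(Cm, Hm)
  r_oh <- pdist(Om, Hm); r_cn <- pdist(Cm, Nm)
  E <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  E[pmin(r_on, r_ch, r_oh, r_cn) < 0.5] <- .ENERGY_CLAMP
  hb <- !is.na(E) & E < .HBOND_CUTOFF & pdist(CAm, CAm) <= 9
  diag(hb) <- FALSE

  contiguous <- function(i, j) i >= 1 && j <= n && (i >= j || !any(break_after[i:(j - 1L)]))
  turn <- function(nlen) {
    t <- logical(n)
    if (n > nlen) for (i in seq_len(n - nlen))
      t[i] <- hb[i, i + nlen] && contiguous(i, i + nlen)
    t
  }
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)

  cand <- list(H = logical(n), G = logical(n), I = logical(n),
               E = logical(n), B = logical(n), T = logical(n), S = logical(n))
  mark_helix <- function(tn, nlen, key) {
    if (n - nlen < 2L) return(invisible())
    for (i in 2:(n - nlen))
      if (tn[i - 1L] && tn[i]) cand[[key]][i:(i + nlen - 1L)] <<- TRUE
  }
  mark_helix(t4, 4L, "H"); mark_helix(t3, 3L, "G"); mark_helix(t5, 5L, "I")

  # bridges: parallel / antiparallel Kabsch-Sander patterns, |i-j| >= 3
  HB <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  bridges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 3L) next
    par <- (HB(i - 1L, j) && HB(j, i + 1L)) || (HB(j - 1L, i) && HB(i, j + 1L))
    anti <- (HB(i, j) && HB(j, i)) || (HB(i - 1L, j + 1L) && HB(j - 1L, i + 1L))
    if (par || anti)
      bridges[[length(bridges) + 1L]] <- c(i, j, if (par) 1L else -1L)
  }
  if (length(bridges)) {
    bm <- do.call(rbind, bridges)
    cand$B[bm[, 1]] <- TRUE; cand$B[bm[, 2]] <- TRUE
    # ladder: same-type bridges at consecutive i, with j advancing +1
    # (parallel) or -1 (antiparallel)
    for (k in seq_len(nrow(bm))) {
      ext <- bm[, 1] == bm[k, 1] + 1L & bm[, 3] == bm[k, 3] &
        bm[, 2] == bm[k, 2] + bm[k, 3]
      if (any(ext)) {
        w <- which(ext)[1]
        cand$E[c(bm[k, 1], bm[w, 1], bm[k, 2], bm[w, 2])] <- TRUE
      }
    }
  }

  # turns (T): interior residues of any isolated n-turn
  for (nlen in c(3L, 4L, 5L)) {
    tn <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(nlen)]]
    for (i in which(tn)) cand$T[(i + 1L):(i + nlen - 1L)] <- TRUE
  }

  # bends (S): CA pseudo-angle > 70 degrees (computed wherever the five
  # CA positions exist, as the reference implementation does)
  if (n >= 5L) for (i in 3:(n - 2L)) {
    if (!complete[i - 2L] || !complete[i] || !complete[i + 2L]) next
    u <- bb[[i]]$CA - bb[[i - 2L]]$CA; v <- bb[[i + 2L]]$CA - bb[[i]]$CA
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    if (acos(pmin(1, pmax(-1, cosang))) * 180 / pi > 70) cand$S[i] <- TRUE
  }

  for (i in seq_len(n)) {
    labels[i] <- if (cand$H[i]) "H" else if (cand$E[i]) "E" else if (cand$B[i]) "B"
      else if (cand$G[i]) "G" else if (cand$I[i]) "I" else if (cand$T[i]) "T"
      else if (cand$S[i]) "S" else "-"
  }
  labels
}

#' Secondary structure over all frames of a trajectory
#'
#' @param traj a [trajectory()].
#' @return character matrix, frames x residues, of DSSP classes.
#' @export
secstruct_series <- function(traj) {
  bbidx <- .backbone_index(traj$topology)
  first <- assign_secstruct(get_frame(traj, 1L), traj$topology, bbidx)
  out <- matrix("-", n_frames(traj), length(first),
                dimnames = list(NULL, names(first)))
  out[1, ] <- first
  if (n_frames(traj) > 1L) for (i in 2:n_frames(traj))
    out[i, ] <- assign_secstruct(get_frame(traj, i), traj$topology, bbidx)
  out
}

#' Binarize DSSP classes into helical / non-helical
#'
#' Helical means pi, alpha or 3-10 helix: classes `H`, `G`, `I`.
#'
#' @param classes character vector or matrix of DSSP classes.
#' @return logical object of the same shape.
#' @export
is_helical <- function(classes) {
  out <- classes %in% c("H", "G", "I")
  if (!is.null(dim(classes))) dim(out) <- dim(classes)
  out
}

#' Replicate-averaged helicity occupancy map
#'
#' Replicate trajectories of unequal length are mapped onto a common
#' fraction-of-trajectory axis with `time_bins` bins; occupancy is the
#' fraction of (replicate, frame) samples in each bin that are helical at
#' each residue. 1 = always helical across replicates (rendered white),
#' 0 = never (black), intermediate = gray.
#'
#' @param maps list of frames x residues logical (helical) matrices, one
#'   per replicate; residue dimension must agree.
#' @param time_bins number of time bins (default 100).
#' @return numeric matrix `time_bins x residues` in `[0, 1]`.
#' @export
helicity_occupancy <- function(maps, time_bins = 100L) {
  if (!is.list(maps)) maps <- list(maps)
  nres <- unique(vapply(maps, ncol, integer(1)))
  if (length(nres) != 1L) stop("replicate maps have mismatched residue counts")
  time_bins <- as.integer(time_bins)
  num <- matrix(0, time_bins, nres)
  den <- matrix(0, time_bins, nres)
  for (m in maps) {
    nf <- nrow(m)
    bin <- pmin(time_bins, ceiling(seq_len(nf) / nf * time_bins))
    for (b in unique(bin)) {
      rows <- bin == b
      num[b, ] <- num[b, ] + colSums(m[rows, , drop = FALSE])
      den[b, ] <- den[b, ] + sum(rows)
    }
  }
  occ <- num / den
  colnames(occ) <- colnames(maps[[1]])
  occ
}
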