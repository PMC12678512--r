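# Multi-model PDB and plain coordinate-table I/O, plus the sequence-level
# bookkeeping used in system preparation (charge census, neutralizing ions,
# disulfide topology, centers of mass).
#
# PDB parsing and writing are delegated to bio3d; this module adds the
# multi-model consistency checks, periodic-box (CRYST1) handling and the
# Trajectory container contract.

#' Read a multi-model PDB file as a Trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without MODEL
#' records yields a single-frame trajectory. The topology is taken from the
#' first model and every model must contain the same number of atoms in the
#' same order. An orthorhombic periodic box is picked up from a `CRYST1`
#' record when present. Solvent residues (WAT/HOH/CL3/CHL) and ions are
#' retained and flagged by residue name.
#'
#' @param path path to a PDB file.
#' @param timestep time between models in ns (default 1).
#' @return a [trajectory()].
#' @export
read_pdb_models <- function(path, timestep = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # per-model atom-count consistency check
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    model_id <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_id, nbins = length(model_starts))
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop(sprintf(
        "inconsistent atom count across models in %s: model %d has %d atoms, expected %d",
        path, bad, counts[bad], counts[1]))
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  known <- c(names(.standard_aa3), .solvent_resnames, .ion_resnames)
  unknown <- setdiff(unique(toupper(at$resid)), known)
  if (length(unknown))
    warning("unknown residue code(s): ", paste(unknown, collapse = ", "),
            "; atoms retained with inferred elements")

  # bio3d leaves resno as-is; build monotone residue indices in file order
  res_key <- paste(at$chain, at$resno, at$insert)
  ridx <- match(res_key, unique(res_key))
  atoms <- data.frame(name = at$elety, residue_index = ridx,
                      residue_name = toupper(at$resid), stringsAsFactors = FALSE)
  top <- topology(atoms, chain_id = at$chain[1])

  nf <- nrow(pdb$xyz)
  coords <- array(NA_real_, c(nf, nrow(at), 3))
  for (i in seq_len(nf))
    coords[i, , ] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)

  box <- NULL
  cry <- lines[rec == "CRYST1"]
  if (length(cry)) {
    edges <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                          substr(cry[1], 25, 33)))
    if (!anyNA(edges) && all(edges > 0) && !all(edges == 1)) box <- edges
  }
  trajectory(top, coords, box = box, timestep = timestep)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Coordinates are written at the PDB format's 3-decimal precision; a
#' `CRYST1` record is emitted when the trajectory carries a periodic box.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(traj, path) {
  top <- traj$topology
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nf, 3 * n_atoms(top))
  for (i in seq_len(nf))
    xyz[i, ] <- as.vector(t(traj$coords[i, , , drop = TRUE]))
  het <- top$atoms$residue_name %in% c(.solvent_resnames, .ion_resnames)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$atoms$residue_index,
                   resid = top$atoms$residue_name,
                   eleno = seq_len(n_atoms(top)),
                   elety = top$atoms$name,
                   chain = top$chain_id,
                   type = ifelse(het, "HETATM", "ATOM"))
  if (!is.null(traj$box)) {
    b <- traj$box[1, ]
    if (!anyNA(b)) {
      cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1], b[2], b[3], 90, 90, 90)
      old <- readLines(path, warn = FALSE)
      writeLines(c(cryst, old), path)
    }
  }
  invisible(path)
}

#' Read a whitespace-delimited per-frame coordinate table
#'
#' Format: columns `frame atom x y z` (1-based indices, Angstrom), one row
#' per atom per frame, optionally preceded by comment lines `# box a b c`
#' and `# timestep dt`. Intended for long synthetic trajectories where PDB
#' is wasteful.
#'
#' @param path file path.
#' @param topology the [topology()] describing each frame's atoms.
#' @return a [trajectory()].
#' @export
read_coord_table <- function(path, topology) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 10L, warn = FALSE)
  hdr <- hdr[startsWith(hdr, "#")]
  box <- NULL; timestep <- 1
  for (h in hdr) {
    tok <- strsplit(trimws(sub("^#", "", h)), "\\s+")[[1]]
    if (tok[1] == "box") box <- as.numeric(tok[2:4])
    if (tok[1] == "timestep") timestep <- as.numeric(tok[2])
  }
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("frame", "atom", "x", "y", "z"))
  nf <- max(tab$frame); na <- n_atoms(topology)
  if (nrow(tab) != nf * na)
    stop(sprintf("coordinate table has %d rows; expected %d frames x %d atoms",
                 nrow(tab), nf, na))
  ord <- order(tab$frame, tab$atom)
  coords <- array(NA_real_, c(nf, na, 3))
  coords[cbind(tab$frame[ord], tab$atom[ord], 1L)] <- tab$x[ord]
  coords[cbind(tab$frame[ord], tab$atom[ord], 2L)] <- tab$y[ord]
  coords[cbind(tab$frame[ord], tab$atom[ord], 3L)] <- tab$z[ord]
  trajectory(topology, coords, box = box, timestep = timestep)
}

#' Write a trajectory as a plain coordinate table
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coord_table <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(traj$box) && !anyNA(traj$box[1, ]))
    writeLines(sprintf("# box %.6f %.6f %.6f", traj$box[1, 1], traj$box[1, 2],
                       traj$box[1, 3]), con)
  writeLines(sprintf("# timestep %g", traj$timestep), con)
  na <- dim(traj$coords)[2]
  for (i in seq_len(n_frames(traj))) {
    m <- traj$coords[i, , , drop = TRUE]
    writeLines(sprintf("%d %d %.6f %.6f %.6f", i, seq_len(na),
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Extract the one-letter protein sequence from a topology
#'
#' Solvent and ion residues are excluded; nonstandard residue codes become
#' `"X"`.
#'
#' @param topology a [topology()].
#' @return a single string, one letter per protein residue.
#' @export
extract_sequence <- function(topology) {
  res <- topology$residues
  res <- res[!(res$name %in% c(.solvent_resnames, .ion_resnames)), ]
  if (nrow(res) == 0L) stop("topology contains no protein residues")
  paste(aa3to1(res$name), collapse = "")
}

#' Charged-residue census at physiological pH
#'
#' Counts charged side chains at pH 7.4: Arg and Lys positive, Asp and Glu
#' negative, His neutral. With `include_termini`, the free N-terminus (+1)
#' and C-terminus (-1) are added to the net charge; for a free peptide they
#' cancel.
#'
#' @param sequence one-letter sequence string.
#' @param include_termini logical; add the terminal +1/-1 contributions.
#' @return object of class `charge_summary` with `n_positive`, `n_negative`,
#'   `net_charge`.
#' @export
count_charged_residues <- function(sequence, include_termini = TRUE) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  s <- strsplit(toupper(sequence), "")[[1]]
  npos <- sum(s %in% c("R", "K"))
  nneg <- sum(s %in% c("D", "E"))
  # free termini contribute +1 (N) and -1 (C): they cancel in the net
  term <- 0L
  structure(list(n_positive = npos, n_negative = nneg,
                 net_charge = npos - nneg + term,
                 include_termini = include_termini),
            class = "charge_summary")
}

#' @export
print.charge_summary <- function(x, ...) {
  cat(sprintf("<charge_summary> +%d / -%d, net %+d (pH 7.4; His neutral)\n",
              x$n_positive, x$n_negative, x$net_charge))
  invisible(x)
}

#' Counterions required to neutralize a net charge
#'
#' @param summary a `charge_summary` (or a bare integer net charge).
#' @return list with `species` (`"anion"`, `"cation"` or `"none"`) and
#'   `count` = |net charge|.
#' @export
neutralizing_ion_count <- function(summary) {
  net <- if (inherits(summary, "charge_summary")) summary$net_charge else as.integer(summary)
  list(species = if (net > 0) "anion" else if (net < 0) "cation" else "none",
       count = abs(net))
}

#' Detect disulfide bonds from cysteine sulfur geometry
#'
#' All CYS (or CYX) SG-SG pairs closer than `cutoff` are matched greedily,
#' nearest pair first, each sulfur used at most once. A typical S-S bond is
#' 2.05 A; the default cutoff of 2.5 A separates bonded from merely
#' adjacent sulfurs.
#'
#' @param frame a [frame()].
#' @param topology matching [topology()].
#' @param cutoff SG-SG distance cutoff in Angstrom.
#' @return integer matrix with columns `res_a`, `res_b` (lower index first),
#'   one row per bond, ordered by `res_a`; zero rows when none found.
#' @export
detect_disulfides <- function(frame, topology, cutoff = 2.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- topology$atoms
  cys_res <- topology$residues$index[topology$residues$name %in% c("CYS", "CYX", "CYM")]
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("res_a", "res_b")))
  if (length(cys_res) == 0L) return(empty)
  sg <- which(at$name == "SG" & at$residue_index %in% cys_res)
  missing <- setdiff(cys_res, at$residue_index[sg])
  if (length(missing))
    warning("CYS residue(s) without SG atom skipped: ",
            paste(missing, collapse = ", "))
  if (length(sg) < 2L) return(empty)
  xyz <- frame$coordinates[sg, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  pairs <- list()
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[m[1], m[2]] >= cutoff) break
    ra <- at$residue_index[sg[m[1]]]; rb <- at$residue_index[sg[m[2]]]
    pairs[[length(pairs) + 1L]] <- sort(c(ra, rb))
    d[m, ] <- Inf; d[, m] <- Inf
  }
  if (!length(pairs)) return(empty)
  out <- do.call(rbind, pairs)
  out <- out[order(out[, 1]), , drop = FALSE]
  colnames(out) <- c("res_a", "res_b")
  out
}

#' Mass-weighted center of mass of a residue range
#'
#' @param frame a [frame()].
#' @param topology matching [topology()].
#' @param residue_range inclusive residue-index interval `c(first, last)`,
#'   or a vector of residue indices.
#' @return length-3 numeric (A).
#' @export
center_of_mass <- function(frame, topology, residue_range) {
  residues <- if (length(residue_range) == 2L && residue_range[2] >= residue_range[1])
    seq(residue_range[1], residue_range[2]) else residue_range
  idx <- atoms_in_residues(topology, residues)
  if (length(idx) == 0L) stop("empty selection: no atoms in residue range")
  w <- topology$atoms$mass[idx]
  colSums(frame$coordinates[idx, , drop = FALSE] * w) / sum(w)
}

#' Mature SP-B peptide sequence
#'
#' The 79-residue mature surfactant protein B chain (preprotein residues
#' 201-279), used as the default sequence of the synthetic hinge-protein
#' generator. Shipped with the package in `inst/extdata/spb_mature.fasta`.
#'
#' @return single 79-character string.
#' @export
spb_mature_sequence <- function() {
  paste0("FPIPLPYCWLCRALIKRIQAMIPKGALAVAVAQVCRVVPLVAGGICQCLAE",
         "RYSVILLDTLLGRMLPQLVCRLVLRCSM")
}
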