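# Core containers: Topology (static chemical identity), Frame (one set of
# coordinates + optional periodic box) and Trajectory (frames x atoms x 3).

#' Construct a Topology
#'
#' A Topology records the static chemical identity of the system: one row
#' per atom with name, element, mass, and 1-based residue index/name.
#' Residue indexing matches the mature-peptide numbering used throughout
#' (e.g. TYR7 is the 7th mature residue).
#'
#' @param atoms data.frame with columns `name`, `residue_index`,
#'   `residue_name`, and optionally `element` and `mass` (inferred from the
#'   atom name when absent).
#' @param chain_id chain identifier (single string).
#' @return an object of class `sapflex_topology` with elements `atoms`
#'   (data.frame), `residues` (data.frame of `index`, `name`) and `chain_id`.
#' @export
topology <- function(atoms, chain_id = "A") {
  stopifnot(is.data.frame(atoms),
            all(c("name", "residue_index", "residue_name") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("topology must contain at least one atom")
  atoms$name <- toupper(trimws(atoms$name))
  atoms$residue_name <- toupper(trimws(atoms$residue_name))
  if (is.null(atoms$element))
    atoms$element <- infer_element(atoms$name, atoms$residue_name)
  if (is.null(atoms$mass))
    atoms$mass <- element_mass(atoms$element)
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  res <- unique(atoms[, c("residue_index", "residue_name")])
  if (is.unsorted(res$residue_index, strictly = FALSE) ||
      anyDuplicated(res$residue_index))
    stop("residue indices must be non-decreasing and unambiguous")
  rownames(atoms) <- NULL
  structure(list(
    atoms = atoms,
    residues = data.frame(index = res$residue_index, name = res$residue_name,
                          stringsAsFactors = FALSE),
    chain_id = chain_id
  ), class = "sapflex_topology")
}

#' @export
print.sapflex_topology <- function(x, ...) {
  cat(sprintf("<sapflex_topology> %d atoms, %d residues, chain %s\n",
              nrow(x$atoms), nrow(x$residues), x$chain_id))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)
n_residues <- function(top) nrow(top$residues)

#' Construct a single coordinate Frame
#'
#' @param coordinates numeric matrix, atoms x 3, in Angstrom.
#' @param box optional length-3 numeric of periodic box edge lengths (A)
#'   for an orthorhombic/cubic box; `NULL` for non-periodic systems.
#' @return object of class `sapflex_frame`.
#' @export
frame <- function(coordinates, box = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be an atoms x 3 matrix")
  storage.mode(coordinates) <- "double"
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(box <= 0)) stop("box edges must be 3 positive lengths")
  }
  structure(list(coordinates = coordinates, box = box), class = "sapflex_frame")
}

#' @export
print.sapflex_frame <- function(x, ...) {
  cat(sprintf("<sapflex_frame> %d atoms%s\n", nrow(x$coordinates),
              if (is.null(x$box)) "" else sprintf(", box %.1f x %.1f x %.1f A",
                                                  x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Construct a Trajectory
#'
#' @param topology a [topology()] object.
#' @param coords 3-D numeric array `frames x atoms x 3` (A), or a list of
#'   `sapflex_frame` objects with consistent atom counts.
#' @param box `NULL`, a length-3 vector (constant box) or a `frames x 3`
#'   matrix of per-frame box edges.
#' @param timestep time between consecutive frames in ns.
#' @return object of class `sapflex_trajectory` with elements `topology`,
#'   `coords` (frames x atoms x 3 array), `box`, `timestep`.
#' @export
trajectory <- function(topology, coords, box = NULL, timestep = 1) {
  stopifnot(inherits(topology, "sapflex_topology"))
  if (is.list(coords) && !is.array(coords)) {
    if (length(coords) == 0L) stop("a trajectory needs at least one frame")
    boxes <- lapply(coords, function(f) f$box)
    mats <- lapply(coords, function(f) f$coordinates)
    coords <- aperm(simplify2array(mats), c(3, 1, 2))
    if (!all(vapply(boxes, is.null, logical(1))) && is.null(box))
      box <- do.call(rbind, lapply(boxes, function(b) if (is.null(b)) rep(NA_real_, 3) else b))
  }
  if (length(dim(coords)) == 2L) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  if (dim(coords)[1] < 1L) stop("a trajectory needs at least one frame")
  if (dim(coords)[2] != n_atoms(topology))
    stop(sprintf("coordinate count (%d atoms) does not match topology (%d atoms)",
                 dim(coords)[2], n_atoms(topology)))
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = dim(coords)[1], ncol = 3, byrow = TRUE)
    if (nrow(box) != dim(coords)[1]) stop("box must have one row per frame")
  }
  if (!is.numeric(timestep) || timestep <= 0) stop("timestep must be positive (ns)")
  structure(list(topology = topology, coords = coords, box = box,
                 timestep = timestep), class = "sapflex_trajectory")
}

#' @export
print.sapflex_trajectory <- function(x, ...) {
  cat(sprintf("<sapflex_trajectory> %d frames x %d atoms, dt = %g ns (%g ns total)\n",
              n_frames(x), dim(x$coords)[2], x$timestep, n_frames(x) * x$timestep))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `sapflex_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame from a trajectory
#' @param traj a `sapflex_trajectory`.
#' @param i frame index (1-based).
#' @return a `sapflex_frame`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  b <- if (is.null(traj$box)) NULL else {
    bi <- traj$box[i, ]
    if (anyNA(bi)) NULL else bi
  }
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  frame(m, box = b)
}

#' Subset a trajectory by frame indices
#' @param traj a `sapflex_trajectory`.
#' @param idx integer vector of frame indices to keep (in order).
#' @return a `sapflex_trajectory`.
#' @export
subset_frames <- function(traj, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop("cannot create an empty trajectory")
  if (any(idx < 1L | idx > n_frames(traj))) stop("frame index out of range")
  trajectory(traj$topology, traj$coords[idx, , , drop = FALSE],
             box = if (is.null(traj$box)) NULL else traj$box[idx, , drop = FALSE],
             timestep = traj$timestep)
}

# indices of atoms belonging to residues in `range` (inclusive residue indices)
atoms_in_residues <- function(top, residues) {
  which(top$atoms$residue_index %in% residues)
}

# atom indices matching a set of atom names, optionally protein-only
select_atoms <- function(top, names = NULL, protein_only = TRUE) {
  keep <- rep(TRUE, n_atoms(top))
  if (protein_only) keep <- keep & !(top$atoms$residue_name %in% c(.solvent_resnames, .ion_resnames))
  if (!is.null(names)) keep <- keep & top$atoms$name %in% toupper(names)
  which(keep)
}
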