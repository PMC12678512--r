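# Independent oracles and fixture builders used across the suite.

# Quaternion-method (Horn) superposition oracle: independent of the SVD
# path under test. Returns the minimal weighted RMSD between paired sets.
quaternion_rmsd <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  P <- sweep(mobile, 2, colSums(mobile * w))
  Q <- sweep(reference, 2, colSums(reference * w))
  M <- t(P * w) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  g <- sum(w * rowSums(P^2)) + sum(w * rowSums(Q^2))
  sqrt(max(0, g - 2 * lambda))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# minimal single-residue-per-atom topology for geometric toy systems
toy_topology <- function(n, mass = NULL, resname = "GLY") {
  atoms <- data.frame(name = rep("CA", n), residue_index = seq_len(n),
                      residue_name = rep(resname, n))
  if (!is.null(mass)) atoms$mass <- mass
  topology(atoms)
}

toy_trajectory <- function(coords_list, top = NULL, timestep = 1) {
  if (is.null(top)) top <- toy_topology(nrow(coords_list[[1]]))
  trajectory(top, lapply(coords_list, frame), timestep = timestep)
}

# write a small multi-model PDB by hand (contract-case fixtures)
write_mini_pdb <- function(path, models) {
  lines <- character(0)
  for (k in seq_along(models)) {
    m <- models[[k]]
    lines <- c(lines, sprintf("MODEL     %4d", k))
    for (i in seq_len(nrow(m$xyz)))
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, m$name[i], m$resname[i], m$resno[i],
        m$xyz[i, 1], m$xyz[i, 2], m$xyz[i, 3], m$element[i]))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

mini_model <- function(xyz, name = "CA", resname = "GLY",
                       resno = seq_len(nrow(xyz)), element = "C") {
  list(xyz = xyz, name = rep_len(name, nrow(xyz)),
       resname = rep_len(resname, nrow(xyz)),
       resno = rep_len(resno, nrow(xyz)),
       element = rep_len(element, nrow(xyz)))
}

# reference DSSP via mdtraj (python); returns per-frame class strings with
# loop as "-"
mdtraj_dssp <- function(pdb_path) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import mdtraj as md",
    "t = md.load(sys.argv[1])",
    "ss = md.compute_dssp(t, simplified=False)",
    "for row in ss:",
    "    print(''.join(c if c != ' ' else '-' for c in row))"
  ), script)
  out <- suppressWarnings(system2("python", c(script, pdb_path),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) stop("mdtraj reference call failed")
  out
}

# single-frame trajectory from a frame + topology
one_frame_traj <- function(model_frame, top) {
  trajectory(top, array(model_frame$coordinates,
                        c(1, nrow(model_frame$coordinates), 3)))
}

# cached synthetic reference model shared across tests (built once)
spb_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_hinge_protein(hinge_params())
    cache
  }
})
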