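# Radial solvent distribution functions about a protein region's center of
# mass, normalized so that bulk solvent density reads 1 — comparable across
# solvents of different molecular density. Periodic distances use the
# minimum-image convention on an orthorhombic box.

# minimum-image displacement for an orthorhombic box (edges = length-3)
.min_image <- function(disp, edges) {
  disp - sweep(round(sweep(disp, 2, edges, "/")), 2, edges, "*")
}

#' Radial solvent distribution about a region
#'
#' For each frame, the distance from the mass-weighted center of mass of
#' the selected residues to every solvent molecule's reference site is
#' histogrammed into spherical shells; the shell densities are divided by
#' the bulk density `N_solvent / V_box` (averaged over frames), so g -> 1
#' at large r in uniform solvent.
#'
#' @param traj a [trajectory()] carrying solvent and a periodic box (a
#'   non-periodic system is accepted; distances are then plain Euclidean
#'   and bulk density must be supplied).
#' @param region inclusive residue-index interval of the protein region.
#' @param solvent_resnames residue names identifying solvent molecules
#'   (default water and chloroform names).
#' @param site_element element of the reference site per solvent molecule:
#'   `"O"` for water, `"C"` for chloroform; `NULL` picks the first atom of
#'   each solvent residue.
#' @param bin_width shell width in A (default 0.5).
#' @param r_max outermost shell radius (default 25 A); must not exceed half
#'   the shortest box edge for periodic systems.
#' @param bulk_density optional molecules per A^3 override (required for
#'   non-periodic systems).
#' @return object of class `radial_distribution`: list with `r_edges`, `g`,
#'   `raw_counts` (summed over frames), `se` (Poisson standard error of g),
#'   `bulk_density`, `n_frames`.
#' @export
radial_solvent_distribution <- function(traj, region,
                                        solvent_resnames = .solvent_resnames,
                                        site_element = "O",
                                        bin_width = 0.5, r_max = 25,
                                        bulk_density = NULL) {
  top <- traj$topology
  at <- top$atoms
  solv_res <- top$residues$index[top$residues$name %in% solvent_resnames]
  site <- vapply(solv_res, function(r) {
    idx <- which(at$residue_index == r)
    if (!is.null(site_element)) {
      hit <- idx[at$element[idx] == site_element]
      if (length(hit)) return(hit[1])
    }
    idx[1]
  }, integer(1))
  nsolv <- length(site)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  nshell <- length(edges) - 1L

  has_box <- !is.null(traj$box) && !anyNA(traj$box)
  if (has_box) {
    if (r_max > min(traj$box) / 2)
      stop(sprintf("r_max %.1f A exceeds half the shortest box edge (%.1f A)",
                   r_max, min(traj$box) / 2))
  } else if (is.null(bulk_density) && nsolv > 0) {
    stop("non-periodic trajectory: supply bulk_density explicitly")
  }

  counts <- numeric(nshell)
  vols <- numeric(0)
  nf <- n_frames(traj)
  if (nsolv > 0) for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    com <- center_of_mass(fr, top, region)
    disp <- sweep(fr$coordinates[site, , drop = FALSE], 2, com)
    if (has_box) {
      disp <- .min_image(disp, traj$box[i, ])
      vols <- c(vols, prod(traj$box[i, ]))
    }
    r <- sqrt(rowSums(disp^2))
    h <- findInterval(r, edges, rightmost.closed = FALSE)
    h <- h[h >= 1L & h <= nshell]
    counts <- counts + tabulate(h, nbins = nshell)
  }
  bulk <- if (!is.null(bulk_density)) bulk_density
          else if (length(vols)) nsolv / mean(vols) else NA_real_
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  if (nsolv == 0) {
    warning("no solvent molecules matched; g is identically zero")
    g <- rep(0, nshell); se <- rep(0, nshell)
  } else {
    g <- counts / (nf * shell_vol * bulk)
    # Poisson uncertainty, floored at one count so empty shells carry an
    # honest error bar instead of zero
    se <- sqrt(pmax(counts, 1)) / (nf * shell_vol * bulk)
  }
  structure(list(r_edges = edges, g = g, raw_counts = counts, se = se,
                 bulk_density = bulk, n_frames = nf,
                 bin_width = bin_width, n_solvent = nsolv),
            class = "radial_distribution")
}

#' @export
print.radial_distribution <- function(x, ...) {
  cat(sprintf("<radial_distribution> %d shells to %.1f A, bulk %.2e /A^3, %d solvent sites\n",
              length(x$g), x$r_edges[length(x$r_edges)], x$bulk_density, x$n_solvent))
  invisible(x)
}

#' Per-shell difference of two radial distributions
#'
#' @param a,b `radial_distribution` objects on identical shell grids.
#' @return data.frame with `r_center`, `diff` (g_a - g_b) and `se`
#'   (propagated Poisson uncertainty).
#' @export
compare_distributions <- function(a, b) {
  if (length(a$r_edges) != length(b$r_edges) ||
      any(abs(a$r_edges - b$r_edges) > 1e-9))
    stop("shell grids differ; distributions are not comparable")
  data.frame(r_center = .bin_centers(a$r_edges),
             diff = a$g - b$g,
             se = sqrt(a$se^2 + b$se^2))
}

#' Tidy table of a radial distribution
#' @param x a `radial_distribution`.
#' @return data.frame `(r_center, g, raw_count, se)`.
#' @export
rdf_table <- function(x) {
  data.frame(r_center = .bin_centers(x$r_edges), g = x$g,
             raw_count = x$raw_counts, se = x$se)
}
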