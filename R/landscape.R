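# Two-distance free-energy landscapes by Boltzmann inversion of binned
# state probabilities: dG_i = -RT ln P_i, reported relative to the occupied
# minimum. Bins are half-open [edge, edge + width) with edges anchored at
# integer multiples of the bin width, so bin identity is data-independent
# and count grids from different replicates can be pooled exactly.

#' Thermodynamic parameters for Boltzmann inversion
#'
#' @param R gas constant in kcal mol-1 K-1 (default 1.9872e-3).
#' @param T simulation temperature in K (default 310, physiological).
#' @return list with `R`, `T` and their product `RT` (kcal/mol).
#' @export
thermo_params <- function(R = 1.9872e-3, T = 310) {
  stopifnot(T > 0, R > 0)
  list(R = R, T = T, RT = R * T)
}

#' Keep only the final portion of a series or trajectory
#'
#' Discards everything before the final `last_duration` ns, the standard
#' guard against residual equilibration in landscape construction.
#'
#' @param x a [trajectory()] or a `conformation_series`.
#' @param last_duration window length in ns.
#' @param timestep frame spacing in ns, required when `x` is a bare
#'   data.frame without a `time` column.
#' @return an object of the same type, trimmed to the final window.
#' @export
select_window <- function(x, last_duration, timestep = NULL) {
  if (last_duration <= 0) stop("window must be positive; use the full series instead")
  if (inherits(x, "sapflex_trajectory")) {
    total <- n_frames(x) * x$timestep
    if (total < last_duration)
      stop(sprintf("trajectory spans %g ns < requested window %g ns; use the full series",
                   total, last_duration))
    keep <- which(seq_len(n_frames(x)) * x$timestep > total - last_duration)
    return(subset_frames(x, keep))
  }
  tm <- if (!is.null(x$time)) x$time else {
    if (is.null(timestep)) stop("timestep required for series without a time column")
    seq_len(nrow(x)) * timestep
  }
  total <- max(tm)
  if (total < last_duration)
    stop(sprintf("series spans %g ns < requested window %g ns; use the full series", total, last_duration))
  out <- x[tm > total - last_duration, , drop = FALSE]
  class(out) <- class(x)
  out
}

#' 2-D state histogram of the two diagnostic separations
#'
#' @param d1,d2 equal-length numeric vectors (A).
#' @param bin_width bin width in A (default 0.1).
#' @return object of class `state_counts`: list with `counts` (matrix d1
#'   bins x d2 bins), `d1_edges`, `d2_edges` (length nbins+1, multiples of
#'   `bin_width`) and `bin_width`.
#' @export
bin_states <- function(d1, d2, bin_width = 0.1) {
  if (length(d1) == 0L) stop("empty series")
  if (length(d1) != length(d2)) stop("d1 and d2 must have equal length")
  if (bin_width <= 0) stop("bin_width must be positive")
  anchor <- function(x) floor(x / bin_width)
  i1 <- anchor(d1); i2 <- anchor(d2)
  r1 <- range(i1); r2 <- range(i2)
  counts <- matrix(0L, r1[2] - r1[1] + 1L, r2[2] - r2[1] + 1L)
  tab <- table(factor(i1, levels = r1[1]:r1[2]), factor(i2, levels = r2[1]:r2[2]))
  counts[] <- as.integer(tab)
  structure(list(counts = counts,
                 d1_edges = (r1[1]:(r1[2] + 1L)) * bin_width,
                 d2_edges = (r2[1]:(r2[2] + 1L)) * bin_width,
                 bin_width = bin_width),
            class = "state_counts")
}

#' Pool state-count grids from several replicates
#'
#' Grids must share the same bin width; the anchored edges make pooling an
#' exact sum on the union grid.
#'
#' @param ... `state_counts` objects (or a single list of them).
#' @return a pooled `state_counts`.
#' @export
pool_counts <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1]], "state_counts")) gs <- gs[[1]]
  bw <- unique(vapply(gs, function(g) g$bin_width, numeric(1)))
  if (length(bw) != 1L) stop("cannot pool grids with different bin widths")
  lo1 <- min(vapply(gs, function(g) g$d1_edges[1], numeric(1)))
  hi1 <- max(vapply(gs, function(g) g$d1_edges[length(g$d1_edges)], numeric(1)))
  lo2 <- min(vapply(gs, function(g) g$d2_edges[1], numeric(1)))
  hi2 <- max(vapply(gs, function(g) g$d2_edges[length(g$d2_edges)], numeric(1)))
  n1 <- round((hi1 - lo1) / bw); n2 <- round((hi2 - lo2) / bw)
  counts <- matrix(0L, n1, n2)
  for (g in gs) {
    o1 <- round((g$d1_edges[1] - lo1) / bw); o2 <- round((g$d2_edges[1] - lo2) / bw)
    idx1 <- (o1 + 1):(o1 + nrow(g$counts)); idx2 <- (o2 + 1):(o2 + ncol(g$counts))
    counts[idx1, idx2] <- counts[idx1, idx2] + g$counts
  }
  structure(list(counts = counts,
                 d1_edges = lo1 + (0:n1) * bw, d2_edges = lo2 + (0:n2) * bw,
                 bin_width = bw), class = "state_counts")
}

#' Relative free-energy landscape from state counts
#'
#' Boltzmann inversion: P_i = count_i / total (replicates pooled before the
#' call or via `...`), dG_i = -RT ln P_i shifted so that the occupied
#' minimum is exactly 0. Unoccupied bins carry `NA` ("undefined"), not an
#' infinite number.
#'
#' @param counts a `state_counts` (additional grids to pool may be passed
#'   via `...`).
#' @param thermo a [thermo_params()] list.
#' @param ... further `state_counts` objects pooled into the estimate.
#' @return object of class `free_energy_landscape`: list with the bin
#'   edges, `counts`, `P`, `dG` (kcal/mol, `NA` where unoccupied) and
#'   `occupied` logical matrix.
#' @export
free_energy <- function(counts, thermo = thermo_params(), ...) {
  extra <- list(...)
  if (length(extra)) counts <- pool_counts(c(list(counts), extra))
  stopifnot(inherits(counts, "state_counts"))
  total <- sum(counts$counts)
  if (total <= 0) stop("total count must be positive")
  P <- counts$counts / total
  occupied <- counts$counts > 0L
  dG <- matrix(NA_real_, nrow(P), ncol(P))
  dG[occupied] <- -thermo$RT * log(P[occupied])
  dG <- dG - min(dG[occupied])
  structure(list(d1_edges = counts$d1_edges, d2_edges = counts$d2_edges,
                 bin_width = counts$bin_width, counts = counts$counts,
                 P = P, dG = dG, occupied = occupied, thermo = thermo),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf("<free_energy_landscape> %d x %d bins (%.2f A), %d occupied, max dG %.2f kcal/mol\n",
              nrow(x$dG), ncol(x$dG), x$bin_width, sum(x$occupied),
              max(x$dG, na.rm = TRUE)))
  invisible(x)
}

.bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Local minima of a free-energy landscape
#'
#' Occupied bins whose dG is strictly lower than that of every occupied
#' neighbor (4- or 8-connected), sorted by ascending dG.
#'
#' An isolated occupied bin has no occupied neighbors and is vacuously a
#' strict minimum; in sparsely sampled landscapes such noise-floor bins can
#' be excluded with `max_dG`, which restricts the report to thermally
#' relevant minima near the global one (1.5 kcal/mol is about 2.4 kT at
#' 310 K).
#'
#' @param landscape a `free_energy_landscape`.
#' @param neighborhood `"8"` (default) or `"4"`.
#' @param max_dG report only minima with dG below this value (kcal/mol);
#'   `Inf` keeps all.
#' @return data.frame with `d1`, `d2` (bin centers, A) and `dG` (kcal/mol).
#' @export
find_minima <- function(landscape, neighborhood = c("8", "4"), max_dG = Inf) {
  neighborhood <- match.arg(neighborhood)
  offs <- if (neighborhood == "4")
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else as.matrix(expand.grid(di = -1:1, dj = -1:1))[-5, ]
  dG <- landscape$dG; occ <- landscape$occupied
  nr <- nrow(dG); nc <- ncol(dG)
  hit <- which(occ, arr.ind = TRUE)
  is_min <- logical(nrow(hit))
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]; j <- hit[k, 2]
    ok <- TRUE
    for (o in seq_len(nrow(offs))) {
      ii <- i + offs[o, 1]; jj <- j + offs[o, 2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (occ[ii, jj] && dG[ii, jj] <= dG[i, j]) { ok <- FALSE; break }
    }
    is_min[k] <- ok
  }
  c1 <- .bin_centers(landscape$d1_edges); c2 <- .bin_centers(landscape$d2_edges)
  out <- data.frame(d1 = c1[hit[is_min, 1]], d2 = c2[hit[is_min, 2]],
                    dG = dG[hit[is_min, , drop = FALSE]])
  out <- out[out$dG <= max_dG, , drop = FALSE]
  out <- out[order(out$dG), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Persistent basin minima of a free-energy landscape
#'
#' Identifies one minimum per basin using topological persistence:
#' occupied bins are flooded in order of increasing dG and united with
#' 8-connected neighbors; when two growing basins meet, the shallower one
#' dies and its persistence is the barrier height above its own minimum.
#' Basins still separate after flooding all occupied bins are connected
#' through unobserved territory, whose free energy is bounded below by the
#' sampling ceiling RT ln(N P_max) (the dG of a single-frame bin): they
#' merge there, except the global minimum, which has infinite persistence.
#' Only minima with persistence of at least `min_persistence` are
#' reported — this separates genuine conformational basins from Poisson
#' sampling noise, whose spurious minima sit behind barriers of order
#' RT ln(count ratio) << 1 kcal/mol.
#'
#' @param landscape a `free_energy_landscape`.
#' @param min_persistence minimum barrier height (kcal/mol) for a basin to
#'   be reported (default 1.0, well above the sampling-noise scale and
#'   below any physically meaningful inter-basin barrier).
#' @return data.frame with `d1`, `d2` (bin centers), `dG` and
#'   `persistence` (kcal/mol, `Inf` for never-merged basins), sorted by dG.
#' @export
basin_minima <- function(landscape, min_persistence = 1.0) {
  dG <- landscape$dG
  nr <- nrow(dG); nc <- ncol(dG)
  occ <- which(landscape$occupied, arr.ind = TRUE)
  ord <- order(dG[occ])
  occ <- occ[ord, , drop = FALSE]
  key <- function(i, j) (j - 1L) * nr + i
  rank_of <- integer(nr * nc)
  rank_of[key(occ[, 1], occ[, 2])] <- seq_len(nrow(occ))
  parent <- seq_len(nrow(occ))
  comp_min <- seq_len(nrow(occ))     # index (into occ) of component minimum
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))[-5, ]
  died <- rep(NA_real_, nrow(occ))   # persistence of dead minima
  for (k in seq_len(nrow(occ))) {
    i <- occ[k, 1]; j <- occ[k, 2]
    roots <- integer(0)
    for (o in seq_len(nrow(offs))) {
      ii <- i + offs[o, 1]; jj <- j + offs[o, 2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      rk <- rank_of[key(ii, jj)]
      if (rk == 0L || rk > k) next
      roots <- c(roots, find(rk))
    }
    roots <- unique(roots)
    if (length(roots) == 0L) next           # k starts its own basin
    # attach k to the deepest neighboring basin; other basins die here
    mins <- vapply(roots, function(r) dG[occ[comp_min[r], 1], occ[comp_min[r], 2]],
                   numeric(1))
    main <- roots[which.min(mins)]
    parent[k] <- main
    for (r in setdiff(roots, main)) {
      died[comp_min[r]] <- dG[i, j] -
        dG[occ[comp_min[r], 1], occ[comp_min[r], 2]]
      parent[r] <- main
    }
  }
  # surviving components merge through unobserved space at the sampling
  # ceiling; the deepest basin alone has infinite persistence
  alive <- unique(vapply(seq_len(nrow(occ)), function(k) find(k), integer(1)))
  pers <- died
  ceiling_dG <- landscape$thermo$RT *
    log(sum(landscape$counts) * max(landscape$P))
  alive_min <- vapply(alive, function(r) dG[occ[comp_min[r], 1], occ[comp_min[r], 2]],
                      numeric(1))
  global <- alive[which.min(alive_min)]
  pers[comp_min[global]] <- Inf
  for (r in setdiff(alive, global))
    pers[comp_min[r]] <- ceiling_dG -
      dG[occ[comp_min[r], 1], occ[comp_min[r], 2]]
  keep <- which(!is.na(pers) & pers >= min_persistence)
  c1 <- .bin_centers(landscape$d1_edges); c2 <- .bin_centers(landscape$d2_edges)
  out <- data.frame(d1 = c1[occ[keep, 1]], d2 = c2[occ[keep, 2]],
                    dG = dG[occ[keep, , drop = FALSE]], persistence = pers[keep])
  out <- out[order(out$dG), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a landscape as a tidy table
#'
#' @param landscape a `free_energy_landscape`.
#' @param occupied_only drop unoccupied bins (default TRUE).
#' @return data.frame `(d1_center, d2_center, count, P, dG)`.
#' @export
landscape_table <- function(landscape, occupied_only = TRUE) {
  c1 <- .bin_centers(landscape$d1_edges); c2 <- .bin_centers(landscape$d2_edges)
  out <- data.frame(d1_center = rep(c1, times = length(c2)),
                    d2_center = rep(c2, each = length(c1)),
                    count = as.vector(landscape$counts),
                    P = as.vector(landscape$P),
                    dG = as.vector(landscape$dG))
  if (occupied_only) out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
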