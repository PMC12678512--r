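# k-means clustering of trajectory frames in superposed-coordinate space.
# Pairwise-RMSD k-means is ill-posed (RMSD is not a Euclidean metric with
# well-defined centroids); the standard surrogate is used instead: frames
# are globally superposed onto the trajectory average and their flattened
# selected coordinates clustered with Lloyd iteration, which reproduces the
# practical behavior of backbone-RMSD clustering tools.

# evaluate expr with a temporary RNG seed, restoring global state after
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' k-means clustering of superposed trajectory frames
#'
#' Frames are superposed onto the iterative trajectory average over the
#' selected atoms, flattened, and clustered by Lloyd's k-means with
#' `n_init` random restarts (best inertia kept). Clusters are reported in
#' descending size order; each cluster's representative is the member frame
#' closest to its centroid.
#'
#' @param traj a [trajectory()].
#' @param k number of clusters (default 5).
#' @param selection atom names clustered on (default backbone N, CA, C).
#' @param seed integer RNG seed (restarts are reproducible; global RNG
#'   state is untouched).
#' @param n_init number of random restarts.
#' @param max_iter maximum Lloyd iterations.
#' @return object of class `cluster_result`: list with `labels` (per-frame
#'   cluster id, 1 = largest), `sizes`, `centers` (k x 3n matrix),
#'   `representatives` (frame indices), `inertia` (A^2).
#' @export
kmeans_frames <- function(traj, k = 5L, selection = c("N", "CA", "C"),
                          seed = 1L, n_init = 10L, max_iter = 300L) {
  nf <- n_frames(traj)
  if (k < 1L) stop("k must be at least 1")
  if (k > nf) stop(sprintf("k = %d exceeds frame count %d", k, nf))
  idx <- .resolve_selection(traj$topology, selection)
  aligned <- align_trajectory(traj, selection = selection)
  X <- matrix(NA_real_, nf, 3L * length(idx))
  for (i in seq_len(nf))
    X[i, ] <- as.vector(aligned$coords[i, idx, , drop = TRUE])
  n_distinct <- nrow(unique(X))
  if (n_distinct < k) {
    warning(sprintf("only %d distinct conformations; reducing k from %d",
                    n_distinct, k))
    k <- n_distinct
  }
  km <- with_local_seed(seed, suppressWarnings(
    stats::kmeans(X, centers = k, nstart = n_init, iter.max = max_iter,
                  algorithm = "Lloyd")))
  # relabel in descending size order
  ord <- order(km$size, decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[km$cluster]
  centers <- km$centers[ord, , drop = FALSE]
  sizes <- km$size[ord]
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    d2 <- rowSums(sweep(X[members, , drop = FALSE], 2, centers[cl, ])^2)
    members[which.min(d2)]
  }, integer(1))
  structure(list(labels = labels, sizes = sizes, centers = centers,
                 representatives = reps, inertia = km$tot.withinss,
                 selection_index = idx),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, sizes: %s, inertia %.2f A^2\n",
              length(x$sizes), paste(x$sizes, collapse = "/"), x$inertia))
  invisible(x)
}

#' Project cluster representatives onto the separation plane
#'
#' Returns the (d1, d2) coordinates of each cluster's representative frame,
#' the points overlaid on free-energy heatmaps.
#'
#' @param result a `cluster_result`.
#' @param series a `conformation_series` covering the clustered frames.
#' @return data.frame with `cluster`, `frame`, `d1`, `d2`, `size`.
#' @export
project_representatives <- function(result, series) {
  reps <- result$representatives
  if (max(reps) > nrow(series)) stop("series does not cover the clustered frames")
  data.frame(cluster = seq_along(reps), frame = reps,
             d1 = series$d1[reps], d2 = series$d2[reps],
             size = result$sizes)
}
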