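# End-to-end orchestration: RMSD -> separations -> classification ->
# free-energy landscape -> clustering -> secondary structure -> (optional)
# solvent distribution, with tidy CSV exports, figure rendering and a
# machine-readable JSON summary. Every default traces to a stated analysis
# parameter (0.1 A bins, final 500 ns window, 310 K, k = 5, backbone
# N/CA/C selection) or to a documented package choice.

#' Pipeline run configuration
#'
#' @param input path(s) to multi-model PDB trajectories (replicates), or
#'   `NULL` to simulate a synthetic hinge trajectory from `synthetic`.
#' @param synthetic a [hinge_params()] list used when `input` is `NULL`.
#' @param selection backbone atom-name selection.
#' @param ranges open/closed [classification_ranges()].
#' @param pairs diagnostic residue pairs (see [conformation_series()]).
#' @param bin_width landscape bin width, A.
#' @param window final analysis window, ns (`NULL` = full series; windows
#'   longer than a trajectory fall back to the full series with a message).
#' @param temperature simulation temperature, K.
#' @param k cluster count.
#' @param rdf optional list of arguments for
#'   [radial_solvent_distribution()] (e.g. `list(region = c(9, 19))`);
#'   `NULL` skips the solvation stage.
#' @param seed integer seed for clustering restarts.
#' @param timestep frame spacing of the inputs, ns.
#' @param min_persistence barrier height (kcal/mol) a landscape basin must
#'   have to be reported as a distinct minimum (see [basin_minima()]);
#'   default 1.0, above the Poisson sampling-noise scale.
#' @param output_dir directory for exports; `NULL` disables writing.
#' @param figures render PNG heatmaps alongside the CSVs.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = hinge_params(),
                       selection = c("N", "CA", "C"),
                       ranges = classification_ranges(),
                       pairs = list(d1 = c(7, 34), d2 = c(45, 70),
                                    d_cys = c(8, 35)),
                       bin_width = 0.1, window = 500, temperature = 310,
                       k = 5L, rdf = NULL, seed = 1L, timestep = 1,
                       min_persistence = 1.0, output_dir = NULL, figures = TRUE) {
  structure(list(input = input, synthetic = synthetic, selection = selection,
                 ranges = ranges, pairs = pairs, bin_width = bin_width,
                 window = window, temperature = temperature, k = k,
                 rdf = rdf, seed = seed, timestep = timestep,
                 min_persistence = min_persistence,
                 output_dir = output_dir, figures = figures),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full conformational-analysis pipeline
#'
#' Executes, per replicate: backbone RMSD against the first frame,
#' diagnostic separations with open/closed classification, pooled
#' free-energy landscape with minima, per-replicate k-means clustering
#' with representatives projected on the landscape, RMSF profiles with
#' flexible-region detection, DSSP helicity occupancy, and optionally a
#' radial solvent distribution. Deterministic under a fixed seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the per-replicate results and a
#'   `summary` list (also written as `summary.json` when `output_dir` is
#'   set).
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  log_msg <- function(...) message(sprintf(...))

  trajs <- .stage("input", {
    if (is.null(cfg$input)) {
      log_msg("simulating synthetic hinge trajectory (seed %d, %d frames)",
              cfg$synthetic$seed, cfg$synthetic$n_frames)
      sim <- simulate_hinge_trajectory(cfg$synthetic)
      attr(sim$trajectory, "ground_truth") <- sim$ground_truth
      list(synthetic = sim$trajectory)
    } else {
      out <- lapply(cfg$input, read_pdb_models, timestep = cfg$timestep)
      names(out) <- make.names(basename(unlist(cfg$input)), unique = TRUE)
      out
    }
  })

  thermo <- thermo_params(T = cfg$temperature)
  res <- list()
  count_grids <- list()
  for (nm in names(trajs)) {
    tr <- trajs[[nm]]
    rmsd <- .stage("rmsd", rmsd_series(tr, get_frame(tr, 1L), cfg$selection))
    series <- .stage("separations",
                     conformation_series(tr, cfg$ranges, cfg$pairs))
    win <- series
    if (!is.null(cfg$window)) {
      total <- n_frames(tr) * tr$timestep
      if (total >= cfg$window) win <- select_window(series, cfg$window)
      else log_msg("replicate %s spans %g ns < window %g ns; using full series",
                   nm, total, cfg$window)
    }
    count_grids[[nm]] <- .stage("landscape",
                                bin_states(win$d1, win$d2, cfg$bin_width))
    clus <- .stage("clustering",
                   kmeans_frames(tr, cfg$k, cfg$selection, seed = cfg$seed))
    reps <- project_representatives(clus, series)
    prof <- .stage("rmsf", rmsf_per_residue(tr, selection = cfg$selection))
    ss <- .stage("secstruct", secstruct_series(tr))
    rdf <- if (!is.null(cfg$rdf))
      .stage("solvation", do.call(radial_solvent_distribution,
                                  c(list(traj = tr), cfg$rdf)))
    res[[nm]] <- list(rmsd = rmsd, series = series, clusters = clus,
                      representatives = reps, rmsf = prof,
                      secstruct = ss, rdf = rdf)
  }

  land <- .stage("landscape", free_energy(pool_counts(count_grids), thermo))
  minima <- basin_minima(land, min_persistence = cfg$min_persistence)
  occ <- .stage("secstruct", helicity_occupancy(
    lapply(res, function(r) is_helical(r$secstruct)),
    time_bins = min(100L, min(vapply(res, function(r) nrow(r$secstruct), integer(1))))))

  summary <- list(
    replicates = names(res),
    n_frames = vapply(trajs, n_frames, integer(1)),
    parameters = list(bin_width = cfg$bin_width, window = cfg$window,
                      temperature = cfg$temperature, k = cfg$k,
                      selection = cfg$selection, seed = cfg$seed,
                      ranges = cfg$ranges),
    state_fractions = lapply(res, function(r) {
      tab <- table(factor(r$series$label,
                          c("open", "closed", "partially_open", "other")))
      as.list(tab / sum(tab))
    }),
    minima = minima,
    cluster_sizes = lapply(res, function(r) r$clusters$sizes),
    flexible_regions = lapply(res, function(r) r$rmsf$peak_regions))

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$output_dir, f)
    for (nm in names(res)) {
      r <- res[[nm]]
      utils::write.csv(data.frame(frame = seq_along(r$rmsd), value = r$rmsd,
                                  replicate = nm),
                       out(paste0("rmsd_", nm, ".csv")), row.names = FALSE)
      utils::write.csv(as.data.frame(r$series),
                       out(paste0("separations_", nm, ".csv")), row.names = FALSE)
      utils::write.csv(data.frame(residue = r$rmsf$residue, value = r$rmsf$rmsf,
                                  replicate = nm),
                       out(paste0("rmsf_", nm, ".csv")), row.names = FALSE)
      utils::write.csv(data.frame(frame = seq_along(r$clusters$labels),
                                  cluster = r$clusters$labels),
                       out(paste0("clusters_", nm, ".csv")), row.names = FALSE)
      if (!is.null(r$rdf))
        utils::write.csv(rdf_table(r$rdf), out(paste0("rdf_", nm, ".csv")),
                         row.names = FALSE)
    }
    utils::write.csv(landscape_table(land), out("landscape.csv"), row.names = FALSE)
    utils::write.csv(occ, out("helicity_occupancy.csv"), row.names = FALSE)
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    if (isTRUE(cfg$figures)) {
      grDevices::png(out("landscape.png"), 900, 700)
      plot_landscape(land, minima = minima,
                     representatives = do.call(rbind, lapply(res, function(r)
                       r$representatives)))
      grDevices::dev.off()
      grDevices::png(out("helicity_occupancy.png"), 900, 500)
      plot_occupancy(occ)
      grDevices::dev.off()
    }
  }
  invisible(list(replicates = res, landscape = land, minima = minima,
                 occupancy = occ, summary = summary))
}

#' Render a free-energy landscape heatmap
#'
#' Low free energy plotted in blue, high in red; unoccupied bins in the
#' top color. Cluster representatives are overlaid as black triangles.
#'
#' @param landscape a `free_energy_landscape`.
#' @param minima optional data.frame from [find_minima()] (plotted as
#'   circles).
#' @param representatives optional data.frame with `d1`, `d2`.
#' @param dG_cap color-scale cap in kcal/mol (`NULL` = data maximum).
#' @return invisibly, `NULL`.
#' @export
plot_landscape <- function(landscape, minima = NULL, representatives = NULL,
                           dG_cap = NULL) {
  z <- landscape$dG
  top <- if (is.null(dG_cap)) max(z, na.rm = TRUE) else dG_cap
  z[is.na(z)] <- top
  z[z > top] <- top
  pal <- grDevices::hcl.colors(64, "RdYlBu", rev = TRUE)
  graphics::image(.bin_centers(landscape$d1_edges),
                  .bin_centers(landscape$d2_edges), z,
                  col = pal, xlab = "d1: helix 1-2 flap separation (A)",
                  ylab = "d2: helix 3-4 flap separation (A)",
                  main = "Relative free energy (kcal/mol)")
  if (!is.null(minima) && nrow(minima))
    graphics::points(minima$d1, minima$d2, pch = 1, cex = 2)
  if (!is.null(representatives) && nrow(representatives))
    graphics::points(representatives$d1, representatives$d2, pch = 17)
  invisible(NULL)
}

#' Render a helicity occupancy map
#'
#' White = helical in all replicates, black = none, gray = some.
#'
#' @param occ matrix from [helicity_occupancy()].
#' @return invisibly, `NULL`.
#' @export
plot_occupancy <- function(occ) {
  graphics::image(seq_len(nrow(occ)) / nrow(occ), seq_len(ncol(occ)), occ,
                  col = grDevices::gray.colors(32, start = 0, end = 1),
                  zlim = c(0, 1), xlab = "fraction of trajectory",
                  ylab = "residue", main = "Helicity occupancy")
  invisible(NULL)
}
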