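# Kabsch superposition, RMSD series, average structures, RMSF and
# flexible-region detection.

test_that("kabsch recovers exact transforms and excludes reflections", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  sp <- kabsch_superpose(X, X)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  # known rotation + translation is inverted exactly
  R <- random_rotation(); t <- c(3, -2, 7)
  Y <- sweep(X %*% t(R), 2, t, "+")
  sp2 <- kabsch_superpose(Y, X)
  expect_lt(sp2$rmsd, 1e-6)
  expect_equal(apply_superposition(Y, sp2), X, tolerance = 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-8)
  expect_equal(crossprod(sp2$rotation), diag(3), tolerance = 1e-8)
  # contracts
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("kabsch agrees with the quaternion oracle on 100 random instances", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    X <- matrix(rnorm(3 * n), n, 3)
    Y <- matrix(rnorm(3 * n), n, 3)
    w <- runif(n, 0.5, 2)
    expect_equal(kabsch_superpose(X, Y, w)$rmsd, quaternion_rmsd(X, Y, w),
                 tolerance = 1e-8)
  }
})

test_that("rmsd series is zero for copies and invariant to rigid motion", {
  set.seed(2)
  base <- matrix(rnorm(30), 10, 3)
  shifted <- sweep(base, 2, c(5, 0, 0), "+")
  R <- random_rotation()
  rotated <- base %*% t(R)
  tr <- toy_trajectory(list(base, shifted, rotated))
  v <- rmsd_series(tr, frame(base), selection = "CA")
  expect_equal(v, c(0, 0, 0), tolerance = 1e-8)
  # superposed RMSD never exceeds raw RMSD
  set.seed(3)
  noisy <- lapply(1:5, function(i) base + matrix(rnorm(30, sd = 0.3), 10, 3))
  trn <- toy_trajectory(noisy)
  fit <- rmsd_series(trn, frame(base), selection = "CA")
  raw <- vapply(noisy, function(m) sqrt(mean(rowSums((m - base)^2))), numeric(1))
  expect_true(all(fit <= raw + 1e-9))
  expect_error(rmsd_series(tr, frame(base), selection = "ZZ"), "selection")
})

test_that("rmsd series equals per-frame superposition on synthetic data", {
  sim <- simulate_hinge_trajectory(hinge_params(n_frames = 10, seed = 8))
  tr <- sim$trajectory
  ref <- get_frame(tr, 1)
  idx <- which(tr$topology$atoms$name %in% c("N", "CA", "C"))
  w <- tr$topology$atoms$mass[idx]
  series <- rmsd_series(tr, ref)
  direct <- vapply(seq_len(n_frames(tr)), function(i)
    kabsch_superpose(tr$coords[i, idx, ], ref$coordinates[idx, ], w)$rmsd,
    numeric(1))
  expect_equal(series, direct)
})

test_that("average structure converges to the generating geometry", {
  # single frame -> that frame
  set.seed(6)
  base <- matrix(rnorm(36), 12, 3)
  tr1 <- toy_trajectory(list(base))
  expect_equal(average_structure(tr1, selection = "CA")$coordinates, base)
  # rotated copies average to zero deviation after alignment
  frames <- lapply(1:4, function(i) base %*% t(random_rotation()))
  tr2 <- toy_trajectory(frames)
  avg <- average_structure(tr2, selection = "CA")
  expect_lt(kabsch_superpose(avg$coordinates, base)$rmsd, 1e-6)
  # noisy trajectory: average within noise/sqrt(N) of truth
  nrep <- 60
  noisy <- lapply(seq_len(nrep), function(i) base + matrix(rnorm(36, sd = 0.5), 12, 3))
  avg2 <- average_structure(toy_trajectory(noisy), selection = "CA")
  expect_lt(kabsch_superpose(avg2$coordinates, base)$rmsd, 3 * 0.5 / sqrt(nrep) * sqrt(3))
})

test_that("rmsf recovers the closed-form sigma*sqrt(3) under pure noise", {
  sigma <- 1
  nf <- 400
  m <- spb_model()
  base <- m$closed$coordinates
  set.seed(9)
  frames <- lapply(seq_len(nf), function(i)
    base + matrix(rnorm(length(base), sd = sigma), nrow(base), 3))
  tr <- trajectory(m$topology, lapply(frames, frame))
  prof <- rmsf_per_residue(tr, align = FALSE)
  expect_s3_class(prof, "flexibility_profile")
  se <- stats::sd(prof$rmsf) / sqrt(length(prof$rmsf))
  expect_lt(abs(mean(prof$rmsf) - sigma * sqrt(3)), 3 * se + 0.02)
  expect_equal(prof$threshold, prof$mean + prof$sd)
})

test_that("static trajectories have zero RMSF and rigid motion cancels", {
  m <- spb_model()
  base <- m$closed$coordinates
  static <- trajectory(m$topology, lapply(1:3, function(i) frame(base)))
  prof <- rmsf_per_residue(static)
  expect_true(all(prof$rmsf < 1e-8))
  # global rigid motion of whole frames is removed by internal alignment
  set.seed(10)
  moved <- lapply(1:5, function(i) {
    frame(sweep(base %*% t(random_rotation()), 2, rnorm(3, sd = 5), "+"))
  })
  prof2 <- rmsf_per_residue(trajectory(m$topology, moved))
  expect_true(all(prof2$rmsf < 1e-6))
})

test_that("flexible regions are maximal runs above mean + sd", {
  mk_prof <- function(rmsf) {
    p <- structure(list(residue = seq_along(rmsf), rmsf = rmsf,
                        mean = mean(rmsf), sd = stats::sd(rmsf)),
                   class = "flexibility_profile")
    p$threshold <- p$mean + p$sd
    p
  }
  flat <- mk_prof(rep(1, 30))
  expect_equal(nrow(find_flexible_regions(flat)), 0L)
  spike <- mk_prof(c(rep(1, 39), 10, rep(1, 39)))
  expect_equal(find_flexible_regions(spike), data.frame(start = 40L, end = 40L))
  # spikes at 1-5 and 23-25 exceed mean + sd by construction
  v <- rep(1, 30); v[1:5] <- 8; v[23:25] <- 8
  expect_equal(find_flexible_regions(mk_prof(v)),
               data.frame(start = c(1L, 23L), end = c(5L, 25L)))
  # a profile with mean 11.4 and sd 2.9 thresholds at 14.3
  p <- mk_prof(rep(1, 10))
  p$mean <- 11.4; p$sd <- 2.9; p$threshold <- p$mean + p$sd
  expect_equal(p$threshold, 14.3)
})
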