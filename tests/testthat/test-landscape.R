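# Binned state probabilities, Boltzmann inversion and minima detection.

test_that("window selection keeps the final duration only", {
  s <- data.frame(time = 1:1000, d1 = rnorm(1000), d2 = rnorm(1000))
  w <- select_window(s, 500)
  expect_equal(range(w$time), c(501, 1000))
  expect_equal(nrow(select_window(s, 1000)), 1000L)
  expect_error(select_window(s, 0), "positive")
  expect_error(select_window(s, 2000), "full series")
  # trajectory windowing (40 frames at 0.25 ns -> final 2.5 ns = 10 frames)
  sim <- simulate_hinge_trajectory(hinge_params(n_frames = 40, seed = 30))
  tw <- select_window(sim$trajectory, 2.5)
  expect_equal(n_frames(tw), 10L)
})

test_that("binning uses half-open width-anchored bins", {
  b <- bin_states(rep(2.05, 7), rep(3.14, 7), 0.1)
  expect_equal(sum(b$counts), 7L)
  expect_equal(sum(b$counts > 0), 1L)
  # two points 0.05 apart inside one anchored bin
  b2 <- bin_states(c(2.01, 2.06), c(1, 1), 0.1)
  expect_equal(sum(b2$counts > 0), 1L)
  # edges are integer multiples of the width
  expect_equal(b2$d1_edges / 0.1, round(b2$d1_edges / 0.1), tolerance = 1e-9)
  # 20 x 20 lattice of distinct 0.1-wide cells -> 400 singleton bins
  g <- expand.grid(d1 = seq(10.05, 11.95, by = 0.1),
                   d2 = seq(20.05, 21.95, by = 0.1))
  b3 <- bin_states(g$d1, g$d2, 0.1)
  expect_equal(sum(b3$counts == 1), 400L)
  expect_equal(sum(b3$counts), 400L)
  expect_error(bin_states(numeric(0), numeric(0)), "empty")
  expect_error(bin_states(1, c(1, 2)), "equal length")
})

test_that("free energy follows -RT ln P with occupied minimum at zero", {
  th <- thermo_params()
  expect_equal(th$RT, 1.9872e-3 * 310)
  # single occupied bin: P = 1, dG = 0
  l1 <- free_energy(bin_states(rep(1, 5), rep(1, 5)), th)
  expect_equal(sum(l1$P), 1)
  expect_equal(l1$dG[l1$occupied], 0)
  # 3:1 occupancy at 310 K -> ddG = RT ln 3
  d1 <- c(rep(1.05, 3), rep(5.05, 1))
  l2 <- free_energy(bin_states(d1, rep(1, 4)), th)
  dGs <- sort(l2$dG[l2$occupied])
  expect_equal(dGs[2] - dGs[1], th$RT * log(3), tolerance = 1e-10)
  # unoccupied bins are undefined, not infinite
  expect_true(all(is.na(l2$dG[!l2$occupied])))
  expect_true(all(is.finite(l2$dG[l2$occupied])))
})

test_that("replicate pooling sums counts before normalizing", {
  a <- bin_states(1.05, 1.05)              # {A: 1}
  b <- bin_states(c(1.05, 2.05, 2.05), rep(1.05, 3))  # {A: 1, B: 2}
  l <- free_energy(a, thermo_params(), b)
  tab <- landscape_table(l)
  expect_equal(sum(tab$count), 4)
  expect_equal(tab$P[abs(tab$d1_center - 1.05) < 1e-9], 0.5)
  expect_equal(sum(l$P), 1, tolerance = 1e-12)
})

test_that("dG is invariant to count scaling and dual to P ordering", {
  set.seed(31)
  d1 <- rnorm(300, 15, 1); d2 <- rnorm(300, 14, 1)
  cnt <- bin_states(d1, d2, 0.5)
  l <- free_energy(cnt)
  scaled <- cnt; scaled$counts <- cnt$counts * 7L
  l7 <- free_energy(scaled)
  expect_equal(l$dG, l7$dG, tolerance = 1e-12)
  # monotone duality on occupied bins: higher count => lower dG
  occ <- which(l$occupied)
  expect_true(all(diff(l$dG[occ][order(l$counts[occ])]) <= 1e-12))
  expect_equal(sum(l$P), 1, tolerance = 1e-12)
})

test_that("minima detection finds constructed basins exactly", {
  # single occupied bin
  l1 <- free_energy(bin_states(1.05, 1.05))
  m1 <- find_minima(l1)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$dG, 0)
  # bowl: counts increase toward the center bin
  d1 <- c(rep(2.05, 10), rep(1.95, 2), rep(2.15, 2), rep(2.05, 2), rep(2.05, 2))
  d2 <- c(rep(2.05, 10), rep(2.05, 2), rep(2.05, 2), rep(1.95, 2), rep(2.15, 2))
  l2 <- free_energy(bin_states(d1, d2))
  m2 <- find_minima(l2)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$d1, m2$d2), c(2.05, 2.05), tolerance = 1e-9)
  # two separated basins centered inside single bins -> exactly two
  # minima (4- and 8-connected agree)
  mk <- function(center, n) cbind(rnorm(n, center[1], 0.05), rnorm(n, center[2], 0.05))
  set.seed(32)
  pts <- rbind(mk(c(15.25, 14.25), 400), mk(c(25.25, 27.25), 400))
  l3 <- free_energy(bin_states(pts[, 1], pts[, 2], 0.5))
  expect_equal(nrow(find_minima(l3, "8")), 2L)
  expect_equal(nrow(find_minima(l3, "4")), 2L)
})

test_that("persistent basin minima are robust to sampling noise", {
  # one bin -> one basin with infinite persistence
  b1 <- basin_minima(free_energy(bin_states(1.05, 1.05)))
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$persistence, Inf)
  # a noisily sampled single Gaussian basin on 0.1 A bins: the raw strict
  # minima are many (Poisson noise), the persistent basin count is one
  set.seed(35)
  l <- free_energy(bin_states(rnorm(2000, 15, 0.35), rnorm(2000, 14, 0.35), 0.1))
  expect_equal(nrow(basin_minima(l)), 1L)
  expect_gte(nrow(find_minima(l)), 1L)
  # two well-separated noisy basins -> exactly two persistent minima
  d1 <- c(rnorm(1500, 15, 0.35), rnorm(1500, 25, 0.35))
  d2 <- c(rnorm(1500, 14, 0.35), rnorm(1500, 27, 0.35))
  l2 <- free_energy(bin_states(d1, d2, 0.1))
  m2 <- basin_minima(l2)
  expect_equal(nrow(m2), 2L)
  expect_setequal(classify_frame(m2$d1, m2$d2), c("open", "closed"))
})

test_that("basin occupancies recover the Markov stationary distribution", {
  p <- hinge_params(n_frames = 10000, rate_open_to_closed = 0.5,
                    rate_closed_to_open = 0.5, seed = 33)
  sim <- simulate_hinge_trajectory(p)
  cs <- conformation_series(sim$trajectory)
  land <- free_energy(bin_states(cs$d1, cs$d2, 0.1))
  tab <- landscape_table(land)
  lab <- classify_frame(tab$d1_center, tab$d2_center)
  p_open <- sum(tab$P[lab == "open"])
  p_closed <- sum(tab$P[lab == "closed"])
  pi_open <- sim$ground_truth$stationary_occupancy[["open"]]
  se <- sqrt(pi_open * (1 - pi_open) / nrow(cs))
  expect_lt(abs(p_open - pi_open), 3 * se + 1e-3)
  expect_gt(p_open + p_closed, 0.99)  # basins capture nearly all mass
})
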