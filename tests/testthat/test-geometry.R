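test_that("dihedral angles follow the IUPAC sign convention", {
  # planar cis and anti arrangements
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  # staggered geometry built from ideal bond vectors: rotating the far
  # substituent by +60 deg about the central bond gives +60
  p2 <- c(0, 0, 0); p3 <- c(0, 0, 1.54)
  p1 <- c(1, 0, -0.5)
  th <- 60 * pi / 180
  p4 <- c(cos(th), sin(th), 1.54 + 0.5)
  expect_equal(dihedral_angle(p1, p2, p3, p4), 60, tolerance = 1e-6)
  # cross-check against an established implementation
  expect_equal(dihedral_angle(p1, p2, p3, p4),
               bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)[1],
               tolerance = 1e-9)
  # degenerate bond frame
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "degenerate")
})

test_that("dihedral reversal symmetry holds for random quads", {
  set.seed(21)
  for (i in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    a1 <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    a2 <- dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_equal(a1, a2, tolerance = 1e-9)
  }
})

test_that("radius of gyration matches a brute-force loop oracle", {
  expect_equal(radius_of_gyration(c(3, -2, 7), 12), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)),
                                  c(1, 1)), 1)
  set.seed(5)
  x <- matrix(rnorm(300, sd = 4), 100, 3)
  m <- runif(100, 1, 16)
  com <- c(sum(m * x[, 1]), sum(m * x[, 2]), sum(m * x[, 3])) / sum(m)
  acc <- 0
  for (i in 1:100) acc <- acc + m[i] * sum((x[i, ] - com)^2)
  expect_equal(radius_of_gyration(x, m), sqrt(acc / sum(m)),
               tolerance = 1e-10)
  # translation invariance
  expect_equal(radius_of_gyration(sweep(x, 2, c(5, -3, 9), "+"), m),
               radius_of_gyration(x, m), tolerance = 1e-10)
})

test_that("Kabsch superposition minimises RMSD with a proper rotation", {
  set.seed(12)
  A <- matrix(rnorm(15), 5, 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation()
  B <- A %*% t(R) + rep(c(2, -1, 4), each = 5)
  fit <- kabsch_superpose(B, A)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "3 atoms")
})

test_that("Kabsch RMSD beats a dense rotation-grid brute force", {
  set.seed(33)
  X <- matrix(rnorm(12), 4, 3); Y <- matrix(rnorm(12), 4, 3)
  best <- kabsch_superpose(X, Y)$rmsd
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  half <- seq(0, pi, length.out = 7)
  for (a in grid) for (b in half) for (g in grid) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
    R <- Rz1 %*% Ry %*% Rz2
    r <- sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
    expect_gte(r, best - 1e-9)
  }
  # agrees with an established implementation
  fit <- bio3d::fit.xyz(fixed = as.vector(t(Y)), mobile = as.vector(t(X)),
                        fixed.inds = 1:12, mobile.inds = 1:12)
  b3d <- bio3d::rmsd(as.vector(t(Y)), fit)
  expect_equal(best, b3d, tolerance = 1e-4)
})

test_that("RMSF is zero for static trajectories and analytic for a flipper", {
  atoms <- make_topology(paste0("C", 1:4), rep("C", 4))
  base <- matrix(rnorm(12, sd = 5), 4, 3)
  co <- array(rep(base, 6), c(4, 3, 6))
  traj <- trajectory(atoms, co, 10)
  expect_equal(unname(rmsf(traj)), rep(0, 4))
  # one atom alternating x = +1 / -1, alignment off
  co2 <- co
  co2[1, 1, ] <- rep(c(1, -1), 3)
  traj2 <- trajectory(atoms, co2, 10)
  out <- rmsf(traj2, align = FALSE)
  expect_equal(unname(out[1]), 1)
  expect_equal(unname(out[2:4]), rep(0, 3))
  expect_error(rmsf(traj, atom_selection = 99), "selection")
})

test_that("RMSF with alignment is invariant to global rigid motion", {
  set.seed(14)
  atoms <- make_topology(paste0("C", 1:6), rep("C", 6))
  co <- array(rnorm(6 * 3 * 8, sd = 3), c(6, 3, 8))
  traj <- trajectory(atoms, co, 10)
  ref <- rmsf(traj, align = TRUE)
  co2 <- co
  for (k in 1:8) {
    R <- random_rotation()
    co2[, , k] <- co[, , k] %*% t(R) + rep(rnorm(3, sd = 10), each = 6)
  }
  moved <- rmsf(trajectory(atoms, co2, 10), align = TRUE)
  expect_equal(unname(moved), unname(ref), tolerance = 1e-6)
})

test_that("distance series track planted separations exactly", {
  atoms <- make_topology(c("C1", "C2"), c("C", "C"))
  co <- array(0, c(2, 3, 5))
  co[2, 1, ] <- 5
  traj <- trajectory(atoms, co, 10)
  expect_equal(distance_series(traj, 1, 2), rep(5, 5))
  expect_equal(distance_series(traj, 1, 1), rep(0, 5))
  b <- gen_breathing_complex(n_frames = 300, period_frames = 60,
                             amplitude = 2.5, seed = 2, noise_sd = 0)
  d <- distance_series(b$traj, b$tip_a, b$tip_b)
  t0 <- seq_len(300) - 1
  expect_equal(d, 20 + 2.5 * sin(2 * pi * t0 / 60), tolerance = 1e-9)
})

test_that("dominant period finds the spectral peak to bin resolution", {
  t0 <- 0:1199
  x <- sin(2 * pi * t0 / 120)
  pe <- dominant_period(x, frame_interval = 10)
  expect_false(pe$aperiodic)
  expect_equal(pe$period, 1200)       # 120 frames x 10 ps
  expect_true(dominant_period(rep(3, 64), 10)$aperiodic)
  expect_error(dominant_period(1:5, 1), "8 samples")
})
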