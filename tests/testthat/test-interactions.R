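test_that("hydrogen-bond detection honours distance and angle cuts", {
  # linear N-H...O at 2.9 A donor-acceptor, 180 deg at the hydrogen
  top <- make_topology(c("N", "H", "O"), c("N", "H", "O"),
                       resnames = c("AMD", "AMD", "CRB"),
                       resids = c(1, 1, 2))
  fr <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  hb <- find_hbonds(fr, top)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, 1); expect_equal(hb$acceptor, 3)
  expect_equal(hb$angle, 180)
  # too far: not detected
  fr2 <- fr; fr2[3, 1] <- 5.0
  expect_equal(nrow(find_hbonds(fr2, top)), 0)
  # bent below the angle cut: not detected
  fr3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.4, 2.2, 0))
  expect_equal(nrow(find_hbonds(fr3, top)), 0)
  # no hydrogens is a hard error with advice
  top_noh <- make_topology(c("N", "O"), c("N", "O"))
  expect_error(find_hbonds(fr[c(1, 3), ], top_noh), "hydrogens")
})

test_that("detection equals a brute-force oracle on 1000 random geometries", {
  # one donor N with one H, one acceptor O, random placements
  top <- make_topology(c("N", "H", "O"), c("N", "H", "O"),
                       resnames = c("AMD", "AMD", "CRB"),
                       resids = c(1, 1, 2))
  crit <- hbond_criteria()
  set.seed(77)
  n_hit_impl <- 0; n_hit_oracle <- 0
  for (i in 1:1000) {
    N <- c(0, 0, 0)
    H <- N + runif(3, -1, 1) * 0.65       # within covalent range of N
    O <- runif(3, -4, 4)
    fr <- rbind(N, H, O)
    impl <- nrow(find_hbonds(fr, top, crit)) > 0
    # independent direct evaluation of the criteria
    d_da <- sqrt(sum((O - N)^2))
    v1 <- N - H; v2 <- O - H
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    oracle <- d_da <= crit$d_max && ang >= crit$angle_min &&
      sqrt(sum((H - N)^2)) <= crit$h_bond_dist && d_da > 0
    expect_identical(impl, oracle)
    n_hit_impl <- n_hit_impl + impl; n_hit_oracle <- n_hit_oracle + oracle
  }
  expect_gt(n_hit_impl, 0)                # the sweep exercised both outcomes
  expect_lt(n_hit_impl, 1000)
})

test_that("multiple hydrogens on one donor are handled without double counting", {
  top <- make_topology(c("N", "H1", "H2", "O"), c("N", "H", "H", "O"),
                       resnames = c("AMD", "AMD", "AMD", "CRB"),
                       resids = c(1, 1, 1, 2))
  # both hydrogens roughly aligned toward the acceptor
  fr <- rbind(c(0, 0, 0), c(0.95, 0.2, 0), c(0.95, -0.2, 0), c(2.9, 0, 0))
  hb <- find_hbonds(fr, top)
  expect_equal(nrow(hb), 2)               # one triple per hydrogen
  expect_equal(anyDuplicated(hb[, c("donor", "hydrogen", "acceptor")]), 0)
})

test_that("salt bridges use a closed distance boundary", {
  top <- make_topology(c("OD1", "NH1"), c("O", "N"),
                       resnames = c("ASP", "ARG"), resids = c(1, 2))
  place <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  expect_equal(nrow(find_salt_bridges(place(3.5), top)), 1)
  expect_equal(nrow(find_salt_bridges(place(4.5), top)), 0)
  expect_equal(nrow(find_salt_bridges(place(4.0), top)), 1)  # boundary in
  # non-charged residues are ignored
  top2 <- make_topology(c("OD1", "NH1"), c("O", "N"),
                        resnames = c("SER", "SER"), resids = c(1, 2))
  expect_equal(nrow(find_salt_bridges(place(3.0), top2)), 0)
})

test_that("occupancy bookkeeping is exact and episode-consistent", {
  toy <- gen_toy_complex(planted_contacts = "hbond",
                         occupancy_schedule = 1.0, n_frames = 12, seed = 1)
  occ <- occupancy(toy$traj, toy$topology)
  expect_equal(occ$occupancy, 100)
  expect_equal(occ$n_episodes, 1L)

  toy2 <- gen_toy_complex(planted_contacts = "hbond",
                          occupancy_schedule = 123 / 400, n_frames = 400,
                          seed = 9)
  occ2 <- occupancy(toy2$traj, toy2$topology)
  expect_equal(occ2$occupancy, 30.75)
  # episodes partition the present-frame set exactly
  ep <- occ2$episodes[[1]]
  frames <- unlist(lapply(seq_len(nrow(ep)),
                          function(i) ep[i, 1]:ep[i, 2]))
  expect_equal(sort(frames), toy2$receipt$true_parameters$present_frames[[1]])
  expect_equal(length(frames), 123)

  # frame-order permutation invariance of the occupancy percentage
  perm <- sample(n_frames(toy2$traj))
  traj_p <- trajectory(toy2$traj$atoms, toy2$traj$coords[, , perm], 10)
  occ_p <- occupancy(traj_p, toy2$topology)
  expect_equal(occ_p$occupancy, occ2$occupancy)

  empty <- trajectory(toy$traj$atoms,
                      array(0, c(nrow(toy$traj$atoms), 3, 0)), 10)
  expect_error(occupancy(empty, toy$topology), "no frames")
})

test_that("planted hydrogen bonds and salt bridges are recovered independently", {
  toy <- gen_toy_complex(planted_contacts = c("hbond", "salt_bridge"),
                         occupancy_schedule = c(0.25, 0.75), n_frames = 80,
                         seed = 4)
  occ <- occupancy(toy$traj, toy$topology)
  hb <- occ[occ$type == "hbond", ]
  sb <- occ[occ$type == "salt_bridge", ]
  expect_equal(hb$occupancy, 25)
  expect_equal(sb$occupancy, 75)
  roll <- attr(occ, "residues")
  expect_true(all(c("hbond", "salt_bridge") %in% roll$type))
})
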