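test_that("state assignment maps the canonical wells and wraps correctly", {
  expect_true(all(assign_states(rep(60, 10)) == "g+"))
  expect_true(all(assign_states(rep(-60, 10)) == "g-"))
  expect_true(all(assign_states(rep(180, 10)) == "t"))
  # crafted series crossing each default boundary once, labels by hand
  s <- c(10, 110, 130, 175, -175, -130, -110, -10, 5, 119)
  expect_equal(as.character(assign_states(s)),
               c("g+", "g+", "t", "t", "t", "t", "g-", "g-", "g+", "g+"))
  # circular wrap: shifting by 360 changes nothing
  expect_equal(as.character(assign_states(s + 360)),
               as.character(assign_states(s)))
  # populations sum to one exactly
  expect_equal(sum(attr(assign_states(s), "populations")), 1)
  # boundary membership is (lo, hi]: 120 is still g+, 120.0001 is t
  expect_equal(as.character(assign_states(c(120, 120.0001))), c("g+", "t"))
})

test_that("rotamer schemes must partition the circle", {
  expect_error(rotamer_scheme(states = c("a", "b"),
                              boundaries = list(rbind(c(0, 100)),
                                                rbind(c(100, 200)))),
               "cover")
  expect_error(rotamer_scheme(states = c("a", "b"),
                              boundaries = list(rbind(c(-180, 30)),
                                                rbind(c(20, 180)))),
               "cover|overlap")
})

test_that("transition rates reproduce hand counts and flag unvisited states", {
  lab <- rep(c("A", "B"), 50)              # strictly alternating, 100 frames
  tr <- transition_rates(lab, frame_interval = 10, min_dwell = 1)
  # 50 A->B transitions over 0.5 ns in A
  expect_equal(tr$k["A", "B"], 100)
  expect_equal(tr$k["B", "A"], 98)         # 49 B->A over 0.5 ns
  expect_equal(sum(tr$counts), 99)

  one <- transition_rates(rep("A", 60), frame_interval = 10, min_dwell = 1,
                          states = c("A", "B"))
  expect_equal(sum(one$counts), 0)
  expect_equal(one$k["A", "B"], 0)         # visited, no exits: rate 0
  expect_true(is.na(one$k["B", "A"]))      # never visited: undefined

  # recrossing filter: a single-frame blip is chatter under min_dwell = 2
  blip <- c(rep("A", 10), "B", rep("A", 10))
  expect_equal(sum(transition_rates(blip, 10, min_dwell = 2)$counts), 0)
  expect_equal(sum(transition_rates(blip, 10, min_dwell = 1)$counts), 2)
})

test_that("rates recover a simulated 2-state chain within 3 standard errors", {
  # independent discrete-chain oracle: geometric dwells from the exact
  # per-step transition probabilities of a (5/ns, 10/ns) process at 10 ps
  k_ab <- 5; k_ba <- 10; dt <- 10          # 1/ns, 1/ns, ps
  p_ab <- k_ab * dt / 1000; p_ba <- k_ba * dt / 1000
  set.seed(8)
  n_runs <- 12000
  dwell_a <- 1 + rgeom(n_runs, p_ab)
  dwell_b <- 1 + rgeom(n_runs, p_ba)
  lab <- rep(rep(c("A", "B"), n_runs), times = as.vector(rbind(dwell_a,
                                                               dwell_b)))
  lab <- lab[seq_len(min(length(lab), 1e6))]
  tr <- transition_rates(lab, frame_interval = dt, min_dwell = 1)
  n_ab <- tr$counts["A", "B"]; n_ba <- tr$counts["B", "A"]
  # Poisson-count standard errors on the rate estimates
  expect_lt(abs(tr$k["A", "B"] - k_ab), 3 * k_ab / sqrt(n_ab))
  expect_lt(abs(tr$k["B", "A"] - k_ba), 3 * k_ba / sqrt(n_ba))
})

test_that("pooling label sequences sums counts and dwell times", {
  l1 <- rep(c("A", "B"), 50)
  l2 <- rep(c("A", "B"), 30)
  pooled <- transition_rates(list(l1, l2), 10, min_dwell = 1)
  single <- transition_rates(l1, 10, min_dwell = 1)
  expect_equal(pooled$counts["A", "B"], 80)
  expect_equal(pooled$time_in_state[["A"]],
               single$time_in_state[["A"]] + 0.3)
})

test_that("activation barriers obey the Arrhenius difference identity", {
  k <- matrix(c(NA, 10, 1, 10, NA, 10, 10, 10, NA), 3, 3, byrow = TRUE,
              dimnames = list(from = c("a", "b", "c"),
                              to = c("a", "b", "c")))
  rm_ <- make_rate_matrix(k)
  bt <- activation_barriers(rm_, temperature = 310)
  rt <- endstate_constants()$r_kcal * 310
  # ratio-10 pair differs by RT ln 10 = 1.418 kcal/mol at 310 K
  expect_equal(bt$e_a["a", "c"] - bt$e_a["a", "b"], rt * log(10),
               tolerance = 1e-6)
  expect_equal(rt * log(10), 1.418, tolerance = 1e-3)
  # datum invariance: differences survive a datum change, values shift
  bt2 <- activation_barriers(rm_, 310, datum_rule = "fixed_c", c_value = 5)
  d1 <- bt$e_a - min(bt$e_a, na.rm = TRUE)
  d2 <- bt2$e_a - min(bt2$e_a, na.rm = TRUE)
  expect_equal(d1, d2, tolerance = 1e-12)
  # min_zero puts the smallest barrier at exactly zero
  expect_equal(min(bt$e_a, na.rm = TRUE), 0)
})

test_that("uniform rates give the uniform barrier pattern of a trimethyl group", {
  k <- matrix(7, 3, 3, dimnames = list(from = c("g+", "t", "g-"),
                                       to = c("g+", "t", "g-")))
  diag(k) <- NA
  bt <- activation_barriers(make_rate_matrix(k), 310)
  off <- bt$e_a[!is.na(bt$e_a)]
  expect_length(off, 6)
  expect_true(all(off == off[1]))
  # zero rate reports an infinite barrier, not a number
  k2 <- k; k2["g+", "t"] <- 0
  bt2 <- activation_barriers(make_rate_matrix(k2), 310)
  expect_true(is.infinite(bt2$e_a["g+", "t"]))
})

test_that("Boltzmann inversion is flat for uniform angles and finds 3 wells", {
  set.seed(3)
  u <- runif(72000, -180, 180)
  prof <- suppressWarnings(torsional_profile(u, 310, bin_width = 5))
  rt <- endstate_constants()$r_kcal * 310
  n_per_bin <- length(u) / nrow(prof)
  expect_lt(max(prof$energy) - min(prof$energy), 3 / sqrt(n_per_bin) * rt * 3)
  expect_true(all(prof$count > 0))

  # a symmetric trimethyl-like landscape shows minima near 60, 180, -60
  spec <- torsion_potential_spec(barrier_heights = c(2, 2, 2))
  g <- gen_dihedral_trajectory(spec, n_steps = 3e5, dt = 0.02,
                               scheme = "langevin", seed = 6)
  prof2 <- torsional_profile(g$series, 310, bin_width = 10)
  for (centre in c(60, 180, -60)) {
    near <- prof2[ang_diff(prof2$theta, centre) <= 20, ]
    expect_lt(min(near$energy, na.rm = TRUE), 0.35)
  }
  # empty bins are NA-flagged, never zero
  narrow <- torsional_profile(rnorm(5000, 60, 5), 310, bin_width = 5)
  expect_true(anyNA(narrow$energy))
  expect_warning(torsional_profile(rnorm(100, 60, 5)), "1000")
})
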