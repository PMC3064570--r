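test_that("nonbonded terms hit their closed forms", {
  # two +1 charges at 332.0636/100 A apart: exactly 100 kcal/mol
  top <- make_topology(c("C1", "C2"), c("C", "C"), charges = 1,
                       lj_sigma = 0.5, lj_epsilon = 0)
  fr <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  nb <- mm_nonbonded(fr, top)
  expect_equal(nb$e_coulomb, 100, tolerance = 1e-4)
  # dielectric divides the Coulomb term
  expect_equal(mm_nonbonded(fr, top, dielectric_internal = 4)$e_coulomb,
               25, tolerance = 1e-4)
  # LJ zero crossing at sigma, well depth -eps at 2^(1/6) sigma
  top2 <- make_topology(c("C1", "C2"), c("C", "C"), charges = 0,
                        lj_sigma = 3.4, lj_epsilon = 0.25)
  at <- function(r) mm_nonbonded(rbind(c(0, 0, 0), c(r, 0, 0)), top2)
  expect_equal(at(3.4)$e_vdw, 0, tolerance = 1e-12)
  expect_equal(at(2^(1 / 6) * 3.4)$e_vdw, -0.25, tolerance = 1e-12)
  # exclusions and 1-4 scaling
  excl <- cbind(1, 2)
  expect_equal(mm_nonbonded(fr, top, pairs_excluded = excl)$e_coulomb, 0)
  expect_equal(mm_nonbonded(fr, top, pairs_14 = excl)$e_coulomb,
               100 / 1.2, tolerance = 1e-4)
  top_bad <- top; top_bad$lj_sigma[2] <- NA
  expect_error(mm_nonbonded(fr, top_bad), "LJ parameters")
})

test_that("bonded terms follow the AMBER conventions", {
  top <- make_topology(c("C1", "C2", "C3", "C4"), rep("C", 4))
  fr <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0), c(0, 1.5, 0.9))
  # bond at equilibrium: zero; stretched by delta: k delta^2 (no 1/2)
  bt <- list(bonds = data.frame(i = 1, j = 2, k = 300, r0 = 1.5))
  expect_equal(mm_bonded(fr, top, bt)$e_bond, 0)
  bt2 <- list(bonds = data.frame(i = 1, j = 2, k = 300, r0 = 1.2))
  expect_equal(mm_bonded(fr, top, bt2)$e_bond, 300 * 0.3^2,
               tolerance = 1e-10)
  # right angle with theta0 = 90: zero
  at <- list(angles = data.frame(i = 1, j = 2, k_atom = 3, k = 50,
                                 theta0 = 90))
  expect_equal(mm_bonded(fr, top, at)$e_angle, 0, tolerance = 1e-12)
  # 3-fold torsion with phase 0 at phi = 60: V (1 + cos 180) = 0
  p2 <- c(0, 0, 0); p3 <- c(0, 0, 1.5); p1 <- c(1, 0, -0.5)
  th <- 60 * pi / 180
  p4 <- c(cos(th), sin(th), 2)
  fr2 <- rbind(p1, p2, p3, p4)
  tor <- list(torsions = data.frame(i = 1, j = 2, k_atom = 3, l = 4,
                                    v = 2.5, n = 3, phase = 0))
  expect_equal(mm_bonded(fr2, top, tor)$e_torsion, 0, tolerance = 1e-9)
  bad <- list(bonds = data.frame(i = 1, j = 99, k = 1, r0 = 1))
  expect_error(mm_bonded(fr, top, bad), "undefined atom")
})

test_that("SASA matches spheres, additivity and a high-density oracle", {
  one <- sasa(c(0, 0, 0), radii = 1.6)
  expect_equal(attr(one, "total"), 4 * pi * 3^2, tolerance = 0.005)
  # far-apart atoms are additive
  two <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.6, 1.9))
  expect_equal(attr(two, "total"), 4 * pi * (3^2 + 3.3^2),
               tolerance = 0.005)
  # fused dimer against a denser sampling of the same construction
  fr <- rbind(c(0, 0, 0), c(2.2, 0, 0))
  coarse <- attr(sasa(fr, c(1.6, 1.6), n_points = 960), "total")
  dense <- attr(sasa(fr, c(1.6, 1.6), n_points = 100000), "total")
  expect_lt(abs(coarse - dense) / dense, 0.01)
  # sampling error shrinks with point density
  very_coarse <- attr(sasa(fr, c(1.6, 1.6), n_points = 60), "total")
  expect_lte(abs(coarse - dense), abs(very_coarse - dense) + 1e-9)
})

test_that("the nonpolar term is linear in SASA with the published sets", {
  expect_equal(nonpolar_solvation(0, 0.00542, 0.92), 0.92)
  expect_equal(nonpolar_solvation(1000, 0.005, 0.0), 5.0)
  expect_equal(nonpolar_solvation(2000, 0.005, 0.0),
               2 * nonpolar_solvation(1000, 0.005, 0.0))
})

test_that("GB reduces to the Born formula and the Still pair expression", {
  # single ion: exact Born formula
  q <- 1.3; a <- 2.1
  e <- gb_polar(c(0, 0, 0), charges = q, gb_radii = a, eps_in = 1,
                eps_out = 80, offset = 0)
  born <- -(332.0636 / 2) * (1 - 1 / 80) * q^2 / a
  expect_equal(as.numeric(e), born, tolerance = 1e-6)
  # all charges zero
  fr <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0))
  expect_equal(as.numeric(gb_polar(fr, charges = rep(0, 3),
                                   gb_radii = rep(1.5, 3))), 0)
  # two distant ions: independent evaluation of the Still expression
  fr2 <- rbind(c(0, 0, 0), c(40, 0, 0))
  qs <- c(1, -1); radii <- c(1.5, 2.0)
  e2 <- gb_polar(fr2, qs, radii, eps_in = 1, eps_out = 80)
  B <- attr(e2, "born_radii")
  pref <- -(332.0636 / 2) * (1 - 1 / 80)
  r2 <- 1600
  fgb <- sqrt(r2 + B[1] * B[2] * exp(-r2 / (4 * B[1] * B[2])))
  oracle <- pref * (qs[1]^2 / B[1] + qs[2]^2 / B[2] +
                      2 * qs[1] * qs[2] / fgb)
  expect_equal(as.numeric(e2), oracle, tolerance = 1e-10)
  # at 40 A the cross term is essentially a screened Coulomb interaction
  expect_equal(as.numeric(e2) - pref * (qs[1]^2 / B[1] + qs[2]^2 / B[2]),
               2 * pref * qs[1] * qs[2] / 40, tolerance = 1e-4)
  expect_error(gb_polar(fr2, qs, radii, eps_in = 80, eps_out = 4),
               "eps_out")
})

test_that("descreening grows Born radii for buried atoms", {
  # a neighbour displaces solvent, pushing the effective radius above the
  # intrinsic (offset-reduced) radius; an infinitely distant neighbour has
  # no effect
  lone <- born_radii(c(0, 0, 0), 1.5)
  pair <- born_radii(rbind(c(0, 0, 0), c(3, 0, 0)), c(1.5, 1.5))
  expect_gt(pair[1], lone)
  far <- born_radii(rbind(c(0, 0, 0), c(500, 0, 0)), c(1.5, 1.5))
  expect_equal(far[1], lone, tolerance = 1e-6)
})

test_that("binding assembly satisfies every arithmetic identity exactly", {
  set.seed(10)
  bs <- binding_summary(d_ele = rnorm(1), d_vdw = rnorm(1),
                        d_int = rnorm(1), d_sa = rnorm(1),
                        d_polar = rnorm(1))
  t <- bs$terms
  expect_identical(t[["d_gas"]], t[["d_ele"]] + t[["d_vdw"]] + t[["d_int"]])
  expect_identical(t[["d_solv"]], t[["d_sa"]] + t[["d_polar"]])
  expect_identical(t[["d_enthalpy"]], t[["d_gas"]] + t[["d_solv"]])
  expect_identical(t[["d_ele_plus_polar"]], t[["d_ele"]] + t[["d_polar"]])
  expect_error(binding_summary(1, 1, d_int = 0.5, 1, 1,
                               protocol = "single_trajectory"),
               "single")
})

test_that("no-interaction tables give zero differences; planted means recover", {
  set.seed(11)
  comps <- c("e_bond", "e_angle", "e_torsion", "e_vdw", "e_coulomb",
             "g_polar", "g_nonpolar")
  rr <- as.data.frame(setNames(lapply(comps, function(x) rnorm(50)), comps))
  ll <- as.data.frame(setNames(lapply(comps, function(x) rnorm(50)), comps))
  cc <- rr + ll
  mk <- function(df, sp) energy_table(cbind(frame = 0:49, df), sp)
  bs <- assemble_binding(mk(cc, "complex"), mk(rr, "receptor"),
                         mk(ll, "ligand"))
  expect_equal(max(abs(bs$terms)), 0, tolerance = 1e-12)

  # generator triplet with planted mean differences, n = 2400
  mC <- c(e_bond = 12, e_angle = 30, e_torsion = 8, e_vdw = -85,
          e_coulomb = -310, g_polar = 255, g_nonpolar = -8.2)
  mR <- c(e_bond = 8, e_angle = 22, e_torsion = 5, e_vdw = -38,
          e_coulomb = -160, g_polar = 130, g_nonpolar = -4.4)
  mL <- c(e_bond = 1, e_angle = 4, e_torsion = 1, e_vdw = -6,
          e_coulomb = -45, g_polar = 32, g_nonpolar = -1.6)
  sds <- setNames(rep(3, 7), names(mC))
  tc <- gen_energy_table(mC, sds, 0, 2400, seed = 21)
  tr <- gen_energy_table(mR, sds, 0, 2400, seed = 22,
                         species_label = "receptor")
  tl <- gen_energy_table(mL, sds, 0, 2400, seed = 23,
                         species_label = "ligand")
  bs2 <- assemble_binding(tc, tr, tl)
  truth <- c(d_ele = -105, d_vdw = -41, d_sa = -2.2, d_polar = 93)
  for (nm in names(truth))
    expect_lt(abs(bs2$terms[[nm]] - truth[[nm]]), 3 * bs2$se[[nm]])
  expect_equal(bs2$terms[["d_int"]],
               (12 + 30 + 8) - (8 + 22 + 5) - (1 + 4 + 1),
               tolerance = 3 * bs2$se[["d_int"]])
})

test_that("single-trajectory assembly cancels internal terms to exactly zero", {
  set.seed(12)
  comps <- c("e_bond", "e_angle", "e_torsion", "e_vdw", "e_coulomb",
             "g_polar", "g_nonpolar")
  rr <- as.data.frame(setNames(lapply(comps, function(x) rnorm(40)), comps))
  ll <- as.data.frame(setNames(lapply(comps, function(x) rnorm(40)), comps))
  cc <- rr + ll       # receptor/ligand extracted from complex snapshots
  mk <- function(df, sp) energy_table(cbind(frame = 0:39, df), sp)
  bs <- assemble_binding(mk(cc, "complex"), mk(rr, "receptor"),
                         mk(ll, "ligand"), protocol = "single_trajectory")
  expect_identical(bs$terms[["d_int"]], 0)
  expect_identical(bs$se[["d_int"]], 0)
})

test_that("per-residue decomposition conserves the enthalpy and splits pairs", {
  # two residues, one pair interaction of -2: each gets -1
  top <- make_topology(c("CA", "CB"), c("C", "C"), resnames = c("ALA", "LEU"),
                       resids = c(1, 2))
  pw <- data.frame(atom_a = 1, atom_b = 2, energy = -2)
  dec <- per_residue_decomposition(pw, top)
  expect_equal(dec$total, c(-1, -1))
  expect_equal(dec$backbone + dec$side_chain, dec$total)
  expect_equal(dec$backbone, c(-1, 0))   # CA backbone, CB side chain

  # random 5-residue toy system against a brute-force re-aggregation
  set.seed(13)
  top5 <- make_topology(sample(c("CA", "CB", "N", "O", "CG"), 15, TRUE),
                        rep("C", 15),
                        resnames = rep(c("ALA", "GLY", "SER", "LEU", "THR"),
                                       each = 3),
                        resids = rep(1:5, each = 3))
  pw5 <- data.frame(atom_a = sample(15, 60, TRUE),
                    atom_b = sample(15, 60, TRUE),
                    frame = sample(0:2, 60, TRUE),
                    energy = rnorm(60))
  dec5 <- per_residue_decomposition(pw5, top5)
  # conservation: residue totals sum to the frame-averaged total energy
  expect_equal(sum(dec5$total), sum(pw5$energy) / 3, tolerance = 1e-10)
  # independent loop oracle
  oracle <- setNames(numeric(5), paste0(c("ALA", "GLY", "SER", "LEU", "THR"),
                                        1:5))
  for (r in seq_len(nrow(pw5))) {
    ra <- paste0(top5$resname[pw5$atom_a[r]], top5$resid[pw5$atom_a[r]])
    rb <- paste0(top5$resname[pw5$atom_b[r]], top5$resid[pw5$atom_b[r]])
    if (pw5$atom_a[r] == pw5$atom_b[r]) {
      oracle[ra] <- oracle[ra] + pw5$energy[r] / 3
    } else {
      oracle[ra] <- oracle[ra] + pw5$energy[r] / 2 / 3
      oracle[rb] <- oracle[rb] + pw5$energy[r] / 2 / 3
    }
  }
  expect_equal(dec5$total[match(names(oracle), dec5$residue)],
               unname(oracle), tolerance = 1e-12)
  expect_error(per_residue_decomposition(
    data.frame(atom_a = 1, atom_b = 99, energy = 1), top), "residue")
})

test_that("hot-spot calling uses an inclusive -1.0 kcal/mol boundary", {
  contrib <- data.frame(residue = c("Asn940", "Edge", "JustOut", "Tyr973"),
                        total = c(-3.88, -1.00, -0.99, -0.6))
  hs <- call_hotspots(contrib)
  expect_equal(hs$residue, c("Asn940", "Edge"))
  expect_false("Tyr973" %in% hs$residue)
  expect_error(call_hotspots(contrib, threshold = 0.5), "negative")
})
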