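## Seeded synthetic-data generators for every input class the pipeline
## consumes: dihedral trajectories with known kinetics, per-snapshot energy
## tables with known means, toy complexes with planted hydrogen bonds and
## salt bridges, and a two-lobe "breathing" trajectory with a known period.
##
## Every generator draws from its own RNG stream (the global RNG state is
## saved and restored) and returns a receipt recording the seed and the
## exact ground-truth parameters, so closed-loop estimator tests can compare
## against truth.

## Evaluate expr with a locally seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Torsional potential specification
#'
#' Describes a periodic 1D potential with wells at the canonical rotamer
#' centres.  \code{well_depths} are the energies of the three minima
#' (kcal/mol, relative; 0 = deepest possible) and \code{barrier_heights}
#' the energies of the barrier tops between circularly adjacent wells, in
#' the order g+/t (top near 120 deg), t/g- (near -120 deg), g-/g+ (near 0
#' deg) for the default centres 60, 180, -60.
#'
#' @param well_centers degrees (default 60, 180, -60).
#' @param well_depths kcal/mol per well, >= 0.
#' @param barrier_heights kcal/mol per adjacent-well pair; each must exceed
#'   both flanking well energies.
#' @param temperature K.
#' @return Object of class \code{torsion_potential_spec}.
#' @export
torsion_potential_spec <- function(well_centers = c(60, 180, -60),
                                   well_depths = c(0, 0, 0),
                                   barrier_heights = c(3, 3, 3),
                                   temperature = 310) {
  stopifnot(length(well_centers) == 3, length(well_depths) == 3,
            length(barrier_heights) == 3, all(well_depths >= 0))
  wc <- wrap_angle(well_centers)
  for (b in seq_len(3)) {
    flank <- c(well_depths[b], well_depths[b %% 3 + 1])
    if (barrier_heights[b] <= max(flank))
      stop("barrier ", b, " does not exceed its flanking well energies")
  }
  structure(list(well_centers = wc, well_depths = well_depths,
                 barrier_heights = barrier_heights,
                 temperature = temperature),
            class = "torsion_potential_spec")
}

## Fit a smooth periodic potential through the spec's wells and barriers:
## truncated Fourier series (orders 1..4) constrained to hit the well
## energies with zero slope at the well centres and the barrier energies at
## the inter-well midpoints.  Returns value/gradient closures (degrees in,
## kcal/mol out).
torsion_potential <- function(spec) {
  wc <- spec$well_centers
  mid <- function(a, b) {          # circular midpoint moving a -> b (ccw)
    d <- (b - a) %% 360
    wrap_angle(a + d / 2)
  }
  ## adjacency order: well 1 -> 2 -> 3 -> 1 counter-clockwise by spec order
  mids <- c(mid(wc[1], wc[2]), mid(wc[2], wc[3]), mid(wc[3], wc[1]))
  kmax <- 4
  basis <- function(th) {          # th degrees -> value basis row
    tr <- th * pi / 180
    c(1, as.vector(rbind(cos(outer(tr, 1:kmax)), sin(outer(tr, 1:kmax)))))
  }
  dbasis <- function(th) {         # d/dtheta (per degree)
    tr <- th * pi / 180
    c(0, as.vector(rbind(-(1:kmax) * sin(outer(tr, 1:kmax)),
                         (1:kmax) * cos(outer(tr, 1:kmax))))) * pi / 180
  }
  A <- rbind(t(vapply(wc, basis, numeric(2 * kmax + 1))),
             t(vapply(mids, basis, numeric(2 * kmax + 1))),
             t(vapply(wc, dbasis, numeric(2 * kmax + 1))))
  b <- c(spec$well_depths, spec$barrier_heights, rep(0, 3))
  coef <- solve(A, b)
  list(
    value = function(th) {
      tr <- th * pi / 180
      out <- rep(coef[1], length(th))
      for (k in 1:kmax)
        out <- out + coef[2 * k] * cos(k * tr) + coef[2 * k + 1] * sin(k * tr)
      out
    },
    grad = function(th) {
      tr <- th * pi / 180
      out <- numeric(length(th))
      for (k in 1:kmax)
        out <- out + (-coef[2 * k] * k * sin(k * tr) +
                        coef[2 * k + 1] * k * cos(k * tr))
      out * pi / 180
    },
    coef = coef, mids = mids)
}

## Arrhenius rates (1/ns) implied by a spec: k(i->j) over adjacent pairs,
## attempt frequency nu0.
spec_rates <- function(spec, attempt_rate = 50) {
  rt <- R_KCAL * spec$temperature
  wc <- spec$well_centers
  lab <- c("g+", "t", "g-")[order(match(wc, spec$well_centers))]
  ## barrier b sits between well b and well (b %% 3) + 1
  k <- matrix(0, 3, 3, dimnames = list(from = c("w1", "w2", "w3"),
                                       to = c("w1", "w2", "w3")))
  for (b in 1:3) {
    i <- b; j <- b %% 3 + 1
    k[i, j] <- attempt_rate *
      exp(-(spec$barrier_heights[b] - spec$well_depths[i]) / rt)
    k[j, i] <- attempt_rate *
      exp(-(spec$barrier_heights[b] - spec$well_depths[j]) / rt)
  }
  k
}

#' Generate a synthetic dihedral trajectory
#'
#' Two schemes over a 3-well torsional landscape:
#' \describe{
#'   \item{markov}{continuous-time jump process between the wells with
#'     Arrhenius rates derived from the spec (or supplied directly via
#'     \code{rates}); emitted angles are the well centre plus Gaussian
#'     jitter (sd \code{jitter_sd}) so state assignment is exercised with
#'     realistic within-well noise.}
#'   \item{langevin}{overdamped (Brownian) dynamics on a smooth periodic
#'     potential interpolating the spec's wells and barriers, integrated
#'     with Euler-Maruyama; samples the Boltzmann distribution of that
#'     potential for long runs.}
#' }
#'
#' @param spec a \code{\link{torsion_potential_spec}}.
#' @param n_steps number of emitted samples.
#' @param dt sample spacing, ps.
#' @param scheme \code{"markov"} or \code{"langevin"}.
#' @param seed integer RNG seed.
#' @param rates optional 3x3 generator rate matrix (1/ns) overriding the
#'   Arrhenius rates (markov scheme).
#' @param attempt_rate Arrhenius prefactor, 1/ns (markov scheme).
#' @param jitter_sd within-well angular jitter sd, degrees (markov scheme).
#' @param friction Langevin friction gamma, kcal ps mol^-1 deg^-2; the
#'   diffusion constant is RT/gamma (langevin scheme).
#' @return List with \code{series} (a \code{dihedral_series}) and
#'   \code{receipt} (seed, scheme and the exact ground-truth parameters:
#'   generator rates for markov; potential coefficients and the true
#'   minima/depths on a fine grid for langevin).
#' @export
gen_dihedral_trajectory <- function(spec, n_steps, dt = 1,
                                    scheme = c("markov", "langevin"),
                                    seed = 1, rates = NULL,
                                    attempt_rate = 50, jitter_sd = 10,
                                    friction = 1e-3) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "torsion_potential_spec"), n_steps >= 2, dt > 0)
  wc <- spec$well_centers
  if (scheme == "markov") {
    k <- rates %||% spec_rates(spec, attempt_rate)   # 1/ns
    diag(k) <- 0
    out_rate <- rowSums(k) / 1000                    # 1/ps
    total_t <- n_steps * dt
    angles <- with_seed(seed, {
      st <- integer(0); tt <- numeric(0)
      s <- sample.int(3, 1)
      t_now <- 0
      while (t_now < total_t) {
        st <- c(st, s); tt <- c(tt, t_now)
        if (out_rate[s] <= 0) break
        t_now <- t_now + stats::rexp(1, out_rate[s])
        s <- sample.int(3, 1, prob = k[s, ] / sum(k[s, ]))
      }
      samp_t <- (seq_len(n_steps) - 1) * dt
      state_at <- st[findInterval(samp_t, tt)]
      wrap_angle(wc[state_at] + stats::rnorm(n_steps, 0, jitter_sd))
    })
    receipt <- list(seed = seed, scheme = "markov",
                    true_parameters = list(spec = spec, rates_per_ns = k,
                                           jitter_sd = jitter_sd, dt = dt))
  } else {
    pot <- torsion_potential(spec)
    rt <- R_KCAL * spec$temperature
    ## explicit Euler-Maruyama stability: drift must not overshoot a well
    grid <- seq(-180, 180, by = 0.5)
    g <- pot$grad(grid)
    curv <- max(abs(diff(g) / 0.5))          # ~ max |E''| per deg^2
    if (dt > friction / curv)
      stop(sprintf("langevin time step too large for stability: dt = %g > gamma/max|E''| = %g ps",
                   dt, friction / curv))
    noise_sd <- sqrt(2 * rt * dt / friction)
    angles <- with_seed(seed, {
      th <- numeric(n_steps)
      th[1] <- wc[which.min(spec$well_depths)]
      xi <- stats::rnorm(n_steps - 1, 0, noise_sd)
      for (t in 2:n_steps) {
        th[t] <- th[t - 1] - pot$grad(th[t - 1]) / friction * dt + xi[t - 1]
      }
      wrap_angle(th)
    })
    ev <- pot$value(grid)
    ## circular local-minimum detection (the grid endpoints coincide)
    gv <- ev[-length(ev)]
    nn <- length(gv)
    left <- gv[c(nn, seq_len(nn - 1))]; right <- gv[c(seq_len(nn)[-1], 1)]
    locmin <- which(gv < left & gv <= right)
    receipt <- list(seed = seed, scheme = "langevin",
                    true_parameters = list(
                      spec = spec, coef = pot$coef, friction = friction,
                      dt = dt,
                      true_minima = grid[locmin],
                      true_min_energies = ev[locmin] - min(ev)))
  }
  series <- structure(list(angles = angles, atom_quad = NA,
                           frame_interval = dt),
                      class = "dihedral_series")
  list(series = series, receipt = receipt)
}

#' Generate a per-snapshot energy table with known means
#'
#' Each component is a stationary Gaussian AR(1) series with the requested
#' marginal mean and sd and lag-1 correlation \code{correlation}.
#'
#' @param component_means named numeric; names from \code{e_bond, e_angle,
#'   e_torsion, e_vdw, e_coulomb, g_polar, g_nonpolar}.
#' @param component_sds same names, >= 0.
#' @param correlation AR(1) coefficient in [0, 1).
#' @param n_snapshots number of rows.
#' @param seed RNG seed.
#' @param species_label species the table represents.
#' @return An \code{energy_table}; attribute \code{"receipt"} carries seed
#'   and true parameters, and \code{"mean_flag"} names any component whose
#'   sample mean strayed beyond 4 standard errors of its target.
#' @export
gen_energy_table <- function(component_means, component_sds,
                             correlation = 0, n_snapshots = 2400, seed = 1,
                             species_label = "complex") {
  stopifnot(all(names(component_means) %in% ENERGY_COMPONENTS),
            all(names(component_means) %in% names(component_sds)),
            all(component_sds >= 0), correlation >= 0, correlation < 1)
  rows <- with_seed(seed, {
    df <- data.frame(frame = seq_len(n_snapshots) - 1L)
    for (cc in names(component_means)) {
      mu <- component_means[[cc]]; sd <- component_sds[[cc]]
      if (sd == 0) { df[[cc]] <- rep(mu, n_snapshots); next }
      eps <- stats::rnorm(n_snapshots)
      x <- numeric(n_snapshots)
      x[1] <- eps[1]
      for (t in 2:n_snapshots)
        x[t] <- correlation * x[t - 1] + sqrt(1 - correlation^2) * eps[t]
      df[[cc]] <- mu + sd * x
    }
    df
  })
  tab <- energy_table(rows, species_label)
  flags <- character()
  for (cc in names(component_means)) {
    sd <- component_sds[[cc]]
    if (sd == 0) next
    if (abs(mean(rows[[cc]]) - component_means[[cc]]) >
        4 * sd / sqrt(n_snapshots)) flags <- c(flags, cc)
  }
  attr(tab, "receipt") <- list(seed = seed, scheme = "gaussian_ar1",
                               true_parameters = list(
                                 means = component_means,
                                 sds = component_sds,
                                 correlation = correlation,
                                 n_snapshots = n_snapshots))
  attr(tab, "mean_flag") <- flags
  tab
}

## Atom templates for planted contacts.  Geometries chosen to satisfy the
## default criteria with wide margin when present and violate them with
## wide margin when absent.
toy_contact_atoms <- function(type, origin, present) {
  if (type == "hbond") {
    ## donor residue: amide N-H; acceptor residue: carbonyl C=O
    d_oa <- if (present) 2.9 else 6.5
    list(
      donor = data.frame(name = c("N", "H"), element = c("N", "H"),
                         resname = "AMD",
                         x = origin[1] + c(0, 1.0), y = origin[2],
                         z = origin[3]),
      acceptor = data.frame(name = c("C", "O"), element = c("C", "O"),
                            resname = "CRB",
                            x = origin[1] + c(d_oa + 1.23, d_oa),
                            y = origin[2], z = origin[3]))
  } else {
    d <- if (present) 3.4 else 6.0
    list(
      donor = data.frame(name = c("CZ", "NH1", "HH11"),
                         element = c("C", "N", "H"), resname = "ARG",
                         x = origin[1] + c(-1.33, 0, 0.5),
                         y = origin[2] + c(0, 0, 0.85), z = origin[3]),
      acceptor = data.frame(name = c("CG", "OD1"), element = c("C", "O"),
                            resname = "ASP",
                            x = origin[1] + c(d + 1.25, d),
                            y = origin[2], z = origin[3]))
  }
}

#' Generate a toy complex with planted interactions
#'
#' Builds a small multi-frame system in which each requested contact (a
#' hydrogen bond or a salt bridge between a dedicated residue pair) is
#' geometrically present in an exact, seeded subset of frames matching its
#' occupancy schedule, and broken (atoms moved apart) in the rest.
#' Contact pairs are spaced 50 Angstrom apart so detections are
#' independent.
#'
#' @param planted_contacts character vector of contact types, each
#'   \code{"hbond"} or \code{"salt_bridge"}.
#' @param occupancy_schedule per-contact fraction of frames present, in
#'   [0, 1]; the number of present frames is exactly
#'   \code{round(fraction * n_frames)}.
#' @param n_frames number of frames.
#' @param n_spectators additional inert residues (single carbon) appended.
#' @param seed RNG seed (selects which frames are present).
#' @param frame_interval ps.
#' @return List with \code{traj} (a \code{trajectory}), \code{topology}
#'   (atom table) and \code{receipt} (exact present-frame sets, 0-based).
#' @export
gen_toy_complex <- function(planted_contacts = c("hbond", "salt_bridge"),
                            occupancy_schedule = c(1, 1), n_frames = 10,
                            n_spectators = 0, seed = 1,
                            frame_interval = 10) {
  stopifnot(length(planted_contacts) == length(occupancy_schedule),
            all(planted_contacts %in% c("hbond", "salt_bridge")),
            all(occupancy_schedule >= 0 & occupancy_schedule <= 1),
            n_frames >= 1)
  present_sets <- with_seed(seed, lapply(occupancy_schedule, function(f) {
    np <- round(f * n_frames)
    sort(sample.int(n_frames, np))
  }))
  build_frame <- function(k) {
    rows <- list(); resid <- 0
    for (ci in seq_along(planted_contacts)) {
      present <- k %in% present_sets[[ci]]
      origin <- c(50 * (ci - 1), 0, 0)
      grp <- toy_contact_atoms(planted_contacts[ci], origin, present)
      for (part in grp) {
        resid <- resid + 1
        part$resid <- resid
        rows[[length(rows) + 1]] <- part
      }
      resid_base <- resid
    }
    for (s in seq_len(n_spectators)) {
      resid <- resid + 1
      rows[[length(rows) + 1]] <- data.frame(
        name = "C1", element = "C", resname = "SPC",
        x = -30 - 10 * s, y = 0, z = 0, resid = resid)
    }
    do.call(rbind, rows)
  }
  f1 <- build_frame(1)
  n_atoms <- nrow(f1)
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  for (k in seq_len(n_frames)) {
    fk <- build_frame(k)
    coords[, , k] <- as.matrix(fk[, c("x", "y", "z")])
  }
  topology <- data.frame(
    serial = seq_len(n_atoms), name = f1$name, resname = f1$resname,
    resid = f1$resid, chain = "A", element = f1$element,
    mass = unname(ELEMENT_MASSES[f1$element]), charge = 0,
    lj_sigma = 3.0, lj_epsilon = 0.1, gb_radius = 1.5,
    backbone = f1$name %in% DEFAULT_BACKBONE_NAMES,
    stringsAsFactors = FALSE)
  traj <- trajectory(topology, coords, frame_interval)
  list(traj = traj, topology = topology,
       receipt = list(seed = seed, scheme = "toy_complex",
                      true_parameters = list(
                        contacts = planted_contacts,
                        schedule = occupancy_schedule,
                        present_frames = lapply(present_sets,
                                                function(x) x - 1L))))
}

#' Generate a two-lobe breathing trajectory
#'
#' Two rigid tetrahedral lobes whose tip separation follows
#' d(t) = base + amplitude * sin(2 pi t / period) plus optional Gaussian
#' coordinate noise, emulating a periodic swing/breathing motion of a
#' two-domain protein.
#'
#' @param n_frames number of frames.
#' @param period_frames oscillation period in frames (>= 4).
#' @param amplitude oscillation amplitude, Angstrom (0 gives a static
#'   separation).
#' @param seed RNG seed (noise only).
#' @param noise_sd Gaussian noise sd added to every coordinate, Angstrom.
#' @param base_separation mean tip separation, Angstrom.
#' @param frame_interval ps.
#' @return List with \code{traj}, the serials \code{tip_a}/\code{tip_b} of
#'   the two tip atoms, and \code{receipt} (true period in frames and ps).
#' @export
gen_breathing_complex <- function(n_frames = 1200, period_frames = 120,
                                  amplitude = 3, seed = 1, noise_sd = 0,
                                  base_separation = 20,
                                  frame_interval = 10) {
  stopifnot(period_frames >= 4, n_frames >= 8, amplitude >= 0)
  tet <- rbind(c(0, 0, 0), c(1.5, 1.5, 0), c(1.5, 0, 1.5), c(0, 1.5, 1.5))
  n_atoms <- 8
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  t0 <- seq_len(n_frames) - 1
  sep <- base_separation + amplitude * sin(2 * pi * t0 / period_frames)
  for (k in seq_len(n_frames)) {
    lobe_b <- tet
    lobe_b[, 1] <- -lobe_b[, 1]              # mirrored lobe
    lobe_b[, 1] <- lobe_b[, 1] + sep[k]
    coords[, , k] <- rbind(tet, lobe_b)
  }
  if (noise_sd > 0)
    coords <- coords + with_seed(seed,
      array(stats::rnorm(length(coords), 0, noise_sd), dim(coords)))
  atoms <- data.frame(
    serial = 1:8, name = paste0("C", c(1:4, 1:4)), resname = "LOB",
    resid = rep(1:2, each = 4), chain = rep(c("A", "B"), each = 4),
    element = "C", mass = 12.011, charge = 0, lj_sigma = 3.4,
    lj_epsilon = 0.1, gb_radius = 1.7, backbone = FALSE,
    stringsAsFactors = FALSE)
  traj <- trajectory(atoms, coords, frame_interval)
  list(traj = traj, tip_a = 1L, tip_b = 5L,
       receipt = list(seed = seed, scheme = "breathing",
                      true_parameters = list(
                        period_frames = period_frames,
                        period_ps = period_frames * frame_interval,
                        amplitude = amplitude, noise_sd = noise_sd,
                        base_separation = base_separation)))
}
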