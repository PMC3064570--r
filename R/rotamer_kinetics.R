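## Rotamer-state kinetics: state assignment of torsional time series,
## transition-rate estimation, Arrhenius activation barriers, and
## Boltzmann-inversion torsional energy profiles.
##
## The three canonical rotameric wells of an sp3-sp3 torsion are gauche+
## (around +60 deg), trans (around 180 deg) and gauche- (around -60 deg).

#' Rotamer state scheme
#'
#' Partition of the torsional circle (-180, 180] into labelled states.  The
#' default uses symmetric 120-degree sectors centred on the three canonical
#' wells: g+ = (0, 120], t = (120, 180] u (-180, -120], g- = (-120, 0].
#'
#' @param states character vector of state labels.
#' @param boundaries list (same length) of interval matrices; each row is an
#'   interval (lo, hi] in degrees.  The intervals must partition the circle.
#' @return Object of class \code{rotamer_scheme}.
#' @export
rotamer_scheme <- function(states = c("g+", "t", "g-"),
                           boundaries = list(
                             rbind(c(0, 120)),
                             rbind(c(120, 180), c(-180, -120)),
                             rbind(c(-120, 0)))) {
  stopifnot(length(states) == length(boundaries), !anyDuplicated(states))
  iv <- do.call(rbind, boundaries)
  if (any(iv[, 2] <= iv[, 1])) stop("empty or inverted interval")
  tot <- sum(iv[, 2] - iv[, 1])
  if (abs(tot - 360) > 1e-9)
    stop("intervals must cover the circle exactly once (cover ", tot, " deg)")
  o <- order(iv[, 1])
  lo <- iv[o, 1]; hi <- iv[o, 2]
  if (any(abs(hi[-length(hi)] - lo[-1]) > 1e-9) || abs(lo[1] - (-180)) > 1e-9)
    stop("intervals overlap or leave gaps")
  structure(list(states = states, boundaries = boundaries),
            class = "rotamer_scheme")
}

#' Assign rotamer states to a dihedral series
#'
#' Each angle (wrapped onto (-180, 180]) is mapped to the state whose
#' interval contains it; intervals are (lo, hi].
#'
#' @param series a \code{dihedral_series}, or a numeric vector of angles in
#'   degrees.
#' @param scheme a \code{rotamer_scheme}.
#' @return Character vector of state labels, one per frame, with the state
#'   population fractions in attribute \code{"populations"}.
#' @export
assign_states <- function(series, scheme = rotamer_scheme()) {
  ang <- if (inherits(series, "dihedral_series")) series$angles else series
  ang <- wrap_angle(ang)
  lab <- rep(NA_character_, length(ang))
  for (s in seq_along(scheme$states)) {
    iv <- scheme$boundaries[[s]]
    for (r in seq_len(nrow(iv)))
      lab[ang > iv[r, 1] & ang <= iv[r, 2]] <- scheme$states[s]
  }
  pops <- table(factor(lab, levels = scheme$states)) / length(lab)
  attr(lab, "populations") <- as.numeric(pops)
  names(attr(lab, "populations")) <- scheme$states
  lab
}

#' Transition rates between rotamer states
#'
#' Counts observed transitions between consecutive (dwell-filtered) state
#' runs and divides by the total time spent in the departing state:
#' k(i -> j) = N(i -> j) / T_i, reported per ns.  Runs shorter than
#' \code{min_dwell} frames are treated as boundary recrossing chatter and
#' removed before counting.  States never visited have their outgoing rates
#' flagged undefined (NA), not zero.
#'
#' Several label sequences (e.g. the 2-3 methyl torsions of one lysine) can
#' be pooled by passing a list; counts and times are then summed.
#'
#' @param labels character vector of state labels, or a list of such vectors.
#' @param frame_interval frame spacing, ps.
#' @param min_dwell minimum run length in frames kept as a genuine visit
#'   (default 2).
#' @param states state space (default: unique labels in order of first use).
#' @return Object of class \code{rate_matrix}: list with \code{k} (1/ns
#'   matrix, NA where undefined), \code{counts}, \code{time_in_state} (ns),
#'   \code{populations}, \code{frame_interval}, \code{min_dwell}.
#' @export
transition_rates <- function(labels, frame_interval = 10, min_dwell = 2,
                             states = NULL) {
  seqs <- if (is.list(labels)) labels else list(labels)
  if (any(vapply(seqs, length, 1L) < 2)) stop("need at least 2 frames")
  if (is.null(states)) states <- unique(unlist(seqs))
  ns <- length(states)
  counts <- matrix(0L, ns, ns, dimnames = list(from = states, to = states))
  time_frames <- stats::setNames(numeric(ns), states)
  pop_frames <- stats::setNames(numeric(ns), states)
  for (lab in seqs) {
    lab <- as.character(lab)        # drop attributes (rle needs a bare vector)
    pop_frames <- pop_frames + table(factor(lab, levels = states))
    r <- rle(lab)
    keep <- r$lengths >= min_dwell
    v <- r$values[keep]; l <- r$lengths[keep]
    if (length(v) > 1) {           # merge adjacent identical survivors
      m <- c(TRUE, v[-1] != v[-length(v)])
      grp <- cumsum(m)
      l <- as.numeric(tapply(l, grp, sum))
      v <- v[m]
    }
    if (length(v) == 0) next
    for (s in states) time_frames[s] <- time_frames[s] + sum(l[v == s])
    if (length(v) > 1)
      for (t in seq_len(length(v) - 1))
        counts[v[t], v[t + 1]] <- counts[v[t], v[t + 1]] + 1L
  }
  time_ns <- time_frames * frame_interval / 1000
  k <- counts / time_ns[row(counts)]
  k[time_ns[row(counts)] == 0] <- NA_real_   # never-visited: undefined
  diag(k) <- NA_real_
  structure(list(k = k, counts = counts, time_in_state = time_ns,
                 populations = as.numeric(pop_frames) / sum(pop_frames),
                 states = states, frame_interval = frame_interval,
                 min_dwell = min_dwell),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("transition rates (1/ns):\n")
  print(round(x$k, 4))
  cat("time in state (ns):\n")
  print(round(x$time_in_state, 4))
  invisible(x)
}

#' Arrhenius activation barriers from transition rates
#'
#' Inverts k = A exp(-Ea / RT) as Ea = -RT ln(k) + c.  Because the
#' prefactor A is unknown, barriers are reported relative to an arbitrary
#' datum: with \code{datum_rule = "min_zero"} (default) the smallest barrier
#' is set to 0; with \code{"fixed_c"} the supplied constant \code{c_value}
#' is used as-is.  Barrier differences are datum-independent and satisfy
#' Ea(i->j) - Ea(k->l) = RT ln( k(k->l) / k(i->j) ) exactly.
#'
#' @param rates a \code{rate_matrix}.
#' @param temperature K (default 310, the usual production temperature).
#' @param datum_rule \code{"min_zero"} or \code{"fixed_c"}.
#' @param c_value additive constant used when \code{datum_rule = "fixed_c"}.
#' @return Object of class \code{barrier_table}: list with \code{e_a}
#'   (kcal/mol matrix; +Inf where the rate is zero, NA where undefined),
#'   \code{datum_rule}, \code{temperature}.
#' @export
activation_barriers <- function(rates, temperature = 310,
                                datum_rule = c("min_zero", "fixed_c"),
                                c_value = 0) {
  datum_rule <- match.arg(datum_rule)
  stopifnot(inherits(rates, "rate_matrix"), temperature > 0)
  rt <- R_KCAL * temperature
  k <- rates$k
  ea <- matrix(NA_real_, nrow(k), ncol(k), dimnames = dimnames(k))
  defined <- !is.na(k)
  ea[defined & k > 0] <- -rt * log(k[defined & k > 0])
  ea[defined & k == 0] <- Inf
  shift <- switch(datum_rule,
                  min_zero = {
                    fin <- ea[is.finite(ea)]
                    if (length(fin)) -min(fin) else 0
                  },
                  fixed_c = c_value)
  ea[defined] <- ea[defined] + shift
  structure(list(e_a = ea, datum_rule = datum_rule, datum_shift = shift,
                 temperature = temperature),
            class = "barrier_table")
}

#' @export
print.barrier_table <- function(x, ...) {
  cat(sprintf("activation barriers (kcal/mol, %s datum, %g K):\n",
              x$datum_rule, x$temperature))
  print(round(x$e_a, 3))
  invisible(x)
}

#' Boltzmann-inversion torsional energy profile
#'
#' Histograms the torsional angles and inverts the empirical density:
#' E(theta) = -RT ln p(theta), shifted so the minimum is 0.  The additive,
#' temperature-dependent constant inherent to the inversion is thereby
#' removed.  Empty bins are flagged (NA), never reported as zero energy.
#'
#' @param series a \code{dihedral_series} or numeric vector of degrees.
#' @param temperature K.
#' @param bin_width histogram bin width, degrees (must divide 360).
#' @return data.frame with \code{theta} (bin midpoint, degrees),
#'   \code{count}, \code{prob} and \code{energy} (kcal/mol, min 0).
#' @export
torsional_profile <- function(series, temperature = 310, bin_width = 5) {
  ang <- if (inherits(series, "dihedral_series")) series$angles else series
  ang <- wrap_angle(ang)
  if (length(ang) < 1000)
    warning("fewer than 1000 samples; profile will be noisy")
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9)
    stop("bin_width must divide 360")
  breaks <- seq(-180, 180, by = bin_width)
  ## (-180, 180] with right-closed bins matches the angle wrapping
  h <- hist(ang, breaks = breaks, plot = FALSE, right = TRUE,
            include.lowest = FALSE)
  prob <- h$counts / sum(h$counts)
  rt <- R_KCAL * temperature
  e <- ifelse(h$counts > 0, -rt * log(prob), NA_real_)
  e <- e - min(e, na.rm = TRUE)
  data.frame(theta = h$mids, count = h$counts, prob = prob, energy = e)
}
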