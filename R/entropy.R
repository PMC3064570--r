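## Solute entropy: Sackur-Tetrode translational, rigid-rotor rotational, and
## quantum harmonic-oscillator vibrational terms, with normal-mode
## frequencies from a (mass-weighted) Hessian and a harmonic-network Hessian
## builder for desk-scale structures.  Entropies are cal/(mol K); the Delta
## assembly reports -T Delta S in kcal/mol.

#' Sackur-Tetrode translational entropy
#'
#' Ideal-gas translational entropy
#' S = R ( ln[ (2 pi m kT / h^2)^{3/2} kT / P ] + 5/2 )
#' at the stated standard-state pressure.
#'
#' @param total_mass molecular mass, amu (> 0).
#' @param temperature K.
#' @param pressure standard-state pressure, Pa (default 1 atm).
#' @return Entropy in cal/(mol K).
#' @export
translational_entropy <- function(total_mass, temperature = 310,
                                  pressure = ATM_PA) {
  stopifnot(total_mass > 0, temperature > 0, pressure > 0)
  m <- total_mass * AMU_KG
  kt <- KB_SI * temperature
  q <- (2 * pi * m * kt / H_SI^2)^1.5 * kt / pressure
  R_CAL * (log(q) + 2.5)
}

#' Moment-of-inertia tensor
#'
#' @param coords \code{n x 3} coordinates (Angstrom).
#' @param masses atom masses (amu).
#' @return 3x3 inertia tensor about the center of mass, amu Angstrom^2.
#' @export
inertia_tensor <- function(coords, masses) {
  coords <- matrix(coords, ncol = 3)
  stopifnot(length(masses) == nrow(coords))
  com <- colSums(coords * masses) / sum(masses)
  x <- sweep(coords, 2, com)
  I <- matrix(0, 3, 3)
  r2 <- rowSums(x^2)
  for (a in 1:3) for (b in 1:3)
    I[a, b] <- sum(masses * ((a == b) * r2 - x[, a] * x[, b]))
  I
}

#' Classical rigid-rotor rotational entropy
#'
#' Nonlinear molecules:
#' S = R ( ln[ sqrt(pi) / sigma * (8 pi^2 kT / h^2)^{3/2}
#'             sqrt(Ia Ib Ic) ] + 3/2 );
#' linear molecules use the two-moment form
#' S = R ( ln[ 8 pi^2 I kT / (sigma h^2) ] + 1 ).  A single atom has no
#' rotational degrees of freedom and returns 0 (flagged).
#'
#' @param inertia 3x3 inertia tensor (amu Angstrom^2), or the principal
#'   moments as a length-3 vector.
#' @param temperature K.
#' @param symmetry_number rotational symmetry number sigma (default 1).
#' @return Entropy in cal/(mol K); attribute \code{"flag"} is set to
#'   "point_mass" or "linear" for the degenerate shapes.
#' @export
rotational_entropy <- function(inertia, temperature = 310,
                               symmetry_number = 1) {
  stopifnot(temperature > 0, symmetry_number >= 1)
  mom <- if (is.matrix(inertia)) {
    if (max(abs(inertia - t(inertia))) > 1e-8) stop("inertia not symmetric")
    eigen(inertia, symmetric = TRUE)$values
  } else as.numeric(inertia)
  mom <- sort(mom, decreasing = TRUE)
  if (any(mom < -1e-8)) stop("inertia tensor not positive semidefinite")
  mom_si <- pmax(mom, 0) * AMU_KG * 1e-20   # kg m^2
  kt <- KB_SI * temperature
  tol <- max(mom_si) * 1e-8
  if (all(mom_si <= 0)) {
    out <- 0
    attr(out, "flag") <- "point_mass"
    return(out)
  }
  if (mom_si[3] <= tol) {                   # linear: one vanishing moment
    I <- mom_si[1]
    out <- R_CAL * (log(8 * pi^2 * I * kt / (symmetry_number * H_SI^2)) + 1)
    attr(out, "flag") <- "linear"
    return(out)
  }
  q <- sqrt(pi) / symmetry_number *
    (8 * pi^2 * kt / H_SI^2)^1.5 * sqrt(prod(mom_si))
  R_CAL * (log(q) + 1.5)
}

#' Normal-mode frequencies from a Hessian
#'
#' Diagonalises the mass-weighted Hessian M^{-1/2} H M^{-1/2} and converts
#' positive eigenvalues to harmonic frequencies in cm^-1.  For a nonlinear
#' molecule the six near-zero rigid-body modes (3 translations + 3
#' rotations) are identified by magnitude and removed.
#'
#' @param hessian symmetric \code{3N x 3N} matrix of second derivatives,
#'   kcal/mol/Angstrom^2.
#' @param masses N atom masses (amu).
#' @param n_rigid number of rigid-body modes to drop (default 6; use 5 for
#'   linear molecules, 0 to keep everything).
#' @param zero_tol eigenvalue magnitude (kcal/mol/A^2/amu) below which a
#'   mode counts as numerically zero.
#' @return Numeric vector of frequencies (cm^-1), increasing; counts of
#'   removed zero modes and imaginary (negative-eigenvalue) modes in
#'   attributes \code{"n_zero"} and \code{"n_imaginary"}.
#' @export
normal_mode_frequencies <- function(hessian, masses, n_rigid = 6,
                                    zero_tol = 1e-8) {
  n3 <- nrow(hessian)
  stopifnot(ncol(hessian) == n3, n3 == 3 * length(masses))
  if (max(abs(hessian - t(hessian))) > 1e-8)
    stop("hessian is not symmetric")
  invsqm <- rep(1 / sqrt(masses), each = 3)
  mwh <- hessian * (invsqm %o% invsqm)
  ev <- eigen((mwh + t(mwh)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev)                      # ascending
  scale_ref <- max(abs(ev), zero_tol)
  near_zero <- abs(ev) <= max(zero_tol, scale_ref * 1e-10)
  drop_idx <- order(abs(ev))[seq_len(min(n_rigid, n3))]
  keep <- setdiff(seq_along(ev), drop_idx)
  ev_keep <- ev[keep]
  n_imag <- sum(ev_keep < -max(zero_tol, scale_ref * 1e-10))
  if (n_imag > 0)
    warning(n_imag, " imaginary frequencies excluded")
  ev_pos <- ev_keep[ev_keep > max(zero_tol, scale_ref * 1e-10)]
  omega <- sqrt(ev_pos * HESS_EIG_TO_OMEGA2)   # s^-1
  nu <- sort(omega / (2 * pi * C_CM))          # cm^-1
  attr(nu, "n_zero") <- sum(near_zero)
  attr(nu, "n_imaginary") <- n_imag
  nu
}

#' Quantum harmonic-oscillator vibrational entropy
#'
#' S = R sum_k [ x_k / (e^{x_k} - 1) - ln(1 - e^{-x_k}) ],
#' x_k = h c nu_k / (k T).  High-frequency modes freeze out (contribute ~0);
#' an empty mode list gives 0.
#'
#' @param frequencies mode frequencies, cm^-1 (> 0; negative entries are
#'   excluded with a warning and reported in attribute
#'   \code{"n_imaginary"}).
#' @param temperature K.
#' @return Entropy in cal/(mol K).
#' @export
vibrational_entropy <- function(frequencies, temperature = 310) {
  stopifnot(temperature > 0)
  if (length(frequencies) == 0) return(0)
  bad <- frequencies <= 0
  if (any(bad)) warning(sum(bad), " non-positive frequencies excluded")
  nu <- frequencies[!bad]
  if (!length(nu)) {
    out <- 0
    attr(out, "n_imaginary") <- sum(bad)
    return(out)
  }
  x <- H_SI * C_CM * nu / (KB_SI * temperature)
  s <- R_CAL * sum(x / (exp(x) - 1) - log1p(-exp(-x)))
  attr(s, "n_imaginary") <- sum(bad)
  s
}

#' Harmonic-network (elastic network) Hessian
#'
#' Builds the Hessian of a network of identical harmonic springs connecting
#' every atom pair within a cutoff, with the native structure as the
#' minimum.  By construction the Hessian has exactly six zero modes (rigid
#' translations and rotations) for a non-degenerate 3D structure.
#'
#' @param coords \code{n x 3} coordinates (Angstrom).
#' @param cutoff spring cutoff, Angstrom (default 8).
#' @param k_spring force constant, kcal/mol/A^2 (default 1).
#' @return \code{3n x 3n} Hessian matrix, kcal/mol/A^2.
#' @export
enm_hessian <- function(coords, cutoff = 8, k_spring = 1) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- coords[j, ] - coords[i, ]
    r2 <- sum(d^2)
    if (r2 > cutoff^2 || r2 == 0) next
    blk <- -k_spring * (d %o% d) / r2
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Entropy terms of one species
#'
#' Convenience wrapper computing the translational, rotational and
#' vibrational entropy of a structure, the latter from a supplied Hessian
#' or a harmonic-network Hessian built on the coordinates.
#'
#' @param coords \code{n x 3} coordinates.
#' @param masses atom masses (amu).
#' @param temperature K.
#' @param hessian optional \code{3n x 3n} Hessian (kcal/mol/A^2); if NULL an
#'   elastic-network Hessian is built with \code{\link{enm_hessian}}.
#' @param symmetry_number rotational symmetry number.
#' @param ... passed to \code{\link{enm_hessian}}.
#' @return Named list with \code{s_trans}, \code{s_rot}, \code{s_vib}
#'   (cal/(mol K)) and \code{temperature}.
#' @export
species_entropy <- function(coords, masses, temperature = 310,
                            hessian = NULL, symmetry_number = 1, ...) {
  coords <- matrix(coords, ncol = 3)
  s_t <- translational_entropy(sum(masses), temperature)
  s_r <- rotational_entropy(inertia_tensor(coords, masses), temperature,
                            symmetry_number)
  if (is.null(hessian)) hessian <- enm_hessian(coords, ...)
  nu <- normal_mode_frequencies(hessian, masses)
  s_v <- vibrational_entropy(nu, temperature)
  list(s_trans = as.numeric(s_t), s_rot = as.numeric(s_r),
       s_vib = as.numeric(s_v), temperature = temperature)
}

#' Assemble the entropic contribution to binding
#'
#' -T Delta S_x = -T (S_x(complex) - S_x(receptor) - S_x(ligand)) per term
#' (x = trans, rot, vib), converted to kcal/mol; the total is the exact sum
#' of the three terms.
#'
#' @param complex_terms,receptor_terms,ligand_terms lists with
#'   \code{s_trans}, \code{s_rot}, \code{s_vib} in cal/(mol K) (as from
#'   \code{\link{species_entropy}}), or named numerics of \code{-T S} terms
#'   in kcal/mol when \code{units = "kcal_ts"}.
#' @param temperature K.
#' @param units \code{"cal_s"} (entropies in cal/(mol K), default) or
#'   \code{"kcal_ts"} (inputs already -T S in kcal/mol).
#' @return Object of class \code{entropy_terms}: named numeric with
#'   \code{minus_t_s_trans}, \code{minus_t_s_rot}, \code{minus_t_s_vib},
#'   \code{minus_t_s_tot} (kcal/mol) and attribute \code{"temperature"}.
#' @export
assemble_entropy <- function(complex_terms, receptor_terms, ligand_terms,
                             temperature = 310,
                             units = c("cal_s", "kcal_ts")) {
  units <- match.arg(units)
  conv <- function(t) {
    if (units == "cal_s")
      c(trans = -temperature * t$s_trans / 1000,
        rot = -temperature * t$s_rot / 1000,
        vib = -temperature * t$s_vib / 1000)
    else c(trans = t[["trans"]], rot = t[["rot"]], vib = t[["vib"]])
  }
  d <- conv(complex_terms) - conv(receptor_terms) - conv(ligand_terms)
  out <- c(minus_t_s_trans = d[["trans"]], minus_t_s_rot = d[["rot"]],
           minus_t_s_vib = d[["vib"]],
           minus_t_s_tot = d[["trans"]] + d[["rot"]] + d[["vib"]])
  attr(out, "temperature") <- temperature
  class(out) <- "entropy_terms"
  out
}

#' @export
print.entropy_terms <- function(x, ...) {
  cat(sprintf("-T Delta S (kcal/mol, %g K):\n", attr(x, "temperature")))
  print(round(unclass(x), 3))
  invisible(x)
}
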