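## MM-GB/SA energetics: molecular-mechanics energy components, implicit
## solvation (Still-form generalized Born polar term, SASA-linear nonpolar
## term), binding free energy assembly with standard errors, and
## per-residue decomposition with hot-spot calling.

## ---- molecular mechanics --------------------------------------------------

#' Nonbonded molecular-mechanics energy of one frame
#'
#' Pairwise 12-6 Lennard-Jones (Lorentz-Berthelot combination, sigma as the
#' zero-crossing distance) plus Coulomb energy with the conversion constant
#' 332.0636 kcal A mol^-1 e^-2, evaluated over all atom pairs with no cutoff
#' (the end-state convention), minus excluded 1-2/1-3 pairs, with optional
#' scaled 1-4 pairs.
#'
#' @param frame \code{n x 3} coordinates (Angstrom).
#' @param topology atom table with \code{charge}, \code{lj_sigma},
#'   \code{lj_epsilon}.
#' @param pairs_excluded 2-column matrix of atom serial pairs excluded
#'   entirely (1-2 and 1-3 neighbours).
#' @param pairs_14 2-column matrix of 1-4 pairs, scaled by
#'   \code{scale_vdw_14} and \code{scale_coul_14}.
#' @param dielectric_internal relative dielectric dividing the Coulomb term.
#' @param scale_vdw_14,scale_coul_14 1-4 scale factors (ff03 convention:
#'   1/2.0 and 1/1.2).
#' @return Named list \code{e_vdw}, \code{e_coulomb} (kcal/mol).
#' @export
mm_nonbonded <- function(frame, topology, pairs_excluded = NULL,
                         pairs_14 = NULL, dielectric_internal = 1,
                         scale_vdw_14 = 1 / 2.0, scale_coul_14 = 1 / 1.2) {
  frame <- matrix(frame, ncol = 3)
  n <- nrow(frame)
  stopifnot(nrow(topology) == n)
  if (anyNA(topology$lj_sigma) || anyNA(topology$lj_epsilon))
    stop("missing LJ parameters for atom serial(s): ",
         paste(topology$serial[is.na(topology$lj_sigma) |
                                 is.na(topology$lj_epsilon)], collapse = ", "))
  if (n < 2) return(list(e_vdw = 0, e_coulomb = 0))
  pair_key <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(character())
    i <- match(m[, 1], topology$serial); j <- match(m[, 2], topology$serial)
    if (anyNA(i) || anyNA(j)) stop("exclusion references unknown serial")
    paste(pmin(i, j), pmax(i, j))
  }
  excl <- pair_key(pairs_excluded)
  p14 <- pair_key(pairs_14)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key <- paste(idx[, 1], idx[, 2])
  keep <- !(key %in% excl)
  idx <- idx[keep, , drop = FALSE]; key <- key[keep]
  is14 <- key %in% p14
  i <- idx[, 1]; j <- idx[, 2]
  r <- sqrt(rowSums((frame[i, , drop = FALSE] - frame[j, , drop = FALSE])^2))
  if (any(r < 1e-9)) stop("coincident atoms in nonbonded evaluation")
  sig <- (topology$lj_sigma[i] + topology$lj_sigma[j]) / 2
  eps <- sqrt(topology$lj_epsilon[i] * topology$lj_epsilon[j])
  sr6 <- (sig / r)^6
  e_lj <- 4 * eps * (sr6^2 - sr6)
  e_c <- COULOMB_KCAL * topology$charge[i] * topology$charge[j] /
    (dielectric_internal * r)
  e_lj[is14] <- e_lj[is14] * scale_vdw_14
  e_c[is14] <- e_c[is14] * scale_coul_14
  list(e_vdw = sum(e_lj), e_coulomb = sum(e_c))
}

#' Bonded molecular-mechanics energy of one frame
#'
#' Harmonic bonds and angles in the AMBER convention (no 1/2 factor:
#' k (r - r0)^2, k (theta - theta0)^2) and periodic cosine torsions
#' V (1 + cos(n phi - phase)).
#'
#' @param frame \code{n x 3} coordinates.
#' @param topology atom table (serials resolve term references).
#' @param bonded_terms list with optional data.frames: \code{bonds}
#'   (\code{i, j, k, r0}; k in kcal/mol/A^2, r0 in Angstrom), \code{angles}
#'   (\code{i, j, k_atom, k, theta0}; k in kcal/mol/rad^2, theta0 degrees),
#'   \code{torsions} (\code{i, j, k_atom, l, v, n, phase}; v kcal/mol,
#'   phase degrees).
#' @return Named list \code{e_bond}, \code{e_angle}, \code{e_torsion}
#'   (kcal/mol).
#' @export
mm_bonded <- function(frame, topology, bonded_terms) {
  frame <- matrix(frame, ncol = 3)
  at <- function(serial) {
    i <- match(serial, topology$serial)
    if (anyNA(i)) stop("bonded term references undefined atom serial(s): ",
                       paste(serial[is.na(i)], collapse = ", "))
    i
  }
  e_bond <- 0
  if (!is.null(bonded_terms$bonds) && nrow(bonded_terms$bonds)) {
    b <- bonded_terms$bonds
    i <- at(b$i); j <- at(b$j)
    r <- sqrt(rowSums((frame[i, , drop = FALSE] -
                         frame[j, , drop = FALSE])^2))
    e_bond <- sum(b$k * (r - b$r0)^2)
  }
  e_angle <- 0
  if (!is.null(bonded_terms$angles) && nrow(bonded_terms$angles)) {
    a <- bonded_terms$angles
    i <- at(a$i); j <- at(a$j); k <- at(a$k_atom)
    th <- vapply(seq_along(i), function(t) {
      v1 <- frame[i[t], ] - frame[j[t], ]; v2 <- frame[k[t], ] - frame[j[t], ]
      acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
    }, numeric(1))
    e_angle <- sum(a$k * (th - a$theta0 * pi / 180)^2)
  }
  e_torsion <- 0
  if (!is.null(bonded_terms$torsions) && nrow(bonded_terms$torsions)) {
    d <- bonded_terms$torsions
    i <- at(d$i); j <- at(d$j); k <- at(d$k_atom); l <- at(d$l)
    phi <- vapply(seq_along(i), function(t)
      dihedral_angle(frame[i[t], ], frame[j[t], ], frame[k[t], ],
                     frame[l[t], ]), numeric(1))
    e_torsion <- sum(d$v * (1 + cos((d$n * phi - d$phase) * pi / 180)))
  }
  list(e_bond = e_bond, e_angle = e_angle, e_torsion = e_torsion)
}

## ---- solvent accessible surface area --------------------------------------

## Deterministic quasi-uniform unit-sphere point set (golden-spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Samples \code{n_points} quasi-uniform points on each atom's solvent
#' sphere (radius + probe) and counts the fraction not buried inside any
#' neighbouring solvent sphere.
#'
#' @param frame \code{n x 3} coordinates (Angstrom).
#' @param radii per-atom radii (Angstrom), > 0.
#' @param probe_radius solvent probe radius (default 1.4 Angstrom).
#' @param n_points sample points per atom (default 960).
#' @return Numeric vector of per-atom SASA (Angstrom^2); total SASA in
#'   attribute \code{"total"}.
#' @export
sasa <- function(frame, radii, probe_radius = 1.4, n_points = 960) {
  frame <- matrix(frame, ncol = 3)
  n <- nrow(frame)
  stopifnot(length(radii) == n, all(radii > 0))
  rs <- radii + probe_radius
  pts <- sphere_points(n_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rs[i], 2, frame[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij2 <- sum((frame[i, ] - frame[j, ])^2)
      if (dij2 >= (rs[i] + rs[j])^2) next
      d2 <- rowSums(sweep(p, 2, frame[j, ])^2)
      acc <- acc & d2 > rs[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rs[i]^2 * sum(acc) / n_points
  }
  attr(out, "total") <- sum(out)
  out
}

#' Nonpolar solvation free energy from SASA
#'
#' The linear surface-area model gamma * SASA + beta.  Published parameter
#' sets: (0.00542, 0.92) for PB-flavoured runs and (0.005, 0.0) for
#' GB-flavoured runs.
#'
#' @param total_sasa total SASA, Angstrom^2 (>= 0).
#' @param gamma surface tension, kcal/mol/A^2.
#' @param beta offset, kcal/mol.
#' @return Nonpolar solvation energy, kcal/mol.
#' @export
nonpolar_solvation <- function(total_sasa, gamma = 0.005, beta = 0.0) {
  stopifnot(total_sasa >= 0)
  gamma * total_sasa + beta
}

## ---- generalized Born polar solvation -------------------------------------

#' Effective Born radii (pairwise descreening with OBC rescaling)
#'
#' Computes per-atom effective Born radii from the intrinsic GB radii via
#' the pairwise analytic Coulomb-field (HCT) descreening integral, followed
#' by the OBC tanh rescaling
#' 1/B_i = 1/rho_i - tanh(alpha Psi - beta Psi^2 + gamma Psi^3) / R_i
#' with rho_i = R_i - offset and Psi = I_i rho_i.
#'
#' @param frame \code{n x 3} coordinates (Angstrom).
#' @param gb_radii intrinsic radii R_i (Angstrom), > 0.
#' @param offset radius offset (Angstrom, default 0.09).
#' @param scaling descreening scale factor applied to neighbour radii
#'   (default 0.8).
#' @param obc OBC coefficients (alpha, beta, gamma); defaults 1.0, 0.8,
#'   4.85.
#' @return Numeric vector of effective Born radii (Angstrom).
#' @export
born_radii <- function(frame, gb_radii, offset = 0.09, scaling = 0.8,
                       obc = c(alpha = 1.0, beta = 0.8, gamma = 4.85)) {
  frame <- matrix(frame, ncol = 3)
  n <- nrow(frame)
  stopifnot(length(gb_radii) == n, all(gb_radii > 0))
  rho <- gb_radii - offset
  if (any(rho <= 0)) stop("gb_radius must exceed the offset")
  I <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
      sr <- scaling * rho[j]
      if (r + sr <= rho[i]) next               # j fully engulfed: no term
      if (r - sr <= rho[i]) L <- rho[i] else L <- r - sr
      U <- r + sr
      term <- (1 / L - 1 / U) + (r / 4) * (1 / U^2 - 1 / L^2) +
        (1 / (2 * r)) * log(L / U) +
        (sr^2 / (4 * r)) * (1 / L^2 - 1 / U^2)
      if (rho[i] < sr - r) term <- term + 2 * (1 / rho[i] - 1 / L)
      acc <- acc + term / 2
    }
    I[i] <- acc
  }
  psi <- I * rho
  binv <- 1 / rho -
    tanh(obc[[1]] * psi - obc[[2]] * psi^2 + obc[[3]] * psi^3) / gb_radii
  unname(1 / binv)
}

#' Still-form generalized Born polar solvation energy
#'
#' Delta G_polar = -(332.0636 / 2) (1/eps_in - 1/eps_out)
#' sum_ij q_i q_j / f_GB(r_ij, B_i, B_j), with
#' f_GB = sqrt(r^2 + B_i B_j exp(-r^2 / (4 B_i B_j))).  The double sum runs
#' over all ordered pairs including i = j (the Born self terms).  For one
#' ion this reduces exactly to the Born formula.
#'
#' @param frame \code{n x 3} coordinates.
#' @param charges partial charges (e).
#' @param gb_radii intrinsic GB radii (Angstrom).
#' @param eps_in,eps_out interior and solvent dielectric constants
#'   (defaults 4 and 80, the protein-in-water convention used here).
#' @param offset,scaling,obc passed to \code{\link{born_radii}}.
#' @param radii_effective optionally supply precomputed effective Born
#'   radii, bypassing \code{\link{born_radii}}.
#' @return Polar solvation energy, kcal/mol; effective radii in attribute
#'   \code{"born_radii"}.
#' @export
gb_polar <- function(frame, charges, gb_radii, eps_in = 4, eps_out = 80,
                     offset = 0.09, scaling = 0.8,
                     obc = c(alpha = 1.0, beta = 0.8, gamma = 4.85),
                     radii_effective = NULL) {
  if (eps_in <= 0) stop("eps_in must be > 0")
  if (eps_out <= eps_in) stop("eps_out must exceed eps_in")
  frame <- matrix(frame, ncol = 3)
  n <- nrow(frame)
  stopifnot(length(charges) == n)
  B <- radii_effective %||% born_radii(frame, gb_radii, offset, scaling, obc)
  pref <- -(COULOMB_KCAL / 2) * (1 / eps_in - 1 / eps_out)
  e <- sum(charges^2 / B)            # self terms (f_GB = B_i at r = 0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r2 <- sum((frame[i, ] - frame[j, ])^2)
      bb <- B[i] * B[j]
      fgb <- sqrt(r2 + bb * exp(-r2 / (4 * bb)))
      e <- e + 2 * charges[i] * charges[j] / fgb
    }
  }
  out <- pref * e
  attr(out, "born_radii") <- B
  out
}

## ---- binding free energy assembly -----------------------------------------

#' Binding summary from already-differenced component means
#'
#' Builds the full end-state record from the five independent Delta terms;
#' all derived sums (Delta E_gas = ele + vdw + int, Delta G_solv = SA +
#' polar, Delta H = gas + solv, polar + ele) are computed exactly on the
#' unrounded inputs.
#'
#' @param d_ele,d_vdw,d_int,d_sa,d_polar component Delta terms, kcal/mol.
#' @param se optional named numeric of standard errors for the five inputs
#'   (names \code{d_ele}, \code{d_vdw}, \code{d_int}, \code{d_sa},
#'   \code{d_polar}).
#' @param protocol \code{"multi_trajectory"} or \code{"single_trajectory"}.
#' @param polar_backend label for the polar column's solver (e.g.
#'   \code{"gb_obc"}, or the name of an external PB solver whose column was
#'   slotted in).
#' @return Object of class \code{binding_summary}.
#' @export
binding_summary <- function(d_ele, d_vdw, d_int, d_sa, d_polar, se = NULL,
                            protocol = c("multi_trajectory",
                                         "single_trajectory"),
                            polar_backend = "gb_obc") {
  protocol <- match.arg(protocol)
  if (protocol == "single_trajectory" && d_int != 0)
    stop("single-trajectory protocol implies d_int = 0 exactly")
  d_gas <- d_ele + d_vdw + d_int
  d_solv <- d_sa + d_polar
  terms <- c(d_ele = d_ele, d_vdw = d_vdw, d_int = d_int, d_gas = d_gas,
             d_sa = d_sa, d_polar = d_polar, d_solv = d_solv,
             d_ele_plus_polar = d_ele + d_polar,
             d_enthalpy = d_gas + d_solv)
  ses <- rep(NA_real_, length(terms))
  names(ses) <- names(terms)
  if (!is.null(se)) {
    need <- c("d_ele", "d_vdw", "d_int", "d_sa", "d_polar")
    stopifnot(all(need %in% names(se)))
    ses[need] <- se[need]
    q <- function(...) sqrt(sum(se[c(...)]^2))
    ses["d_gas"] <- q("d_ele", "d_vdw", "d_int")
    ses["d_solv"] <- q("d_sa", "d_polar")
    ses["d_ele_plus_polar"] <- q("d_ele", "d_polar")
    ses["d_enthalpy"] <- q("d_ele", "d_vdw", "d_int", "d_sa", "d_polar")
  }
  structure(list(terms = terms, se = ses, protocol = protocol,
                 polar_backend = polar_backend),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, digits = 2, ...) {
  cat(sprintf("binding summary (%s protocol, polar: %s), kcal/mol:\n",
              x$protocol, x$polar_backend))
  df <- data.frame(term = names(x$terms),
                   value = round(x$terms, digits),
                   se = round(x$se, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

## Standard error of the mean; optionally block-averaged.
sem <- function(x, block_size = 1) {
  n <- length(x)
  if (block_size > 1) {
    nb <- floor(n / block_size)
    if (nb < 2) stop("too few blocks for block size ", block_size)
    x <- vapply(seq_len(nb), function(b)
      mean(x[((b - 1) * block_size + 1):(b * block_size)]), numeric(1))
  }
  stats::sd(x) / sqrt(length(x))
}

#' Assemble binding free energy components from snapshot tables
#'
#' Each Delta term is mean(complex) - mean(receptor) - mean(ligand) over the
#' per-snapshot energy tables; standard errors are naive SEMs per species
#' combined as sqrt(SE_C^2 + SE_R^2 + SE_L^2), with optional block averaging
#' to expose autocorrelation.  Under the single-trajectory protocol the
#' receptor/ligand internal (bonded) terms cancel exactly by construction
#' and Delta E_int is 0.
#'
#' @param complex_table,receptor_table,ligand_table \code{energy_table}s
#'   with a shared component schema.
#' @param protocol \code{"multi_trajectory"} (three independent runs) or
#'   \code{"single_trajectory"}.
#' @param block_size snapshot block size for the SEs (default 1 = naive).
#' @param polar_backend label for the polar solvation backend.
#' @return A \code{\link{binding_summary}}.
#' @export
assemble_binding <- function(complex_table, receptor_table, ligand_table,
                             protocol = c("multi_trajectory",
                                          "single_trajectory"),
                             block_size = 1, polar_backend = "gb_obc") {
  protocol <- match.arg(protocol)
  tabs <- list(complex = complex_table, receptor = receptor_table,
               ligand = ligand_table)
  stopifnot(all(vapply(tabs, inherits, TRUE, "energy_table")))
  comp <- tabs$complex$components
  for (t in tabs) if (!setequal(t$components, comp))
    stop("energy tables have mismatched component schemas")
  need <- c("e_vdw", "e_coulomb", "g_polar", "g_nonpolar")
  if (protocol == "multi_trajectory")
    need <- c(need, "e_bond", "e_angle", "e_torsion")
  missing <- setdiff(need, comp)
  if (length(missing))
    stop("cannot assemble binding energy: component(s) absent from the ",
         "tables: ", paste(missing, collapse = ", "))
  dmean <- function(cc) {
    if (!cc %in% comp) return(c(d = 0, se = 0))
    m <- vapply(tabs, function(t) mean(t$rows[[cc]]), numeric(1))
    s <- vapply(tabs, function(t) sem(t$rows[[cc]], block_size), numeric(1))
    c(d = m[["complex"]] - m[["receptor"]] - m[["ligand"]],
      se = sqrt(sum(s^2)))
  }
  ele <- dmean("e_coulomb"); vdw <- dmean("e_vdw")
  bnd <- dmean("e_bond"); ang <- dmean("e_angle"); tor <- dmean("e_torsion")
  sa <- dmean("g_nonpolar"); pol <- dmean("g_polar")
  d_int <- bnd[["d"]] + ang[["d"]] + tor[["d"]]
  se_int <- sqrt(bnd[["se"]]^2 + ang[["se"]]^2 + tor[["se"]]^2)
  if (protocol == "single_trajectory") {
    if (abs(d_int) > 1e-6)
      stop("single-trajectory protocol requires internal terms to cancel; ",
           "got Delta E_int = ", format(d_int))
    d_int <- 0; se_int <- 0
  }
  binding_summary(d_ele = ele[["d"]], d_vdw = vdw[["d"]], d_int = d_int,
                  d_sa = sa[["d"]], d_polar = pol[["d"]],
                  se = c(d_ele = ele[["se"]], d_vdw = vdw[["se"]],
                         d_int = se_int, d_sa = sa[["se"]],
                         d_polar = pol[["se"]]),
                  protocol = protocol, polar_backend = polar_backend)
}

## ---- per-residue decomposition and hot spots ------------------------------

#' Per-residue decomposition of the binding enthalpy
#'
#' Splits pairwise snapshot energies half-and-half between the two residues
#' of each atom pair; each atom's half is routed to the residue's backbone
#' or side-chain share by the atom's backbone flag.  Self terms (atom paired
#' with itself) are attributed fully to the atom's residue.  Totals conserve
#' the overall enthalpy: the residue totals sum to the frame-averaged total
#' pairwise energy exactly.
#'
#' @param pairwise data.frame of pairwise snapshot energies with columns
#'   \code{atom_a}, \code{atom_b} (serials), \code{energy} (kcal/mol), and
#'   optionally \code{frame} (averaged over) and \code{component}.
#' @param topology atom table with \code{serial}, \code{resname},
#'   \code{resid}, \code{backbone}.
#' @return data.frame (class \code{residue_contribution}) with
#'   \code{residue}, \code{total}, \code{backbone}, \code{side_chain}
#'   (kcal/mol), sorted by total ascending; per-component split in
#'   attribute \code{"by_component"}, pairwise residue partners in
#'   attribute \code{"partners"}.
#' @export
per_residue_decomposition <- function(pairwise, topology) {
  stopifnot(all(c("atom_a", "atom_b", "energy") %in% names(pairwise)))
  ia <- match(pairwise$atom_a, topology$serial)
  ib <- match(pairwise$atom_b, topology$serial)
  if (anyNA(ia) || anyNA(ib))
    stop("pairwise energy references atom(s) with no residue assignment")
  nfr <- if ("frame" %in% names(pairwise))
    length(unique(pairwise$frame)) else 1L
  res_lab <- paste0(topology$resname, topology$resid)
  half <- pairwise$energy / 2
  full <- ifelse(ia == ib, pairwise$energy, half)  # self terms not halved
  other <- ifelse(ia == ib, 0, half)
  contrib <- data.frame(
    residue = c(res_lab[ia], res_lab[ib]),
    backbone = c(topology$backbone[ia], topology$backbone[ib]),
    energy = c(full, other) / nfr,
    component = if ("component" %in% names(pairwise))
      rep(pairwise$component, 2) else "total",
    partner = c(res_lab[ib], res_lab[ia]))
  agg <- function(split_by) {
    s <- tapply(contrib$energy, split_by, sum)
    s[is.na(s)] <- 0
    s
  }
  tot <- agg(contrib$residue)
  bb <- tapply(contrib$energy[contrib$backbone],
               contrib$residue[contrib$backbone], sum)
  out <- data.frame(residue = names(tot), total = as.numeric(tot))
  out$backbone <- ifelse(out$residue %in% names(bb),
                         as.numeric(bb[out$residue]), 0)
  out$side_chain <- out$total - out$backbone
  out <- out[order(out$total), , drop = FALSE]
  rownames(out) <- NULL
  bycomp <- stats::xtabs(energy ~ residue + component, data = contrib)
  partners <- stats::xtabs(energy ~ residue + partner, data = contrib)
  attr(out, "by_component") <- bycomp
  attr(out, "partners") <- partners
  class(out) <- c("residue_contribution", class(out))
  out
}

#' Call hot-spot residues
#'
#' Residues whose total per-residue contribution to the binding enthalpy is
#' at least as favourable as the threshold (total <= threshold, default
#' -1.0 kcal/mol; the boundary is inclusive, so -1.00 is a hot spot and
#' -0.99 is not), sorted most-favourable first.
#'
#' @param contributions data.frame with \code{residue} and \code{total}
#'   (e.g. from \code{\link{per_residue_decomposition}}).
#' @param threshold kcal/mol, must be negative (favourable convention).
#' @return data.frame of the selected rows, sorted by total ascending.
#' @export
call_hotspots <- function(contributions, threshold = -1.0) {
  if (threshold >= 0) stop("threshold must be negative (favourable side)")
  sel <- contributions[!is.na(contributions$total) &
                         contributions$total <= threshold, , drop = FALSE]
  sel <- sel[order(sel$total), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}
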