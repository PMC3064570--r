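## Hydrogen-bond and salt-bridge detection with trajectory occupancies.
##
## Geometric criteria: a hydrogen bond is a donor heavy atom D (N or O by
## default) with a covalently attached hydrogen H and an acceptor heavy atom
## A (N or O) such that d(D, A) <= d_max and the D-H...A angle at the
## hydrogen is >= angle_min.  A salt bridge pairs an anionic carboxylate
## oxygen with a cationic nitrogen within d_max.  Occupancy is the percent
## of trajectory frames in which a given contact satisfies the criteria.

#' Hydrogen-bond geometric criteria
#'
#' @param d_max maximum donor-acceptor heavy-atom distance, Angstrom
#'   (default 3.5).
#' @param angle_min minimum donor-hydrogen-acceptor angle, degrees
#'   (default 120).
#' @param donor_elements,acceptor_elements element sets for donor and
#'   acceptor heavy atoms.
#' @param h_bond_dist maximum covalent H-to-heavy-atom distance used to
#'   attach hydrogens to donors (Angstrom).
#' @return Object of class \code{hbond_criteria}.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_min = 120,
                           donor_elements = c("N", "O"),
                           acceptor_elements = c("N", "O"),
                           h_bond_dist = 1.25) {
  stopifnot(d_max > 0, angle_min > 0, angle_min <= 180)
  structure(list(d_max = d_max, angle_min = angle_min,
                 donor_elements = donor_elements,
                 acceptor_elements = acceptor_elements,
                 h_bond_dist = h_bond_dist),
            class = "hbond_criteria")
}

## Attach each hydrogen to its nearest heavy atom within h_bond_dist.
attach_hydrogens <- function(frame, topology, h_bond_dist) {
  is_h <- toupper(topology$element) == "H"
  heavy <- which(!is_h)
  hyd <- which(is_h)
  if (length(hyd) == 0) return(NULL)
  out <- integer(length(hyd))
  for (i in seq_along(hyd)) {
    d2 <- rowSums(sweep(frame[heavy, , drop = FALSE], 2,
                        frame[hyd[i], ])^2)
    j <- which.min(d2)
    out[i] <- if (d2[j] <= h_bond_dist^2) heavy[j] else NA_integer_
  }
  data.frame(h = hyd, heavy = out)[!is.na(out), , drop = FALSE]
}

#' Find hydrogen bonds in one frame
#'
#' @param frame \code{n x 3} coordinate matrix (Angstrom), rows matching
#'   \code{topology}.
#' @param topology atom table (see \code{\link{read_topology}}); hydrogens
#'   must be present.
#' @param criteria an \code{\link{hbond_criteria}}.
#' @return data.frame with columns \code{donor}, \code{hydrogen},
#'   \code{acceptor} (atom serials), \code{distance} (D-A, Angstrom) and
#'   \code{angle} (D-H-A, degrees).  Multiple hydrogens on one donor are
#'   handled symmetrically; each (donor, hydrogen, acceptor) triple appears
#'   at most once.
#' @export
find_hbonds <- function(frame, topology, criteria = hbond_criteria()) {
  frame <- matrix(frame, ncol = 3)
  stopifnot(nrow(frame) == nrow(topology))
  el <- toupper(topology$element)
  if (!any(el == "H"))
    stop("no hydrogens in topology; heavy-atom-only detection is not ",
         "meaningful with D-H-A angle criteria")
  hh <- attach_hydrogens(frame, topology, criteria$h_bond_dist)
  don_ok <- el %in% toupper(criteria$donor_elements)
  acc_idx <- which(el %in% toupper(criteria$acceptor_elements))
  res <- list()
  if (!is.null(hh) && nrow(hh) > 0) {
    hh <- hh[don_ok[hh$heavy], , drop = FALSE]
    for (r in seq_len(nrow(hh))) {
      d <- hh$heavy[r]; h <- hh$h[r]
      acc <- setdiff(acc_idx, d)
      if (!length(acc)) next
      dv <- sweep(frame[acc, , drop = FALSE], 2, frame[d, ])
      dist_da <- sqrt(rowSums(dv^2))
      keep <- dist_da <= criteria$d_max
      if (!any(keep)) next
      acc <- acc[keep]; dist_da <- dist_da[keep]
      v1 <- frame[d, ] - frame[h, ]
      ang <- vapply(acc, function(a) {
        v2 <- frame[a, ] - frame[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      }, numeric(1))
      keep2 <- ang >= criteria$angle_min
      if (!any(keep2)) next
      res[[length(res) + 1]] <- data.frame(
        donor = topology$serial[d], hydrogen = topology$serial[h],
        acceptor = topology$serial[acc[keep2]],
        distance = dist_da[keep2], angle = ang[keep2])
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  out <- do.call(rbind, res)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

## Default charged-group atom-name sets for salt bridges.  Methylated
## lysines (resnames MLZ/MLY/M3L/KM2/KM3) keep their N-zeta cationic.
SB_ANION_NAMES <- c("OD1", "OD2", "OE1", "OE2", "OXT")
SB_CATION_NAMES <- c("NH1", "NH2", "NE", "NZ", "ND1", "NE2")
SB_ANION_RES <- c("ASP", "GLU")
SB_CATION_RES <- c("ARG", "LYS", "HIS", "HIP", "MLZ", "MLY", "M3L",
                   "KM2", "KM3")

#' Find salt bridges in one frame
#'
#' Pairs any anionic carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2, terminal
#' OXT) with any cationic nitrogen (Arg NH1/NH2/NE, Lys and methylated-Lys
#' NZ, His ND1/NE2) at distance <= \code{d_max}; the boundary is closed.
#'
#' @param frame \code{n x 3} coordinate matrix.
#' @param topology atom table.
#' @param d_max cutoff, Angstrom (default 4.0).
#' @param anion_names,cation_names,anion_res,cation_res configurable atom
#'   and residue name sets.
#' @return data.frame with \code{anion}, \code{cation} serials, residue
#'   labels and \code{distance}.
#' @export
find_salt_bridges <- function(frame, topology, d_max = 4.0,
                              anion_names = SB_ANION_NAMES,
                              cation_names = SB_CATION_NAMES,
                              anion_res = SB_ANION_RES,
                              cation_res = SB_CATION_RES) {
  frame <- matrix(frame, ncol = 3)
  an <- which(topology$name %in% anion_names &
                (topology$resname %in% anion_res |
                   topology$name == "OXT"))
  ca <- which(topology$name %in% cation_names &
                topology$resname %in% cation_res)
  out <- list()
  for (i in an) {
    if (!length(ca)) break
    dv <- sweep(frame[ca, , drop = FALSE], 2, frame[i, ])
    dd <- sqrt(rowSums(dv^2))
    keep <- dd <= d_max
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      anion = topology$serial[i], cation = topology$serial[ca[keep]],
      anion_residue = paste0(topology$resname[i], topology$resid[i]),
      cation_residue = paste0(topology$resname[ca[keep]],
                              topology$resid[ca[keep]]),
      distance = dd[keep])
  }
  if (!length(out))
    return(data.frame(anion = integer(), cation = integer(),
                      anion_residue = character(),
                      cation_residue = character(), distance = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contact occupancy over a trajectory
#'
#' Detects hydrogen bonds (and optionally salt bridges) in every frame and
#' reports, per unique donor-acceptor atom pair, the percent of frames in
#' which the contact is present, together with its presence episodes
#' (maximal runs of consecutive frames, 0-based, inclusive).  A residue-pair
#' roll-up (max occupancy over atom pairs) is attached as attribute
#' \code{"residues"}.
#'
#' @param traj a \code{trajectory} with >= 1 frame.
#' @param topology atom table matching the trajectory.
#' @param criteria an \code{\link{hbond_criteria}}.
#' @param salt_bridges also include salt bridges (at \code{sb_dmax})?
#' @param sb_dmax salt-bridge cutoff, Angstrom.
#' @return data.frame with \code{donor}, \code{acceptor}, \code{type},
#'   \code{donor_residue}, \code{acceptor_residue}, \code{occupancy}
#'   (percent), \code{n_episodes} and \code{episodes} (list column of
#'   2-column matrices).
#' @export
occupancy <- function(traj, topology, criteria = hbond_criteria(),
                      salt_bridges = TRUE, sb_dmax = 4.0) {
  nf <- n_frames(traj)
  if (nf < 1) stop("no frames")
  present <- list()  # key -> integer frame vector
  meta <- list()
  for (k in seq_len(nf)) {
    xyz <- frame_coords(traj, k)
    hb <- find_hbonds(xyz, topology, criteria)
    pairs <- if (nrow(hb))
      data.frame(donor = hb$donor, acceptor = hb$acceptor, type = "hbond")
    else data.frame(donor = integer(), acceptor = integer(),
                    type = character())
    if (salt_bridges) {
      sb <- find_salt_bridges(xyz, topology, d_max = sb_dmax)
      if (nrow(sb))
        pairs <- rbind(pairs, data.frame(donor = sb$cation,
                                         acceptor = sb$anion,
                                         type = "salt_bridge"))
    }
    pairs <- unique(pairs)
    if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
      key <- paste(pairs$donor[r], pairs$acceptor[r], pairs$type[r],
                   sep = "|")
      present[[key]] <- c(present[[key]], k - 1L)   # 0-based frames
      if (is.null(meta[[key]]))
        meta[[key]] <- pairs[r, , drop = FALSE]
    }
  }
  if (!length(present))
    return(data.frame(donor = integer(), acceptor = integer(),
                      type = character(), donor_residue = character(),
                      acceptor_residue = character(), occupancy = numeric(),
                      n_episodes = integer()))
  res_label <- function(serial) {
    i <- match(serial, topology$serial)
    paste0(topology$resname[i], topology$resid[i])
  }
  keys <- names(present)
  episodes <- lapply(present, function(fr) {
    fr <- sort(fr)
    brk <- c(0, which(diff(fr) > 1), length(fr))
    t(vapply(seq_len(length(brk) - 1), function(b)
      c(start_frame = fr[brk[b] + 1], end_frame = fr[brk[b + 1]]),
      numeric(2)))
  })
  out <- do.call(rbind, meta[keys])
  out$donor_residue <- res_label(out$donor)
  out$acceptor_residue <- res_label(out$acceptor)
  out$occupancy <- 100 * vapply(present, length, 1L)[keys] / nf
  out$n_episodes <- vapply(episodes, nrow, 1L)[keys]
  out$episodes <- I(episodes[keys])
  rownames(out) <- NULL
  rollkey <- paste(out$donor_residue, out$acceptor_residue, out$type)
  roll <- do.call(rbind, lapply(split(out, rollkey), function(g)
    data.frame(donor_residue = g$donor_residue[1],
               acceptor_residue = g$acceptor_residue[1], type = g$type[1],
               occupancy = max(g$occupancy))))
  rownames(roll) <- NULL
  attr(out, "residues") <- roll
  out
}
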