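## Geometric observables: dihedral angles, radius of gyration, Kabsch
## superposition / RMSD, RMSF, distance series and dominant period.

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking along the p2-p3 bond, a clockwise rotation
#' of the far bond relative to the near bond is positive.  The angle is
#' reported in degrees on (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("degenerate dihedral: collinear bond frame")
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2n[3] - n1[3] * b2n[2],
          n1[3] * b2n[1] - n1[1] * b2n[3],
          n1[1] * b2n[2] - n1[2] * b2n[1])
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Dihedral time series over a trajectory
#'
#' Computes the torsion defined by four atom serials in every frame.  For a
#' methylated lysine the quad of interest is C-delta, C-epsilon, N-zeta and a
#' methyl carbon, which tracks the rotameric state of the methyl ammonium
#' group.
#'
#' @param traj a \code{trajectory}.
#' @param atom_quad four atom serials.
#' @return Object of class \code{dihedral_series}: list with \code{angles}
#'   (degrees, one per frame), \code{atom_quad} and \code{frame_interval}
#'   (ps).
#' @export
dihedral_series <- function(traj, atom_quad) {
  stopifnot(length(atom_quad) == 4)
  idx <- match(atom_quad, traj$atoms$serial)
  if (anyNA(idx)) stop("unknown atom serial(s): ",
                       paste(atom_quad[is.na(idx)], collapse = ", "))
  ang <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- frame_coords(traj, k)
    dihedral_angle(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
  }, numeric(1))
  structure(list(angles = ang, atom_quad = atom_quad,
                 frame_interval = traj$frame_interval),
            class = "dihedral_series")
}

#' Mass-weighted radius of gyration of one frame
#'
#' @param frame \code{n x 3} coordinate matrix (Angstrom).
#' @param masses atom masses (amu), all > 0.
#' @return Rg in Angstrom, about the center of mass.
#' @export
radius_of_gyration <- function(frame, masses) {
  frame <- matrix(frame, ncol = 3)
  stopifnot(nrow(frame) >= 1, length(masses) == nrow(frame), all(masses > 0))
  com <- colSums(frame * masses) / sum(masses)
  d2 <- rowSums(sweep(frame, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Radius-of-gyration time series
#' @param traj a \code{trajectory} (atom masses taken from its atom table).
#' @return Numeric vector, one Rg (Angstrom) per frame.
#' @export
rg_series <- function(traj) {
  m <- traj$atoms$mass
  vapply(seq_len(n_frames(traj)),
         function(k) radius_of_gyration(frame_coords(traj, k), m), numeric(1))
}

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD of \code{mobile} onto \code{reference}, via SVD of the
#' weighted covariance with the usual determinant sign correction so the
#' rotation is never a reflection.
#'
#' @param mobile,reference \code{n x 3} matrices, n >= 3, matched row order.
#' @param weights per-atom non-negative weights (default uniform).
#' @return List with \code{rotation} (3x3, det +1), \code{translation}
#'   (length 3), \code{rmsd} (Angstrom) and \code{transformed} (the moved
#'   mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- matrix(mobile, ncol = 3); reference <- matrix(reference, ncol = 3)
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 atoms for superposition")
  stopifnot(nrow(reference) == n)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- A %*% t(R)
  moved <- sweep(moved, 2, cr, "+")
  rmsd <- sqrt(sum(w * rowSums((moved - reference)^2)))
  list(rotation = R, translation = cr - as.vector(R %*% cm), rmsd = rmsd,
       transformed = moved)
}

#' RMSD time series against a reference frame
#' @param traj a \code{trajectory}.
#' @param reference \code{n x 3} reference coordinates (default: frame 1).
#' @param atom_selection optional atom serials to superpose on.
#' @return Numeric vector of minimised RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = NULL, atom_selection = NULL) {
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  idx <- if (is.null(atom_selection)) seq_len(nrow(traj$atoms)) else
    match(atom_selection, traj$atoms$serial)
  if (anyNA(idx)) stop("unknown atom serial(s) in selection")
  vapply(seq_len(n_frames(traj)), function(k)
    kabsch_superpose(frame_coords(traj, k)[idx, , drop = FALSE],
                     matrix(reference, ncol = 3)[idx, , drop = FALSE])$rmsd,
    numeric(1))
}

#' Root-mean-square fluctuation per atom
#'
#' RMSF of each selected atom about its time-mean position.  With
#' \code{align = TRUE} frames are first iteratively superposed onto the
#' running mean structure (until the mean structure moves by < 1e-6 Angstrom
#' RMSD, at most 10 iterations), removing global rigid motion.
#'
#' @param traj a \code{trajectory} with >= 2 frames.
#' @param atom_selection atom serials (default all atoms).
#' @param align superpose frames onto the mean structure first?
#' @return Named numeric vector of per-atom RMSF (Angstrom).
#' @export
rmsf <- function(traj, atom_selection = NULL, align = TRUE) {
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  idx <- if (is.null(atom_selection)) seq_len(nrow(traj$atoms)) else
    match(atom_selection, traj$atoms$serial)
  if (length(idx) == 0 || anyNA(idx)) stop("empty or invalid atom selection")
  X <- lapply(seq_len(nf), function(k)
    frame_coords(traj, k)[idx, , drop = FALSE])
  if (align && length(idx) >= 3) {
    ## canonical starting orientation: superpose everything onto frame 1
    ## first, so the iteration's fixed point is invariant to rigid motions
    ## applied to individual input frames
    X <- c(X[1], lapply(X[-1],
                        function(f) kabsch_superpose(f, X[[1]])$transformed))
    mean_str <- Reduce(`+`, X) / nf
    for (it in 1:10) {
      X <- lapply(X, function(f) kabsch_superpose(f, mean_str)$transformed)
      new_mean <- Reduce(`+`, X) / nf
      shift <- sqrt(mean(rowSums((new_mean - mean_str)^2)))
      mean_str <- new_mean
      if (shift < 1e-6) break
    }
  }
  mean_str <- Reduce(`+`, X) / nf
  msd <- Reduce(`+`, lapply(X, function(f) rowSums((f - mean_str)^2))) / nf
  out <- sqrt(msd)
  names(out) <- traj$atoms$serial[idx]
  out
}

#' Inter-atom distance time series
#'
#' Euclidean distance between two atoms in every frame; the observable used
#' to track e.g. the flap-to-core "breathing" distance of a two-lobe
#' structure.
#'
#' @param traj a \code{trajectory}.
#' @param atom_a,atom_b atom serials.
#' @return Numeric vector of distances (Angstrom) per frame.
#' @export
distance_series <- function(traj, atom_a, atom_b) {
  ia <- match(atom_a, traj$atoms$serial); ib <- match(atom_b, traj$atoms$serial)
  if (is.na(ia) || is.na(ib)) stop("unknown atom serial")
  vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- frame_coords(traj, k)
    sqrt(sum((xyz[ia, ] - xyz[ib, ])^2))
  }, numeric(1))
}

#' Dominant period of a time series
#'
#' FFT periodogram after mean removal.  The highest non-zero-frequency peak
#' is reported as the dominant period when its power exceeds
#' \code{prominence} times the median non-zero-frequency spectral power;
#' otherwise the series is called aperiodic.
#'
#' @param series numeric vector, length >= 8.
#' @param frame_interval sample spacing (ps).
#' @param prominence peak-to-median power ratio required (default 3).
#' @return Object of class \code{period_estimate}: list with \code{period}
#'   (ps, or NA when aperiodic), \code{aperiodic} flag, \code{method},
#'   and \code{confidence_span} (the +/- one-frequency-bin interval, ps).
#' @export
dominant_period <- function(series, frame_interval = 1, prominence = 3) {
  n <- length(series)
  if (n < 8) stop("need at least 8 samples")
  x <- series - mean(series)
  p <- Mod(stats::fft(x))^2
  half <- 2:floor(n / 2 + 1)              # positive frequencies
  pw <- p[half]
  k <- seq_along(pw)                      # cycles per record
  med <- stats::median(pw)
  peak <- which.max(pw)
  aper <- med <= 0 || pw[peak] < prominence * med
  if (aper || pw[peak] == 0) {
    return(structure(list(period = NA_real_, aperiodic = TRUE,
                          method = "fft_periodogram",
                          confidence_span = c(NA_real_, NA_real_)),
                     class = "period_estimate"))
  }
  period <- n * frame_interval / k[peak]
  lo <- n * frame_interval / (k[peak] + 1)
  hi <- if (k[peak] > 1) n * frame_interval / (k[peak] - 1) else Inf
  structure(list(period = period, aperiodic = FALSE,
                 method = "fft_periodogram",
                 confidence_span = c(lo, hi)),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  if (x$aperiodic) cat("period estimate: aperiodic\n")
  else cat(sprintf("period estimate: %.4g ps (bin span %.4g-%.4g ps, %s)\n",
                   x$period, x$confidence_span[1], x$confidence_span[2],
                   x$method))
  invisible(x)
}
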