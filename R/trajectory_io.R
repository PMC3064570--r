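## Trajectory, topology and energy-table input/output.
##
## Coordinates are Angstrom throughout, time in ps, frames 0-based in all
## reports.  Atom order is a stable contract: no operation in the package
## reorders atoms of a trajectory.

## Bundled element masses (amu) for PDB files lacking a topology sidecar.
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, CL = 35.45,
                    BR = 79.904, I = 126.904, `NA` = 22.990, K = 39.098,
                    MG = 24.305, CA = 40.078, ZN = 65.38, FE = 55.845)

DEFAULT_BACKBONE_NAMES <- c("N", "CA", "C", "O", "H", "HA")

#' Construct a trajectory object
#'
#' A trajectory couples an atom table with an ordered stack of coordinate
#' frames.  Every frame must supply exactly one (x, y, z) triple per atom.
#'
#' @param atoms data.frame with at least columns \code{serial}, \code{name},
#'   \code{resname}, \code{resid}; optionally \code{chain}, \code{element},
#'   \code{mass}, \code{charge}, \code{lj_sigma}, \code{lj_epsilon},
#'   \code{gb_radius}, \code{backbone}.
#' @param coords numeric array of dimension \code{c(n_atoms, 3, n_frames)}, in
#'   Angstrom.
#' @param frame_interval time between consecutive frames, ps (> 0).
#' @return An object of class \code{trajectory}.
#' @export
trajectory <- function(atoms, coords, frame_interval = 10) {
  stopifnot(is.data.frame(atoms))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(atoms))
    stop("coords has ", dim(coords)[1], " atoms but atom table has ",
         nrow(atoms))
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0 (ps)")
  structure(list(atoms = atoms, coords = coords,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, %.3g ps/frame\n",
              nrow(x$atoms), n_frames(x), x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{trajectory}.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one coordinate frame
#' @param traj a \code{trajectory}.
#' @param i frame index, 1-based.
#' @return \code{n_atoms x 3} matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[, , i], ncol = 3)
}

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE"), two,
                substr(gsub("^[0-9]+", "", nm), 1, 1))
  out
}

## ---- multi-model PDB ------------------------------------------------------

#' Read a multi-model PDB file as a trajectory
#'
#' Frames are ordered by MODEL number; a file without MODEL records yields a
#' single-frame trajectory.  Atom identity (name/residue) is taken from the
#' first model and must agree in count across models.
#'
#' @param path PDB file path.
#' @param frame_interval frame spacing in ps (default 10, the usual snapshot
#'   cadence for end-state analysis).
#' @return A \code{trajectory}.  Atoms carry \code{mass} looked up from a
#'   bundled element table (with a warning for unknown elements).
#' @export
read_pdb_models <- function(path, frame_interval = 10) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) {
    groups <- list(which(is_atom))
    model_ids <- 1L
  } else {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    groups <- lapply(seq_along(model_starts), function(k) {
      idx <- seq(model_starts[k], model_ends[k])
      idx[is_atom[idx]]
    })
    model_ids <- as.integer(sub("^MODEL\\s+", "", lines[model_starts]))
  }
  if (length(groups[[1]]) == 0) stop("no ATOM/HETATM records in ", path)

  parse_block <- function(idx) {
    ln <- lines[idx]
    data.frame(
      serial  = as.integer(substr(ln, 7, 11)),
      name    = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 21)),
      chain   = trimws(substr(ln, 22, 22)),
      resid   = as.integer(substr(ln, 23, 26)),
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      element = trimws(substr(ln, 77, 78)),
      stringsAsFactors = FALSE)
  }

  first <- parse_block(groups[[1]])
  n_atoms <- nrow(first)
  for (k in seq_along(groups)) {
    if (length(groups[[k]]) != n_atoms)
      stop(sprintf("MODEL %d has %d atoms; expected %d",
                   model_ids[k], length(groups[[k]]), n_atoms))
  }
  coords <- array(NA_real_, c(n_atoms, 3, length(groups)))
  for (k in seq_along(groups)) {
    blk <- parse_block(groups[[k]])
    coords[, , k] <- as.matrix(blk[, c("x", "y", "z")])
  }

  el <- first$element
  el[el == ""] <- guess_element(first$name[el == ""])
  el <- toupper(el)
  unknown <- !(el %in% names(ELEMENT_MASSES))
  if (any(unknown)) {
    warning("unknown element(s): ", paste(unique(el[unknown]), collapse = ", "),
            "; mass set from first letter where possible")
    el2 <- substr(el[unknown], 1, 1)
    el[unknown] <- ifelse(el2 %in% names(ELEMENT_MASSES), el2, "C")
  }
  atoms <- data.frame(serial = first$serial, name = first$name,
                      resname = first$resname, resid = first$resid,
                      chain = first$chain, element = el,
                      mass = unname(ELEMENT_MASSES[el]),
                      stringsAsFactors = FALSE)
  atoms$backbone <- atoms$name %in% DEFAULT_BACKBONE_NAMES
  trajectory(atoms, coords, frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame with a REMARK provenance header.
#' Coordinates are written with 3 decimals (the PDB fixed-width precision).
#'
#' @param traj a \code{trajectory}.
#' @param path output path.
#' @param seed optional RNG seed recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_pdb_models <- function(traj, path, seed = NULL) {
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("endstate")),
                  error = function(e) "dev")
  writeLines(sprintf("REMARK   1 endstate %s", ver), con)
  if (!is.null(seed))
    writeLines(sprintf("REMARK   1 seed %d", as.integer(seed)), con)
  nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
               sprintf("%-4s", a$name))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frame_coords(traj, k)
    writeLines(sprintf(
      "ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial, nm, a$resname, a$chain, a$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- topology sidecar -----------------------------------------------------

#' Read a topology sidecar table
#'
#' The topology is a TSV carrying the per-atom force-field inputs the
#' energetics module needs (partial charges, LJ parameters, intrinsic GB
#' radii), which cannot be recovered from PDB columns.  Expected header:
#' \code{serial name resname resid chain element mass charge lj_sigma
#' lj_epsilon gb_radius}.  Both "." and "," decimal separators are accepted.
#'
#' @param path TSV path.
#' @param backbone_names atom names flagged as backbone (default
#'   N, CA, C, O, H, HA).
#' @return data.frame of atoms ordered by serial, with logical
#'   \code{backbone} column.
#' @export
read_topology <- function(path, backbone_names = DEFAULT_BACKBONE_NAMES) {
  raw <- read_tsv_table(path)
  need <- c("serial", "name", "resname", "resid", "chain", "element",
            "mass", "charge", "lj_sigma", "lj_epsilon", "gb_radius")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("topology is missing column(s): ", paste(missing, collapse = ", "))
  top <- data.frame(
    serial = as.integer(raw$serial), name = raw$name, resname = raw$resname,
    resid = as.integer(raw$resid), chain = raw$chain, element = raw$element,
    mass = parse_num(raw$mass), charge = parse_num(raw$charge),
    lj_sigma = parse_num(raw$lj_sigma), lj_epsilon = parse_num(raw$lj_epsilon),
    gb_radius = parse_num(raw$gb_radius), stringsAsFactors = FALSE)
  if (anyDuplicated(top$serial))
    stop("duplicate atom serial(s): ",
         paste(unique(top$serial[duplicated(top$serial)]), collapse = ", "))
  if (anyNA(top$charge)) stop("non-numeric charge in topology")
  if (any(!is.na(top$mass) & top$mass <= 0)) stop("non-positive mass")
  top <- top[order(top$serial), , drop = FALSE]
  rownames(top) <- NULL
  top$backbone <- top$name %in% backbone_names
  top
}

#' Write a topology sidecar table
#' @param top data.frame as returned by \code{\link{read_topology}}.
#' @param path output TSV path.
#' @param seed optional seed recorded in the provenance header.
#' @return \code{path}, invisibly.
#' @export
write_topology <- function(top, path, seed = NULL) {
  cols <- c("serial", "name", "resname", "resid", "chain", "element",
            "mass", "charge", "lj_sigma", "lj_epsilon", "gb_radius")
  write_tsv_report(top[, cols], path, seed = seed)
}

## ---- per-snapshot energy tables -------------------------------------------

ENERGY_COMPONENTS <- c("e_bond", "e_angle", "e_torsion", "e_vdw", "e_coulomb",
                       "g_polar", "g_nonpolar")

#' Construct a per-snapshot energy-component table
#'
#' @param rows data.frame with column \code{frame} and any subset of
#'   \code{e_bond, e_angle, e_torsion, e_vdw, e_coulomb, g_polar, g_nonpolar}
#'   (kcal/mol).  Missing components are treated as absent, never as zero.
#' @param species_label one of \code{"complex"}, \code{"receptor"},
#'   \code{"ligand"}.
#' @return Object of class \code{energy_table}.
#' @export
energy_table <- function(rows, species_label = c("complex", "receptor",
                                                 "ligand")) {
  species_label <- match.arg(species_label)
  stopifnot(is.data.frame(rows), nrow(rows) >= 1, "frame" %in% names(rows))
  if (anyDuplicated(rows$frame))
    stop("duplicate frame index in energy table")
  rows <- rows[order(rows$frame), , drop = FALSE]
  rownames(rows) <- NULL
  comp <- intersect(ENERGY_COMPONENTS, names(rows))
  if (any(!vapply(rows[comp], function(x) all(is.finite(x)), logical(1))))
    stop("non-finite energy component value")
  structure(list(rows = rows, species = species_label, components = comp),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat(sprintf("energy_table (%s): %d snapshots, components: %s\n",
              x$species, nrow(x$rows), paste(x$components, collapse = ", ")))
  invisible(x)
}

#' Read a per-snapshot energy table
#'
#' @param path TSV with columns \code{frame} plus energy components in
#'   kcal/mol; comma decimals accepted.
#' @param species_label species the table belongs to.
#' @return An \code{energy_table}; columns absent from the file are marked
#'   absent (downstream assembly refuses to silently treat them as zero).
#' @export
read_energy_table <- function(path, species_label = "complex") {
  raw <- read_tsv_table(path)
  if (!"frame" %in% names(raw)) stop("energy table needs a 'frame' column")
  rows <- data.frame(frame = as.integer(raw$frame))
  for (cc in intersect(ENERGY_COMPONENTS, names(raw)))
    rows[[cc]] <- parse_num(raw[[cc]])
  energy_table(rows, species_label)
}

#' Write a per-snapshot energy table
#' @param tab an \code{energy_table}.
#' @param path output TSV path.
#' @param seed optional seed recorded in the provenance header.
#' @return \code{path}, invisibly.
#' @export
write_energy_table <- function(tab, path, seed = NULL) {
  write_tsv_report(tab$rows, path, seed = seed,
                   extra = sprintf("species: %s", tab$species))
}
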