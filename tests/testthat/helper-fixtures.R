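# Shared fixture builders.  Everything is generated in code; nothing binary.

# Minimal atom/topology table with sensible force-field-ish defaults.
make_topology <- function(names, elements, resnames = "GLY",
                          resids = 1, charges = 0, lj_sigma = 3.0,
                          lj_epsilon = 0.1, gb_radius = 1.5,
                          chain = "A") {
  n <- length(names)
  data.frame(serial = seq_len(n), name = names,
             resname = rep_len(resnames, n), resid = rep_len(resids, n),
             chain = rep_len(chain, n), element = elements,
             mass = rep_len(12, n), charge = rep_len(charges, n),
             lj_sigma = rep_len(lj_sigma, n),
             lj_epsilon = rep_len(lj_epsilon, n),
             gb_radius = rep_len(gb_radius, n),
             backbone = names %in% c("N", "CA", "C", "O", "H", "HA"),
             stringsAsFactors = FALSE)
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# Multi-model PDB text for a coordinate array (n_atoms x 3 x n_frames).
write_test_pdb <- function(coords, path, drop_atom_in_model = NULL) {
  n_atoms <- dim(coords)[1]
  lines <- character()
  for (k in seq_len(dim(coords)[3])) {
    lines <- c(lines, sprintf("MODEL     %4d", k))
    for (a in seq_len(n_atoms)) {
      if (!is.null(drop_atom_in_model) && k == drop_atom_in_model &&
          a == n_atoms) next
      lines <- c(lines, sprintf(
        "ATOM  %5d  C%-2d LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
        a, a, coords[a, 1, k], coords[a, 2, k], coords[a, 3, k]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Wrapped absolute angular difference in degrees.
ang_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# Frozen rate matrix object for barrier arithmetic tests.
make_rate_matrix <- function(k, frame_interval = 10) {
  states <- rownames(k)
  structure(list(k = k, counts = matrix(0L, nrow(k), ncol(k),
                                        dimnames = dimnames(k)),
                 time_in_state = stats::setNames(rep(1, nrow(k)), states),
                 populations = rep(1 / nrow(k), nrow(k)), states = states,
                 frame_interval = frame_interval, min_dwell = 1),
            class = "rate_matrix")
}
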