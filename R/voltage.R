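#' Constant-field ion-crossing experiment
#'
#' Applies a constant electric field along +z to a mixed ionic solution with
#' a frozen pore sheet and counts ion crossings of the membrane plane
#' through the pore aperture. The field is given in the conventional
#' kcal/mol/Angstrom/e and converted internally to kJ/mol/Angstrom/e.
#'
#' @param system A `pore_system` from [gen_solution()].
#' @param field Field strength, kcal/mol/Angstrom/e.
#' @param seed Integer seed.
#' @param n_steps Dynamics steps.
#' @param ff A [force_field()].
#' @param dt_fs,friction,temperature Integrator settings.
#' @param equilibrate_first Minimize + thermalize before the field run.
#' @param aperture_margin Added to the nominal pore radius for the radial
#'   crossing gate, Angstrom.
#' @return A list of class `crossing_record`: per-species field-direction
#'   crossing counts, the K+/(K+ + Na+) selectivity ratio, field, duration,
#'   seed.
#' @export
run_voltage <- function(system, field, seed, n_steps = 25000,
                        ff = force_field(), dt_fs = 2, friction = 1,
                        temperature = 300, equilibrate_first = TRUE,
                        aperture_margin = 2) {
  frame <- system$frame
  ion_species <- frame$species[system$ion_index]
  if (!length(system$ion_index)) {
    warning("no ions in the system: empty crossing record")
    return(structure(list(counts = integer(), ratio_K = NaN, field = field,
                          duration_ps = 0, seed = seed),
                     class = "crossing_record"))
  }
  vel <- NULL
  if (equilibrate_first) {
    eq <- equilibrate(frame, ff, seed = seed, temperature = temperature,
                      minimize_steps = 300, equil_ps = 2, dt_fs = dt_fs)
    frame <- eq$frame
    vel <- eq$velocities
  }
  cfg <- integrator_config(dt_fs = dt_fs, friction = friction,
                           temperature = temperature, seed = seed + 1)
  res <- integrate_frame(frame, cfg, n_steps = n_steps, ff = ff,
                         sample_stride = 0, field_E = field * 4.184,
                         count_crossings = TRUE,
                         aperture = system$sheet$nominal_radius +
                           aperture_margin,
                         velocities = vel)
  up <- res$crossings_up[system$ion_index]
  names(up) <- ion_species
  counts <- tapply(up, ion_species, sum)
  nK <- if ("K" %in% names(counts)) counts[["K"]] else 0L
  nNa <- if ("NA" %in% names(counts)) counts[["NA"]] else 0L
  ratio <- if (nK + nNa > 0) nK / (nK + nNa) else NaN
  structure(list(counts = counts,
                 crossings_up = res$crossings_up[system$ion_index],
                 crossings_down = res$crossings_down[system$ion_index],
                 ratio_K = ratio, field = field,
                 duration_ps = n_steps * dt_fs / 1000, seed = seed),
            class = "crossing_record")
}

#' @export
print.crossing_record <- function(x, ...) {
  cat(sprintf("crossing_record: field %.2f kcal/mol/A/e, %.1f ps\n",
              x$field, x$duration_ps))
  print(x$counts)
  cat(sprintf("  K+/(K+ + Na+) selectivity: %s\n", format(x$ratio_K)))
  invisible(x)
}

#' Count pore-plane crossings along a saved trajectory
#'
#' Counts sign changes of the wrapped z coordinate of an atom between
#' consecutive frames, gated on the radial distance from the pore axis.
#'
#' @param traj An [md_trajectory()].
#' @param atom Atom index (or species label resolved in the first frame).
#' @param aperture Radial gate, Angstrom (Inf disables the gate).
#' @return A list: `total`, `up`, `down` crossing counts.
#' @export
count_plane_crossings <- function(traj, atom, aperture = Inf) {
  if (is.character(atom)) {
    atom <- select_species(traj$frames[[1]], atom)
    if (length(atom) != 1) stop("species selection must name a single atom")
  }
  box <- traj$frames[[1]]$box
  zs <- vapply(traj$frames, function(f) f$xyz[atom, 3], 0)
  xs <- vapply(traj$frames, function(f) f$xyz[atom, 1], 0)
  ys <- vapply(traj$frames, function(f) f$xyz[atom, 2], 0)
  zw <- zs - box[3] * round(zs / box[3])
  up <- 0L; down <- 0L
  for (i in seq_along(zw)[-1]) {
    if (zw[i] * zw[i - 1] < 0 && abs(zw[i] - zw[i - 1]) < box[3] / 2) {
      rx <- xs[i] - box[1] * round(xs[i] / box[1])
      ry <- ys[i] - box[2] * round(ys[i] / box[2])
      if (sqrt(rx^2 + ry^2) < aperture) {
        if (zw[i] > 0) up <- up + 1L else down <- down + 1L
      }
    }
  }
  list(total = up + down, up = up, down = down)
}
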