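#' Langevin integrator configuration
#'
#' @param dt_fs Timestep, fs (2 fs with rigid waters).
#' @param friction Langevin friction, 1/ps (0 gives microcanonical
#'   velocity-Verlet dynamics).
#' @param temperature Target temperature, K.
#' @param seed Integer seed; mandatory for every stochastic run.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt_fs = 2, friction = 1, temperature = 300,
                              seed) {
  if (missing(seed)) stop("seed is mandatory for stochastic dynamics")
  if (dt_fs <= 0 || temperature <= 0 || friction < 0)
    stop("need dt_fs > 0, temperature > 0, friction >= 0")
  structure(list(dt_fs = dt_fs, friction = friction,
                 temperature = temperature, seed = as.integer(seed)),
            class = "integrator_config")
}

#' Forces and potential energy of a frame
#'
#' Lennard-Jones with C1 switching plus reaction-field Coulomb, under
#' minimum image, with intra-water pairs and wall-wall pairs excluded.
#' Frozen wall atoms receive forces but never move.
#'
#' @param frame An [md_frame()].
#' @param ff A [force_field()].
#' @return A list: `forces` (N x 3, kJ/mol/Angstrom), `energy`, `energy_lj`,
#'   `energy_coulomb` (kJ/mol).
#' @export
compute_forces <- function(frame, ff = force_field()) {
  at <- ff_atom_tables(frame, ff)
  sw <- effective_switching(ff, frame$box)
  .compute_forces_cpp(frame$xyz, at$mass, at$charge, at$eps, at$rmh,
                      at$mol, at$wall, frame$box, at$water_idx,
                      sw["r_on"], sw["r_off"], ff$eps_rf)
}

#' Steepest-descent energy minimization
#'
#' Displacement-capped steepest descent with rigid-water constraints
#' restored after every step; relaxes generated lattices before dynamics.
#'
#' @param frame An [md_frame()].
#' @param ff A [force_field()].
#' @param n_steps Iterations (default 500).
#' @param max_disp Per-step displacement cap, Angstrom.
#' @return The minimized [md_frame()].
#' @export
minimize_frame <- function(frame, ff = force_field(), n_steps = 500,
                           max_disp = 0.1) {
  at <- ff_atom_tables(frame, ff)
  sw <- effective_switching(ff, frame$box)
  xyz <- .minimize_cpp(frame$xyz, at$mass, at$charge, at$eps, at$rmh,
                       at$mol, at$wall, frame$box, at$water_idx,
                       sw["r_on"], sw["r_off"], ff$eps_rf, n_steps, max_disp)
  md_frame(frame$box, xyz, frame$species, validate = FALSE)
}

#' Langevin dynamics of a frame
#'
#' BAOAB-split Langevin dynamics with SHAKE/RATTLE rigid-water constraints.
#' Bit-reproducible for a given seed. Optionally applies a constant
#' electric field along +z and counts ion crossings of the z = 0 plane
#' through the pore aperture.
#'
#' @param frame Starting [md_frame()].
#' @param config An [integrator_config()].
#' @param n_steps Number of steps.
#' @param ff A [force_field()].
#' @param traj_stride Save a frame every this many steps (0 = none).
#' @param sample_stride Sample energies/temperature every this many steps.
#' @param field_E Constant field along +z, kJ/mol/Angstrom/e (0 = off).
#' @param count_crossings Track signed pore crossings of free ions.
#' @param aperture Radial aperture for crossing counting, Angstrom.
#' @param velocities Optional N x 3 starting velocities (restart).
#' @return A list of class `sim_result`: `final` frame, `velocities`,
#'   `trajectory` ([md_trajectory()] or NULL), `samples` data.frame
#'   (`t_ps`, `potential`, `kinetic`, `temperature`), `ndf`, crossing
#'   counts, and the seed.
#' @export
integrate_frame <- function(frame, config, n_steps, ff = force_field(),
                            traj_stride = 0, sample_stride = 50,
                            field_E = 0, count_crossings = FALSE,
                            aperture = Inf, velocities = NULL) {
  at <- ff_atom_tables(frame, ff)
  sw <- effective_switching(ff, frame$box)
  res <- .sim_run_cpp(frame$xyz, at$mass, at$charge, at$eps, at$rmh,
                      at$mol, at$wall, frame$box, at$water_idx,
                      sw["r_on"], sw["r_off"], ff$eps_rf,
                      config$dt_fs, config$friction, config$temperature,
                      as.integer(n_steps), config$seed,
                      as.integer(traj_stride), as.integer(sample_stride),
                      field_E, 0L, 0, count_crossings,
                      if (is.finite(aperture)) aperture else 1e6,
                      velocities)
  traj <- NULL
  if (traj_stride > 0 && length(res$frames))
    traj <- md_trajectory(
      lapply(res$frames, function(m) md_frame(frame$box, m, frame$species,
                                              validate = FALSE)),
      metadata = list(seed = config$seed))
  structure(list(
    final = md_frame(frame$box, res$xyz, frame$species, validate = FALSE),
    velocities = res$velocities,
    trajectory = traj,
    samples = res$samples,
    ndf = res$ndf,
    crossings_up = res$crossings_up,
    crossings_down = res$crossings_down,
    seed = config$seed), class = "sim_result")
}

#' Minimize then thermalize a generated system
#'
#' Convenience preparation: steepest descent followed by a short strongly
#' damped Langevin run.
#'
#' @param frame An [md_frame()].
#' @param ff A [force_field()].
#' @param seed Integer seed.
#' @param temperature Target temperature, K.
#' @param minimize_steps,equil_ps Minimization iterations and equilibration
#'   length (ps).
#' @param dt_fs Timestep, fs.
#' @return A list: `frame` (equilibrated), `velocities`.
#' @export
equilibrate <- function(frame, ff = force_field(), seed, temperature = 300,
                        minimize_steps = 500, equil_ps = 5, dt_fs = 2) {
  fr <- minimize_frame(frame, ff, n_steps = minimize_steps)
  cfg <- integrator_config(dt_fs = dt_fs, friction = 5,
                           temperature = temperature, seed = seed)
  res <- integrate_frame(fr, cfg, n_steps = round(equil_ps * 1000 / dt_fs),
                         ff = ff, sample_stride = 0)
  list(frame = res$final, velocities = res$velocities)
}

#' Instantaneous kinetic temperature of a simulation result
#'
#' @param result A `sim_result` from [integrate_frame()].
#' @return Mean and standard deviation of the sampled temperature, K.
#' @export
mean_temperature <- function(result) {
  s <- result$samples
  if (!nrow(s)) stop("no samples recorded")
  c(mean = mean(s$temperature), sd = stats::sd(s$temperature))
}
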