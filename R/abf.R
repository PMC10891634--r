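#' Adaptive-biasing-force configuration
#'
#' The collective variable (CV) is the axial distance from the test ion to
#' the pore plane. The CV range is broken into consecutive overlapping
#' windows (width 2.6 Angstrom, overlap 0.2 Angstrom by default) sampled
#' independently and stitched on their shared bins.
#'
#' @param cv_range Length-2 CV range, Angstrom.
#' @param window_width Window width, Angstrom (study protocol 2.5-2.7).
#' @param overlap Window overlap, Angstrom (at least one bin).
#' @param bin_width ABF bin width, Angstrom.
#' @param ramp Per-bin sample count before the full opposing mean force is
#'   applied (linear ramp below it).
#' @param steps_per_window Dynamics steps per window.
#' @return An object of class `abf_config` with the window bounds.
#' @export
abf_config <- function(cv_range = c(2, 12), window_width = 2.6,
                       overlap = 0.2, bin_width = 0.1, ramp = 500,
                       steps_per_window = 20000) {
  if (overlap < bin_width) stop("windows must overlap by at least one bin")
  if (ramp < 1) stop("ramp threshold must be >= 1")
  # snap to the bin grid so window bins line up globally
  snap <- function(x) round(x / bin_width) * bin_width
  cv_range <- snap(cv_range); window_width <- snap(window_width)
  overlap <- snap(overlap)
  lo <- cv_range[1]
  windows <- list()
  while (TRUE) {
    hi <- min(lo + window_width, cv_range[2])
    windows[[length(windows) + 1]] <- c(lo = lo, hi = hi)
    if (hi >= cv_range[2] - 1e-9) break
    lo <- hi - overlap
  }
  structure(list(cv_range = cv_range, window_width = window_width,
                 overlap = overlap, bin_width = bin_width, ramp = ramp,
                 steps_per_window = steps_per_window, windows = windows),
            class = "abf_config")
}

# assemble a PMF from per-bin force sums/counts: mean force, integration
# from the largest CV (anchor = 0), convergence flags
pmf_from_accumulators <- function(centers, force_sum, count, ramp,
                                  seed = NULL, config = NULL) {
  mean_force <- ifelse(count > 0, force_sum / pmax(count, 1), NA_real_)
  converged <- count >= ramp
  # interpolate across unvisited bins for the integral only
  mf <- mean_force
  if (anyNA(mf)) {
    ok <- !is.na(mf)
    if (sum(ok) < 2) stop("too few visited bins to integrate a PMF")
    mf <- stats::approx(centers[ok], mf[ok], xout = centers, rule = 2)$y
  }
  n <- length(centers)
  dx <- diff(centers)
  A <- numeric(n)
  for (i in seq(n - 1, 1)) {
    # dA/dxi = -<F>; integrate downward from the anchor at the largest CV
    A[i] <- A[i + 1] + 0.5 * (mf[i] + mf[i + 1]) * dx[i]
  }
  structure(list(cv = centers, mean_force = mean_force, free_energy = A,
                 samples = as.integer(count), converged = converged,
                 seed = seed,
                 config_hash = if (is.null(config)) NULL else
                   config_hash(config)),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %d bins over [%.2f, %.2f], %d converged\n",
              length(x$cv), min(x$cv), max(x$cv), sum(x$converged)))
  cat(sprintf("  barrier (max - anchor): %.3f kJ/mol\n", max(x$free_energy)))
  invisible(x)
}

#' Barrier height of a PMF profile
#'
#' @param profile A `pmf_profile`.
#' @param converged_only Use converged bins only.
#' @return `max(A) - min(A)` over the selected bins, kJ/mol.
#' @export
pmf_barrier <- function(profile, converged_only = TRUE) {
  A <- profile$free_energy
  if (converged_only && any(profile$converged)) A <- A[profile$converged]
  max(A) - min(A)
}

#' ABF potential of mean force for an ion entering a nanopore
#'
#' Runs windowed adaptive-biasing-force Langevin dynamics of a test ion
#' restrained to the axis of a frozen graphene-like nanopore in a periodic
#' water box. Each window gets an independently generated, minimized and
#' thermalized system with the ion started in its lower third; per-bin
#' mean forces are pooled on the shared global bin grid and integrated into
#' a PMF anchored at the largest CV.
#'
#' @param pore_radius Nominal pore radius, Angstrom.
#' @param ion Test-ion species (`"K"` or `"NA"`).
#' @param seed Integer seed (window seeds are derived from it).
#' @param config An [abf_config()].
#' @param box Box edges, Angstrom.
#' @param n_waters Water count (default from density and box).
#' @param density Water density, g/cm^3.
#' @param ff A [force_field()].
#' @param dt_fs,friction,temperature Integrator settings.
#' @param k_trans Transverse harmonic restraint to the pore axis,
#'   kJ/mol/Angstrom^2.
#' @param k_wall Window-boundary restraint, kJ/mol/Angstrom^2.
#' @param equil_steps Discarded thermalization steps per window.
#' @param min_steps Minimization iterations per window.
#' @param traj_stride Collect frames every this many steps (0 = none);
#'   frames from all windows are concatenated for water-structure analyses.
#' @param sequential Drag one continuous system through the windows from
#'   the largest CV inward, instead of the default independent system per
#'   window (independent windows cover steep near-contact regions better,
#'   because each starts with the ion already placed there).
#' @return A `pmf_profile` with extra fields `windows` (per-window
#'   accumulators) and `trajectory`.
#' @export
run_abf <- function(pore_radius = 3.7, ion = "K", seed,
                    config = abf_config(), box = c(40, 40, 60),
                    n_waters = NULL, density = 0.997, ff = force_field(),
                    dt_fs = 2, friction = 1, temperature = 300,
                    k_trans = 40, k_wall = 100, equil_steps = 1000,
                    min_steps = 300, traj_stride = 0, sequential = FALSE) {
  centers <- seq(config$cv_range[1] + config$bin_width / 2,
                 config$cv_range[2] - config$bin_width / 2 + 1e-9,
                 by = config$bin_width)
  gsum <- numeric(length(centers))
  gcount <- integer(length(centers))
  windows_out <- list()
  all_frames <- list()
  worder <- if (sequential) rev(seq_along(config$windows)) else
    seq_along(config$windows)
  state <- NULL   # carried frame + velocities in sequential mode
  fr <- NULL; at <- NULL; sw <- NULL; ion_index <- NULL
  for (w in worder) {
    win <- config$windows[[w]]
    wseed <- (seed * 1009L + w * 7919L) %% 2147483647L
    if (is.null(state)) {
      # start in the lower third: for sub-critical pores the free energy
      # climbs toward contact, and a walker seeded there samples the hard
      # bins before sliding downhill
      sys <- gen_pore_system(pore_radius = pore_radius, ion = ion,
                             ion_z = win["lo"] + 0.35 * (win["hi"] - win["lo"]),
                             box = box, seed = wseed, density = density,
                             n_waters = n_waters)
      fr <- minimize_frame(sys$frame, ff, n_steps = min_steps)
      at <- ff_atom_tables(fr, ff)
      sw <- effective_switching(ff, fr$box)
      ion_index <- sys$ion_index
    } else {
      fr <- md_frame(fr$box, state$xyz, fr$species, validate = FALSE)
    }
    # thermalize inside the window restraints, no bias, no estimate
    pre <- .sim_abf_cpp(fr$xyz, at$mass, at$charge, at$eps, at$rmh, at$mol,
                        at$wall, fr$box, at$water_idx, sw["r_on"],
                        sw["r_off"], ff$eps_rf, dt_fs, 5, temperature,
                        as.integer(equil_steps), wseed, ion_index,
                        win["lo"], win["hi"], config$bin_width,
                        .Machine$integer.max, k_trans, k_wall, 0L,
                        if (is.null(state)) NULL else state$velocities,
                        NULL, NULL, .Machine$integer.max)
    # production: the bias adapts over the whole run (keeps sampling
    # covering the window); the reported mean force only accumulates after
    # a burn-in, dropping the adaptation transient
    n_steps <- as.integer(config$steps_per_window)
    burn <- as.integer(ceiling(0.4 * n_steps))
    res <- .sim_abf_cpp(pre$xyz, at$mass, at$charge, at$eps, at$rmh, at$mol,
                        at$wall, fr$box, at$water_idx, sw["r_on"],
                        sw["r_off"], ff$eps_rf, dt_fs, friction, temperature,
                        n_steps, wseed + 1L,
                        ion_index, win["lo"], win["hi"],
                        config$bin_width, as.integer(config$ramp), k_trans,
                        k_wall, as.integer(traj_stride),
                        pre$velocities, NULL, NULL, burn)
    if (sequential) state <- list(xyz = res$xyz,
                                  velocities = res$velocities)
    # map window bins onto the global grid
    idx <- round((res$bin_centers - centers[1]) / config$bin_width) + 1L
    ok <- idx >= 1 & idx <= length(centers)
    gsum[idx[ok]] <- gsum[idx[ok]] + res$force_sum[ok]
    gcount[idx[ok]] <- gcount[idx[ok]] + res$count[ok]
    windows_out[[w]] <- list(lo = unname(win["lo"]), hi = unname(win["hi"]),
                             seed = wseed, count = res$count)
    if (traj_stride > 0 && length(res$frames)) {
      template_species <- fr$species
      all_frames <- c(all_frames, lapply(res$frames, function(m)
        md_frame(fr$box, m, fr$species, validate = FALSE)))
    }
  }
  prof <- pmf_from_accumulators(centers, gsum, gcount, config$ramp,
                                seed = seed,
                                config = list(pore_radius = pore_radius,
                                              ion = ion, box = box,
                                              abf = unclass(config)))
  prof$windows <- windows_out
  prof$trajectory <- if (length(all_frames))
    md_trajectory(all_frames, metadata = list(seed = seed)) else NULL
  prof$ion <- ion
  prof$pore_radius <- pore_radius
  prof
}

#' ABF on an analytic one-dimensional landscape
#'
#' Validates the bias estimator: a single Langevin particle on a closed-form
#' potential, with the recovered PMF comparable to the exact one.
#'
#' @param landscape A [gen_toy_landscape()] object.
#' @param lo,hi Sampled CV range.
#' @param seed Integer seed.
#' @param bin_width Bin width.
#' @param ramp Per-bin ramp-up threshold.
#' @param n_steps Dynamics steps.
#' @param dt,gamma Timestep and friction (generic units).
#' @param kT Thermal energy (kJ/mol scale by default).
#' @param mass Particle mass.
#' @param x0 Starting position (default window center).
#' @param apply_bias Apply the adaptive bias (TRUE) or sample unbiased.
#' @return A `pmf_profile`.
#' @export
abf_landscape <- function(landscape, lo = -3, hi = 3, seed,
                          bin_width = 0.1, ramp = 200, n_steps = 400000,
                          dt = 0.01, gamma = 1, kT = 2.494, mass = 1,
                          x0 = NULL, apply_bias = TRUE) {
  form <- match(landscape$form, c("flat", "harmonic", "double-well")) - 1L
  pars <- switch(landscape$form,
    flat = c(0, 0),
    harmonic = c(landscape$params$k, landscape$params$x0),
    "double-well" = c(landscape$params$height, landscape$params$b))
  if (is.null(x0)) x0 <- (lo + hi) / 2
  res <- .abf1d_cpp(form, pars, lo, hi, bin_width, as.integer(ramp),
                    as.integer(n_steps), dt, gamma, kT, mass,
                    as.integer(seed), x0, apply_bias)
  pmf_from_accumulators(res$bin_centers, res$force_sum, res$count, ramp,
                        seed = seed,
                        config = list(form = landscape$form,
                                      params = landscape$params))
}

#' Pool ABF profiles from replicate runs
#'
#' Merges the per-bin force accumulators of replicate `pmf_profile`s
#' (identical bin grids) into one better-sampled profile; statistically
#' equivalent to having run one longer simulation per window.
#'
#' @param profiles List of `pmf_profile`s from [run_abf()] with identical
#'   bin centers.
#' @param ramp Convergence threshold for the pooled profile.
#' @return A pooled `pmf_profile`.
#' @export
pool_pmf <- function(profiles, ramp = 300) {
  stopifnot(length(profiles) >= 1)
  cv <- profiles[[1]]$cv
  for (p in profiles)
    if (!isTRUE(all.equal(p$cv, cv)))
      stop("profiles must share one bin grid")
  fsum <- numeric(length(cv))
  count <- integer(length(cv))
  for (p in profiles) {
    add <- ifelse(p$samples > 0, p$mean_force * p$samples, 0)
    fsum <- fsum + add
    count <- count + p$samples
  }
  pmf_from_accumulators(cv, fsum, count, ramp,
                        seed = profiles[[1]]$seed)
}
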