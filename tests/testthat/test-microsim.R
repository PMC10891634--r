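test_that("Lennard-Jones pair at its minimum distance feels no force", {
  ff <- force_field()
  rmin <- 2 * ff$species$C$rmin_half
  fr <- md_frame(c(20, 20, 20), rbind(c(0, 0, 0), c(rmin, 0, 0)),
                 c("C", "C"))
  # wall-wall pairs are excluded, so promote one to a fake mobile species:
  # use two neutral carbons via a modified parameter set on K labels
  ff2 <- ff
  ff2$species$K$charge <- 0
  ff2$species$K$epsilon <- ff$species$C$epsilon
  ff2$species$K$rmin_half <- ff$species$C$rmin_half
  fr2 <- md_frame(c(20, 20, 20), rbind(c(0, 0, 0), c(rmin, 0, 0)),
                  c("K", "K"))
  f <- compute_forces(fr2, ff2)
  expect_lt(max(abs(f$forces)), 1e-10)
  expect_equal(f$energy, -ff$species$C$epsilon, tolerance = 1e-10)
})

test_that("Coulomb energy carries the 1389.35 kJ A/mol constant through the
           reaction field", {
  ff <- force_field()
  ff$species$K$epsilon <- 0
  ff$species$CL$epsilon <- 0
  r <- 5
  fr <- md_frame(c(30, 30, 30), rbind(c(0, 0, 0), c(r, 0, 0)),
                 c("K", "CL"))
  f <- compute_forces(fr, ff)
  # hand evaluation: conducting-boundary reaction field at cutoff 12
  rc <- 12
  krf <- 1 / (2 * rc^3)
  crf <- 1 / rc + krf * rc^2
  want <- 1389.35457 * (1) * (-1) * (1 / r + krf * r^2 - crf)
  expect_equal(f$energy_coulomb, want, tolerance = 1e-9)
  # the bare-Coulomb part dominates: remove the RF correction and recover
  # 1389.35 / 5 to a tenth of a percent of itself
  bare <- f$energy_coulomb - 1389.35457 * (-1) * (krf * r^2 - crf)
  expect_equal(bare, -1389.35457 / 5, tolerance = 1e-9)
})

test_that("analytic forces match central-difference energy gradients", {
  ff <- force_field()
  fr <- gen_water_box(box = c(14, 14, 14), seed = 21, n_waters = 25,
                      extra_species = c("K", "CL"),
                      extra_xyz = rbind(c(3, 3, 3), c(-3, -3, -3)))
  f0 <- compute_forces(fr, ff)
  expect_lt(max(abs(colSums(f0$forces))), 1e-9)  # isolated system: zero net
  h <- 1e-5
  set.seed(22)
  for (i in sample(nrow(fr$xyz), 6)) {
    for (k in 1:3) {
      xp <- fr; xp$xyz[i, k] <- xp$xyz[i, k] + h
      xm <- fr; xm$xyz[i, k] <- xm$xyz[i, k] - h
      num <- -(compute_forces(xp, ff)$energy -
                 compute_forces(xm, ff)$energy) / (2 * h)
      expect_equal(num, f0$forces[i, k],
                   tolerance = 1e-6 * max(1, abs(f0$forces[i, k])))
    }
  }
  expect_error(compute_forces(md_frame(c(10, 10, 10),
                                       matrix(0, 1, 3), "XX"), ff),
               "parameterization")
})

test_that("frictionless dynamics conserve energy and rigid waters stay
           rigid", {
  ff <- force_field()
  eq <- equilibrated_box()
  cfg <- integrator_config(dt_fs = 1, friction = 0, temperature = 300,
                           seed = 51)
  r <- integrate_frame(eq$frame, cfg, 10000, ff, sample_stride = 50,
                       velocities = eq$velocities)
  E <- r$samples$potential + r$samples$kinetic
  t <- r$samples$t_ps
  drift <- abs(coef(lm(E ~ t))[2] * (max(t) - min(t)))
  expect_lt(drift / abs(mean(E)), 1e-4)   # < 0.01% over 10^4 steps
  # constraints restored to tolerance at the end
  wi <- water_index(r$final)
  d1 <- sqrt(rowSums((r$final$xyz[wi[, 2], ] - r$final$xyz[wi[, 1], ])^2))
  dhh <- sqrt(rowSums((r$final$xyz[wi[, 3], ] - r$final$xyz[wi[, 2], ])^2))
  expect_lt(max(abs(d1 - 0.9572)), 1e-5)
  expect_lt(max(abs(dhh - 2 * 0.9572 * sin(104.52 / 2 * pi / 180))), 1e-5)
})

test_that("the thermostat holds the equipartition temperature", {
  ff <- force_field()
  eq <- equilibrated_box()
  cfg <- integrator_config(dt_fs = 2, friction = 1, temperature = 300,
                           seed = 52)
  r <- integrate_frame(eq$frame, cfg, 4000, ff, sample_stride = 20,
                       velocities = eq$velocities)
  Tm <- mean(r$samples$temperature)
  se <- sd(r$samples$temperature) / sqrt(nrow(r$samples) / 10) # lag margin
  expect_lt(abs(Tm - 300), max(3 * se, 12))
})

test_that("trajectories are bit-identical for the same seed", {
  ff <- force_field()
  eq <- equilibrated_box()
  cfg <- integrator_config(dt_fs = 2, friction = 2, temperature = 300,
                           seed = 53)
  r1 <- integrate_frame(eq$frame, cfg, 300, ff, traj_stride = 100,
                        velocities = eq$velocities)
  r2 <- integrate_frame(eq$frame, cfg, 300, ff, traj_stride = 100,
                        velocities = eq$velocities)
  expect_identical(r1$final$xyz, r2$final$xyz)
  expect_identical(r1$velocities, r2$velocities)
  r3 <- integrate_frame(eq$frame,
                        integrator_config(dt_fs = 2, friction = 2,
                                          temperature = 300, seed = 54),
                        300, ff, velocities = NULL)
  expect_false(identical(r1$final$xyz, r3$final$xyz))
})

test_that("a Langevin harmonic oscillator reproduces the Boltzmann
           variance", {
  k <- 2; kT <- 2.494
  L <- gen_toy_landscape("harmonic", list(k = k, x0 = 0))
  prof <- abf_landscape(L, lo = -5, hi = 5, seed = 61, n_steps = 5e6,
                        bin_width = 0.1, apply_bias = FALSE)
  p <- prof$samples / sum(prof$samples)
  v <- sum(p * prof$cv^2) - sum(p * prof$cv)^2
  expect_lt(abs(v - kT / k) / (kT / k), 0.02)
})

test_that("the adaptive bias recovers closed-form landscapes", {
  kT <- 2.494
  # harmonic: RMS against the exact parabola under 0.1 kT
  L <- gen_toy_landscape("harmonic", list(k = 2, x0 = 0))
  prof <- abf_landscape(L, lo = -3, hi = 3, seed = 62, n_steps = 4e5)
  ref <- L$pmf(prof$cv)
  dev <- (prof$free_energy - mean(prof$free_energy)) - (ref - mean(ref))
  expect_lt(sqrt(mean(dev^2)), 0.1 * kT)
  # double well: barrier within 5% of the dense-grid reference
  dw <- gen_toy_landscape("double-well", list(height = 6, b = 1.5))
  prof2 <- abf_landscape(dw, lo = -2.6, hi = 2.6, seed = 63, n_steps = 6e5)
  xs <- seq(-1.5, 1.5, by = 1e-4)
  ref_barrier <- max(dw$U(xs)) - min(dw$U(xs))
  mid <- abs(prof2$cv) < 0.3
  wells <- prof2$cv < -1 | prof2$cv > 1
  got <- max(prof2$free_energy[mid]) - min(prof2$free_energy[wells])
  expect_lt(abs(got - ref_barrier) / ref_barrier, 0.05)
  # flat landscape: recovered PMF flat within sampling noise
  fl <- gen_toy_landscape("flat")
  prof3 <- abf_landscape(fl, lo = -2, hi = 2, seed = 64, n_steps = 3e5)
  expect_lt(diff(range(prof3$free_energy)), 0.3 * kT)
})
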