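test_that("the crossing counter scores a scripted trajectory exactly", {
  # an ion shuttling through the plane three times inside the aperture,
  # plus one passage far off-axis that the radial gate must reject
  zs <- c(4, 2, -2, -3, 1, 3, -4, 4, 4)
  xs <- c(0, 0, 0, 0, 0, 0, 0, 10, 10)
  frames <- lapply(seq_along(zs), function(i)
    md_frame(c(24, 24, 24), rbind(c(xs[i], 0, zs[i])), "K"))
  traj <- md_trajectory(frames)
  got <- count_plane_crossings(traj, "K", aperture = 5)
  expect_identical(got$total, 3L)
  expect_identical(got$down, 2L)
  expect_identical(got$up, 1L)
  # widening the gate picks up the off-axis passage
  expect_identical(count_plane_crossings(traj, "K", aperture = Inf)$total,
                   4L)
})

test_that("field-driven runs cross more with stronger fields and sit still
           without one", {
  ff <- force_field()
  sys <- gen_solution(pore_radius = 3.7, n_K = 3, n_Na = 3, n_Cl = 6,
                      box = c(18, 18, 24), seed = 71, n_waters = 140)
  r0 <- run_voltage(sys, field = 0, seed = 72, n_steps = 3000, ff = ff)
  rhi <- run_voltage(sys, field = 8, seed = 72, n_steps = 3000, ff = ff)
  total0 <- sum(r0$crossings_up) + sum(r0$crossings_down)
  expect_lt(total0, 3)   # no drive: essentially no pore traffic
  expect_gte(sum(rhi$crossings_up), sum(r0$crossings_up))
  expect_true(is.nan(rhi$ratio_K) || (rhi$ratio_K >= 0 && rhi$ratio_K <= 1))
  # empty-ion systems yield an empty record with a warning
  empty <- list(frame = gen_water_box(box = c(14, 14, 14), seed = 1,
                                      n_waters = 10),
                ion_index = integer(),
                sheet = list(nominal_radius = 3.7))
  expect_warning(r <- run_voltage(empty, field = 2, seed = 1,
                                  n_steps = 10, ff = ff), "no ions")
  expect_identical(r$duration_ps, 0)
})
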