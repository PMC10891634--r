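test_that("water counts follow density arithmetic and generation is a pure
           function of the seed", {
  # independent density arithmetic for the 40 x 40 x 60 study box
  vol_cm3 <- 40 * 40 * 60 * 1e-24
  want <- round(0.997 * vol_cm3 * 6.02214076e23 / 18.0154)
  expect_identical(waters_for_density(c(40, 40, 60), 0.997), want)
  expect_identical(waters_for_density(c(40, 40, 60), 1.0),
                   round(1.0 * vol_cm3 * 6.02214076e23 / 18.0154))
  b1 <- gen_water_box(box = c(14, 14, 14), seed = 4, n_waters = 30)
  b2 <- gen_water_box(box = c(14, 14, 14), seed = 4, n_waters = 30)
  b3 <- gen_water_box(box = c(14, 14, 14), seed = 5, n_waters = 30)
  expect_identical(b1$xyz, b2$xyz)
  expect_false(identical(b1$xyz, b3$xyz))
  # zero waters is a valid empty frame
  empty <- gen_water_box(box = c(10, 10, 10), seed = 1, n_waters = 0)
  expect_identical(nrow(empty$xyz), 0L)
  expect_error(gen_water_box(box = c(10, 10, 10), seed = 1, density = 2),
               "0.8-1.2")
  expect_error(gen_water_box(box = c(8, 8, 8), seed = 1, n_waters = 60,
                             exclude = matrix(0, 1, 3),
                             exclude_radius = 6), "packing")
})

test_that("graphene sheets have the honeycomb bond length and the pore
           removal matches a distance filter", {
  intact <- gen_graphene_pore(c(30, 30, 40), pore_radius = 0)
  expect_identical(intact$n_removed, 0L)
  # nearest-neighbor distance on the intact sheet is the C-C bond
  d <- as.matrix(dist(intact$xyz[, 1:2]))
  diag(d) <- Inf
  expect_equal(min(d), 1.42, tolerance = 1e-9)
  # brute-force removal oracle
  pore <- gen_graphene_pore(c(30, 30, 40), pore_radius = 3.7)
  rad <- sqrt(rowSums(intact$xyz[, 1:2]^2))
  expect_identical(pore$n_removed, sum(rad < 3.7))
  keep <- intact$xyz[rad >= 3.7, ]
  expect_equal(sort(keep[, 1]), sort(pore$xyz[, 1]), tolerance = 1e-12)
  # monotone removal and the accessible-radius convention
  p56 <- gen_graphene_pore(c(30, 30, 40), pore_radius = 5.6)
  expect_gt(p56$n_removed, pore$n_removed)
  expect_equal(pore$accessible_radius,
               min(sqrt(rowSums(pore$xyz[, 1:2]^2))) - 1.9924,
               tolerance = 1e-12)
  expect_error(gen_graphene_pore(c(12, 12, 20), pore_radius = 6),
               "degenerate")
})

test_that("toy landscapes expose consistent potentials, gradients and
           closed-form PMFs", {
  h <- gen_toy_landscape("harmonic", list(k = 1, x0 = 0))
  x <- seq(-2, 2, by = 0.1)
  expect_equal(h$pmf(x), 0.5 * x^2, tolerance = 1e-14)
  expect_equal(which.min(h$pmf(x)), which(x == 0))
  f <- gen_toy_landscape("flat")
  expect_true(all(f$grad(x) == 0))
  dw <- gen_toy_landscape("double-well", list(height = 5, b = 1.5))
  # barrier from a dense grid scan of the stated form
  xs <- seq(-1.5, 1.5, by = 1e-4)
  expect_equal(max(dw$U(xs)) - min(dw$U(xs)), 5, tolerance = 1e-6)
  # gradient consistent with a numerical derivative
  num <- (dw$U(x + 1e-6) - dw$U(x - 1e-6)) / 2e-6
  expect_equal(dw$grad(x), num, tolerance = 1e-5)
})

test_that("ion-water and pore systems assemble with the expected species
           bookkeeping", {
  sys <- gen_ion_water_system("NA", n_waters = 40, seed = 8)
  expect_identical(sum(sys$species == "NA"), 1L)
  expect_identical(sum(sys$species == "OW"), 40L)
  ps <- gen_pore_system(pore_radius = 3.7, ion = "K", ion_z = 6,
                        box = c(18, 18, 26), seed = 8)
  expect_identical(ps$frame$species[ps$ion_index], "K")
  expect_true(all(ps$frame$species[ps$wall_index] == "C"))
  expect_equal(ps$frame$xyz[ps$ion_index, 3], 6, tolerance = 1e-12)
  sol <- gen_solution(pore_radius = 3.7, n_K = 3, n_Na = 3, n_Cl = 6,
                      box = c(20, 20, 26), seed = 8)
  expect_identical(sol$charge, 0)
  expect_identical(as.integer(sort(table(sol$frame$species[sol$ion_index]))),
                   c(3L, 3L, 6L))
})
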