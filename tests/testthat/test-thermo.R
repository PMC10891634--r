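test_that("hydration free energy has the two-term structure and limits", {
  p <- water_params()
  # interfacial term vanishes for a macroscopic solute
  expect_lt(abs(hydration_free_energy(1e9, p) - p$dG_water_water), 1e-6)
  # the two terms are equal at the critical radius
  Rc <- critical_radius(p)
  expect_equal(hydration_free_energy(Rc, p), 2 * p$dG_water_water,
               tolerance = 1e-12)
  # hand evaluation of the closed form at R = 3.25
  expect_equal(hydration_free_energy(3.25, p),
               -4.58 + 8 * (-2.66) * 1.4 / 3.25, tolerance = 1e-12)
  # strictly increasing in R, bounded above by the bulk term
  R <- seq(0.5, 30, by = 0.25)
  g <- hydration_free_energy(R, p)
  expect_true(all(diff(g) > 0))
  expect_true(all(g < p$dG_water_water))
  expect_error(hydration_free_energy(-1, p), "positive")
})

test_that("critical radius matches a bisection oracle and scales linearly", {
  p <- water_params()
  expect_equal(critical_radius(p), 6.5, tolerance = 0.05 / 6.5)
  # brute-force root of dG_solute_water(R) = dG_water_water
  for (seed in 1:5) {
    set.seed(seed)
    q <- water_params(dG_DDAA = -runif(1, 0.5, 5), r_H2O = runif(1, 1, 2),
                      dG_water_water = -runif(1, 2, 8))
    f <- function(R) 8 * q$dG_DDAA * q$r_H2O / R - q$dG_water_water
    root <- uniroot(f, c(1e-3, 1e3), tol = 1e-12)$root
    expect_equal(critical_radius(q), root, tolerance = 1e-8)
  }
  # halving dG_DDAA halves the radius
  p2 <- water_params(dG_DDAA = -2.66 / 2)
  expect_equal(critical_radius(p2), critical_radius(p) / 2,
               tolerance = 1e-12)
})

test_that("solvation regimes flip exactly at the critical radius", {
  p <- water_params()
  expect_identical(classify_regime(5, p), "initial")
  expect_identical(classify_regime(8, p), "hydrophobic")
  expect_identical(classify_regime(critical_radius(p), p), "critical")
})

test_that("two identical spheres go critical at half the single radius", {
  p <- water_params()
  expect_equal(pair_critical_distance(p), 3.25, tolerance = 0.05 / 3.25)
  p13 <- water_params(dG_water_water = -4.58 * critical_radius(p) / 13)
  expect_equal(critical_radius(p13), 13, tolerance = 1e-9)
  expect_equal(pair_critical_distance(p13), 6.5, tolerance = 1e-9)
  expect_equal(pair_critical_distance(p), critical_radius(p) / 2,
               tolerance = 1e-14)
})

test_that("membrane measure has its closed-form endpoints and decay", {
  w <- 20
  expect_equal(membrane_measure(0, w), pi * w, tolerance = 1e-14)
  # 3-4-5 triangle
  expect_equal(membrane_measure(15, 20), pi * 10, tolerance = 1e-12)
  d <- seq(0, 500, by = 0.5)
  m <- membrane_measure(d, w)
  expect_true(all(diff(m) < 0))
  # large-distance series pi w^2 / (2 d) for d/w > 100
  dfar <- c(2500, 5000, 10000)
  expect_equal(membrane_measure(dfar, w), pi * w^2 / (2 * dfar),
               tolerance = 1e-4)
  expect_error(membrane_measure(-1, w), "non-negative")
})

test_that("circle measure is the reciprocal center-center distance", {
  g <- ion_pore_geometry(r_ion = 1.3, R_pore = 3.7, sep = 0)
  expect_equal(circle_measure(g), 0.2, tolerance = 1e-14)
  expect_equal(circle_measure(ion_pore_geometry(1.3, 3.7, sep = 1e9)), 0,
               tolerance = 1e-8)
  g2 <- ion_pore_geometry(r_ion = 2.6, R_pore = 7.4, sep = 0)
  expect_equal(circle_measure(g2), circle_measure(g) / 2, tolerance = 1e-14)
})

test_that("ion-filter decomposition satisfies the difference identity and
           kappa linearity", {
  p <- water_params()
  for (seed in 1:5) {
    set.seed(seed)
    g <- ion_pore_geometry(runif(1, 0.5, 2), runif(1, 1, 6),
                           w_membrane = runif(1, 10, 30),
                           d_axial = runif(1, 0, 10), sep = runif(1, 0, 5))
    e <- ion_filter_energy(g, p)
    expect_equal(e$dG_ion_filter, e$dG_ion_membrane - e$dG_ion_circle,
                 tolerance = 1e-14)
    e2 <- ion_filter_energy(g, p, kappa = 2 * default_kappa(p),
                            c_mem = e$c_mem)
    expect_equal(e2$dG_ion_membrane, 2 * e$dG_ion_membrane, tolerance = 1e-12)
    expect_equal(e2$dG_ion_circle, 2 * e$dG_ion_circle, tolerance = 1e-12)
    expect_equal(e2$dG_ion_filter, 2 * e$dG_ion_filter, tolerance = 1e-12)
  }
  # degenerate pore: circle term evaluated at R_pore = 0
  g0 <- ion_pore_geometry(r_ion = 1.3, R_pore = 0, sep = 0)
  e0 <- ion_filter_energy(g0, p)
  expect_equal(e0$dG_ion_circle, default_kappa(p) / 1.3, tolerance = 1e-12)
  # hydration bookkeeping: dG_hydration = water-water + solute-water, and
  # the solute-water term is n_HB * dG_DDAA * interfacial ratio
  expect_equal(e0$dG_hydration, e0$dG_water_water_term + e0$dG_solute_water,
               tolerance = 1e-14)
  expect_equal(e0$dG_solute_water,
               p$n_HB * p$dG_DDAA * e0$R_interfacial_ratio,
               tolerance = 1e-12)
})

test_that("critical contact solves the balance to high precision", {
  p <- water_params()
  cc <- critical_contact(p, r_ion = 1.33)
  expect_lt(abs(cc$residual), 1e-9 * abs(p$dG_water_water))
  expect_equal(cc$d_c, cc$R_pore_c + cc$r_ion_c, tolerance = 1e-10)
  # involution: feeding back the conjugate size recovers the input
  cc2 <- critical_contact(p, R_pore = cc$R_pore_c)
  expect_equal(cc2$r_ion_c, 1.33, tolerance = 1e-6)
  # dense-grid oracle for the root
  D <- seq(0.01, 50, by = 1e-4)
  bal <- abs(cc$kappa * cc$c_mem * membrane_measure(0, cc$w_membrane) -
               cc$kappa / D - p$dG_water_water)
  expect_lt(abs(D[which.min(bal)] - cc$d_c), 1e-3)
  expect_error(critical_contact(p, r_ion = 100), "exceeds")
})

test_that("barrier height vanishes at the critical combination and is
           monotone in ion size and pore radius", {
  p <- water_params()
  cc <- critical_contact(p, r_ion = 1.33)
  # exactly critical combination
  gcrit <- ion_pore_geometry(r_ion = cc$r_ion_c, R_pore = cc$R_pore_c)
  expect_equal(barrier_height(gcrit, p, cc)$barrier, 0, tolerance = 1e-12)
  # larger ion, lower barrier at a fixed pore (K+ vs Na+ logic)
  bNa <- barrier_height(ion_pore_geometry(0.95, 3.7), p, cc)
  bK <- barrier_height(ion_pore_geometry(1.33, 3.7), p, cc)
  expect_gt(bNa$barrier, bK$barrier)
  # wider pore, lower barrier for the same ion
  bars <- vapply(c(1.8, 3.7, 5.6), function(Rp)
    barrier_height(ion_pore_geometry(1.33, Rp), p, cc)$barrier, 0)
  expect_true(all(diff(bars) < 0) || (bars[3] == 0 && bars[1] > bars[2]))
  expect_gt(bars[1], bars[2])
  # non-negative, zero in the hydrophobic regime
  bh <- barrier_height(ion_pore_geometry(2, 6.5), p, cc)
  expect_identical(bh$regime, "hydrophobic")
  expect_identical(bh$barrier, 0)
  # partial differences over a grid are <= 0 in both directions
  r_grid <- seq(0.5, 2.5, by = 0.25)
  R_grid <- seq(1, 7, by = 0.5)
  B <- outer(r_grid, R_grid, Vectorize(function(r, R)
    barrier_height(ion_pore_geometry(r, R), p, cc)$barrier))
  expect_true(all(apply(B, 2, diff) <= 1e-12))
  expect_true(all(apply(B, 1, diff) <= 1e-12))
})

test_that("selectivity map is monotone along pore radius and consistent with
           the barrier and critical loci", {
  p <- water_params()
  r_grid <- seq(0.6, 3, by = 0.2)
  R_grid <- seq(0.8, 7, by = 0.2)
  m <- selectivity_map(r_grid, R_grid, p)
  rank <- c(forbidden = 1, barrier = 2, `free-pass` = 3)
  for (r in r_grid) {
    lab <- m$label[m$r_ion == r][order(m$R_pore[m$r_ion == r])]
    expect_true(all(diff(rank[lab]) >= 0))
  }
  # single cell reproduces barrier_height
  cc <- critical_contact(p, r_ion = r_grid[1])
  cell <- m[m$r_ion == 1.4 & abs(m$R_pore - 3) < 1e-9, ]
  bh <- barrier_height(ion_pore_geometry(1.4, 3), p, cc)
  expect_equal(cell$barrier_kJmol, bh$barrier, tolerance = 1e-10)
  # the barrier/free-pass boundary matches the critical contact locus
  dc <- attr(m, "d_c")
  free <- m$label == "free-pass"
  barr <- m$label == "barrier"
  expect_true(all(m$r_ion[free] + m$R_pore[free] >= dc - 1e-9))
  expect_true(all(m$r_ion[barr] + m$R_pore[barr] < dc + 1e-9))
})

test_that("relative selectivity follows the site-minus-bulk convention", {
  r0 <- relative_selectivity(-10, -10, -10, -10)
  expect_identical(r0$ddG, 0)
  expect_identical(r0$preferred_ion, "none")
  r1 <- relative_selectivity(-20, -12, -20, -10)
  expect_gt(r1$ddG, 0)
  r2 <- relative_selectivity(-17, -9, -13, -11,
                             labels = c("K", "Na"))
  r2s <- relative_selectivity(-13, -11, -17, -9,
                              labels = c("Na", "K"))
  expect_equal(r2$ddG, -r2s$ddG, tolerance = 1e-14)
  expect_identical(r2$preferred_ion, "K")
})

test_that("energy unit conversion is the pure 4.184 factor both ways", {
  x <- c(-29.792, 0, 12.3)
  expect_equal(convert_energy(x, "kJ/mol", "kcal/mol"), x / 4.184,
               tolerance = 1e-14)
  expect_equal(convert_energy(convert_energy(x, "kJ/mol", "kcal/mol"),
                              "kcal/mol", "kJ/mol"), x, tolerance = 1e-14)
})
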