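test_that("the geometric criterion accepts an ideal dimer and rejects a
           stretched one", {
  # linear dimer: donor H points straight at the acceptor oxygen
  mk_dimer <- function(r_OO) {
    half <- 104.52 / 2 * pi / 180
    don <- rbind(c(0, 0, 0), c(0.9572, 0, 0),
                 c(0.9572 * cos(2 * half), 0.9572 * sin(2 * half), 0))
    acc <- rbind(c(r_OO, 0, 0), c(r_OO + 0.24, 0.9268, 0),
                 c(r_OO + 0.24, -0.9268, 0))
    md_frame(c(15, 15, 15), rbind(don, acc), rep(c("OW", "HW", "HW"), 2))
  }
  b1 <- detect_hbonds(mk_dimer(2.8))
  expect_identical(nrow(b1), 1L)
  expect_identical(b1$donor, 1L)
  expect_identical(b1$acceptor, 2L)
  expect_lt(b1$angle, 5)
  expect_identical(nrow(detect_hbonds(mk_dimer(3.6))), 0L)
  # cutoff larger than half the box is refused
  expect_error(detect_hbonds(mk_dimer(2.8), hbond_criteria(r_OO_max = 8)),
               "box too small")
})

test_that("vectorized bond detection equals the brute-force oracle on
           random frames", {
  set.seed(101)
  for (rep in 1:20) {
    fr <- random_water_frame(n = 40, box = c(12, 12, 12))
    got <- detect_hbonds(fr)
    want <- oracle_hbonds(fr)
    key <- function(b) sort(paste(b$donor, b$h, b$acceptor))
    expect_identical(key(got), key(want))
  }
})

test_that("motif census classifies the constructed fixtures and balances
           its books", {
  for (m in c("DDAA", "DDA", "DAA", "DA")) {
    cen <- motif_census(gen_motif_fixture(m))
    expect_identical(unname(cen$class_per_water[1]), m)
  }
  expect_identical(nrow(detect_hbonds(gen_motif_fixture("dimer"))), 1L)
  tri <- motif_census(gen_motif_fixture("trimer-ring"))
  expect_identical(unname(tri$class_per_water), rep("DA", 3))
  # bookkeeping on random frames: classes sum to N, donated = accepted =
  # bonds, n_HB_mean = 2 bonds / N
  set.seed(202)
  for (rep in 1:5) {
    fr <- random_water_frame(n = 35)
    bonds <- detect_hbonds(fr)
    cen <- motif_census(fr, bonds = bonds)
    expect_identical(sum(cen$counts), cen$n_waters)
    expect_identical(sum(cen$donated), nrow(bonds))
    expect_identical(sum(cen$accepted), nrow(bonds))
    expect_equal(cen$n_HB_mean, 2 * nrow(bonds) / cen$n_waters)
  }
})

test_that("interfacial/bulk partition matches an all-pairs oracle and always
           adds up", {
  # one ion with one water at 3.0 under a 3.5 cutoff
  half <- 104.52 / 2 * pi / 180
  wat <- rbind(c(3, 0, 0), c(3 + 0.9572 * sin(half), 0, 0.9572 * cos(half)),
               c(3 - 0.9572 * sin(half), 0, 0.9572 * cos(half)))
  fr <- md_frame(c(20, 20, 20), rbind(wat, c(0, 0, 0)),
                 c("OW", "HW", "HW", "K"))
  part <- partition_water(fr, select_species(fr, "K"), 3.5)
  expect_identical(part$interfacial_count, 1L)
  # no solute atoms: everything is bulk, with a warning
  expect_warning(p0 <- partition_water(fr, integer(0), 3.5), "bulk")
  expect_identical(p0$interfacial_count, 0L)
  # random frames with a wall atom row vs direct distance oracle
  set.seed(303)
  for (rep in 1:5) {
    fr <- random_water_frame(n = 30)
    wallxyz <- cbind(stats::runif(4, -6, 6), stats::runif(4, -6, 6), 0)
    fr2 <- md_frame(fr$box, rbind(fr$xyz, wallxyz),
                    c(fr$species, rep("C", 4)))
    part <- partition_water(fr2, select_species(fr2, "C"), 3.2)
    wi <- water_index(fr2)
    want <- vapply(seq_len(nrow(wi)), function(k) {
      d <- sweep(wallxyz, 2, fr2$xyz[wi[k, 1], ])
      for (ax in 1:3) d[, ax] <- d[, ax] - fr2$box[ax] * round(d[, ax] / fr2$box[ax])
      any(sqrt(rowSums(d^2)) < 3.2)
    }, TRUE)
    expect_identical(part$interfacial, unname(want))
    expect_identical(part$interfacial_count + part$bulk_count, nrow(wi))
  }
})

test_that("mean H-bond counts per water are exact on a dimer and match a
           per-frame oracle", {
  dimer <- gen_motif_fixture("dimer")
  traj <- md_trajectory(list(dimer, dimer))
  m <- mean_hbonds(traj)
  expect_equal(m$n_HB, 1.0, tolerance = 1e-14)
  set.seed(404)
  fr <- random_water_frame(n = 30)
  m2 <- mean_hbonds(fr)
  bonds <- oracle_hbonds(fr)
  nhb <- tabulate(bonds$donor, 30) + tabulate(bonds$acceptor, 30)
  expect_equal(m2$n_HB, mean(nhb), tolerance = 1e-12)
})

test_that("analyses are invariant under rigid translation and water
           relabeling", {
  set.seed(505)
  fr <- random_water_frame(n = 30)
  shift <- c(3.7, -8.1, 15.4)
  fr_t <- md_frame(fr$box, sweep(fr$xyz, 2, shift, "+"), fr$species)
  key <- function(b) sort(paste(b$donor, b$h, b$acceptor))
  expect_identical(key(detect_hbonds(fr)), key(detect_hbonds(fr_t)))
  expect_identical(motif_census(fr)$counts, motif_census(fr_t)$counts)
  # permute whole waters
  perm <- sample(30)
  idx <- as.vector(t(cbind(3 * perm - 2, 3 * perm - 1, 3 * perm)))
  fr_p <- md_frame(fr$box, fr$xyz[idx, ], fr$species[idx])
  expect_identical(motif_census(fr)$counts, motif_census(fr_p)$counts)
  expect_identical(sort(motif_census(fr)$class_per_water),
                   sort(motif_census(fr_p)$class_per_water))
})
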