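test_that("ideal-gas RDF is flat and its number integral matches direct
           counting", {
  set.seed(606)
  frames <- lapply(1:20, function(i) {
    xyz <- cbind(runif(200, -10, 10), runif(200, -10, 10),
                 runif(200, -10, 10))
    md_frame(c(20, 20, 20), xyz, rep("NA", 200))
  })
  traj <- md_trajectory(frames)
  prof <- rdf(traj, "NA", "NA", bin_width = 0.25, r_max = 9)
  inner <- prof$r > 1
  expect_lt(max(abs(prof$g[inner] - 1)), 0.2)
  expect_true(all(diff(prof$n_integral) >= 0))
  # counting oracle at r_max
  want <- mean(vapply(frames, function(fr) {
    d <- pair_distances(fr, 1:200, 1:200)
    diag(d) <- Inf
    mean(rowSums(d < 9))
  }, 0))
  expect_equal(prof$n_integral[length(prof$n_integral)], want,
               tolerance = 0.02)
})

test_that("two fixed particles occupy a single RDF bin at their distance", {
  a <- 4.6
  fr <- md_frame(c(20, 20, 20), rbind(c(0, 0, 0), c(a, 0, 0)),
                 c("K", "CL"))
  prof <- rdf(fr, "K", "CL", bin_width = 0.05, r_max = 8)
  occupied <- which(prof$g > 0)
  expect_identical(length(occupied), 1L)
  expect_lt(abs(prof$r[occupied] - a), 0.05)
  expect_error(rdf(fr, "K", "CL", r_max = 15), "half the smallest box")
})

test_that("first-shell minimum finding follows the smoothed profile rule", {
  r <- seq(0.025, 8, by = 0.05)
  g <- 3 * exp(-((r - 2.8) / 0.3)^2) + 1 - exp(-((r - 1) / 1.6)^2)
  fm <- first_shell_minimum(r, g)
  expect_lt(abs(fm$maximum - 2.8), 0.15)
  expect_gt(fm$minimum, 3.2)
  # monotone profile has no shell structure
  expect_true(is.na(first_shell_minimum(r, r * 0 + 1)$minimum) ||
                is.na(first_shell_minimum(r, r * 0 + 1)$maximum))
})

test_that("coordination number counts a constructed octahedral shell
           exactly", {
  half <- 104.52 / 2 * pi / 180
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  blocks <- lapply(seq_len(6), function(i) {
    O <- 2.4 * dirs[i, ]
    u <- dirs[i, ]
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- p - sum(p * u) * u
    p <- p / sqrt(sum(p^2))
    rbind(O, O + 0.9572 * u, O + 0.9572 * (cos(2 * half) * u +
                                             sin(2 * half) * p))
  })
  fr <- md_frame(c(20, 20, 20), rbind(do.call(rbind, blocks), c(0, 0, 0)),
                 c(rep(c("OW", "HW", "HW"), 6), "NA"))
  cn <- coordination_number(md_trajectory(list(fr)), "NA", cutoff = 3.0)
  expect_identical(cn$coordination_number, 6)
})
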