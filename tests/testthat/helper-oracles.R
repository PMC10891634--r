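# Brute-force oracles and small system builders shared across tests.

# plain-loop O(N^2) hydrogen-bond detector: every donor hydrogen against
# every acceptor under minimum image, nearest eligible acceptor kept
oracle_hbonds <- function(frame, criteria = hbond_criteria()) {
  wi <- water_index(frame)
  nw <- nrow(wi)
  box <- frame$box
  rows <- list()
  for (d in seq_len(nw)) {
    for (h in 1:2) {
      best <- NULL
      bestr <- Inf
      for (a in seq_len(nw)) {
        if (a == d) next
        roo_vec <- frame$xyz[wi[a, 1], ] - frame$xyz[wi[d, 1], ]
        roo_vec <- roo_vec - box * round(roo_vec / box)
        roo <- sqrt(sum(roo_vec^2))
        if (roo >= criteria$r_OO_max) next
        oh <- frame$xyz[wi[d, h + 1], ] - frame$xyz[wi[d, 1], ]
        oh <- oh - box * round(oh / box)
        ang <- acos(sum(roo_vec * oh) / (roo * sqrt(sum(oh^2)))) * 180 / pi
        if (ang >= criteria$angle_OOH_max) next
        if (roo < bestr) {
          bestr <- roo
          best <- a
        }
      }
      if (!is.null(best))
        rows[[length(rows) + 1]] <-
          data.frame(donor = d, h = h, acceptor = best, r_OO = bestr)
    }
  }
  if (!length(rows))
    return(data.frame(donor = integer(), h = integer(),
                      acceptor = integer(), r_OO = numeric()))
  do.call(rbind, rows)
}

rotation_from_quaternion <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# waters at uniformly random positions/orientations (overlaps allowed;
# these frames stress the geometry code, not the physics)
random_water_frame <- function(n = 40, box = c(12, 12, 12)) {
  half <- 104.52 / 2 * pi / 180
  r <- 0.9572
  tmpl <- rbind(c(0, 0, 0),
                c(r * sin(half), 0, r * cos(half)),
                c(-r * sin(half), 0, r * cos(half)))
  xyz <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    rot <- rotation_from_quaternion(stats::rnorm(4))
    pos <- stats::runif(3, -box / 2, box / 2)
    xyz[(3 * i - 2):(3 * i), ] <- sweep(tmpl %*% t(rot), 2, pos, "+")
  }
  md_frame(box, xyz, rep(c("OW", "HW", "HW"), n))
}

# a small pre-equilibrated water box, cached per session for the heavier
# simulator tests
equilibrated_box <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ff <- force_field()
      b <- gen_water_box(box = c(16, 16, 16), seed = 42, n_waters = 80)
      eq <- equilibrate(b, ff, seed = 43, minimize_steps = 600, equil_ps = 2)
      cache <<- eq
    }
    cache
  }
})
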