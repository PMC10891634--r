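# TIP3P-like rigid geometry used by every generated water
OH_LENGTH <- 0.9572
HOH_ANGLE <- 104.52
WATER_MOLAR_MASS <- 18.0154
AVOGADRO <- 6.02214076e23

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("a single finite seed is mandatory for every stochastic generator")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# local body-frame coordinates of a rigid 3-site water (O at origin)
water_template <- function() {
  half <- HOH_ANGLE / 2 * pi / 180
  rbind(c(0, 0, 0),
        c(OH_LENGTH * sin(half), 0, OH_LENGTH * cos(half)),
        c(-OH_LENGTH * sin(half), 0, OH_LENGTH * cos(half)))
}

random_rotation <- function() {
  # uniform rotation from a random unit quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Number of waters filling a box at a mass density
#'
#' @param box Box edges, Angstrom.
#' @param density Mass density, g/cm^3.
#' @return Integer water count.
#' @export
waters_for_density <- function(box, density = 0.997) {
  round(density * prod(box) * 1e-24 * AVOGADRO / WATER_MOLAR_MASS)
}

#' Generate a periodic box of rigid waters
#'
#' Places rigid 3-site waters on a jittered cubic lattice at the target
#' density (or explicit count) with random orientations; lattice sites too
#' close to any `exclude` position are skipped. Coordinates are centered on
#' the box (`[-L/2, L/2)` per axis). Deterministic per seed.
#'
#' @param box Box edges, Angstrom (default the 40 x 40 x 60 study box).
#' @param seed Integer seed (mandatory).
#' @param n_waters Water count; default from `density`.
#' @param density Mass density, g/cm^3 (sanity range 0.8-1.2 when used).
#' @param exclude Optional matrix of positions lattice sites must avoid.
#' @param exclude_radius Site-exclusion radius, Angstrom.
#' @param extra_species,extra_xyz Atoms appended after the waters (ions,
#'   wall).
#' @return An [md_frame()].
#' @export
gen_water_box <- function(box = c(40, 40, 60), seed, n_waters = NULL,
                          density = 0.997, exclude = NULL,
                          exclude_radius = 2.6, extra_species = character(),
                          extra_xyz = NULL) {
  if (is.null(n_waters)) {
    if (density < 0.8 || density > 1.2)
      stop("density outside the physically sane 0.8-1.2 g/cm^3 range")
    n_waters <- waters_for_density(box, density)
  }
  with_seed(seed, {
    tmpl <- water_template()
    if (n_waters > 0) {
      # oversample the lattice so exclusion zones still leave enough sites
      s <- (prod(box) / (1.4 * n_waters))^(1 / 3)
      nx <- ceiling(box[1] / s); ny <- ceiling(box[2] / s)
      nz <- ceiling(box[3] / s)
      while (nx * ny * nz < n_waters) nz <- nz + 1
      g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
      sites <- cbind((g$x - 0.5) * box[1] / nx - box[1] / 2,
                     (g$y - 0.5) * box[2] / ny - box[2] / 2,
                     (g$z - 0.5) * box[3] / nz - box[3] / 2)
      sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
      if (!is.null(exclude) && nrow(exclude) > 0) {
        keep <- rep(TRUE, nrow(sites))
        for (k in seq_len(nrow(sites))) {
          d <- sweep(exclude, 2, sites[k, ])
          for (ax in 1:3) d[, ax] <- d[, ax] - box[ax] * round(d[, ax] / box[ax])
          if (min(rowSums(d^2)) < exclude_radius^2) keep[k] <- FALSE
        }
        sites <- sites[keep, , drop = FALSE]
      }
      if (nrow(sites) < n_waters)
        stop("packing error: cannot place ", n_waters,
             " waters (only ", nrow(sites), " admissible lattice sites)")
      sites <- sites[seq_len(n_waters), , drop = FALSE]
      jitter_amp <- 0.1 * s
      sites <- sites + matrix(stats::runif(3 * n_waters, -jitter_amp,
                                           jitter_amp), ncol = 3)
      xyz <- matrix(0, 3 * n_waters, 3)
      for (k in seq_len(n_waters)) {
        rot <- random_rotation()
        xyz[(3 * k - 2):(3 * k), ] <-
          sweep(tmpl %*% t(rot), 2, sites[k, ], "+")
      }
      species <- rep(c("OW", "HW", "HW"), n_waters)
    } else {
      xyz <- matrix(0, 0, 3)
      species <- character()
    }
    if (!is.null(extra_xyz) && nrow(extra_xyz) > 0) {
      xyz <- rbind(xyz, extra_xyz)
      species <- c(species, extra_species)
    }
    md_frame(box, xyz, species)
  })
}

#' Generate a graphene-like pore sheet
#'
#' Honeycomb lattice (C-C 1.42 Angstrom) of neutral carbons in the z = 0
#' plane, trimmed to the box with an edge margin, with every atom within
#' `pore_radius` of the z axis removed. The accessible radius (closest
#' remaining carbon center minus the carbon LJ radius) is reported alongside
#' the nominal one.
#'
#' @param box Box edges, Angstrom (x and y bound the sheet).
#' @param pore_radius Nominal pore radius, Angstrom; 0 keeps the sheet
#'   intact.
#' @param cc_bond C-C bond length, Angstrom.
#' @param r_carbon_lj Carbon LJ radius subtracted for the accessible radius.
#' @param margin Edge margin keeping lattice atoms off the periodic seam.
#' @return A list of class `pore_sheet`: `xyz` (n x 3), `species` (`"C"`),
#'   `nominal_radius`, `accessible_radius`, `n_removed`.
#' @export
gen_graphene_pore <- function(box = c(40, 40, 60), pore_radius = 3.7,
                              cc_bond = 1.42, r_carbon_lj = 1.9924,
                              margin = 0.8) {
  if (pore_radius < 0) stop("pore radius must be non-negative")
  if (pore_radius >= min(box[1:2]) / 2 - margin)
    stop("degenerate sheet: pore radius reaches the sheet edge")
  a1 <- c(sqrt(3) * cc_bond, 0)
  a2 <- c(sqrt(3) * cc_bond / 2, 1.5 * cc_bond)
  nmax <- ceiling(max(box[1:2]) / cc_bond)
  ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  A <- cbind(ij$i * a1[1] + ij$j * a2[1], ij$i * a1[2] + ij$j * a2[2])
  B <- cbind(A[, 1], A[, 2] + cc_bond)
  pts <- rbind(A, B)
  keep <- abs(pts[, 1]) <= box[1] / 2 - margin &
    abs(pts[, 2]) <= box[2] / 2 - margin
  pts <- pts[keep, , drop = FALSE]
  rad <- sqrt(rowSums(pts^2))
  removed <- rad < pore_radius
  pts <- pts[!removed, , drop = FALSE]
  if (!nrow(pts)) stop("degenerate sheet: no carbons remain")
  structure(list(xyz = cbind(pts, 0), species = rep("C", nrow(pts)),
                 nominal_radius = pore_radius,
                 accessible_radius = min(sqrt(rowSums(pts^2))) - r_carbon_lj,
                 n_removed = sum(removed), cc_bond = cc_bond),
            class = "pore_sheet")
}

#' Hand-built hydrogen-bond motif fixtures
#'
#' Small frames whose central water classifies as the requested motif under
#' the default geometric criteria: tetrahedral `DDAA`, `DDA`, `DAA`, `DA`,
#' a two-water `dimer` (one bond), and a cyclic `trimer-ring` (every water
#' DA).
#'
#' @param motif One of `"DDAA"`, `"DDA"`, `"DAA"`, `"DA"`, `"dimer"`,
#'   `"trimer-ring"`.
#' @param box Box edges, Angstrom.
#' @param r_OO Placed O-O bond distance, Angstrom.
#' @return An [md_frame()]; the central water is the first one.
#' @export
gen_motif_fixture <- function(motif = c("DDAA", "DDA", "DAA", "DA", "dimer",
                                        "trimer-ring"),
                              box = c(20, 20, 20), r_OO = 2.8) {
  motif <- match.arg(motif)
  t1 <- c(1, 1, 1) / sqrt(3); t2 <- c(1, -1, -1) / sqrt(3)
  t3 <- c(-1, 1, -1) / sqrt(3); t4 <- c(-1, -1, 1) / sqrt(3)
  perp <- function(v) {            # any unit vector orthogonal to v
    u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- u - sum(u * v) * v
    w / sqrt(sum(w^2))
  }
  water_at <- function(O, h1_dir, h2_dir)
    rbind(O, O + OH_LENGTH * h1_dir, O + OH_LENGTH * h2_dir)
  acceptor_at <- function(dir) {   # accepts from the center, donates nowhere
    O <- r_OO * dir
    water_at(O, dir, perp(dir))
  }
  donor_at <- function(dir) {      # donates into the center
    O <- r_OO * dir
    water_at(O, -dir, perp(dir))
  }
  blocks <- switch(motif,
    "DDAA" = list(water_at(c(0, 0, 0), t1, t2), acceptor_at(t1),
                  acceptor_at(t2), donor_at(t3), donor_at(t4)),
    "DDA" = list(water_at(c(0, 0, 0), t1, t2), acceptor_at(t1),
                 acceptor_at(t2), donor_at(t3)),
    "DAA" = list(water_at(c(0, 0, 0), t1, t2), acceptor_at(t1),
                 donor_at(t3), donor_at(t4)),
    "DA" = list(water_at(c(0, 0, 0), t1, t2), acceptor_at(t1),
                donor_at(t3)),
    "dimer" = list(water_at(c(0, 0, 0), t1, t2), acceptor_at(t1)),
    "trimer-ring" = {
      side <- r_OO
      ang <- c(90, 210, 330) * pi / 180
      Rring <- side / sqrt(3)
      O <- cbind(Rring * cos(ang), Rring * sin(ang), 0)
      lapply(1:3, function(i) {
        nxt <- if (i == 3) 1 else i + 1
        e <- O[nxt, ] - O[i, ]
        e <- e / sqrt(sum(e^2))
        water_at(O[i, ], e, c(0, 0, 1))
      })
    })
  xyz <- do.call(rbind, blocks)
  md_frame(box, xyz, rep(c("OW", "HW", "HW"), length(blocks)))
}

#' Analytic collective-variable landscapes for bias-estimator validation
#'
#' @param form `"flat"`, `"harmonic"` or `"double-well"`.
#' @param params Named list: `k`, `x0` (harmonic; defaults 1, 0); `height`,
#'   `b` (double-well `U = height ((x^2-b^2)^2)/b^4`; defaults 5, 1.5).
#' @return A list of class `toy_landscape`: `form`, `params`, callables
#'   `U(x)`, `grad(x)` and the closed-form `pmf(x)` (equal to `U` up to a
#'   constant).
#' @export
gen_toy_landscape <- function(form = c("flat", "harmonic", "double-well"),
                              params = list()) {
  form <- match.arg(form)
  p <- switch(form,
    flat = list(),
    harmonic = utils::modifyList(list(k = 1, x0 = 0), params),
    "double-well" = utils::modifyList(list(height = 5, b = 1.5), params))
  fns <- switch(form,
    flat = list(U = function(x) 0 * x, grad = function(x) 0 * x),
    harmonic = list(U = function(x) 0.5 * p$k * (x - p$x0)^2,
                    grad = function(x) p$k * (x - p$x0)),
    "double-well" = list(
      U = function(x) p$height * (x^2 - p$b^2)^2 / p$b^4,
      grad = function(x) p$height * 4 * x * (x^2 - p$b^2) / p$b^4))
  structure(list(form = form, params = p, U = fns$U, grad = fns$grad,
                 pmf = fns$U), class = "toy_landscape")
}

#' Generate a single ion in a periodic water box
#'
#' The bulk-hydration system: one ion at the box center surrounded by rigid
#' waters at the target density (the ion displaces one water's volume).
#'
#' @param ion Species label: `"NA"`, `"K"` or `"CL"`.
#' @param n_waters Water count (default 300).
#' @param seed Integer seed.
#' @param density Mass density of the water component, g/cm^3.
#' @return An [md_frame()] with the ion as the last atom.
#' @export
gen_ion_water_system <- function(ion = "NA", n_waters = 300, seed,
                                 density = 0.997) {
  L <- ((n_waters + 1) * WATER_MOLAR_MASS / (density * 1e-24 * AVOGADRO))^(1 / 3)
  gen_water_box(box = rep(L, 3), seed = seed, n_waters = n_waters,
                exclude = matrix(0, 1, 3), exclude_radius = 2.8,
                extra_species = ion, extra_xyz = matrix(0, 1, 3))
}

#' Generate an ion + graphene-pore + water system
#'
#' The pore-permeation system: a frozen graphene-like sheet with a nanopore
#' in the z = 0 plane, a single test ion on the pore axis, and rigid waters
#' filling the rest of the box.
#'
#' @param pore_radius Nominal pore radius, Angstrom (study values 1.8, 3.7,
#'   5.6).
#' @param ion Test-ion species label.
#' @param ion_z Initial axial position of the ion, Angstrom.
#' @param box Box edges, Angstrom (default the 40 x 40 x 60 study box).
#' @param seed Integer seed.
#' @param density Water density, g/cm^3.
#' @param n_waters Optional explicit water count.
#' @return A list of class `pore_system`: `frame` (waters, then wall
#'   carbons, then the ion last), `sheet`, `ion_index`, `wall_index`.
#' @export
gen_pore_system <- function(pore_radius = 3.7, ion = "K", ion_z = 8,
                            box = c(40, 40, 60), seed, density = 0.997,
                            n_waters = NULL) {
  sheet <- gen_graphene_pore(box, pore_radius)
  ion_pos <- matrix(c(0, 0, ion_z), 1, 3)
  if (is.null(n_waters)) {
    # waters fill the box volume outside the sheet exclusion slab
    vol <- prod(box) - box[1] * box[2] * 6.0 - 30
    n_waters <- round(density * vol * 1e-24 * AVOGADRO / WATER_MOLAR_MASS)
  }
  frame <- gen_water_box(box, seed = seed, n_waters = n_waters,
                         exclude = rbind(sheet$xyz, ion_pos),
                         exclude_radius = 2.8,
                         extra_species = c(sheet$species, ion),
                         extra_xyz = rbind(sheet$xyz, ion_pos))
  structure(list(frame = frame, sheet = sheet,
                 ion_index = nrow(frame$xyz),
                 wall_index = 3L * n_waters + seq_along(sheet$species),
                 seed = seed),
            class = "pore_system")
}

#' Generate a mixed ionic solution with a pore sheet (voltage analog)
#'
#' Composition follows the study's voltage experiment: 10 KCl + 10 NaCl
#' (counter-ions included for exact neutrality), a graphene-like pore sheet
#' at z = 0, and waters at the target density.
#'
#' @param pore_radius Nominal pore radius, Angstrom.
#' @param n_K,n_Na,n_Cl Ion counts (defaults 10, 10, 20).
#' @param box Box edges, Angstrom.
#' @param seed Integer seed.
#' @param density Water density, g/cm^3.
#' @param n_waters Optional explicit water count.
#' @return A list of class `pore_system` with ions of all species; the net
#'   charge is reported in `charge`.
#' @export
gen_solution <- function(pore_radius = 3.7, n_K = 10, n_Na = 10, n_Cl = 20,
                         box = c(40, 40, 60), seed, density = 0.997,
                         n_waters = NULL) {
  sheet <- gen_graphene_pore(box, pore_radius)
  n_ions <- n_K + n_Na + n_Cl
  ion_species <- c(rep("K", n_K), rep("NA", n_Na), rep("CL", n_Cl))
  ion_xyz <- with_seed(seed + 1, {
    # ions on random positions away from the sheet plane
    ion_xyz <- matrix(0, n_ions, 3)
    k <- 0
    while (k < n_ions) {
      cand <- c(stats::runif(1, -box[1] / 2 + 1, box[1] / 2 - 1),
                stats::runif(1, -box[2] / 2 + 1, box[2] / 2 - 1),
                stats::runif(1, -box[3] / 2 + 1, box[3] / 2 - 1))
      if (abs(cand[3]) < 3) next
      if (k > 0) {
        d <- sweep(ion_xyz[seq_len(k), , drop = FALSE], 2, cand)
        for (ax in 1:3) d[, ax] <- d[, ax] - box[ax] * round(d[, ax] / box[ax])
        if (min(rowSums(d^2)) < 3.5^2) next
      }
      k <- k + 1
      ion_xyz[k, ] <- cand
    }
    ion_xyz
  })
  if (is.null(n_waters)) {
    vol <- prod(box) - box[1] * box[2] * 6.0 - n_ions * 30
    n_waters <- round(density * vol * 1e-24 * AVOGADRO / WATER_MOLAR_MASS)
  }
  frame <- gen_water_box(box, seed = seed, n_waters = n_waters,
                         exclude = rbind(sheet$xyz, ion_xyz),
                         exclude_radius = 2.8,
                         extra_species = c(sheet$species, ion_species),
                         extra_xyz = rbind(sheet$xyz, ion_xyz))
  charge <- n_K + n_Na - n_Cl
  structure(list(frame = frame, sheet = sheet,
                 ion_index = 3L * n_waters + length(sheet$species) +
                   seq_len(n_ions),
                 wall_index = 3L * n_waters + seq_along(sheet$species),
                 charge = charge, seed = seed),
            class = "pore_system")
}
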