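#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond exists between two waters when the oxygen-oxygen distance
#' and the angle at the donor oxygen (between the donor-to-acceptor O-O
#' vector and the donor O-H bond) are below the cutoffs; defaults 3.5
#' Angstrom and 30 degrees.
#'
#' @param r_OO_max O-O distance cutoff, Angstrom.
#' @param angle_OOH_max Donor-angle cutoff, degrees.
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(r_OO_max = 3.5, angle_OOH_max = 30) {
  if (r_OO_max <= 0 || angle_OOH_max <= 0)
    stop("criteria must be strictly positive")
  structure(list(r_OO_max = r_OO_max, angle_OOH_max = angle_OOH_max),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds in a frame
#'
#' Applies the geometric criterion under minimum image. Each donor hydrogen
#' is matched to at most one acceptor (the nearest eligible one), so a water
#' donates at most two bonds; accepted bonds are not capped.
#'
#' @param frame An [md_frame()] containing waters.
#' @param criteria An [hbond_criteria()].
#' @return data.frame with one row per bond: `donor`, `h` (1 or 2),
#'   `acceptor` (water indices into [water_index()] rows), `r_OO`, `angle`.
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria()) {
  if (min(frame$box) <= 2 * criteria$r_OO_max)
    stop("box too small for the O-O cutoff: minimum image is ambiguous")
  wi <- water_index(frame)
  nw <- nrow(wi)
  empty <- data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      r_OO = numeric(), angle = numeric())
  if (nw < 2) return(empty)
  O <- frame$xyz[wi[, 1], , drop = FALSE]
  dOO <- pair_distances(frame, wi[, 1], wi[, 1])
  diag(dOO) <- Inf
  cand <- which(dOO < criteria$r_OO_max, arr.ind = TRUE)  # donor i -> acceptor j
  if (!nrow(cand)) return(empty)
  di <- cand[, 1]; ai <- cand[, 2]
  # unit O->O' vectors under minimum image
  u <- min_image_disp(O[ai, , drop = FALSE], O[di, , drop = FALSE], frame$box)
  u <- u / sqrt(rowSums(u^2))
  cosmax <- cos(criteria$angle_OOH_max * pi / 180)
  rows <- list()
  for (h in 1:2) {
    oh <- min_image_disp(frame$xyz[wi[di, h + 1], , drop = FALSE],
                         O[di, , drop = FALSE], frame$box)
    oh <- oh / sqrt(rowSums(oh^2))
    cosang <- rowSums(u * oh)
    ok <- cosang > cosmax
    if (any(ok))
      rows[[h]] <- data.frame(donor = di[ok], h = h, acceptor = ai[ok],
                              r_OO = dOO[cbind(di[ok], ai[ok])],
                              angle = acos(pmin(1, cosang[ok])) * 180 / pi)
  }
  bonds <- do.call(rbind, rows)
  if (is.null(bonds) || !nrow(bonds)) return(empty)
  # nearest eligible acceptor per donor hydrogen
  key <- paste(bonds$donor, bonds$h)
  bonds <- bonds[order(key, bonds$r_OO), ]
  bonds <- bonds[!duplicated(paste(bonds$donor, bonds$h)), ]
  rownames(bonds) <- NULL
  bonds[order(bonds$donor, bonds$h), ]
}

#' Census of local hydrogen-bonding motifs
#'
#' Classifies each water by its (donated, accepted) bond counts:
#' (2,2) DDAA, (2,1) DDA, (1,2) DAA, (1,1) DA, everything else `other`
#' (including free waters and over-accepting ones).
#'
#' @inheritParams detect_hbonds
#' @param bonds Optional precomputed [detect_hbonds()] table.
#' @return A list of class `motif_counts`: per-class counts, the per-water
#'   class vector, and `n_HB_mean = 2 * bonds / waters`.
#' @export
motif_census <- function(frame, criteria = hbond_criteria(), bonds = NULL) {
  wi <- water_index(frame)
  nw <- nrow(wi)
  if (is.null(bonds)) bonds <- detect_hbonds(frame, criteria)
  donated <- tabulate(bonds$donor, nbins = nw)
  accepted <- tabulate(bonds$acceptor, nbins = nw)
  cls <- rep("other", nw)
  cls[donated == 2 & accepted == 2] <- "DDAA"
  cls[donated == 2 & accepted == 1] <- "DDA"
  cls[donated == 1 & accepted == 2] <- "DAA"
  cls[donated == 1 & accepted == 1] <- "DA"
  counts <- vapply(c("DDAA", "DDA", "DAA", "DA", "other"),
                   function(k) sum(cls == k), 0L)
  structure(list(counts = counts, class_per_water = cls,
                 donated = donated, accepted = accepted,
                 n_waters = nw,
                 n_HB_mean = if (nw) 2 * nrow(bonds) / nw else NaN),
            class = "motif_counts")
}

#' @export
print.motif_counts <- function(x, ...) {
  cat("Hydrogen-bond motif census over", x$n_waters, "waters\n")
  print(x$counts)
  cat(sprintf("  mean H-bonds per water: %.3f\n", x$n_HB_mean))
  invisible(x)
}

#' Partition waters into interfacial and bulk
#'
#' A water is interfacial when its oxygen lies within `shell_cutoff`
#' (minimum image) of any selected solute/wall atom; all others are bulk.
#'
#' @param frame An [md_frame()].
#' @param solute Integer atom indices of the solute/wall selection (e.g.
#'   `select_species(frame, c("K", "C"))`).
#' @param shell_cutoff Interfacial shell cutoff, Angstrom (default 3.5).
#' @return A list of class `water_partition`: counts, logical
#'   `interfacial` per water, and the cutoff.
#' @export
partition_water <- function(frame, solute, shell_cutoff = 3.5) {
  if (shell_cutoff <= 0) stop("shell_cutoff must be positive")
  wi <- water_index(frame)
  nw <- nrow(wi)
  if (!length(solute)) {
    warning("empty solute selection: all waters classified as bulk")
    interf <- rep(FALSE, nw)
  } else {
    d <- pair_distances(frame, wi[, 1], solute)
    interf <- apply(d < shell_cutoff, 1, any)
  }
  structure(list(interfacial_count = sum(interf),
                 bulk_count = sum(!interf),
                 interfacial = interf, shell_cutoff = shell_cutoff,
                 n_waters = nw),
            class = "water_partition")
}

#' Mean hydrogen bonds per water over a trajectory
#'
#' For each frame, counts the bonds touching each water (as donor or
#' acceptor) and averages over the requested subset; frame means are then
#' averaged over the trajectory.
#'
#' @param traj An [md_trajectory()] (or single frame).
#' @param subset `"all"`, `"interfacial"` or `"bulk"`.
#' @param solute_species Species labels defining the interface (used when
#'   `subset != "all"`).
#' @param shell_cutoff Interfacial cutoff, Angstrom.
#' @param criteria An [hbond_criteria()].
#' @return A list: `n_HB` (trajectory mean), `per_frame` vector, `subset`.
#' @export
mean_hbonds <- function(traj, subset = c("all", "interfacial", "bulk"),
                        solute_species = c("C", "K", "NA", "CL"),
                        shell_cutoff = 3.5, criteria = hbond_criteria()) {
  subset <- match.arg(subset)
  if (inherits(traj, "md_frame")) traj <- md_trajectory(list(traj))
  per_frame <- vapply(traj$frames, function(fr) {
    wi <- water_index(fr)
    bonds <- detect_hbonds(fr, criteria)
    nhb <- tabulate(bonds$donor, nbins = nrow(wi)) +
      tabulate(bonds$acceptor, nbins = nrow(wi))
    keep <- rep(TRUE, nrow(wi))
    if (subset != "all") {
      sol <- select_species(fr, solute_species)
      part <- partition_water(fr, sol, shell_cutoff)
      keep <- if (subset == "interfacial") part$interfacial else
        !part$interfacial
    }
    if (!any(keep)) return(NA_real_)
    mean(nhb[keep])
  }, 0)
  if (all(is.na(per_frame)))
    stop("undefined mean: the '", subset, "' subset is empty in every frame")
  list(n_HB = mean(per_frame, na.rm = TRUE), per_frame = per_frame,
       subset = subset)
}

#' Interfacial/bulk water series along a trajectory
#'
#' @inheritParams mean_hbonds
#' @return data.frame with one row per frame: `frame`, `interfacial`,
#'   `bulk`, `total`.
#' @export
partition_series <- function(traj, solute_species = c("C", "K", "NA", "CL"),
                             shell_cutoff = 3.5) {
  if (inherits(traj, "md_frame")) traj <- md_trajectory(list(traj))
  rows <- lapply(seq_along(traj$frames), function(i) {
    fr <- traj$frames[[i]]
    part <- partition_water(fr, select_species(fr, solute_species),
                            shell_cutoff)
    data.frame(frame = i, interfacial = part$interfacial_count,
               bulk = part$bulk_count, total = part$n_waters)
  })
  do.call(rbind, rows)
}
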