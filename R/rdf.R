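#' Radial distribution function between two selections
#'
#' Shell-normalized pair histogram under minimum image, averaged over frames,
#' with the running coordination number `n(r)` (mean target count within `r`
#' of a center, by direct cumulative counting). Self pairs are excluded when
#' the selections overlap.
#'
#' @param traj An [md_trajectory()] (or single frame).
#' @param center,target Integer atom indices, or species labels resolved per
#'   frame via [select_species()].
#' @param bin_width Histogram bin width, Angstrom (default 0.05).
#' @param r_max Histogram range; must not exceed half the smallest box edge.
#' @return A list of class `rdf_profile`: `r` (bin centers), `g`,
#'   `n_integral`, `first_minimum`, `first_maximum`, `coordination_number`
#'   (n at the first minimum), `bin_width`.
#' @export
rdf <- function(traj, center, target, bin_width = 0.05, r_max = NULL) {
  if (inherits(traj, "md_frame")) traj <- md_trajectory(list(traj))
  box0 <- traj$frames[[1]]$box
  if (is.null(r_max)) r_max <- min(box0) / 2
  if (r_max > min(box0) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box edge: minimum image ambiguous")
  nb <- ceiling(r_max / bin_width)
  counts <- numeric(nb)
  shell_rho_sum <- 0
  nframes <- length(traj$frames)
  for (fr in traj$frames) {
    ci <- if (is.character(center)) select_species(fr, center) else center
    ti <- if (is.character(target)) select_species(fr, target) else target
    if (!length(ci) || !length(ti)) stop("empty center or target selection")
    d <- pair_distances(fr, ci, ti)
    if (length(intersect(ci, ti))) {
      self <- outer(ci, ti, "==")
      d[self] <- Inf
    }
    d <- d[d < r_max]
    counts <- counts + tabulate(pmin(nb, floor(d / bin_width) + 1L),
                                nbins = nb)
    n_excl <- length(intersect(ci, ti))
    rho <- (length(ti) - n_excl / length(ci)) / prod(fr$box)
    shell_rho_sum <- shell_rho_sum + length(ci) * rho
  }
  edges <- seq(0, nb * bin_width, by = bin_width)
  vol <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (vol * shell_rho_sum)
  r_mid <- edges[-1] - bin_width / 2
  # coordination integral by direct cumulative counting (exact, no quadrature)
  n_centers_frames <- sum(vapply(traj$frames, function(fr) {
    ci <- if (is.character(center)) select_species(fr, center) else center
    length(ci)
  }, 0))
  n_integral <- cumsum(counts) / n_centers_frames
  fm <- first_shell_minimum(r_mid, g)
  cn <- if (is.na(fm$minimum)) NA_real_ else
    n_integral[max(which(r_mid <= fm$minimum))]
  structure(list(r = r_mid, g = g, n_integral = n_integral,
                 first_minimum = fm$minimum, first_maximum = fm$maximum,
                 coordination_number = cn, bin_width = bin_width,
                 n_frames = nframes),
            class = "rdf_profile")
}

#' First-shell boundary of a radial distribution function
#'
#' Smooths g(r) with a 5-bin moving average and returns the first local
#' minimum after the first local maximum. Bins before the first non-zero g
#' are ignored.
#'
#' @param r Bin centers.
#' @param g g(r) values.
#' @param k Moving-average window (odd; default 5).
#' @return list(maximum=, minimum=) in the units of `r` (NA when absent).
#' @export
first_shell_minimum <- function(r, g, k = 5) {
  if (length(g) < k + 2) return(list(maximum = NA_real_, minimum = NA_real_))
  gs <- stats::filter(g, rep(1 / k, k), sides = 2)
  gs <- as.numeric(gs)
  valid <- which(!is.na(gs))
  start <- which(g > 0)[1]
  if (is.na(start)) return(list(maximum = NA_real_, minimum = NA_real_))
  idx <- valid[valid > start]
  imax <- NA_integer_
  for (i in idx[-c(1, length(idx))]) {
    # a genuine peak falls off on the far side (flat profiles have none)
    if (gs[i] >= gs[i - 1] && gs[i] > gs[i + 1] && gs[i] > 0.5) {
      imax <- i; break
    }
  }
  if (is.na(imax)) return(list(maximum = NA_real_, minimum = NA_real_))
  imin <- NA_integer_
  for (i in idx[idx > imax]) {
    if (i >= max(idx)) break
    if (gs[i] < gs[i - 1] && gs[i] <= gs[i + 1]) { imin <- i; break }
  }
  list(maximum = r[imax],
       minimum = if (is.na(imin)) NA_real_ else r[imin])
}

#' First-shell coordination number of an ion
#'
#' Mean count of water oxygens within a cutoff of the ion, averaged over
#' frames. With `cutoff = "auto"` the cutoff is the first minimum of the
#' ion-oxygen radial distribution function.
#'
#' @param traj An [md_trajectory()].
#' @param ion Species label (e.g. `"NA"`, `"K"`) or atom index of the ion.
#' @param cutoff Shell cutoff in Angstrom, or `"auto"`.
#' @param bin_width RDF bin width used for the auto cutoff.
#' @return A list of class `coordination_result`: `coordination_number`,
#'   `cutoff`, `rdf` (when auto), `per_frame` counts.
#' @export
coordination_number <- function(traj, ion, cutoff = "auto",
                                bin_width = 0.05) {
  if (inherits(traj, "md_frame")) traj <- md_trajectory(list(traj))
  prof <- NULL
  if (identical(cutoff, "auto")) {
    prof <- rdf(traj, ion, "OW", bin_width = bin_width)
    cutoff <- prof$first_minimum
    if (is.na(cutoff))
      stop("auto cutoff failed: no first-shell minimum found in the RDF")
  }
  per_frame <- vapply(traj$frames, function(fr) {
    ii <- if (is.character(ion)) select_species(fr, ion) else ion
    oi <- select_species(fr, "OW")
    if (!length(ii)) stop("ion not present in frame")
    if (!length(oi)) {
      warning("no waters in frame: coordination number is zero")
      return(0)
    }
    mean(vapply(ii, function(i)
      sum(pair_distances(fr, i, oi) < cutoff), 0))
  }, 0)
  structure(list(coordination_number = mean(per_frame), cutoff = cutoff,
                 rdf = prof, per_frame = per_frame),
            class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("first-shell coordination number: %.2f (cutoff %.2f Angstrom, %d frames)\n",
              x$coordination_number, x$cutoff, length(x$per_frame)))
  invisible(x)
}
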