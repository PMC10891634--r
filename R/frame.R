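#' Periodic simulation frame
#'
#' A snapshot of a periodic orthorhombic system: box edge lengths, Cartesian
#' coordinates and species labels. Waters are stored as contiguous O, H, H
#' triplets with species `"OW"`, `"HW"`, `"HW"`; ions carry their chemical
#' label (`"NA"`, `"K"`, `"CL"`), frozen wall atoms are `"C"`.
#'
#' @param box Numeric length-3, box edges in Angstrom.
#' @param xyz N x 3 numeric matrix of coordinates, Angstrom.
#' @param species Character vector of length N.
#' @param validate Check O-H geometry and finiteness.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(box, xyz, species, validate = TRUE) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths")
  if (nrow(xyz) != length(species))
    stop("coordinate rows and species labels disagree")
  fr <- structure(list(box = as.numeric(box), xyz = xyz,
                       species = as.character(species)),
                  class = "md_frame")
  if (validate && nrow(xyz) > 0) {
    if (any(!is.finite(xyz))) stop("non-finite coordinates")
    wi <- water_index(fr)
    if (nrow(wi) > 0) {
      d1 <- sqrt(rowSums(min_image_disp(xyz[wi[, 2], , drop = FALSE],
                                        xyz[wi[, 1], , drop = FALSE], box)^2))
      d2 <- sqrt(rowSums(min_image_disp(xyz[wi[, 3], , drop = FALSE],
                                        xyz[wi[, 1], , drop = FALSE], box)^2))
      if (any(d1 < 0.8 | d1 > 1.2 | d2 < 0.8 | d2 > 1.2))
        stop("intramolecular O-H distance outside 0.8-1.2 Angstrom")
    }
  }
  fr
}

#' @export
print.md_frame <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf("md_frame: %d atoms in %.2f x %.2f x %.2f Angstrom box\n",
              nrow(x$xyz), x$box[1], x$box[2], x$box[3]))
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Row indices of water O, H, H triplets in a frame
#'
#' @param frame An [md_frame()].
#' @return Integer matrix with one row per water and columns `O`, `H1`, `H2`.
#' @export
water_index <- function(frame) {
  sp <- frame$species
  o <- which(sp == "OW")
  if (length(o) == 0)
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("O", "H1", "H2"))))
  ok <- o + 2 <= length(sp) & sp[o + 1] == "HW" & sp[o + 2] == "HW"
  if (!all(ok))
    stop("malformed water: every OW must be followed by two HW records")
  cbind(O = o, H1 = o + 1L, H2 = o + 2L)
}

#' Minimum-image displacement between coordinate sets
#'
#' @param a,b Matrices (or vectors) of coordinates; recycled row-wise.
#' @param box Box edges, Angstrom.
#' @return Matrix of displacements `a - b` wrapped into the primary image.
#' @export
min_image_disp <- function(a, b, box) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  d <- sweep(a, 1, 0) - b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE]
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' All minimum-image distances between two selections in a frame
#'
#' @param frame An [md_frame()].
#' @param i,j Integer row indices of the two selections.
#' @return `length(i)` x `length(j)` matrix of distances, Angstrom.
#' @export
pair_distances <- function(frame, i, j) {
  xi <- frame$xyz[i, , drop = FALSE]
  xj <- frame$xyz[j, , drop = FALSE]
  box <- frame$box
  out <- matrix(0, length(i), length(j))
  for (k in 1:3) {
    d <- outer(xi[, k], xj[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}

#' Trajectory: an ordered list of frames
#'
#' @param frames List of [md_frame()] objects with consistent species.
#' @param metadata Named list (seed, generator spec, ...).
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, metadata = list()) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  sp0 <- frames[[1]]$species
  for (f in frames)
    if (!identical(f$species, sp0))
      stop("all frames of a trajectory must share one species vector")
  structure(list(frames = frames, metadata = metadata),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames, %d atoms\n",
              length(x$frames), nrow(x$frames[[1]]$xyz)))
  if (!is.null(x$metadata$seed)) cat("  seed:", x$metadata$seed, "\n")
  invisible(x)
}

#' @export
length.md_trajectory <- function(x) length(x$frames)

#' Atom indices matching species labels
#'
#' @param frame An [md_frame()].
#' @param species Character vector of labels to match.
#' @return Integer indices.
#' @export
select_species <- function(frame, species) {
  which(frame$species %in% species)
}
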