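#' Load the force-field parameter set
#'
#' Reads the versioned YAML parameter file shipped with the package (TIP3P
#' water, CHARMM-compatible ion Lennard-Jones parameters, neutral sheet
#' carbon) and converts energies to kJ/mol. The van der Waals switching
#' range defaults to 10-12 Angstrom; electrostatics use a reaction field
#' with a conducting boundary (`eps_rf = Inf`) so force and potential vanish
#' continuously at the cutoff.
#'
#' @param path YAML parameter file; default the packaged one.
#' @param r_on,r_off Switching range override, Angstrom.
#' @param eps_rf Reaction-field dielectric override.
#' @return An object of class `force_field`.
#' @export
force_field <- function(path = system.file("extdata", "forcefield.yaml",
                                           package = "poresel"),
                        r_on = NULL, r_off = NULL, eps_rf = NULL) {
  raw <- yaml::read_yaml(path)
  sp <- lapply(raw$species, function(s) {
    s$epsilon <- s$epsilon * 4.184  # kcal/mol -> kJ/mol
    s
  })
  ff <- structure(list(
    species = sp,
    r_on = r_on %||% raw$switching$r_on,
    r_off = r_off %||% raw$switching$r_off,
    eps_rf = eps_rf %||% {
      e <- raw$electrostatics$eps_rf
      if (is.character(e) || is.null(e)) Inf else as.numeric(e)
    },
    water_geometry = raw$water_geometry,
    version = raw$version), class = "force_field")
  if (ff$r_on >= ff$r_off) stop("switching requires r_on < r_off")
  ff
}

#' @export
print.force_field <- function(x, ...) {
  cat("force_field v", x$version, ": species ",
      paste(names(x$species), collapse = ", "), "\n", sep = "")
  cat(sprintf("  LJ switching %g-%g Angstrom, reaction field eps_rf = %s\n",
              x$r_on, x$r_off, format(x$eps_rf)))
  invisible(x)
}

# per-atom parameter vectors for the C++ core; waters share a molecule id,
# everything else is isolated (-1); wall atoms are the frozen "C" species
ff_atom_tables <- function(frame, ff) {
  sp <- frame$species
  missing <- setdiff(unique(sp), names(ff$species))
  if (length(missing))
    stop("parameterization error: no force-field entry for species ",
         paste(missing, collapse = ", "))
  get_par <- function(field) vapply(sp, function(s) ff$species[[s]][[field]], 0)
  mol <- rep(-1L, length(sp))
  wi <- water_index(frame)
  if (nrow(wi)) {
    for (k in seq_len(nrow(wi))) mol[wi[k, ]] <- k
  }
  list(mass = unname(get_par("mass")), charge = unname(get_par("charge")),
       eps = unname(get_par("epsilon")), rmh = unname(get_par("rmin_half")),
       mol = mol, wall = sp == "C", water_idx = wi)
}

# cap the switching range at half the smallest box edge (minimum image)
effective_switching <- function(ff, box) {
  r_off <- min(ff$r_off, min(box) / 2 - 1e-6)
  r_on <- min(ff$r_on, r_off - 2)
  c(r_on = r_on, r_off = r_off)
}

#' Total charge of a frame under a force field
#'
#' @param frame An [md_frame()].
#' @param ff A [force_field()].
#' @return Net charge in e.
#' @export
total_charge <- function(frame, ff = force_field()) {
  sum(vapply(frame$species, function(s) ff$species[[s]]$charge, 0))
}
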