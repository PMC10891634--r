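#' Write frames as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying the box
#' (`box <lx> <ly> <lz>`) plus any metadata tags, then one
#' `species x y z` row per atom (Angstrom, C locale).
#'
#' @param traj An [md_trajectory()] or single [md_frame()].
#' @param path Output file.
#' @param digits Coordinate digits written.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, digits = 9) {
  if (inherits(traj, "md_frame")) traj <- md_trajectory(list(traj))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- ""
  if (!is.null(traj$metadata$seed))
    meta <- paste0(" seed=", traj$metadata$seed)
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (fr in traj$frames) {
    writeLines(as.character(nrow(fr$xyz)), con)
    writeLines(sprintf("box %.9f %.9f %.9f%s", fr$box[1], fr$box[2],
                       fr$box[3], meta), con)
    writeLines(sprintf(fmt, fr$species, fr$xyz[, 1], fr$xyz[, 2],
                       fr$xyz[, 3]), con)
  }
  invisible(path)
}

#' Write frames as PDB (CRYST1 + MODEL blocks)
#'
#' @inheritParams write_xyz
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  if (inherits(traj, "md_frame")) traj <- md_trajectory(list(traj))
  con <- file(path, "w")
  on.exit(close(con))
  resname <- function(sp) switch(sp, OW = "HOH", HW = "HOH", C = "WAL", "ION")
  for (m in seq_along(traj$frames)) {
    fr <- traj$frames[[m]]
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      fr$box[1], fr$box[2], fr$box[3], 90, 90, 90), con)
    writeLines(sprintf("MODEL     %4d", m), con)
    n <- nrow(fr$xyz)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(n) %% 100000L, substr(fr$species, 1, 4),
      vapply(fr$species, resname, ""), seq_len(n) %% 10000L,
      fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory from XYZ or PDB
#'
#' Format is inferred from the extension (`.xyz` / `.pdb`) unless given.
#' XYZ frames must carry the box on the comment line; PDB frames take it from
#' `CRYST1`. Truncated or malformed frames raise an error naming the line.
#'
#' @param path Input file.
#' @param format `"auto"`, `"xyz"` or `"pdb"`.
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (format == "xyz") read_xyz(path) else read_pdb(path)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  seed <- NULL
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("XYZ parse error at line ", i, ": expected an atom count")
    n <- as.integer(lines[i])
    if (i + 1L > length(lines))
      stop("XYZ parse error: truncated frame header after line ", i)
    hdr <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(hdr) < 4 || hdr[1] != "box")
      stop("XYZ parse error at line ", i + 1L,
           ": comment line must start with 'box lx ly lz'")
    box <- as.numeric(hdr[2:4])
    sd <- grep("^seed=", hdr, value = TRUE)
    if (length(sd)) seed <- as.integer(sub("^seed=", "", sd[1]))
    if (i + 1L + n > length(lines))
      stop("XYZ parse error: frame starting at line ", i,
           " declares ", n, " atoms but the file is truncated")
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) < 4))
      stop("XYZ parse error near line ", i + 1L + which(lengths(parts) < 4)[1],
           ": expected 'species x y z'")
    species <- vapply(parts, `[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (any(!is.finite(xyz)))
      stop("XYZ parse error: non-numeric coordinate in frame at line ", i)
    frames[[length(frames) + 1L]] <- md_frame(box, xyz, species,
                                              validate = FALSE)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  md_trajectory(frames, metadata = if (is.null(seed)) list() else
    list(seed = seed))
}

read_pdb <- function(path) {
  lines <- readLines(path)
  box <- NULL
  frames <- list()
  cur_sp <- character()
  cur_xyz <- list()
  flush_model <- function() {
    if (!length(cur_sp)) return()
    if (is.null(box)) stop("PDB parse error: ATOM records before CRYST1")
    frames[[length(frames) + 1L]] <<- md_frame(
      box, do.call(rbind, cur_xyz), cur_sp, validate = FALSE)
    cur_sp <<- character(); cur_xyz <<- list()
  }
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    rec <- substr(l, 1, 6)
    if (rec == "CRYST1") {
      box <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                          substr(l, 25, 33)))
      if (any(!is.finite(box)))
        stop("PDB parse error at line ", ln, ": bad CRYST1 box")
    } else if (rec == "ATOM  " || rec == "HETATM") {
      xyz <- as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                          substr(l, 47, 54)))
      if (any(!is.finite(xyz)))
        stop("PDB parse error at line ", ln, ": bad coordinates")
      cur_sp <- c(cur_sp, trimws(substr(l, 13, 16)))
      cur_xyz[[length(cur_xyz) + 1L]] <- xyz
    } else if (rec == "ENDMDL") {
      flush_model()
    }
  }
  flush_model()
  if (!length(frames)) stop("no frames found in ", path)
  md_trajectory(frames)
}

#' Write a PMF profile as TSV
#'
#' Columns `cv_A`, `mean_force`, `free_energy_kJmol`, `samples`, `converged`;
#' comment headers carry the seed and a hash of the run configuration. The
#' anchor bin prints a free energy of exactly 0.
#'
#' @param profile A `pmf_profile` (see [run_abf()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", profile$seed %||% "NA"), con)
  writeLines(sprintf("# config_hash: %s", profile$config_hash %||% "NA"), con)
  writeLines("cv_A\tmean_force\tfree_energy_kJmol\tsamples\tconverged", con)
  writeLines(sprintf("%.6f\t%.10g\t%.10g\t%d\t%d",
                     profile$cv, profile$mean_force, profile$free_energy,
                     profile$samples, as.integer(profile$converged)), con)
  invisible(path)
}

#' Read a PMF TSV written by [write_pmf()]
#'
#' @param path Input file.
#' @return A `pmf_profile` list.
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  seed <- sub("^# seed: ", "", grep("^# seed:", hdr, value = TRUE)[1])
  hash <- sub("^# config_hash: ", "",
              grep("^# config_hash:", hdr, value = TRUE)[1])
  tab <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]))
  structure(list(cv = tab$cv_A, mean_force = tab$mean_force,
                 free_energy = tab$free_energy_kJmol, samples = tab$samples,
                 converged = as.logical(tab$converged),
                 seed = if (seed == "NA") NULL else as.integer(seed),
                 config_hash = if (hash == "NA") NULL else hash),
            class = "pmf_profile")
}

#' Write a JSON run manifest next to an output file
#'
#' @param path Manifest path (`.json`).
#' @param config Named list snapshot of the run configuration.
#' @param seed Integer seed (or NULL for deterministic stages).
#' @param inputs,outputs Character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL,
                           inputs = character(), outputs = character()) {
  obj <- list(package = "poresel",
              version = as.character(utils::packageVersion("poresel")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"),
              seed = seed, config = config,
              inputs = inputs, outputs = outputs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # stable polynomial fingerprint, not a cryptographic hash
  h <- 0
  for (b in utils::head(utf8ToInt(as.character(s)), 4096))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
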