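# File formats and configuration: XYZ and PDB trajectories (nm internally;
# PDB is converted from angstrom at the boundary), YAML topology and run
# configuration, CSV energy tables, and the MD-engine adapter descriptor.

#' Write / read an XYZ trajectory
#'
#' Plain multi-frame XYZ with coordinates in nm and element symbols derived
#' from the atom roles (O for oxygen, H for hydrogens, M for the virtual
#' site). Frame order is preserved exactly.
#'
#' @param frames a [supercell_frames()] ensemble.
#' @param path output file.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, digits = 9) {
  n_at <- dim(frames$coords)[2]
  elem <- substr(frames$roles, 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (f in seq_len(n_frames(frames))) {
    writeLines(as.character(n_at), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf(fmt, elem, frames$coords[f, , 1],
                       frames$coords[f, , 2], frames$coords[f, , 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @param topology a [water_topology()] assigning roles and molecule ids.
#' @param temperature optional kelvin tag.
#' @export
read_xyz <- function(path, topology, temperature = NULL) {
  lines <- readLines(path)
  i <- 1L
  coords_list <- list()
  frame_idx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n_at <- suppressWarnings(as.integer(trimws(lines[i])))
    frame_idx <- frame_idx + 1L
    if (is.na(n_at)) {
      abort(sprintf("malformed atom count at frame %d", frame_idx))
    }
    if (i + 1L + n_at > length(lines)) {
      abort(sprintf("truncated trajectory at frame %d", frame_idx))
    }
    block <- lines[(i + 2L):(i + 1L + n_at)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4L)) {
      abort(sprintf("malformed coordinate line in frame %d", frame_idx))
    }
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      abort(sprintf("non-numeric coordinates in frame %d", frame_idx))
    }
    if (frame_idx > 1L && n_at != nrow(coords_list[[1]])) {
      abort(sprintf("atom count drift at frame %d", frame_idx))
    }
    coords_list[[frame_idx]] <- xyz
    i <- i + 2L + n_at
  }
  if (!length(coords_list)) abort("empty trajectory")
  coords <- array(0, c(length(coords_list), nrow(coords_list[[1]]), 3))
  for (f in seq_along(coords_list)) coords[f, , ] <- coords_list[[f]]
  supercell_frames(coords, topology, temperature = temperature)
}

#' Read a PDB-format trajectory
#'
#' Minimal reader for MODEL/ATOM/HETATM records; coordinates are converted
#' from angstrom to nm. Roles and molecule ids come from the topology
#' (records must follow the topology's molecule-major atom ordering).
#'
#' @param path PDB file.
#' @param topology a [water_topology()].
#' @param temperature optional kelvin tag.
#' @return a [supercell_frames()] ensemble.
#' @export
read_pdb <- function(path, topology, temperature = NULL) {
  lines <- readLines(path)
  atom <- grepl("^(ATOM  |HETATM)", lines)
  model_breaks <- cumsum(grepl("^MODEL", lines))
  if (max(model_breaks) == 0) model_breaks <- rep(1L, length(lines))
  at_lines <- lines[atom]
  at_model <- model_breaks[atom]
  frames_split <- split(at_lines, at_model)
  n_at <- length(frames_split[[1]])
  coords <- array(0, c(length(frames_split), n_at, 3))
  for (f in seq_along(frames_split)) {
    ln <- frames_split[[f]]
    if (length(ln) != n_at) abort(sprintf("atom count drift in MODEL %d", f))
    coords[f, , 1] <- as.numeric(substr(ln, 31, 38)) / 10
    coords[f, , 2] <- as.numeric(substr(ln, 39, 46)) / 10
    coords[f, , 3] <- as.numeric(substr(ln, 47, 54)) / 10
  }
  supercell_frames(coords, topology, temperature = temperature)
}

#' Read a topology configuration (YAML)
#'
#' Expected keys: `n_mol`, optional `masses` (named `O`, `H`) and
#' `vsite_weights` (3 scalars summing to 1, a force-field property).
#'
#' @param path YAML file.
#' @return a [water_topology()].
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$n_mol)) abort("topology must declare n_mol")
  masses <- if (!is.null(y$masses)) unlist(y$masses) else
    c(O = 15.999, H = 1.008)
  water_topology(y$n_mol, masses = masses,
                 vsite_weights = if (!is.null(y$vsite_weights))
                   as.numeric(y$vsite_weights) else NULL)
}

#' Run configuration with temperature normalisation
#'
#' Bundles the options of a run; temperatures given in Celsius are converted
#' to kelvin once, here. The configuration is serialisable to YAML and is
#' stamped with a content hash so outputs can be traced to their settings.
#'
#' @param model_kind `"H"` or `"C"`.
#' @param temperature numeric temperature.
#' @param temperature_units `"K"` or `"C"`.
#' @param seed integer seed.
#' @param ... further options stored verbatim.
#' @return object of class `run_config`.
#' @export
run_config <- function(model_kind = "H", temperature = 123.15,
                       temperature_units = "K", seed = 1L, ...) {
  cfg <- list(model_kind = model_kind,
              temperature = as_kelvin(temperature, temperature_units),
              seed = as.integer(seed), ...)
  key <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1)), collapse = ";")
  chars <- utf8ToInt(key)
  cfg$hash <- sprintf("%08x", sum(chars * seq_along(chars)) %% 2147483647)
  structure(cfg, class = "run_config")
}

#' MD-engine adapter descriptor
#'
#' Emits the simulation protocol used to generate locally ergodic NVT data
#' for a crystal supercell: PME electrostatics with error tolerance 1e-5, a
#' real-space cutoff of 0.31 nm with switching at 0.279 nm (the cutoff fits
#' the shortest supercell box length of 0.6358 nm), a Langevin
#' middle-scheme integrator with friction 20 ps^-1, a 2 fs timestep with a
#' configuration saved every 50 steps (100 fs between frames), NPT
#' pre-equilibration at 1 atm with anisotropic box moves, and NVT
#' production started from the frame whose box best matches the NPT
#' average. The descriptor is engine-agnostic data; driving an actual
#' engine is left to external tooling, and the rest of the package is fully
#' functional without one.
#'
#' @param n_mol molecules in the supercell.
#' @param temperature kelvin.
#' @param production_ns NVT production length (ns); 20 ns at the default
#'   save stride yields 200000 frames.
#' @return object of class `md_adapter_config` (a named list, YAML
#'   round-trippable).
#' @export
md_adapter_config <- function(n_mol, temperature, production_ns = 20) {
  stopifnot(n_mol >= 1, temperature > 0, production_ns > 0)
  timestep_fs <- 2
  save_stride <- 50L
  frame_interval_fs <- timestep_fs * save_stride
  structure(
    list(
      force_field = "TIP4P/Ice",
      n_mol = as.integer(n_mol),
      temperature_K = temperature,
      pme_tolerance = 1e-5,
      cutoff_nm = 0.31,
      switching_nm = 0.279,
      integrator = "LangevinMiddle",
      friction_per_ps = 20,
      timestep_fs = timestep_fs,
      save_stride_steps = save_stride,
      frame_interval_fs = frame_interval_fs,
      npt_equilibration = list(length_ns = 1, pressure_atm = 1,
                               barostat = "MonteCarloAnisotropic",
                               start_from = "box closest to NPT average"),
      production_ns = production_ns,
      n_frames = as.integer(round(production_ns * 1e6 / frame_interval_fs))
    ),
    class = "md_adapter_config"
  )
}

#' @rdname md_adapter_config
#' @param x an `md_adapter_config`.
#' @param path YAML output path.
#' @export
write_md_adapter_config <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname md_adapter_config
#' @export
read_md_adapter_config <- function(path) {
  structure(yaml::read_yaml(path), class = "md_adapter_config")
}
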