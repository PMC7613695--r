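# File formats: XYZ geometries, native frequency files, a read-only subset
# of the Molden frequency dialect, surface-model round-tripping, initial
# condition serialization and run manifests.  Native structured formats
# carry a schema tag; readers reject unknown major versions.

# standard atomic weights (amu) for the elements this package encounters
.ATOMIC_WEIGHTS <- c(
  H = 1.008, D = 2.014, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998, Ne = 20.180,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, Ar = 39.95, K = 39.098, Ca = 40.078,
  Fe = 55.845, Br = 79.904, I = 126.90)

.element_mass <- function(el) {
  m <- .ATOMIC_WEIGHTS[el]
  if (any(is.na(m)))
    stop("unknown element(s): ", paste(el[is.na(m)], collapse = ", "))
  unname(m)
}

#' Read an XYZ geometry file
#'
#' @param path Path to a standard XYZ file (atom count, comment line,
#'   then `element x y z` records in Angstrom).
#' @return List with `elements`, `coordinates` (matrix, Angstrom),
#'   `masses` (amu, from the bundled standard-atomic-weight table) and
#'   `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("XYZ file too short: ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop("line 1: expected an atom count in ", path)
  if (length(lines) < nat + 2)
    stop("XYZ file declares ", nat, " atoms but has only ",
         length(lines) - 2, " records")
  el <- character(nat)
  xyz <- matrix(NA_real_, nat, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(nat)) {
    f <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(f) < 4)
      stop("line ", i + 2, ": malformed XYZ record in ", path)
    el[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(v)))
      stop("line ", i + 2, ": non-numeric coordinate in ", path)
    xyz[i, ] <- v
  }
  list(elements = el, coordinates = xyz, masses = .element_mass(el),
       comment = lines[2])
}

#' Write an XYZ geometry file
#'
#' @param elements Character vector of element symbols.
#' @param coordinates Numeric matrix (n x 3, Angstrom).
#' @param path Output file.
#' @param comment Comment line.
#' @return The path, invisibly.
#' @export
write_xyz <- function(elements, coordinates, path, comment = "") {
  stopifnot(length(elements) == nrow(coordinates))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(length(elements)), comment), con)
  writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", elements,
                     coordinates[, 1], coordinates[, 2], coordinates[, 3]),
             con)
  invisible(path)
}

#' Write a normal-mode set in the native frequency format
#'
#' @param modes A [normal_modes()] result.
#' @param path Output file (YAML).
#' @return The path, invisibly.
#' @export
write_frequency_file <- function(modes, path) {
  yaml::write_yaml(list(
    schema = "surfhop-frequencies/1",
    reference = as.list(modes$reference),
    masses = as.list(modes$masses),
    freq_cm1 = as.numeric(modes$freq_cm1),
    modes = lapply(seq_len(ncol(modes$modes)),
                   function(k) as.numeric(modes$modes[, k]))
  ), path, precision = 17)
  invisible(path)
}

#' Read a native frequency file
#'
#' Imaginary modes (negative wavenumbers) are read and kept; the Wigner
#' sampler downstream rejects them.
#'
#' @param path Path to a file written by [write_frequency_file()].
#' @return A `normal_mode_set`.
#' @export
read_frequency_file <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema) || !grepl("^surfhop-frequencies/1", x$schema))
    stop("unsupported frequency-file schema: ", x$schema)
  modes <- do.call(cbind, lapply(x$modes, as.numeric))
  structure(list(
    reference = unlist(x$reference),
    masses = unlist(x$masses),
    freq_cm1 = as.numeric(x$freq_cm1),
    modes = modes,
    state = "imported"
  ), class = "normal_mode_set")
}

#' Read normal modes from a Molden frequency file (read-only subset)
#'
#' Parses the `[FREQ]`, `[FR-COORD]` and `[FR-NORM-COORD]` sections of
#' the Molden frequency dialect.  Coordinates are converted from Bohr to
#' Angstrom, masses filled from the standard-atomic-weight table and the
#' displacement vectors renormalized to an orthonormal mass-weighted set
#' (column-wise normalization; Molden files store unnormalized Cartesian
#' displacements).
#'
#' @param path Path to the Molden file.
#' @return A `normal_mode_set` over Cartesian coordinates (3 per atom).
#' @export
read_molden_frequencies <- function(path) {
  lines <- readLines(path)
  tag <- function(name) grep(paste0("^\\s*\\[", name, "\\]"), lines,
                             ignore.case = TRUE)
  sec <- function(name) {
    i <- tag(name)
    if (!length(i)) stop("Molden file lacks a [", name, "] section: ", path)
    j <- grep("^\\s*\\[", lines)
    j <- j[j > i[1]]
    end <- if (length(j)) j[1] - 1 else length(lines)
    lines[(i[1] + 1):end]
  }
  freq <- as.numeric(trimws(sec("FREQ")))
  coord <- sec("FR-COORD")
  f <- strsplit(trimws(coord), "\\s+")
  el <- vapply(f, `[`, "", 1)
  bohr <- 0.529177210903
  xyz <- t(vapply(f, function(v) as.numeric(v[2:4]), numeric(3))) * bohr
  nat <- length(el)
  nm <- sec("FR-NORM-COORD")
  vib <- grep("^\\s*[Vv]ibration", nm)
  if (length(vib) != length(freq))
    stop("Molden file: ", length(freq), " frequencies but ", length(vib),
         " vibration blocks")
  masses3 <- rep(.element_mass(el), each = 3)
  modes <- matrix(0, 3 * nat, length(freq))
  for (k in seq_along(vib)) {
    end <- if (k < length(vib)) vib[k + 1] - 1 else length(nm)
    rows <- nm[(vib[k] + 1):end]
    disp <- as.numeric(unlist(strsplit(trimws(rows), "\\s+")))
    if (length(disp) != 3 * nat)
      stop("Molden file: vibration block ", k, " has ", length(disp),
           " numbers, expected ", 3 * nat)
    v <- disp * sqrt(masses3)          # mass-weight
    modes[, k] <- v / sqrt(sum(v^2))   # normalize
  }
  ref <- as.numeric(t(xyz))
  names(ref) <- paste0(rep(el, each = 3), rep(seq_len(nat), each = 3),
                       "_", rep(c("x", "y", "z"), nat))
  structure(list(
    reference = ref,
    masses = stats::setNames(masses3, names(ref)),
    freq_cm1 = freq,
    modes = modes,
    state = "molden",
    elements = el
  ), class = "normal_mode_set")
}

#' Export a surface model to a structured file
#'
#' The file round-trips through [read_surface_model()], so dynamics runs
#' on a calibrated model are reproducible without re-running the
#' calibration.
#'
#' @param model A [surface_model()].
#' @param path Output file (YAML).
#' @return The path, invisibly.
#' @export
write_surface_model <- function(model, path) {
  yaml::write_yaml(list(
    schema = "surfhop-model/1",
    coords = model$coords,
    masses = as.list(model$masses),
    reference = as.list(model$reference),
    states = lapply(seq_len(model$nstates), function(i)
      as.list(model$states[i, ])),
    origins = as.numeric(model$origins),
    coupling = lapply(seq_len(model$nstates),
                      function(i) as.numeric(model$coupling[i, ])),
    soc = lapply(seq_len(model$nstates),
                 function(i) as.numeric(model$soc[i, ])),
    fosc = as.numeric(model$fosc),
    terms = lapply(seq_len(nrow(model$terms)), function(i)
      as.list(model$terms[i, ])),
    name = model$meta$name
  ), path, precision = 17)
  invisible(path)
}

#' Read a surface model written by [write_surface_model()]
#'
#' @param path Path to the model file.
#' @return A [surface_model()].
#' @export
read_surface_model <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema) || !grepl("^surfhop-model/1", x$schema))
    stop("unsupported model schema: ", x$schema)
  states <- do.call(rbind, lapply(x$states, as.data.frame))
  terms <- do.call(rbind, lapply(x$terms, as.data.frame))
  n <- nrow(states)
  surface_model(
    coords = unlist(x$coords),
    masses = unlist(x$masses),
    reference = unlist(x$reference),
    states = states,
    origins = as.numeric(x$origins),
    coupling = do.call(rbind, lapply(x$coupling, as.numeric)),
    soc = do.call(rbind, lapply(x$soc, as.numeric)),
    fosc = as.numeric(x$fosc),
    terms = terms,
    meta = list(name = x$name))
}

#' Serialize selected initial conditions
#'
#' @param ics A [select_excitation_window()] result.
#' @param path Output file (YAML).
#' @return The path, invisibly.
#' @export
write_initial_conditions <- function(ics, path) {
  yaml::write_yaml(list(
    schema = "surfhop-initial-conditions/1",
    window = as.numeric(ics$window),
    seed = ics$seed,
    coords = colnames(ics$positions),
    conditions = lapply(seq_len(nrow(ics$conditions)), function(i) list(
      sample = ics$conditions$sample[i],
      adiabat = ics$conditions$adiabat[i],
      label = ics$conditions$label[i],
      E_exc = ics$conditions$E_exc[i],
      f_osc = ics$conditions$f_osc[i],
      position = as.numeric(ics$positions[i, ]),
      momentum = as.numeric(ics$momenta[i, ])))
  ), path, precision = 17)
  invisible(path)
}

#' Read serialized initial conditions
#'
#' @param path Path written by [write_initial_conditions()].
#' @return An `initial_conditions` object.
#' @export
read_initial_conditions <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema) || !grepl("^surfhop-initial-conditions/1", x$schema))
    stop("unsupported initial-conditions schema: ", x$schema)
  cond <- do.call(rbind, lapply(x$conditions, function(ci)
    data.frame(sample = ci$sample, adiabat = ci$adiabat, label = ci$label,
               E_exc = ci$E_exc, f_osc = ci$f_osc)))
  pos <- do.call(rbind, lapply(x$conditions, function(ci)
    as.numeric(ci$position)))
  mom <- do.call(rbind, lapply(x$conditions, function(ci)
    as.numeric(ci$momentum)))
  colnames(pos) <- colnames(mom) <- unlist(x$coords)
  structure(list(conditions = cond, positions = pos, momenta = mom,
                 counts = table(cond$label),
                 window = as.numeric(x$window), seed = x$seed),
            class = "initial_conditions")
}

#' Write a per-step trajectory log as CSV
#'
#' Columns: time, active state index and label, per-state adiabatic
#' energies, per-state populations, gap to the ground state and the model
#' coordinates.
#'
#' @param trajectory An `sh_trajectory`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trajectory_log <- function(trajectory, path) {
  E <- trajectory$energies
  colnames(E) <- paste0("E_", seq_len(ncol(E)) - 1)
  P <- trajectory$populations
  colnames(P) <- paste0("pop_", seq_len(ncol(P)) - 1)
  gap <- trajectory$energies[cbind(seq_along(trajectory$active),
                                   trajectory$active)] -
         trajectory$energies[, 1]
  df <- data.frame(time_fs = trajectory$times,
                   active = trajectory$active,
                   label = trajectory$label,
                   E, P, gap_to_S0 = gap,
                   trajectory$positions, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Build a run manifest
#'
#' Captures everything needed to reproduce a pipeline stage byte for
#' byte: the configuration snapshot, the master seed, per-trajectory
#' seeds, the package version and the md5 checksums of the input files.
#'
#' @param config Configuration list (e.g. a [dynamics_config()]).
#' @param seed Master seed.
#' @param inputs Character vector of input file paths (checksummed).
#' @param extra Optional named list merged into the manifest.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config, seed, inputs = character(0),
                         extra = list()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  c(list(
    package = "surfhop",
    version = as.character(utils::packageVersion("surfhop")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    input_checksums = sums
  ), extra)
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
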