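#' Construct a topology
#'
#' A topology holds the static atom metadata of a molecular system: one row
#' per atom, in the canonical coordinate order shared by every frame of a
#' trajectory built on it.
#'
#' @param atoms data frame with columns `serial` (integer, unique), `name`
#'   (atom name), `element` (element symbol), `resname` (3-letter residue
#'   code), `resid` (integer residue number as printed in the source file),
#'   `chain` (single-character subunit label), and logical `is_water`,
#'   `is_ion`. Missing `is_water`/`is_ion` columns are derived from residue
#'   names; a missing `element` column is derived from atom names.
#' @param metadata free-form provenance list (source file, box vectors, ...).
#'
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, metadata = list()) {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "resname", "resid", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("topology atoms missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  atoms$chain <- as.character(atoms$chain)
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$is_water)) atoms$is_water <- atoms$resname %in% WATER_RESNAMES
  if (is.null(atoms$is_ion)) atoms$is_ion <- atoms$resname %in% ION_RESNAMES
  if (anyDuplicated(atoms$serial)) {
    stop("atom serial numbers must be unique within a topology")
  }
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    stop("chain/resid/name triples must be unique within a topology")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "topology")
}

WATER_RESNAMES <- c("HOH", "SOL", "WAT", "TIP3", "TIP4", "SPC")
ION_RESNAMES <- c("CA", "CA2", "NA", "CL", "K", "MG", "ZN", "NA+", "CL-", "CAL")

# Element from the atom name, PDB-style: strip digits, take the leading
# letters; two-letter symbols only for common hetero/ion names.
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1, 1)
  two <- c("CL", "NA", "MG", "ZN", "FE", "BR", "CA")
  # a bare ion-like name (CL, NA, MG, ZN, FE, CA) is taken as the 2-letter
  # element; protein atom names like "CA"/"CB" are carbon, so only names of
  # length 2 that are not standard protein atoms qualify
  protein_names <- c("CA", "CB", "CG", "CD", "CE", "CZ", "CH", "ND", "NE",
                     "NH", "NZ", "OD", "OE", "OG", "OH", "SD", "SG")
  is_two <- nm %in% two & !(nm %in% protein_names)
  el[is_two] <- nm[is_two]
  el
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("topology: %d atoms, %d residues, chains [%s]\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              paste(sort(unique(a$chain)), collapse = ", ")))
  cat(sprintf("  waters: %d molecules; ion atoms: %d\n",
              length(unique(paste(a$chain, a$resid)[a$is_water])),
              sum(a$is_ion)))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a `topology`.
#' @return Integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Subunit (chain) labels present in a topology
#' @param top a `topology`.
#' @return Character vector of chain identifiers.
#' @export
subunit_ids <- function(top) sort(unique(top$atoms$chain))

#' Construct a trajectory
#'
#' @param top a `topology`.
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames`, in nm.
#' @param times frame times in ps, strictly increasing, `times[1] >= 0`.
#' @param total_time_ps duration of the run; defaults to the last frame time.
#'
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(top, coords, times, total_time_ps = NULL) {
  stopifnot(inherits(top, "topology"))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != n_atoms(top)) {
    stop(sprintf("coordinate array has %d atoms but topology has %d",
                 dim(coords)[1], n_atoms(top)))
  }
  times <- as.numeric(times)
  if (length(times) != dim(coords)[3]) {
    stop("length(times) must equal the number of frames")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (times[1] < 0) stop("times must start at or after 0 ps")
  if (is.null(total_time_ps)) total_time_ps <- times[length(times)]
  if (total_time_ps < times[length(times)]) {
    stop("total_time_ps must be at least the last frame time")
  }
  structure(list(topology = top, coords = coords, times = times,
                 total_time_ps = as.numeric(total_time_ps)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %g..%g ps (T = %g ps)\n",
              n_frames(x), n_atoms(x$topology), x$times[1],
              x$times[length(x$times)], x$total_time_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` coordinate matrix in nm.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Construct a time series
#'
#' @param times times in ps.
#' @param values one value per time.
#' @param label short description.
#' @param units unit string (`"nm"`, `"nm^2"`, `"degrees"`, `"count"`, ...).
#' @return An object of class `time_series`.
#' @export
time_series <- function(times, values, label = "", units = "") {
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label, units = units),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("time_series '%s' [%s]: %d points, t = %g..%g ps\n",
              x$label, x$units, length(x$times),
              if (length(x$times)) x$times[1] else NA,
              if (length(x$times)) x$times[length(x$times)] else NA))
  invisible(x)
}

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time_ps = x$times, value = x$values)
}
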