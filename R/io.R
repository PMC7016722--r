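#' Read a molecular structure file
#'
#' Reads a PDB or GRO file into a [topology] plus the first coordinate frame.
#' Coordinates are always returned in nm (PDB Angstrom values are scaled by
#' 0.1; GRO files are already in nm). Water residues (HOH/SOL/WAT/TIP/SPC)
#' are flagged `is_water`; monatomic ion residues (CA/NA/CL/MG/K/ZN and
#' charged variants) are flagged `is_ion`. For a multi-MODEL PDB only MODEL 1
#' is returned; use [read_trajectory] for all frames.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return A list with elements `topology` and `coords` (`n_atoms x 3` nm).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- resolve_format(path, match.arg(format))
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- switch(format,
    pdb = read_pdb_file(path, multi = FALSE),
    gro = read_gro_file(path)
  )
  list(topology = parsed$topology, coords = parsed$coords[, , 1, drop = TRUE])
}

#' Read a trajectory
#'
#' Multi-MODEL PDB blocks or sequential GRO frames become trajectory frames.
#' Frame times are taken from per-frame metadata when present (GRO `t=` title
#' fields); otherwise frames are spaced uniformly by `dt_ps` starting at 0.
#'
#' @param paths one or more file paths, read in order.
#' @param topology optional `topology` the frames must match; derived from
#'   the first frame when `NULL`.
#' @param format `"auto"`, `"pdb"` or `"gro"`.
#' @param dt_ps uniform frame spacing in ps used when the files carry no
#'   per-frame times (default 10 ps).
#' @param total_time_ps optional run duration; defaults to the last frame time.
#' @return A [trajectory].
#' @export
read_trajectory <- function(paths, topology = NULL,
                            format = c("auto", "pdb", "gro"),
                            dt_ps = 10, total_time_ps = NULL) {
  format_arg <- match.arg(format)
  coords_list <- list()
  times_list <- list()
  frame_offset <- 0L
  for (path in paths) {
    fmt <- resolve_format(path, format_arg)
    if (!file.exists(path)) stop("file not found: ", path)
    parsed <- switch(fmt,
      pdb = read_pdb_file(path, multi = TRUE),
      gro = read_gro_file(path)
    )
    if (is.null(topology)) topology <- parsed$topology
    nf <- dim(parsed$coords)[3]
    for (k in seq_len(nf)) {
      if (dim(parsed$coords)[1] != n_atoms(topology)) {
        stop(sprintf("frame %d has %d atoms but topology has %d",
                     frame_offset + k, dim(parsed$coords)[1], n_atoms(topology)))
      }
    }
    coords_list[[length(coords_list) + 1L]] <- parsed$coords
    times_list[[length(times_list) + 1L]] <- parsed$times
    frame_offset <- frame_offset + nf
  }
  coords <- array(unlist(coords_list, use.names = FALSE),
                  dim = c(n_atoms(topology), 3, frame_offset))
  times <- unlist(times_list, use.names = FALSE)
  if (anyNA(times)) {
    times <- seq(0, by = dt_ps, length.out = frame_offset)
  }
  trajectory(topology, coords, times, total_time_ps = total_time_ps)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  stop("unsupported format for '", path,
       "': expected a .pdb or .gro file, or pass format= explicitly")
}

# Pre-scan for malformed ATOM/HETATM records so parse errors can name the
# offending line; bio3d does the heavy parsing afterwards.
validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed PDB record at line %d of %s: record shorter than the coordinate fields", i, path))
    }
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz)))) {
      stop(sprintf("malformed PDB record at line %d of %s: non-numeric coordinate field", i, path))
    }
  }
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1) {
    model_ends <- which(rec == "ENDMDL")
    counts <- vapply(seq_along(model_starts), function(m) {
      to <- if (m <= length(model_ends)) model_ends[m] else length(lines)
      sum(is_atom[model_starts[m]:to])
    }, integer(1))
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop(sprintf("frame %d of %s has %d atoms but frame 1 has %d",
                   bad, path, counts[bad], counts[1]))
    }
  }
  known <- c("ATOM  ", "HETATM", "MODEL ", "ENDMDL", "TER   ", "CRYST1",
             "END   ", "END", "TER")
  unknown <- !(trimws(rec) %in% trimws(known)) & nzchar(trimws(lines))
  if (any(unknown)) {
    message(sprintf("read_structure: ignoring %d non-coordinate PDB record(s) in %s (e.g. '%s')",
                    sum(unknown), path, trimws(rec[which(unknown)[1]])))
  }
  invisible(TRUE)
}

read_pdb_file <- function(path, multi = FALSE) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  a <- pdb$atom
  chain <- ifelse(is.na(a$chain), " ", a$chain)
  element <- a$elesy
  element[is.na(element) | !nzchar(trimws(element))] <-
    guess_element(a$elety[is.na(element) | !nzchar(trimws(element))])
  element <- trimws(element)
  atoms <- data.frame(serial = a$eleno, name = a$elety, element = toupper(element),
                      resname = a$resid, resid = a$resno, chain = chain,
                      stringsAsFactors = FALSE)
  metadata <- list(source = path, format = "pdb")
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) > 0) {
    box_a <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                           substr(cryst[1], 16, 24),
                                           substr(cryst[1], 25, 33))))
    metadata$box_nm <- box_a * 0.1
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  coords <- array(NA_real_, c(na, 3, nf))
  for (k in seq_len(nf)) {
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) * 0.1
  }
  list(topology = topology(atoms, metadata), coords = coords,
       times = rep(NA_real_, nf))
}

read_gro_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  times <- numeric(0)
  atoms <- NULL
  box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    if (i + 1L > length(lines)) stop(sprintf("malformed GRO file %s: truncated at line %d", path, i))
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1) {
      stop(sprintf("malformed GRO record at line %d of %s: expected an atom count", i + 1L, path))
    }
    if (i + 1L + nat + 1L > length(lines)) {
      stop(sprintf("malformed GRO file %s: frame starting at line %d is truncated", path, i))
    }
    body <- lines[(i + 2L):(i + 1L + nat)]
    xyz <- matrix(NA_real_, nat, 3)
    for (k in seq_len(nat)) {
      ln <- body[k]
      if (nchar(ln) < 44) {
        stop(sprintf("malformed GRO record at line %d of %s: line too short", i + 1L + k, path))
      }
      xyz[k, ] <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                                substr(ln, 29, 36),
                                                substr(ln, 37, 44))))
      if (anyNA(xyz[k, ])) {
        stop(sprintf("malformed GRO record at line %d of %s: non-numeric coordinate", i + 1L + k, path))
      }
    }
    if (is.null(atoms)) {
      atoms <- data.frame(
        serial = suppressWarnings(as.integer(substr(body, 16, 20))),
        name = trimws(substr(body, 11, 15)),
        resname = trimws(substr(body, 6, 10)),
        resid = suppressWarnings(as.integer(substr(body, 1, 5))),
        chain = "A",
        stringsAsFactors = FALSE)
      if (anyNA(atoms$serial)) atoms$serial <- seq_len(nat)
    }
    box <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 1L + nat + 1L]),
                                                "\\s+")[[1]]))
    tmatch <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    times <- c(times, if (length(tmatch) == 2) as.numeric(tmatch[2]) else NA_real_)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 1L + nat + 1L + 1L
  }
  if (length(frames) == 0) stop("no frames found in GRO file ", path)
  metadata <- list(source = path, format = "gro", box_nm = box)
  coords <- array(unlist(frames, use.names = FALSE),
                  dim = c(nrow(frames[[1]]), 3, length(frames)))
  # GRO frames are column-stacked per frame already in atom-major order:
  # rebuild properly since unlist concatenates by column within each matrix
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  list(topology = topology(atoms, metadata), coords = coords, times = times)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' Coordinates are written in Angstrom (nm x 10) at standard PDB precision
#' (0.001 Angstrom).
#'
#' @param traj a [trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$topology$atoms
  nf <- n_frames(traj)
  na <- nrow(a)
  xyz <- matrix(NA_real_, nf, 3 * na)
  for (k in seq_len(nf)) {
    xyz[k, ] <- as.vector(t(traj$coords[, , k])) * 10
  }
  bio3d::write.pdb(file = path, xyz = xyz, eleno = a$serial, elety = a$name,
                   resid = a$resname, resno = a$resid,
                   chain = ifelse(a$chain == " ", "", a$chain),
                   elesy = a$element,
                   o = rep(1, na), b = rep(0, na))
  invisible(path)
}

#' Write a time series to disk
#'
#' The `xvg` dialect is XMGRACE-compatible: `@`-prefixed title and axis
#' headers followed by two whitespace-separated columns. The `csv` dialect
#' has a `time_ps,value` header row.
#'
#' @param series a [time_series].
#' @param path output file path.
#' @param format `"xvg"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = c("xvg", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "time_series"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  if (format == "xvg") {
    writeLines(c(sprintf("@    title \"%s\"", series$label),
                 "@    xaxis  label \"Time (ps)\"",
                 sprintf("@    yaxis  label \"%s\"", series$units)), con)
    writeLines(sprintf("%.10g %.10g", series$times, series$values), con)
  } else {
    writeLines("time_ps,value", con)
    writeLines(sprintf("%.10g,%.10g", series$times, series$values), con)
  }
  invisible(path)
}

#' Read a time series written by [write_series]
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"xvg"` or `"csv"`.
#' @return A [time_series] (label/units recovered from xvg headers).
#' @export
read_series <- function(path, format = c("auto", "xvg", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "xvg"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "xvg") {
    hdr <- lines[startsWith(lines, "@")]
    data <- lines[!startsWith(lines, "@") & !startsWith(lines, "#") & nzchar(trimws(lines))]
    vals <- do.call(rbind, lapply(strsplit(trimws(data), "\\s+"), as.numeric))
    lab <- sub('.*title "(.*)".*', "\\1", hdr[grepl("title", hdr)][1])
    uni <- sub('.*yaxis *label "(.*)".*', "\\1", hdr[grepl("yaxis", hdr)][1])
    time_series(vals[, 1], vals[, 2],
                label = if (is.na(lab)) "" else lab,
                units = if (is.na(uni)) "" else uni)
  } else {
    df <- utils::read.csv(path)
    time_series(df$time_ps, df$value)
  }
}
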