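#' Default van der Waals radii (nm)
#'
#' GROMOS-like united-atom radii used by the Shrake-Rupley surface. The
#' table is deliberately small; pass a named vector to the SASA functions to
#' extend or override it.
#'
#' @return Named numeric vector of radii in nm, keyed by element symbol.
#' @export
default_vdw_radii <- function() {
  c(H = 0.120, C = 0.172, N = 0.155, O = 0.150, S = 0.180, P = 0.180,
    CA = 0.197, MG = 0.173, "NA" = 0.227, CL = 0.175, K = 0.275, ZN = 0.139)
}

# Deterministic spiral (Fibonacci) lattice on the unit sphere.
sphere_points <- function(n_points) {
  stopifnot(n_points >= 32)
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

sasa_radii_for <- function(top, idx, radii) {
  el <- top$atoms$element[idx]
  r <- radii[el]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(sort(unique(el[is.na(r)])), collapse = ", "))
  }
  as.numeric(r)
}

#' Solvent-accessible surface area of one frame
#'
#' Shrake-Rupley SASA: each selected atom is inflated by the probe radius
#' and covered with a deterministic spiral lattice of test points; the
#' exposed fraction (points not buried inside any other selected atom's
#' inflated sphere) times the inflated sphere area is summed over atoms.
#'
#' @param frame `n_atoms x 3` coordinate matrix in nm (a full-topology frame).
#' @param selection atoms included in the surface (selection or indices).
#' @param top the `topology` the frame belongs to (for element lookup).
#' @param radii named per-element vdW radii in nm, see [default_vdw_radii].
#' @param probe probe radius in nm (default 0.14, a water-sized probe).
#' @param n_points test points per atom (default 960; at least 32).
#' @return Total SASA in nm^2 (attribute `per_atom` carries the per-atom
#'   areas).
#' @export
sasa_frame <- function(frame, selection, top, radii = default_vdw_radii(),
                       probe = 0.14, n_points = 960) {
  stopifnot(probe >= 0)
  idx <- selection_indices(selection)
  if (length(idx) == 0) stop("empty selection")
  r_ext <- sasa_radii_for(top, idx, radii) + probe
  pts <- sphere_points(n_points)
  per_atom <- cpp_sasa_atoms(as.matrix(frame)[idx, , drop = FALSE], r_ext, pts)
  structure(sum(per_atom), per_atom = per_atom)
}

#' SASA over a trajectory with a frequency distribution
#'
#' @param traj a [trajectory].
#' @param selection atoms included in the surface.
#' @param radii,probe,n_points as in [sasa_frame].
#' @param bin_width_nm2 histogram bin width in nm^2 (default 0.5).
#' @return An object of class `sasa_result`: list with `series` (a
#'   [time_series] in nm^2) and `histogram` (data frame `bin_center`,
#'   `count`; counts sum to the number of frames).
#' @export
sasa_series <- function(traj, selection, radii = default_vdw_radii(),
                        probe = 0.14, n_points = 960, bin_width_nm2 = 0.5) {
  idx <- selection_indices(selection)
  if (length(idx) == 0) stop("empty selection")
  top <- traj$topology
  r_ext <- sasa_radii_for(top, idx, radii) + probe
  pts <- sphere_points(n_points)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    sum(cpp_sasa_atoms(traj$coords[idx, , k, drop = TRUE], r_ext, pts))
  }, numeric(1))
  series <- time_series(traj$times, vals, label = "SASA", units = "nm^2")
  lo <- floor(min(vals) / bin_width_nm2) * bin_width_nm2
  hi <- ceiling(max(vals) / bin_width_nm2) * bin_width_nm2
  if (hi <= lo) hi <- lo + bin_width_nm2
  breaks <- seq(lo, hi, by = bin_width_nm2)
  h <- hist(vals, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  structure(list(series = series,
                 histogram = data.frame(bin_center = h$mids, count = h$counts)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  v <- x$series$values
  cat(sprintf("sasa_result: %d frames, mean %.2f nm^2 (range %.2f..%.2f)\n",
              length(v), mean(v), min(v), max(v)))
  invisible(x)
}
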