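#' Ion-to-residue minimum-distance trace
#'
#' Per frame, the minimum distance between any atom of the ion selection and
#' any heavy atom of the residue. Selecting several ions pools them
#' ("collective" mode: the trace follows whichever ion is nearest).
#'
#' @param traj a [trajectory].
#' @param ion atom selection of one or more ion atoms (non-empty).
#' @param residue `c(chain, resid)` pair (resid coerced to integer).
#' @param oxygens_only restrict the residue side to oxygen atoms
#'   (carboxylate-focused mode).
#' @return A `distance_trace` (see [min_distance_trace]).
#' @export
ion_residue_distance_trace <- function(traj, ion, residue, oxygens_only = FALSE) {
  a <- traj$topology$atoms
  ii <- selection_indices(ion)
  if (length(ii) == 0) stop("empty ion selection")
  chain <- as.character(residue[1])
  resid <- as.integer(residue[2])
  ir <- which(a$chain == chain & a$resid == resid & a$element != "H")
  if (oxygens_only) ir <- ir[a$element[ir] == "O"]
  if (length(ir) == 0) {
    stop(sprintf("residue %d in chain %s not found (or has no matching atoms)",
                 resid, chain))
  }
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    min(cross_dist(coords_slice(traj$coords, ii, k),
                   coords_slice(traj$coords, ir, k)))
  }, numeric(1))
  lab <- sprintf("ion vs %s%d", chain, resid)
  distance_trace(lab, time_series(traj$times, vals, label = lab, units = "nm"))
}

#' Detect first and second ion encounters on a residue
#'
#' An encounter begins at the first frame whose distance drops below the
#' cutoff after the trace has been at or above the cutoff continuously for
#' at least `gap_tol_ps` (the trajectory start counts as "outside").
#' Sub-threshold episodes separated by excursions shorter than `gap_tol_ps`
#' are merged into one encounter. At most two encounters are recorded: FET
#' (first encounter time) and SET (second encounter time).
#'
#' @param trace a `distance_trace` (or bare [time_series] in nm).
#' @param cutoff_nm encounter distance cutoff (default 0.5 nm).
#' @param gap_tol_ps minimum out-of-shell excursion separating two distinct
#'   encounters (default 50 ps).
#' @return An object of class `encounter_record`: list with `ion_label`,
#'   `residue`, `FET`, `SET` (ps, `NA` when absent), and the `cutoff_nm`
#'   and `gap_tol_ps` used. Feed it to [total_residence_time].
#' @export
detect_encounters <- function(trace, cutoff_nm = 0.5, gap_tol_ps = 50) {
  if (cutoff_nm <= 0) stop("cutoff must be positive")
  series <- if (inherits(trace, "distance_trace")) trace$series else trace
  stopifnot(inherits(series, "time_series"))
  if (length(series$values) == 0) stop("empty distance trace")
  t <- series$times
  inside <- series$values < cutoff_nm
  # contiguous inside-episodes as (start index, end index)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  epi <- cbind(starts[r$values], ends[r$values])
  if (nrow(epi) > 1) {
    # merge episodes separated by excursions shorter than gap_tol_ps:
    # the excursion spans times (t[end_i], t[start_{i+1}])
    merged <- epi[1, , drop = FALSE]
    for (e in seq_len(nrow(epi))[-1]) {
      gap <- t[epi[e, 1]] - t[merged[nrow(merged), 2]]
      if (gap < gap_tol_ps) {
        merged[nrow(merged), 2] <- epi[e, 2]
      } else {
        merged <- rbind(merged, epi[e, ])
      }
    }
    epi <- merged
  }
  FET <- if (nrow(epi) >= 1) t[epi[1, 1]] else NA_real_
  SET <- if (nrow(epi) >= 2) t[epi[2, 1]] else NA_real_
  structure(list(ion_label = if (inherits(trace, "distance_trace")) trace$pair_label else "",
                 residue = NULL, FET = FET, SET = SET,
                 cutoff_nm = cutoff_nm, gap_tol_ps = gap_tol_ps),
            class = "encounter_record")
}

#' @export
print.encounter_record <- function(x, ...) {
  cat(sprintf("encounter_record '%s': FET = %s ps, SET = %s ps (cutoff %.2f nm)\n",
              x$ion_label,
              if (is.na(x$FET)) "none" else format(x$FET),
              if (is.na(x$SET)) "none" else format(x$SET), x$cutoff_nm))
  invisible(x)
}

#' Total residence time from encounter times
#'
#' Implements the printed residence-time arithmetic for a run of duration
#' `T`: with only a first encounter, `TRT = T - FET`; with only a second,
#' `TRT = T - SET`; with both, `TRT = (SET - FET) + (T - SET)` (algebraically
#' `T - FET`, kept in the two-term form); with no encounter, `TRT = 0`.
#'
#' @param record an `encounter_record` from [detect_encounters], or a list
#'   with `FET`/`SET` entries (ps, `NA` for absent).
#' @param T_ps trajectory duration in ps (e.g. 80000).
#' @return Total residence time in ps.
#' @seealso [trt_from_times] for the vectorised form.
#' @export
total_residence_time <- function(record, T_ps) {
  # absence is encoded as NA in records; a genuine encounter at t = 0 counts
  trt_from_times(record$FET %||% NA_real_, record$SET %||% NA_real_, T_ps,
                 zero_means_absent = FALSE)
}

#' Vectorised total residence time
#'
#' @param fet,set encounter times in ps; `NA` (or 0 for `set`, matching the
#'   printed tables where a 0 second encounter means "none") marks an absent
#'   encounter.
#' @param T_ps trajectory duration in ps.
#' @param zero_means_absent treat 0 entries as absent encounters (default
#'   TRUE, the printed-table convention; a true encounter at t = 0 ps is not
#'   representable in that convention).
#' @return Numeric vector of residence times in ps.
#' @export
trt_from_times <- function(fet, set, T_ps, zero_means_absent = TRUE) {
  n <- max(length(fet), length(set))
  fet <- rep_len(as.numeric(fet), n)
  set <- rep_len(as.numeric(set), n)
  if (zero_means_absent) {
    fet[!is.na(fet) & fet == 0] <- NA_real_
    set[!is.na(set) & set == 0] <- NA_real_
  }
  if (any(fet > T_ps, na.rm = TRUE) || any(set > T_ps, na.rm = TRUE)) {
    stop("encounter time exceeds the trajectory duration")
  }
  out <- numeric(n)
  both <- !is.na(fet) & !is.na(set)
  fonly <- !is.na(fet) & is.na(set)
  sonly <- is.na(fet) & !is.na(set)
  out[fonly] <- T_ps - fet[fonly]
  out[sonly] <- T_ps - set[sonly]
  out[both] <- (set[both] - fet[both]) + (T_ps - set[both])
  out
}

#' Binding-site occupancy table
#'
#' For each residue, the fraction of frames in which any selected ion atom
#' lies within the shell cutoff of the residue's heavy atoms.
#'
#' @param traj a [trajectory].
#' @param ions ion atom selection.
#' @param residues data frame with columns `chain` and `resid` (or a list of
#'   `c(chain, resid)` pairs).
#' @param shell_cutoff_nm solvation-shell cutoff (default 0.3 nm).
#' @param oxygens_only carboxylate-focused residue-side filter.
#' @return Data frame `chain`, `resid`, `occupancy` plus attribute
#'   `shell_cutoff_nm`.
#' @export
binding_site_occupancy <- function(traj, ions, residues, shell_cutoff_nm = 0.3,
                                   oxygens_only = FALSE) {
  if (is.list(residues) && !is.data.frame(residues)) {
    residues <- data.frame(chain = vapply(residues, `[`, "", 1),
                           resid = as.integer(vapply(residues, `[`, "", 2)),
                           stringsAsFactors = FALSE)
  }
  if (nrow(residues) == 0) stop("residue list must be non-empty")
  occ <- vapply(seq_len(nrow(residues)), function(i) {
    tr <- ion_residue_distance_trace(traj, ions,
                                     c(residues$chain[i], residues$resid[i]),
                                     oxygens_only = oxygens_only)
    mean(tr$series$values < shell_cutoff_nm)
  }, numeric(1))
  out <- data.frame(chain = residues$chain, resid = residues$resid,
                    occupancy = occ, stringsAsFactors = FALSE)
  attr(out, "shell_cutoff_nm") <- shell_cutoff_nm
  out
}

#' Hydration-shell water count series
#'
#' Per frame, the number of distinct water molecules whose oxygen lies
#' within the cutoff of any selected ion atom, plus a centred running mean.
#' Two documented presets for the cutoff: 0.3 nm (first shell) and 0.5 nm
#' (extended shell, the bulk-coordination regime of 15-18 waters).
#'
#' @param traj a [trajectory] whose topology contains water molecules.
#' @param ion ion atom selection.
#' @param cutoff_nm shell cutoff in nm (explicit; no default by design).
#' @param smoothing_window_ps running-mean window (default 500 ps).
#' @return An object of class `hydration_series`: list with `ion_label`,
#'   `series` (integer counts), `running_mean` (a [time_series]) and
#'   `cutoff_nm`.
#' @export
hydration_count_series <- function(traj, ion, cutoff_nm,
                                   smoothing_window_ps = 500) {
  a <- traj$topology$atoms
  ii <- selection_indices(ion)
  if (length(ii) == 0) stop("empty ion selection")
  iw <- which(a$is_water & a$element == "O")
  if (length(iw) == 0) stop("topology contains no water molecules")
  counts <- vapply(seq_len(n_frames(traj)), function(k) {
    D <- cross_dist(coords_slice(traj$coords, iw, k),
                    coords_slice(traj$coords, ii, k))
    sum(apply(D < cutoff_nm, 1, any))
  }, numeric(1))
  series <- time_series(traj$times, counts, label = "waters in shell",
                        units = "count")
  structure(list(ion_label = attr(ion, "expression") %||% "ion",
                 series = series,
                 running_mean = running_mean_trace(series, smoothing_window_ps),
                 cutoff_nm = cutoff_nm),
            class = "hydration_series")
}

#' @export
print.hydration_series <- function(x, ...) {
  cat(sprintf("hydration_series '%s': mean %.2f waters within %.2f nm\n",
              x$ion_label, mean(x$series$values), x$cutoff_nm))
  invisible(x)
}
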