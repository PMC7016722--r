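#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` over a fit
#' selection, returning a proper rotation (determinant +1) and translation
#' minimising the RMSD over the fit atoms, plus the transformed coordinates
#' of all mobile atoms.
#'
#' @param mobile `n x 3` coordinate matrix (nm).
#' @param reference `n x 3` coordinate matrix (nm), same atom order.
#' @param fit_selection indices of the atoms used for the fit (an
#'   [select_atoms] result or integer vector); defaults to all atoms. At
#'   least 3 non-collinear atoms are required.
#' @return List with `rotation` (3x3), `translation` (length 3), `coords`
#'   (transformed mobile coordinates, `n x 3`).
#' @export
kabsch_superpose <- function(mobile, reference, fit_selection = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  idx <- if (is.null(fit_selection)) seq_len(nrow(mobile)) else selection_indices(fit_selection)
  if (length(idx) < 3) stop("degenerate fit: need at least 3 fit atoms")
  M <- mobile[idx, , drop = FALSE]
  R <- reference[idx, , drop = FALSE]
  mc <- colMeans(M)
  rc <- colMeans(R)
  Mc <- sweep(M, 2, mc)
  Rc <- sweep(R, 2, rc)
  # collinearity check: a line has a rank-1 centred coordinate matrix
  sv_ref <- svd(Rc, nu = 0, nv = 0)$d
  if (sv_ref[2] < 1e-10 * max(sv_ref[1], 1e-300)) {
    stop("degenerate fit: fit atoms are collinear")
  }
  H <- crossprod(Mc, Rc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  rot <- s$v %*% D %*% t(s$u)
  trans <- rc - as.vector(rot %*% mc)
  coords <- t(rot %*% t(mobile)) + matrix(trans, nrow(mobile), 3, byrow = TRUE)
  list(rotation = rot, translation = trans, coords = coords)
}

# plain RMSD between equal-shaped coordinate matrices (no fitting)
rmsd_between <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD series after superposition
#'
#' Each frame is superposed onto the reference over `selection` before the
#' RMSD over the same selection is computed, so rigid-body motion does not
#' contribute.
#'
#' @param traj a [trajectory].
#' @param reference reference coordinates (`n_atoms x 3` nm) or a frame
#'   index into `traj` (default: frame 1).
#' @param selection atoms used for both fit and RMSD (default: all atoms).
#' @return A [time_series] in nm.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL) {
  if (length(reference) == 1 && is.numeric(reference)) {
    reference <- frame_coords(traj, reference)
  }
  idx <- if (is.null(selection)) seq_len(n_atoms(traj$topology)) else selection_indices(selection)
  if (length(idx) == 0) stop("empty selection")
  ref <- reference[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    mob <- traj$coords[idx, , k, drop = TRUE]
    fit <- kabsch_superpose(mob, ref)
    rmsd_between(fit$coords, ref)
  }, numeric(1))
  time_series(traj$times, vals, label = "RMSD", units = "nm")
}

#' Per-residue RMSF
#'
#' Frames are superposed onto the time-averaged structure of the selection
#' (one round of mean-structure iteration starting from frame 1), then the
#' per-atom root-mean-square deviation from the averaged position is
#' computed and averaged within each residue.
#'
#' @param traj a [trajectory].
#' @param selection atoms analysed (default: all atoms).
#' @param superpose set to `FALSE` if the trajectory is already superposed.
#' @return Data frame with columns `chain`, `resid`, `resname`, `rmsf_nm`.
#' @export
rmsf_per_residue <- function(traj, selection = NULL, superpose = TRUE) {
  idx <- if (is.null(selection)) seq_len(n_atoms(traj$topology)) else selection_indices(selection)
  if (length(idx) == 0) stop("empty selection")
  nf <- n_frames(traj)
  sub <- traj$coords[idx, , , drop = FALSE]
  if (superpose && length(idx) >= 3) {
    ref <- sub[, , 1, drop = TRUE]
    for (pass in 1:2) {
      for (k in seq_len(nf)) {
        sub[, , k] <- kabsch_superpose(sub[, , k, drop = TRUE], ref)$coords
      }
      ref <- apply(sub, c(1, 2), mean)
    }
  }
  mean_pos <- apply(sub, c(1, 2), mean)
  dev2 <- vapply(seq_len(nf), function(k) {
    rowSums((sub[, , k, drop = TRUE] - mean_pos)^2)
  }, numeric(length(idx)))
  if (length(idx) == 1) dev2 <- matrix(dev2, nrow = 1)
  rmsf_atom <- sqrt(rowMeans(dev2))
  a <- traj$topology$atoms[idx, ]
  key <- paste(a$chain, a$resid)
  agg <- tapply(rmsf_atom, key, mean)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resid = a$resid[first],
                    resname = a$resname[first],
                    rmsf_nm = as.numeric(agg[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resid), , drop = FALSE]
}

#' Interhelical (helix-loop-helix opening) angle series
#'
#' The opening of the helix-loop-helix unit is measured as the angle at the
#' EF-site anchor C-alpha (the vertex) between the vectors pointing to the
#' C-alpha atoms of the two helix anchors, per frame, in degrees. For the
#' S100A1 topology the anchors are Lys56 (H3), Glu73 (EF site, vertex) and
#' Trp90 (H4).
#'
#' @param traj a [trajectory].
#' @param subunit chain identifier.
#' @param anchors integer triple `(resA, res_vertex, resC)`.
#' @return An object of class `angle_series`: list with `subunit`,
#'   `anchor_residues` and `series` (a [time_series] in degrees).
#' @export
interhelical_angle_series <- function(traj, subunit, anchors = c(56L, 73L, 90L)) {
  stopifnot(length(anchors) == 3)
  a <- traj$topology$atoms
  ca_idx <- vapply(anchors, function(r) {
    i <- which(a$chain == subunit & a$resid == r & a$name == "CA")
    if (length(i) != 1) {
      stop(sprintf("no CA atom for residue %d in subunit %s", r, subunit))
    }
    i
  }, integer(1))
  pa <- traj$coords[ca_idx[1], , , drop = TRUE]
  pv <- traj$coords[ca_idx[2], , , drop = TRUE]
  pc <- traj$coords[ca_idx[3], , , drop = TRUE]
  if (n_frames(traj) == 1) {
    pa <- matrix(pa, 3, 1); pv <- matrix(pv, 3, 1); pc <- matrix(pc, 3, 1)
  }
  v1 <- pa - pv
  v2 <- pc - pv
  n1 <- sqrt(colSums(v1^2))
  n2 <- sqrt(colSums(v2^2))
  if (any(n1 == 0) || any(n2 == 0)) {
    stop("undefined angle: zero-length anchor vector")
  }
  cosang <- pmin(1, pmax(-1, colSums(v1 * v2) / (n1 * n2)))
  structure(list(subunit = subunit, anchor_residues = anchors,
                 series = time_series(traj$times, acos(cosang) * 180 / pi,
                                      label = sprintf("interhelical angle %s", subunit),
                                      units = "degrees")),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("angle_series: subunit %s, anchors (%s)\n", x$subunit,
              paste(x$anchor_residues, collapse = ", ")))
  print(x$series)
  invisible(x)
}

#' Windowed angle statistics
#'
#' Splits an angle series into consecutive time windows `(prev_end, end_i]`
#' (in ns) and reports the mean and sample standard deviation per window,
#' the summary style used for interhelical-angle tables (e.g. windows ending
#' at 10, 40 and 80 or 100 ns).
#'
#' @param angle an `angle_series` from [interhelical_angle_series] (or a
#'   bare [time_series] in degrees).
#' @param window_ends_ns increasing window end times in ns.
#' @return Data frame with `window_end_ns`, `mean_deg`, `sd_deg`, `n_frames`.
#' @export
block_average_angles <- function(angle, window_ends_ns) {
  series <- if (inherits(angle, "angle_series")) angle$series else angle
  stopifnot(inherits(series, "time_series"))
  if (any(diff(window_ends_ns) <= 0)) stop("window ends must be increasing")
  t_ns <- series$times / 1000
  prev <- 0
  out <- data.frame(window_end_ns = window_ends_ns, mean_deg = NA_real_,
                    sd_deg = NA_real_, n_frames = NA_integer_)
  for (i in seq_along(window_ends_ns)) {
    w <- window_ends_ns[i]
    inwin <- t_ns > prev & t_ns <= w
    if (!any(inwin)) {
      stop(sprintf("empty angle window (%g, %g] ns", prev, w))
    }
    v <- series$values[inwin]
    out$mean_deg[i] <- mean(v)
    out$sd_deg[i] <- if (length(v) > 1) stats::sd(v) else 0
    out$n_frames[i] <- sum(inwin)
    prev <- w
  }
  out
}
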