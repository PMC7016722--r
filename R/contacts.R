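# matrix slice of a coordinate cube that stays a matrix for length-1 index sets
coords_slice <- function(coords, idx, k) {
  m <- coords[idx, , k, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

cross_dist <- function(A, B) {
  # Euclidean cross-distance matrix, rows of A x rows of B
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

heavy_indices <- function(top, sel) {
  idx <- selection_indices(sel)
  idx[top$atoms$element[idx] != "H"]
}

#' Minimum-distance trace between two selections
#'
#' Per frame, the minimum over all cross pairs of Euclidean distance between
#' the two atom sets.
#'
#' @param traj a [trajectory].
#' @param selA,selB atom selections (non-empty).
#' @param pair_label label stored on the result.
#' @return An object of class `distance_trace`: list with `pair_label` and
#'   `series` (a [time_series] in nm).
#' @export
min_distance_trace <- function(traj, selA, selB, pair_label = NULL) {
  ia <- selection_indices(selA)
  ib <- selection_indices(selB)
  if (length(ia) == 0 || length(ib) == 0) stop("empty selection")
  if (is.null(pair_label)) {
    pair_label <- paste0(attr(selA, "expression") %||% "A", " vs ",
                         attr(selB, "expression") %||% "B")
  }
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    min(cross_dist(coords_slice(traj$coords, ia, k),
                   coords_slice(traj$coords, ib, k)))
  }, numeric(1))
  distance_trace(pair_label, time_series(traj$times, vals,
                                         label = pair_label, units = "nm"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

distance_trace <- function(pair_label, series) {
  structure(list(pair_label = pair_label, series = series),
            class = "distance_trace")
}

#' @export
print.distance_trace <- function(x, ...) {
  cat(sprintf("distance_trace '%s': min %.3f nm, mean %.3f nm over %d frames\n",
              x$pair_label, min(x$series$values), mean(x$series$values),
              length(x$series$values)))
  invisible(x)
}

CONTACT_CLASSES <- c("none", "blue", "green", "yellow", "orange", "red")

#' Classify a residue-pair distance into the five contact classes
#'
#' Residue pairs whose minimum distance never drops below 0.4 nm are not
#' contacts (`none`). Otherwise the time-averaged minimum distance is
#' binned: `red` below 0.15 nm, `orange` in \[0.15, 0.25), `yellow` in
#' \[0.25, 0.30), `green` in \[0.30, 0.35) and `blue` at or above 0.35 nm.
#' The red/orange boundaries are midpoints around the nominal 0.1 and
#' 0.2 nm class centres so the classes are exhaustive and disjoint.
#'
#' @param mean_nm time-averaged minimum distance (nm), vectorised.
#' @param min_nm overall minimum distance (nm), vectorised.
#' @return Character vector of class codes.
#' @export
classify_mean_distance <- function(mean_nm, min_nm) {
  if (any(mean_nm <= 0) || any(min_nm <= 0)) {
    stop("distances must be positive")
  }
  out <- ifelse(min_nm >= 0.4, "none",
         ifelse(mean_nm < 0.15, "red",
         ifelse(mean_nm < 0.25, "orange",
         ifelse(mean_nm < 0.30, "yellow",
         ifelse(mean_nm < 0.35, "green", "blue")))))
  out
}

#' Inter-subunit contact map
#'
#' For every residue pair across two subunits, the per-frame minimum
#' heavy-atom cross distance is averaged over a time window; cells are
#' classified with [classify_mean_distance].
#'
#' @param traj a [trajectory].
#' @param subunit_a,subunit_b chain identifiers.
#' @param window `c(t_start_ps, t_end_ps)` window (inclusive); default all
#'   frames.
#' @param mean_type `"arithmetic"` (default) or `"geometric"` averaging of
#'   the per-frame minima.
#' @return An object of class `contact_map`: residue vectors `residues_a`,
#'   `residues_b`, matrices `mean_distance`, `min_distance` (nm) and
#'   `class_code`.
#' @export
contact_map <- function(traj, subunit_a, subunit_b, window = NULL,
                        mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  top <- traj$topology
  a <- top$atoms
  ia <- which(a$chain == subunit_a & !a$is_water & !a$is_ion & a$element != "H")
  ib <- which(a$chain == subunit_b & !a$is_water & !a$is_ion & a$element != "H")
  if (length(ia) == 0 || length(ib) == 0) {
    stop("no heavy atoms found for the requested subunits")
  }
  frames <- seq_len(n_frames(traj))
  if (!is.null(window)) {
    frames <- which(traj$times >= window[1] & traj$times <= window[2])
    if (length(frames) == 0) stop("empty contact-map window")
  }
  res_a <- sort(unique(a$resid[ia]))
  res_b <- sort(unique(a$resid[ib]))
  ga <- match(a$resid[ia], res_a)
  gb <- match(a$resid[ib], res_b)
  acc <- matrix(0, length(res_a), length(res_b))
  mn <- matrix(Inf, length(res_a), length(res_b))
  for (k in frames) {
    dk <- cpp_group_min_cross(coords_slice(traj$coords, ia, k),
                              coords_slice(traj$coords, ib, k),
                              ga, gb, length(res_a), length(res_b))
    acc <- acc + (if (mean_type == "geometric") log(dk) else dk)
    mn <- pmin(mn, dk)
  }
  mean_d <- acc / length(frames)
  if (mean_type == "geometric") mean_d <- exp(mean_d)
  cls <- matrix(classify_mean_distance(as.vector(mean_d), as.vector(mn)),
                nrow(mean_d), ncol(mean_d))
  dimnames(mean_d) <- dimnames(mn) <- dimnames(cls) <- list(res_a, res_b)
  structure(list(residues_a = res_a, residues_b = res_b,
                 mean_distance = mean_d, min_distance = mn, class_code = cls,
                 subunit_a = subunit_a, subunit_b = subunit_b),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  tab <- table(factor(x$class_code, levels = CONTACT_CLASSES))
  cat(sprintf("contact_map %s x %s: %d x %d residues\n", x$subunit_a,
              x$subunit_b, length(x$residues_a), length(x$residues_b)))
  print(tab)
  invisible(x)
}

#' Long-format data frame of a contact map
#' @param x a `contact_map`.
#' @param contacts_only drop `none` cells (default TRUE).
#' @param ... unused.
#' @return Data frame `resA`, `resB`, `mean_nm`, `min_nm`, `class`.
#' @export
as.data.frame.contact_map <- function(x, contacts_only = TRUE, ...) {
  df <- expand.grid(resA = x$residues_a, resB = x$residues_b,
                    KEEP.OUT.ATTRS = FALSE)
  df$mean_nm <- as.vector(x$mean_distance)
  df$min_nm <- as.vector(x$min_distance)
  df$class <- as.vector(x$class_code)
  if (contacts_only) df <- df[df$class != "none", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Geometric hydrogen-bond count series
#'
#' Distance-only criterion: per frame, the number of cross pairs of N/O
#' heavy atoms (one from each selection) within the cutoff. Each atom may
#' participate in several pairs. An optional donor-H-acceptor angle
#' criterion (>= `min_angle_deg`) is applied when `use_angle = TRUE` and
#' hydrogens are present: a hydrogen within 0.12 nm of the donor heavy atom
#' is taken as covalently bound.
#'
#' @param traj a [trajectory].
#' @param selA,selB atom selections; automatically restricted to N/O heavy
#'   atoms.
#' @param cutoff_nm heavy-atom distance cutoff (default 0.35 nm).
#' @param use_angle apply the angular criterion (default FALSE).
#' @param min_angle_deg donor-H-acceptor angle threshold (default 150).
#' @return An object of class `hbond_series`: list with `series` (integer
#'   counts), `cutoff_nm` and `criterion`.
#' @export
hbond_count_series <- function(traj, selA, selB, cutoff_nm = 0.35,
                               use_angle = FALSE, min_angle_deg = 150) {
  top <- traj$topology
  ia <- selection_indices(selA)
  ib <- selection_indices(selB)
  ia <- ia[top$atoms$element[ia] %in% c("N", "O")]
  ib <- ib[top$atoms$element[ib] %in% c("N", "O")]
  if (length(ia) == 0 || length(ib) == 0) {
    stop("no N/O donor/acceptor atoms left after filtering the selections")
  }
  h_idx <- which(top$atoms$element == "H")
  counts <- vapply(seq_len(n_frames(traj)), function(k) {
    A <- coords_slice(traj$coords, ia, k)
    B <- coords_slice(traj$coords, ib, k)
    D <- cross_dist(A, B)
    pairs <- which(D < cutoff_nm, arr.ind = TRUE)
    if (!use_angle || nrow(pairs) == 0 || length(h_idx) == 0) {
      return(nrow(pairs))
    }
    H <- coords_slice(traj$coords, h_idx, k)
    ok <- logical(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      don <- A[pairs[p, 1], ]
      acc <- B[pairs[p, 2], ]
      hd <- cross_dist(H, matrix(don, 1, 3))
      bonded <- which(hd < 0.12)
      ang_ok <- FALSE
      for (h in bonded) {
        v1 <- don - H[h, ]
        v2 <- acc - H[h, ]
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        if (ang >= min_angle_deg) { ang_ok <- TRUE; break }
      }
      ok[p] <- ang_ok
    }
    sum(ok)
  }, numeric(1))
  criterion <- if (use_angle) {
    sprintf("N/O pairs < %.2f nm with D-H...A angle >= %g deg", cutoff_nm, min_angle_deg)
  } else {
    sprintf("N/O heavy-atom pairs < %.2f nm", cutoff_nm)
  }
  structure(list(series = time_series(traj$times, counts,
                                      label = "H-bond count", units = "count"),
                 cutoff_nm = cutoff_nm, criterion = criterion),
            class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("hbond_series (%s): mean %.2f over %d frames\n", x$criterion,
              mean(x$series$values), length(x$series$values)))
  invisible(x)
}
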