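#' Pairwise RMSD matrix over a trajectory
#'
#' Entry (i, j) is the RMSD between frames i and j over the selection after
#' optimal pairwise superposition (Kabsch). Computed in compiled code via
#' the Gram/SVD identity; the diagonal is 0 and the matrix symmetric.
#'
#' @param traj a [trajectory] with at least 2 frames.
#' @param selection atoms used for fit and RMSD (default: all atoms).
#' @param stride analyse every `stride`-th frame (default 1). The returned
#'   matrix carries the analysed frame indices and times as attributes.
#' @return Symmetric numeric matrix in nm with attributes `frames`, `times`.
#' @export
pairwise_rmsd_matrix <- function(traj, selection = NULL, stride = 1L) {
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  idx <- if (is.null(selection)) seq_len(n_atoms(traj$topology)) else selection_indices(selection)
  if (length(idx) < 3) stop("degenerate selection: need at least 3 atoms")
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  m <- cpp_pairwise_rmsd(traj$coords[idx, , frames, drop = FALSE])
  attr(m, "frames") <- frames
  attr(m, "times") <- traj$times[frames]
  m
}

#' GROMOS neighbor-counting conformational clustering
#'
#' Iteratively takes the frame with the most neighbors within the RMSD
#' cutoff as a cluster centroid, assigns the centroid and its neighbors to
#' that cluster, removes them, and repeats on the remaining frames. Ties in
#' neighbor count are broken by the lowest frame index, making the result
#' deterministic. Cluster 1 is the largest (extraction order is
#' non-increasing in size).
#'
#' @param matrix symmetric pairwise-RMSD matrix with zero diagonal, e.g.
#'   from [pairwise_rmsd_matrix].
#' @param cutoff_nm neighbor cutoff (default 0.2 nm).
#' @return An object of class `cluster_result`: `labels` (cluster id per
#'   frame, 1 = largest), `sizes`, `centroids` (representative frame index
#'   per cluster) and `cutoff_nm`.
#' @export
gromos_cluster <- function(matrix, cutoff_nm = 0.2) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix must be symmetric")
  n <- nrow(m)
  neigh <- m < cutoff_nm
  diag(neigh) <- TRUE
  labels <- integer(n)
  centroids <- integer(0)
  sizes <- integer(0)
  remaining <- rep(TRUE, n)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- colSums(neigh[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    centre <- which.max(counts)  # ties: lowest index
    members <- which(remaining & neigh[centre, ])
    labels[members] <- cl
    centroids[cl] <- centre
    sizes[cl] <- length(members)
    remaining[members] <- FALSE
  }
  structure(list(labels = labels, sizes = sizes, centroids = centroids,
                 cutoff_nm = cutoff_nm,
                 frames = attr(matrix, "frames") %||% seq_len(n),
                 times = attr(matrix, "times")),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d frames (cutoff %.2f nm)\n",
              length(x$sizes), length(x$labels), x$cutoff_nm))
  cat("  sizes:", paste(utils::head(x$sizes, 10), collapse = ", "),
      if (length(x$sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Temporal distribution of cluster membership
#'
#' Turns per-frame cluster labels into a cluster-id time series and, per
#' cluster, the list of contiguous time spans it occupies. Span boundaries
#' sit at the first frame of each contiguous run; the last span ends at the
#' final frame time, so span lengths sum to `times[n] - times[1]`.
#'
#' @param result a `cluster_result`.
#' @param times frame times in ps (defaults to the times recorded on the
#'   result, if any).
#' @return List with `series` (a [time_series] of cluster ids) and `spans`
#'   (data frame `cluster`, `start_ps`, `end_ps`, `duration_ps`).
#' @export
temporal_distribution <- function(result, times = NULL) {
  labels <- result$labels
  if (is.null(times)) times <- result$times
  if (is.null(times)) stop("frame times are required")
  stopifnot(length(times) == length(labels))
  r <- rle(labels)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  # run k occupies [t_first(k), t_first(k+1)); the last run ends at times[n]
  start_ps <- times[starts_idx]
  end_ps <- c(times[starts_idx[-1]], times[length(times)])
  spans <- data.frame(cluster = r$values, start_ps = start_ps,
                      end_ps = end_ps, duration_ps = end_ps - start_ps)
  list(series = time_series(times, labels, label = "cluster id", units = "id"),
       spans = spans)
}

#' Centred running mean of a time series
#'
#' Mean over all points within `window_ps / 2` of each time point;
#' truncated windows at the edges. The 100-ps-window mean cluster-id trace
#' is the classic use.
#'
#' @param series a [time_series].
#' @param window_ps window width in ps (must be at least the frame spacing).
#' @return A [time_series] of the same length.
#' @export
running_mean_trace <- function(series, window_ps = 100) {
  stopifnot(inherits(series, "time_series"))
  t <- series$times
  v <- series$values
  n <- length(t)
  if (n > 1 && window_ps < min(diff(t))) {
    stop("running-mean window is smaller than the frame spacing")
  }
  half <- window_ps / 2
  # cumulative sums + binary search for window edges
  cs <- c(0, cumsum(v))
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  time_series(t, out, label = paste(series$label, "(running mean)"),
              units = series$units)
}
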