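# quick topology builder: one row per atom spec "chain/resid/resname/name"
make_toy_top <- function(..., element = NULL) {
  specs <- strsplit(c(...), "/", fixed = TRUE)
  atoms <- data.frame(
    serial = seq_along(specs),
    chain = vapply(specs, `[`, "", 1),
    resid = as.integer(vapply(specs, `[`, "", 2)),
    resname = vapply(specs, `[`, "", 3),
    name = vapply(specs, `[`, "", 4),
    stringsAsFactors = FALSE)
  if (!is.null(element)) atoms$element <- element
  topology(atoms)
}

# trajectory from a list of n_atoms x 3 coordinate matrices
make_toy_traj <- function(top, frames, dt_ps = 10, t0 = 0) {
  coords <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  trajectory(top, coords, seq(t0, by = dt_ps, length.out = length(frames)))
}

# uniformly random proper rotation
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a small dimer used across tests
small_dimer <- function(n = 30L) {
  build_toy_dimer(toy_dimer_spec(n_residues = n,
                                 anchors = c(5L, 15L, 25L),
                                 ef_site_residues = c(8L, 12L, 20L)))
}

# brute-force GROMOS clustering oracle: literal neighbor-count simulation
brute_gromos <- function(m, cutoff) {
  n <- nrow(m)
  remaining <- seq_len(n)
  labels <- integer(n)
  cl <- 0L
  while (length(remaining) > 0) {
    cl <- cl + 1L
    best <- NA_integer_
    best_count <- -1L
    for (i in remaining) {
      cnt <- sum(m[i, remaining] < cutoff)  # includes i (diagonal 0)
      if (cnt > best_count) { best_count <- cnt; best <- i }
    }
    members <- remaining[m[best, remaining] < cutoff]
    labels[members] <- cl
    remaining <- setdiff(remaining, members)
  }
  labels
}

# random symmetric zero-diagonal "RMSD" matrix
rand_rmsd_matrix <- function(n, scale = 0.4) {
  m <- matrix(runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
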