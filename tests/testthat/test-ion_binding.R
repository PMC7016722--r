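ion_res_top <- function() {
  make_toy_top("A/1/GLU/CA", "A/1/GLU/OE1", "I/1/CA/CA", "I/2/CA/CA",
               element = c("C", "O", "CA", "CA"))
}

test_that("ion-residue traces take the minimum over pooled ions", {
  top <- ion_res_top()
  f <- rbind(c(0, 0, 0), c(0.25, 0, 0), c(0.45, 0, 0), c(5, 0, 0))
  traj <- make_toy_traj(top, rep(list(f), 4))
  ions <- select_atoms(top, "ion")
  tr <- ion_residue_distance_trace(traj, ions, c("A", 1))
  expect_equal(tr$series$values, rep(0.2, 4))  # nearer ion, nearer atom
  ox <- ion_residue_distance_trace(traj, ions, c("A", 1), oxygens_only = TRUE)
  expect_equal(ox$series$values, rep(0.2, 4))
  one_far <- ion_residue_distance_trace(traj,
                                        select_atoms(top, "ion and resid 2"),
                                        c("A", 1))
  expect_equal(one_far$series$values, rep(4.75, 4))
  expect_error(ion_residue_distance_trace(traj, ions, c("A", 9)), "not found")
})

test_that("a scripted exponential approach is reproduced exactly at zero noise", {
  d <- small_dimer()
  ion <- ion_schedule("CA1", c("A", 12),
                      make_schedule(sched_exp(0, 2000, 1.8, 0.25), T_ps = 2000))
  g <- generate_trajectory(d, T_ps = 2000, dt_ps = 10,
                           ion_schedules = list(ion), seed = 14)
  tr <- ion_residue_distance_trace(g$trajectory,
                                   select_atoms(g$trajectory$topology, "ion"),
                                   c("A", 12))
  expect_equal(tr$series$values, g$truth$ions$CA1$distance, tolerance = 1e-9)
})

test_that("encounter detection: first/second entries, merging, oversampling", {
  mk <- function(t, v) time_series(t, v, units = "nm")
  t <- seq(0, 20000, by = 100)
  never <- mk(t, rep(0.8, length(t)))
  rec0 <- detect_encounters(never)
  expect_true(is.na(rec0$FET) && is.na(rec0$SET))
  once <- mk(t, ifelse(t >= 5000, 0.3, 0.8))
  rec1 <- detect_encounters(once)
  expect_equal(rec1$FET, 5000)
  expect_true(is.na(rec1$SET))
  # two entries separated by a 2000 ps excursion; brute-force frame scan
  v <- rep(0.8, length(t))
  v[t >= 3000 & t < 9000] <- 0.3
  v[t >= 11000] <- 0.3
  rec2 <- detect_encounters(mk(t, v))
  expect_equal(rec2$FET, 3000)
  expect_equal(rec2$SET, 11000)
  inside <- v < 0.5
  expect_equal(rec2$FET, t[which(inside)[1]])  # frame-scan oracle
  # a 30 ps excursion (below gap_tol) merges into one encounter
  t2 <- seq(0, 1000, by = 10)
  v2 <- rep(0.3, length(t2))
  v2[t2 > 500 & t2 <= 530] <- 0.8
  rec3 <- detect_encounters(mk(t2, v2), gap_tol_ps = 50)
  expect_equal(rec3$FET, 0)
  expect_true(is.na(rec3$SET))
  # duplicating every sample at the same time changes nothing
  dup <- mk(rep(t, each = 2), rep(v, each = 2))
  rec4 <- detect_encounters(dup)
  expect_equal(rec4$FET, rec2$FET)
  expect_equal(rec4$SET, rec2$SET)
  expect_error(detect_encounters(once, cutoff_nm = 0), "positive")
})

test_that("residence-time arithmetic reproduces the published convention", {
  expect_equal(trt_from_times(280, 0, 80000), 79720)
  expect_equal(trt_from_times(588, 0, 80000), 79412)
  expect_equal(trt_from_times(0, 0, 80000), 0)
  expect_equal(trt_from_times(100, 200, 80000), 79900)
  rec <- structure(list(FET = 280, SET = NA_real_), class = "encounter_record")
  expect_equal(total_residence_time(rec, 80000), 79720)
  rec0 <- structure(list(FET = 0, SET = NA_real_), class = "encounter_record")
  expect_equal(total_residence_time(rec0, 80000), 80000)  # genuine t=0 entry
  expect_error(trt_from_times(90000, 0, 80000), "exceeds")
})

test_that("the two-encounter formula collapses to T - FET for random records", {
  set.seed(15)
  n <- 1e5
  T_ps <- 80000
  fet <- runif(n, 1, T_ps - 2)
  set <- fet + runif(n, 0.5, T_ps - fet - 1)
  trt <- trt_from_times(fet, set, T_ps, zero_means_absent = FALSE)
  expect_equal(trt, T_ps - fet, tolerance = 1e-12)
  expect_true(all(trt <= T_ps))
  expect_true(all(trt > 0))
})

test_that("occupancy fractions recover scripted dual-site schedules", {
  d <- small_dimer()
  T_ps <- 4000
  # 80% of frames inside the 0.3 nm shell of A8, then hops to A20 for 20%
  ion1 <- ion_schedule("CA1", c("A", 8),
                       make_schedule(sched_hold(0, 3190, 0.2),
                                     sched_hold(3190, T_ps, 3.0), T_ps = T_ps))
  ion2 <- ion_schedule("CA2", c("A", 20),
                       make_schedule(sched_hold(0, 3190, 3.0),
                                     sched_hold(3190, T_ps, 0.2), T_ps = T_ps))
  g <- generate_trajectory(d, T_ps = T_ps, dt_ps = 10,
                           ion_schedules = list(ion1, ion2), seed = 16)
  top <- g$trajectory$topology
  occ1 <- binding_site_occupancy(g$trajectory,
                                 select_atoms(top, "ion and resid 1"),
                                 data.frame(chain = "A", resid = 8L))
  occ2 <- binding_site_occupancy(g$trajectory,
                                 select_atoms(top, "ion and resid 2"),
                                 data.frame(chain = "A", resid = 20L))
  nfr <- n_frames(g$trajectory)
  expect_equal(occ1$occupancy, g$truth$ions$CA1$occupancy, tolerance = 1 / nfr)
  expect_equal(occ2$occupancy, g$truth$ions$CA2$occupancy, tolerance = 1 / nfr)
  expect_lt(abs(occ1$occupancy - 0.8), 2 / nfr)
  # one ion visiting exclusive sites: occupancies sum to <= 1
  occ_both <- binding_site_occupancy(g$trajectory,
                                     select_atoms(top, "ion and resid 1"),
                                     data.frame(chain = c("A", "A"),
                                                resid = c(8L, 20L)))
  expect_lte(sum(occ_both$occupancy), 1)
  expect_error(binding_site_occupancy(g$trajectory, select_atoms(top, "ion"),
                                      data.frame(chain = character(0),
                                                 resid = integer(0))),
               "non-empty")
})

test_that("hydration counts waters by oxygen and flags waterless systems", {
  # 7 water oxygens inside 0.3 nm, 3 outside
  specs <- c("I/1/CA/CA", paste0("W/", 1:10, "/SOL/OW"))
  top <- make_toy_top(specs, element = c("CA", rep("O", 10)))
  top$atoms$is_water <- c(FALSE, rep(TRUE, 10))
  top$atoms$is_ion <- c(TRUE, rep(FALSE, 10))
  dirs <- matrix(rnorm(30), 10, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  f <- rbind(c(0, 0, 0), dirs * c(rep(0.2, 7), rep(2, 3)))
  traj <- make_toy_traj(top, rep(list(f), 3))
  h <- hydration_count_series(traj, select_atoms(top, "ion"), 0.3,
                              smoothing_window_ps = 20)
  expect_equal(h$series$values, rep(7, 3))
  expect_equal(h$running_mean$values, rep(7, 3))
  d <- small_dimer()
  g <- generate_trajectory(d, T_ps = 20, dt_ps = 10, seed = 1)
  expect_error(hydration_count_series(g$trajectory,
                                      select_atoms(g$trajectory$topology, "name CA"),
                                      0.3), "no water")
})

test_that("scripted desolvation puts the count minimum at the scripted time", {
  d <- small_dimer()
  T_ps <- 3000
  ion <- ion_schedule("CA1", c("A", 12),
                      make_schedule(sched_hold(0, T_ps, 6.0), T_ps = T_ps))
  # locate the (static) scripted ion so the bath can be centred on it
  g0 <- generate_trajectory(d, T_ps = 10, dt_ps = 10,
                            ion_schedules = list(ion_schedule("CA1", c("A", 12),
                                                              make_schedule(sched_hold(0, 10, 6.0), T_ps = 10))),
                            seed = 17)
  ion_pos <- frame_coords(g0$trajectory, 1)[select_atoms(g0$trajectory$topology, "ion"), ]
  w <- water_spec(400, box_nm = 3, center = as.numeric(ion_pos),
                  desolvation = list(ion_label = "CA1", t_min_ps = 1500,
                                     width_ps = 300, depth = 0.8))
  g <- generate_trajectory(d, T_ps = T_ps, dt_ps = 10,
                           ion_schedules = list(ion), waters = w, seed = 17)
  ion_idx <- select_atoms(g$trajectory$topology, "ion")
  smooth <- 300
  h <- hydration_count_series(g$trajectory, ion_idx, 0.5,
                              smoothing_window_ps = smooth)
  t_min <- h$running_mean$times[which.min(h$running_mean$values)]
  expect_lt(abs(t_min - g$truth$hydration$t_min_ps), smooth + 100)
})
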