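test_that("the toy dimer realises the requested layout", {
  spec <- toy_dimer_spec()
  d <- build_toy_dimer(spec)
  a <- d$topology$atoms
  expect_setequal(unique(a$chain), c("A", "B"))
  expect_equal(length(unique(a$resid[a$chain == "A"])), 100)
  # anchors resolve to CA atoms and the angle is computable on frame 1
  traj1 <- trajectory(d$topology, d$coords, 0)
  expect_no_error(interhelical_angle_series(traj1, "A", spec$anchors))
  # every EF-site residue carries a side-chain oxygen
  for (r in spec$ef_site_residues) {
    expect_gte(sum(a$chain == "A" & a$resid == r & a$element == "O" &
                   a$name == "OE1"), 1)
  }
  expect_error(toy_dimer_spec(n_residues = 50, anchors = c(10, 30, 60)),
               "within the chain")
})

test_that("equal seeds give bit-identical trajectories", {
  d <- small_dimer()
  sch <- make_schedule(sched_linear(0, 500, 60, 100), T_ps = 500)
  ion <- ion_schedule("CA1", c("A", 8),
                      make_schedule(sched_exp(0, 500, 1.5, 0.3), T_ps = 500))
  w <- water_spec(30, box_nm = 4)
  g1 <- generate_trajectory(d, T_ps = 500, dt_ps = 10, angle_schedule = sch,
                            ion_schedules = list(ion), waters = w, seed = 23,
                            noise_sigma_nm = 0.01)
  g2 <- generate_trajectory(d, T_ps = 500, dt_ps = 10, angle_schedule = sch,
                            ion_schedules = list(ion), waters = w, seed = 23,
                            noise_sigma_nm = 0.01)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  g3 <- generate_trajectory(d, T_ps = 500, dt_ps = 10, angle_schedule = sch,
                            ion_schedules = list(ion), waters = w, seed = 24,
                            noise_sigma_nm = 0.01)
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
})

test_that("a constant angle schedule is realised to machine precision", {
  d <- small_dimer()
  sch <- make_schedule(sched_hold(0, 300, 70), T_ps = 300)
  g <- generate_trajectory(d, T_ps = 300, dt_ps = 10, angle_schedule = sch,
                           seed = 25)
  for (ch in c("A", "B")) {
    ang <- interhelical_angle_series(g$trajectory, ch, d$spec$anchors)
    expect_equal(ang$series$values, rep(70, n_frames(g$trajectory)),
                 tolerance = 1e-6)
  }
})

test_that("scripted encounters land at the schedule's crossing time", {
  d <- small_dimer()
  T_ps <- 12000
  ion <- ion_schedule("CA1", c("A", 20),
                      make_schedule(sched_hold(0, 6000, 1.5),
                                    sched_linear(6000, 10000, 1.5, 0.25),
                                    sched_hold(10000, T_ps, 0.25), T_ps = T_ps))
  g <- generate_trajectory(d, T_ps = T_ps, dt_ps = 10,
                           ion_schedules = list(ion), seed = 26)
  tr <- ion_residue_distance_trace(g$trajectory,
                                   select_atoms(g$trajectory$topology, "ion"),
                                   c("A", 20))
  rec <- detect_encounters(tr)
  # first sub-0.5-nm time of the schedule: 6000 + 4000 * (1.0 / 1.25) = 9200,
  # so the first sampled frame below the cutoff is 9210
  expect_equal(rec$FET, 9210)
  expect_equal(rec$FET, g$truth$ions$CA1$FET)
  expect_gte(rec$FET, 6000)
  expect_lte(rec$FET, 10000)
})

test_that("analysis on re-read files matches the in-memory pipeline", {
  d <- small_dimer()
  T_ps <- 1000
  # endpoints chosen so the 0.5 nm crossing falls between frame times: PDB
  # precision must not flip the crossing frame
  ion <- ion_schedule("CA1", c("A", 12),
                      make_schedule(sched_linear(0, 600, 1.17, 0.23),
                                    sched_hold(600, T_ps, 0.23), T_ps = T_ps))
  g <- generate_trajectory(d, T_ps = T_ps, dt_ps = 10,
                           ion_schedules = list(ion), seed = 27)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(g$trajectory, f)
  back <- read_trajectory(f, dt_ps = 10)
  for (tr in list(g$trajectory, back)) {
    rec <- detect_encounters(ion_residue_distance_trace(tr,
                                                        select_atoms(tr$topology, "ion"),
                                                        c("A", 12)))
    expect_equal(rec$FET, g$truth$ions$CA1$FET)
    expect_true(is.na(rec$SET))
  }
})

test_that("the bulk-ion preset hydrates to the published 15-18 waters", {
  b <- bulk_ion_preset(seed = 1, n_frames = 300)
  h <- hydration_count_series(b$trajectory,
                              select_atoms(b$trajectory$topology, "ion"),
                              b$truth$shell_cutoff_nm)
  m <- mean(h$series$values)
  expect_gte(m, 15)
  expect_lte(m, 18)
  expect_equal(m, b$truth$expected_count, tolerance = 0.05)
  # doubling the box at fixed density leaves the local count unchanged
  b2 <- bulk_ion_preset(seed = 1, n_frames = 100, box_nm = 2.52)
  h2 <- hydration_count_series(b2$trajectory,
                               select_atoms(b2$trajectory$topology, "ion"),
                               b2$truth$shell_cutoff_nm)
  expect_equal(mean(h2$series$values), m, tolerance = 0.1 * m)
})

test_that("full-pipeline recovery is exact at zero noise (small systems)", {
  for (seed in 1:2) {
    d <- small_dimer()
    T_ps <- 5000
    sch <- list(A = make_schedule(sched_hold(0, 2000, 70),
                                  sched_hold(2000, T_ps, 95), T_ps = T_ps),
                B = make_schedule(sched_hold(0, 3500, 65), T_ps = T_ps,
                                  sched_hold(3500, T_ps, 100)))
    # ramp endpoints keep the 0.5 and 0.3 nm crossings off the frame grid
    ion <- ion_schedule("CA1", c("A", 8),
                        make_schedule(sched_hold(0, 1000, 1.18),
                                      sched_linear(1000, 1500, 1.18, 0.21),
                                      sched_hold(1500, 2500, 0.21),
                                      sched_hold(2500, 2800, 0.9),
                                      sched_linear(2800, 3000, 0.9, 0.24),
                                      sched_hold(3000, T_ps, 0.24), T_ps = T_ps))
    g <- generate_trajectory(d, T_ps = T_ps, dt_ps = 10, angle_schedule = sch,
                             ion_schedules = list(ion), seed = seed)
    tr <- g$trajectory
    # angles per window
    for (ch in c("A", "B")) {
      w <- block_average_angles(interhelical_angle_series(tr, ch, d$spec$anchors),
                                c(1, 2.5, 5))
      truth_vals <- g$truth$angles[, ch]
      t_ns <- g$truth$times / 1000
      want <- vapply(list(c(0, 1), c(1, 2.5), c(2.5, 5)), function(win) {
        mean(truth_vals[t_ns > win[1] & t_ns <= win[2]])
      }, numeric(1))
      expect_equal(w$mean_deg, want, tolerance = 1e-3)
    }
    # encounters: FET and SET exactly as scripted
    rec <- detect_encounters(ion_residue_distance_trace(tr,
                                                        select_atoms(tr$topology, "ion"),
                                                        c("A", 8)))
    expect_equal(rec$FET, g$truth$ions$CA1$FET)
    expect_equal(rec$SET, g$truth$ions$CA1$SET)
    # occupancy
    occ <- binding_site_occupancy(tr, select_atoms(tr$topology, "ion"),
                                  data.frame(chain = "A", resid = 8L))
    expect_lt(abs(occ$occupancy - g$truth$ions$CA1$occupancy),
              1.5 / n_frames(tr))
    # cluster labels and spans
    m <- pairwise_rmsd_matrix(tr, select_atoms(tr$topology, "name CA"))
    cl <- gromos_cluster(m, 0.2)
    expect_equal(cl$labels, g$truth$cluster$labels)
    td <- temporal_distribution(cl)
    td_truth <- temporal_distribution(structure(list(labels = g$truth$cluster$labels),
                                                class = "cluster_result"),
                                      times = g$truth$times)
    expect_equal(td$spans, td_truth$spans)
  }
})

test_that("moderate coordinate noise keeps FET within the gap tolerance", {
  d <- small_dimer()
  T_ps <- 3000
  ok <- 0
  for (seed in 1:10) {
    ion <- ion_schedule("CA1", c("A", 20),
                        make_schedule(sched_hold(0, 2000, 1.5),
                                      sched_linear(2000, 2100, 1.5, 0.25),
                                      sched_hold(2100, T_ps, 0.25), T_ps = T_ps))
    g <- generate_trajectory(d, T_ps = T_ps, dt_ps = 10,
                             ion_schedules = list(ion), seed = seed,
                             noise_sigma_nm = 0.02)
    rec <- detect_encounters(ion_residue_distance_trace(g$trajectory,
                                                        select_atoms(g$trajectory$topology, "ion"),
                                                        c("A", 20)))
    if (!is.na(rec$FET) && abs(rec$FET - g$truth$ions$CA1$FET) <= 50) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("the generator validates its inputs", {
  d <- small_dimer()
  expect_error(make_schedule(sched_hold(0, 100, 70), T_ps = 200), "cover")
  expect_error(make_schedule(sched_hold(0, 100, 70),
                             sched_hold(150, 200, 80), T_ps = 200),
               "contiguous")
  expect_error(generate_trajectory(d, T_ps = 105, dt_ps = 10, seed = 1),
               "divide")
  bad_ion <- ion_schedule("CA1", c("A", 999),
                          make_schedule(sched_hold(0, 100, 1), T_ps = 100))
  expect_error(generate_trajectory(d, T_ps = 100, dt_ps = 10,
                                   ion_schedules = list(bad_ion), seed = 1),
               "target residue")
})
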