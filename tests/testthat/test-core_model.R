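pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     record = "ATOM") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          record, serial, name, resname, chain, resid, x, y, z)
}

test_that("PDB coordinates convert to nm and water/ion flags are set", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "ALA", "A", 1, 10, 0, 0),
               pdb_line(2, "OW", "SOL", "W", 2, 1, 2, 3, record = "HETATM"),
               pdb_line(3, "CA", "CA", "I", 3, 5, 5, 5, record = "HETATM"),
               "END"), f)
  s <- read_structure(f)
  expect_equal(s$coords[1, ], c(1.0, 0, 0))
  expect_false(s$topology$atoms$is_water[1])
  expect_true(s$topology$atoms$is_water[2])
  expect_true(s$topology$atoms$is_ion[3])
})

test_that("GRO coordinates stay in nm and the box lands in metadata", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("toy system, t= 250.0",
               "    2",
               "    1ALA      N    1   0.100   0.200   0.300",
               "    1ALA     CA    2   0.400   0.500   0.600",
               "   2.50000   2.50000   2.50000"), f)
  s <- read_structure(f)
  expect_equal(s$coords[2, ], c(0.4, 0.5, 0.6))
  expect_equal(s$topology$metadata$box_nm, c(2.5, 2.5, 2.5))
  tr <- read_trajectory(f)
  expect_equal(tr$times, 250)
})

test_that("multi-MODEL files: structure keeps MODEL 1, trajectory keeps all", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- unlist(lapply(1:5, function(m) {
    c(sprintf("MODEL     %4d", m),
      pdb_line(1, "CA", "ALA", "A", 1, m, 0, 0),
      pdb_line(2, "CA", "ALA", "A", 2, m + 3, 0, 0),
      "ENDMDL")
  }))
  writeLines(lines, f)
  # independent oracle: count ATOM records inside the first MODEL block
  raw <- readLines(f)
  first_block <- raw[(which(grepl("^MODEL", raw))[1] + 1):(which(grepl("^ENDMDL", raw))[1] - 1)]
  n_model1 <- sum(grepl("^ATOM", first_block))
  s <- read_structure(f)
  expect_equal(n_atoms(s$topology), n_model1)
  expect_equal(s$coords[1, 1], 0.1)
  tr <- read_trajectory(f, dt_ps = 10)
  expect_equal(n_frames(tr), 5)
  expect_equal(tr$times, seq(0, 40, by = 10))
  expect_equal(tr$coords[1, 1, ], (1:5) * 0.1)
})

test_that("malformed and mismatched PDB records fail with a location", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0),
               "ATOM      2  CA  ALA A   2      bad"), f)
  expect_error(read_structure(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0),
               pdb_line(2, "CA", "ALA", "A", 2, 2, 0, 0),
               "ENDMDL",
               "MODEL        2",
               pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0),
               "ENDMDL"), f2)
  expect_error(read_trajectory(f2), "frame 2")
  expect_error(read_structure("x.xtc"), "unsupported format")
})

test_that("write-then-read round trip preserves coordinates and order", {
  d <- small_dimer()
  g <- generate_trajectory(d, T_ps = 200, dt_ps = 10,
                           angle_schedule = make_schedule(sched_linear(0, 200, 60, 100),
                                                          T_ps = 200),
                           seed = 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(g$trajectory, f)
  back <- read_trajectory(f, dt_ps = 10)
  expect_equal(n_frames(back), n_frames(g$trajectory))
  expect_equal(back$topology$atoms$name, g$trajectory$topology$atoms$name)
  expect_lt(max(abs(back$coords - g$trajectory$coords)), 1e-3)
})

test_that("selection language resolves the documented idioms", {
  d <- build_toy_dimer(toy_dimer_spec())
  top <- d$topology
  expect_length(select_atoms(top, "chain A and resid 73 and name CA"), 1)
  expect_length(select_atoms(top, "backbone"), 2 * 100 * 4)
  # 10-residue single chain: 40 backbone atoms
  ten <- make_toy_top(unlist(lapply(1:10, function(r) {
    paste0("A/", r, "/ALA/", c("N", "CA", "C", "O"))
  })))
  expect_length(select_atoms(ten, "backbone"), 40)
  # 3-site waters
  g <- generate_trajectory(small_dimer(), T_ps = 20, dt_ps = 10, seed = 1,
                           waters = water_spec(50, box_nm = 4))
  expect_length(select_atoms(g$trajectory$topology, "water"), 150)
  expect_length(select_atoms(g$trajectory$topology, "water and name OW"), 50)
})

test_that("selection algebra equals brute-force set operations", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    atoms <- data.frame(serial = 1:n,
                        chain = sample(c("A", "B"), n, TRUE),
                        resid = sample(1:5, n, TRUE),
                        resname = sample(c("ALA", "GLU", "HOH"), n, TRUE),
                        name = NA, stringsAsFactors = FALSE)
    atoms$name <- paste0(sample(c("N", "CA", "C", "O"), n, TRUE), seq_len(n))
    atoms <- atoms[!duplicated(atoms[, c("chain", "resid", "name")]), ]
    atoms$serial <- seq_len(nrow(atoms))
    top <- topology(atoms)
    a <- which(top$atoms$chain == "A")
    b <- which(top$atoms$resid %in% c(2, 3))
    expect_equal(as.integer(select_atoms(top, "chain A or resid 2 3")),
                 sort(union(a, b)))
    expect_equal(as.integer(select_atoms(top, "chain A and resid 2 3")),
                 sort(intersect(a, b)))
    expect_equal(as.integer(select_atoms(top, "not (chain A and resid 2 3)")),
                 sort(setdiff(seq_len(nrow(top$atoms)), intersect(a, b))))
    expect_equal(as.integer(select_atoms(top, "water")),
                 which(top$atoms$resname == "HOH"))
  }
})

test_that("selection syntax errors report a position", {
  top <- small_dimer()$topology
  expect_error(select_atoms(top, "chain"), "position 1")
  expect_error(select_atoms(top, "resid abc"), "position")
  expect_error(select_atoms(top, "(chain A"), "parenthesis")
  expect_error(select_atoms(top, "chain A and or ion"), "syntax error")
  expect_length(select_atoms(top, "resname XXX"), 0)  # empty is allowed
})

test_that("series files round trip through xvg and csv", {
  s <- time_series(c(0, 10, 20), c(1.234567, 2.5, 3.75),
                   label = "toy", units = "nm")
  fx <- withr::local_tempfile(fileext = ".xvg")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_series(s, fx, "xvg")
  write_series(s, fc, "csv")
  expect_length(grep("^@", readLines(fx)), 3)
  expect_length(grep("^[0-9]", readLines(fx)), 3)
  back <- read_series(fx)
  expect_equal(back$values, s$values, tolerance = 1e-6)
  expect_equal(back$label, "toy")
  df <- utils::read.csv(fc)
  expect_type(df$value, "double")
  expect_equal(df$time_ps, s$times)
})
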