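test_that("selection table matches the pinned atom counts and triplet math", {
  tab <- selection_table()
  expect_setequal(names(tab), c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"))
  pinned <- c(ALA = 5, SER = 6, TYR = 7, ILE = 8, MET = 8, GLN = 9,
              ARG = 10, GLY = 4)
  for (res in names(pinned))
    expect_length(selected_atoms(res), pinned[[res]])
  expect_identical(selected_atoms("TYR"),
                   c("N", "CA", "CB", "CG", "OH", "C", "O"))
  # C(k,3) for every residue, via enumeration
  for (res in names(tab)) {
    k <- length(tab[[res]])
    expect_identical(nrow(enumerate_triplets(res)),
                     as.integer(choose(k, 3)), info = res)
  }
  expect_error(selected_atoms("XXX"), "XXX")
})

test_that("triplet enumeration is canonical and deterministic", {
  tr <- enumerate_triplets(c("A1", "A2", "A3", "A4"))
  expect_identical(nrow(tr), 4L)
  # vertex is always the middle atom in topological order
  expect_identical(tr$vertex, c("A2", "A2", "A3", "A3"))
  expect_identical(tr$atom_a, c("A1", "A1", "A1", "A2"))
  expect_identical(enumerate_triplets(c("X", "Y", "Z"))$vertex, "Y")
  expect_error(enumerate_triplets(c("A", "B")), "at least 3")
  # ANSR worked example triplets: O-C-N and O-CA-N appear among ALA's 10
  ids <- with(enumerate_triplets("ALA"), paste(atom_a, vertex, atom_b))
  expect_true(all(c("N C O", "N CA O") %in% ids))
})

test_that("three_atom_angle matches a law-of-cosines oracle and is invariant", {
  expect_equal(three_atom_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), pi / 2)
  # equilateral triangle
  eq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(three_atom_angle(eq[2, ], eq[1, ], eq[3, ]), pi / 3)
  # collinear with the vertex in the middle
  expect_equal(three_atom_angle(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)), pi)
  set.seed(42)
  for (i in 1:1000) {
    p <- matrix(stats::rnorm(9), 3L)
    ang <- three_atom_angle(p[1, ], p[2, ], p[3, ])
    expect_lt(abs(ang - law_of_cosines_angle(p[1, ], p[2, ], p[3, ])), 1e-9)
    # symmetry in the arms
    expect_identical(ang, three_atom_angle(p[3, ], p[2, ], p[1, ]))
    # rigid motion + uniform scaling invariance
    R <- random_rotation(); t <- stats::rnorm(3); s <- stats::runif(1, 0.5, 3)
    q <- s * p %*% t(R) + rep(t, each = 3L)
    expect_lt(abs(ang - three_atom_angle(q[1, ], q[2, ], q[3, ])), 1e-9)
  }
  expect_error(three_atom_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length arm")
})

test_that("measure_angle_series recovers a prescribed schedule and segments", {
  g <- gen_angle_series("ss", 40, seed = 3,
                        segments = cbind(c(0L, 20L), c(20L, 40L)))
  toy <- gen_toy_trajectory(2, dynamics = list("1" = g))
  ser <- measure_angle_series(toy$trajectory, 1, "N", "CA", "O")
  expect_lt(max(abs(ser$values - g$series$values)), 1e-6)
  expect_identical(unname(ser$segments[, 1]), c(0L, 20L))
  expect_identical(unname(ser$segments[, 2]), c(20L, 40L))
  expect_error(measure_angle_series(toy$trajectory, 1, "N", "CA", "ZZ"),
               "ZZ")
  # single-frame trajectory
  toy1 <- gen_toy_trajectory(1)
  s1 <- measure_angle_series(toy1$trajectory, 1, "N", "CA", "O")
  expect_length(s1$values, 1L)
  expect_equal(s1$values, 1.6, tolerance = 1e-9)
})

test_that("rmsd_series agrees with a Kabsch oracle and removes rigid motion", {
  set.seed(7)
  n_at <- 20L
  base <- stats::rnorm(3L * n_at)
  frames <- rbind(base, base, base, base)
  # frame 2: rigidly moved copy; frames 3-4: perturbed
  R <- random_rotation()
  frames[2, ] <- as.vector(t(matrix(base, ncol = 3L, byrow = TRUE) %*% t(R) +
                             rep(c(1, -2, 3), each = n_at)))
  frames[3, ] <- base + stats::rnorm(3L * n_at, sd = 0.3)
  frames[4, ] <- base + stats::rnorm(3L * n_at, sd = 0.8)
  atom <- data.frame(eleno = 1:n_at, elety = paste0("X", 1:n_at),
                     resid = "ALA", resno = 1L)
  ts <- trajectory_set(atom, frames)
  r <- rmsd_series(ts, 1L)
  expect_equal(r[1], 0)
  expect_lt(r[2], 1e-9)       # rigid copy superposes exactly
  expect_true(all(r >= 0))
  for (f in 3:4)
    expect_equal(r[f], kabsch_rmsd(frames[1, ], frames[f, ]),
                 tolerance = 1e-6)
  # one displaced atom among many identical ones: RMSD ~ d/sqrt(n)
  d <- 0.5
  shifted <- base; shifted[1] <- shifted[1] + d
  ts2 <- trajectory_set(atom, rbind(base, shifted))
  expect_equal(rmsd_series(ts2, 1L)[2], kabsch_rmsd(base, shifted),
               tolerance = 1e-6)
  expect_equal(rmsd_series(ts2, 1L)[2], d / sqrt(n_at), tolerance = 0.1)
  expect_error(rmsd_series(ts, 1L, atom_rows = integer()), "empty")
  expect_error(rmsd_series(ts, 1L, atom_rows = 99L), "absent")
})

test_that("pair_distance_series is plain Euclidean distance per frame", {
  atom <- data.frame(eleno = 1:2, elety = "CA", resid = "ALA", resno = 1:2)
  xyz <- rbind(c(0, 0, 0, 3, 4, 0), c(0, 0, 0, 0, 0, 0))
  ts <- trajectory_set(atom, xyz)
  expect_equal(pair_distance_series(ts, 1, 2), c(5, 0))
  expect_error(pair_distance_series(ts, 1, 3), "residue 3")
  # scripted separation recovered
  sep <- seq(1, 2, length.out = 11L)
  xyz2 <- cbind(0, 0, 0, sep, 0, 0)
  ts2 <- trajectory_set(atom, xyz2)
  expect_equal(pair_distance_series(ts2, 1, 2), sep)
})

test_that("trajectory round-trips through multi-model PDB files", {
  g <- gen_angle_series("ss", 30, seed = 9)
  toy <- gen_toy_trajectory(2, dynamics = list("2" = g))
  pdb_f <- tempfile(fileext = ".pdb")
  trj_f <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(toy$trajectory, pdb_f, trj_f)
  ts <- read_trajectories(pdb_f, c(trj_f, trj_f))
  expect_identical(n_frames(ts), 60L)
  expect_identical(unname(ts$segments[, 1]), c(0L, 30L))
  ser <- measure_angle_series(ts, 2, "N", "CA", "O")
  # PDB stores 3 decimals; angles survive to ~1e-3 rad
  expect_lt(max(abs(ser$values - rep(g$series$values, 2L))), 5e-3)
  expect_error(read_trajectories(pdb_f, "traj.xtc"), "XTC")
})
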