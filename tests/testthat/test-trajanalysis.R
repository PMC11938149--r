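# Trajectory I/O, contact frequencies, hydrogen bonds, RMSD series,
# clustering.

static_traj <- function(n_frames = 4, seed = 17, n_contacts = 3) {
  cx <- make_complex(10, 10, n_contacts, seed = seed)
  make_trajectory(cx, n_frames = n_frames, jitter_sigma = 0, seed = seed)
}

test_that("trajectories load from multi-model PDB and from directories", {
  tr <- static_traj(4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(nmrdock:::new_structure3d(tr$trajectory$topology,
                                            tr$trajectory$frames), f)
  t1 <- read_trajectory(f)
  expect_length(t1$frames, 4)

  dir <- withr::local_tempdir()
  for (k in 1:10) {
    s1 <- nmrdock:::new_structure3d(tr$trajectory$topology,
                                    list(tr$trajectory$frames[[1]] + k))
    write_structure(s1, file.path(dir, sprintf("frame_%02d.pdb", k)))
  }
  t2 <- read_trajectory(dir)
  expect_length(t2$frames, 10)
  # name order: frame k differs from frame 1 by the constant k - 1
  expect_equal(t2$frames[[7]] - t2$frames[[1]],
               matrix(6, nrow(t2$frames[[1]]), 3), tolerance = 1e-3,
               ignore_attr = TRUE)

  # mismatched frame is reported with its index
  s_short <- nmrdock:::new_structure3d(tr$trajectory$topology[-1, ],
                                       list(tr$trajectory$frames[[1]][-1, ]))
  write_structure(s_short, file.path(dir, "frame_11.pdb"))
  expect_error(read_trajectory(dir), "frame 11")
})

test_that("contact frequency: static 0/100, windowing, partial contacts", {
  tr <- static_traj(4)
  cm <- contact_frequency(tr$trajectory, "A", "B")
  expect_true(all(cm$frequency == 100))
  expect_equal(nrow(cm), 3)

  # escape at frame 4 of 5: contacts in frames 1-3 -> 60%
  cx <- make_complex(10, 10, 3, seed = 23)
  esc <- make_trajectory(cx, n_frames = 5, jitter_sigma = 0, escape_at = 4)
  cme <- contact_frequency(esc$trajectory, "A", "B")
  expect_true(all(cme$frequency == 100 * 3 / 5))
  # restricting the window to the contact frames gives 100
  cmw <- contact_frequency(esc$trajectory, "A", "B", window = c(1, 3))
  expect_true(all(cmw$frequency == 100))
  # window after escape: no contacts at all
  cma <- contact_frequency(esc$trajectory, "A", "B", window = c(4, 5))
  expect_equal(nrow(cma), 0)
  expect_error(contact_frequency(esc$trajectory, "A", "B", window = c(4, 9)),
               "out of range")
  expect_error(contact_frequency(esc$trajectory, "A", "B",
                                 window = integer(0)), "empty")
})

test_that("hydrogen bonds respect the distance and angle boundaries", {
  # comfortably inside
  expect_equal(nrow(hbonds(hb_toy_traj(2.9, 0), "A", "B")), 1)
  # boundary: exactly 3.0 A / 20 deg counts (<=)
  expect_equal(nrow(hbonds(hb_toy_traj(3.0, 0), "A", "B")), 1)
  hb20 <- hbonds(hb_toy_traj(2.9, 19.99), "A", "B")
  expect_equal(nrow(hb20), 1)
  expect_equal(hb20$mean_dev, 19.99, tolerance = 1e-3)
  # beyond either cutoff: rejected
  expect_equal(nrow(hbonds(hb_toy_traj(3.01, 0), "A", "B")), 0)
  expect_equal(nrow(hbonds(hb_toy_traj(2.9, 30), "A", "B")), 0)
  expect_equal(nrow(hbonds(hb_toy_traj(2.9, 20.5), "A", "B")), 0)
  # loosening cutoffs never removes a record (monotonicity)
  base <- hbonds(hb_toy_traj(2.9, 15), "A", "B")
  loose <- hbonds(hb_toy_traj(2.9, 15), "A", "B", d_cut = 3.5, ang_cut = 40)
  expect_true(all(paste(base$donor, base$acceptor) %in%
                    paste(loose$donor, loose$acceptor)))
  # hydrogens are mandatory
  s <- hb_toy_traj(2.9, 0)
  noh <- structure(list(topology = s$topology[1:2, ],
                        frames = list(s$frames[[1]][1:2, ]), dt = NA_real_),
                   class = "trajectory")
  expect_error(hbonds(noh, "A", "B"), "no hydrogens")
})

test_that("planted hydrogen bonds persist at the designed frequency", {
  cx <- make_complex(12, 12, 4, seed = 29)
  tr <- make_trajectory(cx, n_frames = 10, jitter_sigma = 0.02,
                        escape_at = 9, seed = 3)
  hb <- hbonds(tr$trajectory, "A", "B")
  planted <- cx$truth$hbonds
  expect_equal(sort(unique(hb$donor_res)), planted$donor_res)
  # 8 of 10 frames, one-frame granularity
  expect_true(all(abs(hb$frequency - 80) <= 10))
})

test_that("ligand RMSD series: zeros, analytic jump, rigid invariance", {
  tr <- static_traj(3)
  rs <- ligand_rmsd_series(tr$trajectory, "chain A and backbone",
                           "chain B and backbone")
  expect_equal(rs$series, rep(0, 3), tolerance = 1e-9)

  # translate the ligand by (3,4,0) in frame 2 only -> exactly 5
  traj <- tr$trajectory
  lig <- traj$topology$chain == "B"
  traj$frames[[2]][lig, ] <- sweep(traj$frames[[2]][lig, ], 2, c(3, 4, 0), "+")
  rs2 <- ligand_rmsd_series(traj, "chain A and backbone", "chain B and backbone")
  expect_equal(rs2$series[2], 5, tolerance = 1e-9)
  expect_equal(rs2$series[c(1, 3)], c(0, 0), tolerance = 1e-9)

  # excluded tails drop out of the selection (rmsd unchanged here since
  # the whole ligand moved rigidly); excluding everything is an error
  rs3 <- ligand_rmsd_series(traj, "chain A and backbone",
                            "chain B and backbone", exclude = "1-5")
  expect_equal(rs3$series[2], 5, tolerance = 1e-9)
  expect_error(ligand_rmsd_series(traj, "chain A and backbone",
                                  "chain B and backbone", exclude = "1-10"),
               "empty")

  # invariance under one global rigid transform of every frame
  set.seed(6)
  R <- random_rotation(); tvec <- rnorm(3, 0, 10)
  traj_r <- traj
  traj_r$frames <- lapply(traj$frames, function(m) apply_rigid(m, R, tvec))
  rs4 <- ligand_rmsd_series(traj_r, "chain A and backbone", "chain B and backbone")
  expect_equal(rs4$series, rs2$series, tolerance = 1e-8)
})

test_that("jittered trajectories match the closed-form RMSD expectation", {
  sig <- 0.05
  means <- vapply(1:12, function(sd) {
    tr <- make_trajectory(make_complex(17, 17, 6, seed = sd),
                          n_frames = 8, jitter_sigma = sig, seed = sd + 90)
    ligand_rmsd_series(tr$trajectory, "chain A and backbone",
                       "chain B and backbone")$mean * 8 / 7  # frame 1 is exact
  }, numeric(1))
  expect_lt(abs(mean(means) - sqrt(3) * sig) / (sqrt(3) * sig), 0.10)
})

test_that("clustering: sizes, representative membership, tie rules", {
  # 7 frames near pose 1, 3 near pose 2 (well separated)
  cx <- make_complex(8, 8, 3, seed = 41)
  base <- cx$structure$xyz[[1]]
  lig <- cx$structure$atoms$chain == "B"
  set.seed(10)
  frames <- lapply(1:10, function(k) {
    m <- base + matrix(rnorm(length(base), 0, 0.05), ncol = 3)
    if (k > 7) m[lig, ] <- sweep(m[lig, ], 2, c(0, 30, 0), "+")
    m
  })
  traj <- structure(list(topology = cx$structure$atoms, frames = frames,
                         dt = NA_real_), class = "trajectory")
  cl <- cluster_frames(traj, "chain B and backbone", threshold = 2,
                       align_sel = "chain A and backbone")
  expect_equal(sort(cl$sizes, decreasing = TRUE), c(7, 3))
  expect_lte(cl$representative, 7)          # from the populated cluster
  expect_equal(unname(cl$labels[cl$representative]),
               as.integer(names(which.max(table(cl$labels)))))

  # identical frames: one cluster, representative frame 1
  same <- structure(list(topology = cx$structure$atoms,
                         frames = rep(list(base), 5), dt = NA_real_),
                    class = "trajectory")
  cls <- cluster_frames(same, "all", threshold = 1)
  expect_equal(length(cls$sizes), 1)
  expect_equal(cls$representative, 1)

  # threshold below the minimum pairwise distance: all singletons,
  # representative is the lowest frame index
  cl1 <- cluster_frames(traj, "chain B and backbone", threshold = 1e-6,
                        align_sel = "chain A and backbone")
  expect_equal(length(cl1$sizes), 10)
  expect_equal(cl1$representative, 1)

  expect_error(cluster_frames(traj, "all", threshold = 0), "threshold")
  expect_error(cluster_frames(same, "chain Q", threshold = 1))

  # permuting the frame order permutes labels but not the partition
  perm <- c(4, 9, 1, 7, 10, 2, 5, 3, 8, 6)
  traj_p <- traj; traj_p$frames <- traj$frames[perm]
  clp <- cluster_frames(traj_p, "chain B and backbone", threshold = 2,
                        align_sel = "chain A and backbone")
  part <- function(lab) unname(lapply(split(seq_along(lab), lab), sort))
  got <- part(clp$labels[order(perm)])
  expect_setequal(lapply(part(cl$labels), paste, collapse = ","),
                  lapply(got, paste, collapse = ","))
})
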