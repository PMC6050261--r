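make_traj <- function(frames, times, natoms = 4, role = "ligand") {
  meta <- data.frame(name = paste0("C", seq_len(natoms)), element = "C",
                     resid = 1L, residue = "Lig", role = role)
  trajectory(frames, times, meta)
}

still_frames <- function(n, natoms = 4) {
  base <- matrix(seq_len(natoms * 3), ncol = 3) * 1.0
  replicate(n, base, simplify = FALSE)
}

test_that("the final-window view keeps frames with time > t_end - window", {
  tr <- make_traj(still_frames(101), times = 0:100)
  expect_equal(n_frames(traj_window(tr, 10)), 10)
  expect_equal(n_frames(traj_window(tr, 100)), 100)
  tr2 <- make_traj(still_frames(201), times = seq(0, 100, by = 0.5))
  expect_equal(n_frames(traj_window(tr2, 10)), 20)
  expect_error(traj_window(tr, 200), "shorter than")
})

test_that("trajectory construction validates its invariants", {
  expect_error(make_traj(still_frames(3), times = c(0, 2, 1)),
               "strictly increasing")
  frames <- still_frames(2)
  frames[[2]] <- frames[[2]][1:3, ]
  expect_error(make_traj(frames, times = 0:1), "same atom count")
})

test_that("rmsd series is zero for identical frames and has the translation closed form", {
  tr <- make_traj(still_frames(5), times = 0:4)
  rs <- rmsd_series(tr)
  expect_equal(nrow(rs), 5)
  expect_equal(rs$rmsd, rep(0, 5))
  # ligand translated by 2 A in every frame but the first, receptor fixed
  lig <- matrix(rnorm(12), ncol = 3)
  rec <- matrix(rnorm(30) * 5, ncol = 3)
  frames <- lapply(0:4, function(k) {
    rbind(if (k == 0) lig else sweep(lig, 2, c(2, 0, 0), `+`), rec)
  })
  meta <- data.frame(name = c(paste0("L", 1:4), paste0("R", 1:10)),
                     element = "C", resid = 1L, residue = "x",
                     role = rep(c("ligand", "receptor"), c(4, 10)))
  tr2 <- trajectory(frames, 0:4, meta)
  rs2 <- rmsd_series(tr2, fit = 5:14)
  expect_equal(rs2$rmsd, c(0, 2, 2, 2, 2), tolerance = 1e-9)
  expect_error(rmsd_series(tr, selection = integer(0)), "empty selection")
})

test_that("RMSF is zero for a static ligand and exact for a two-frame oscillation", {
  tr <- make_traj(still_frames(6), times = 0:5)
  expect_equal(ligand_rmsf(tr), 0)
  # one atom alternating x = +1 / -1, others static; selection = that atom
  f1 <- matrix(0, 4, 3); f2 <- matrix(0, 4, 3)
  f1[2, 1] <- 1; f2[2, 1] <- -1
  tr2 <- make_traj(list(f1, f2), times = 0:1)
  expect_equal(ligand_rmsf(tr2, selection = 2), 1.0)
  expect_error(ligand_rmsf(make_traj(still_frames(1), 0)), "at least two")
})

test_that("doubling the oscillation amplitude doubles the RMSF", {
  set.seed(1)
  base <- matrix(rnorm(12), ncol = 3)
  osc <- matrix(rnorm(12), ncol = 3)
  mk <- function(amp) {
    frames <- lapply(0:9, function(k) base + amp * (-1)^k * osc)
    make_traj(frames, times = 0:9)
  }
  expect_equal(ligand_rmsf(mk(2)), 2 * ligand_rmsf(mk(1)), tolerance = 1e-9)
})

test_that("RMSF is invariant under a global rigid translation with receptor superposition", {
  set.seed(2)
  lig <- matrix(rnorm(12), ncol = 3)
  rec <- matrix(rnorm(30) * 4, ncol = 3)
  jit <- lapply(1:8, function(k) matrix(rnorm(12, sd = 0.3), ncol = 3))
  frames_a <- lapply(1:8, function(k) rbind(lig + jit[[k]], rec))
  shift <- c(5, -3, 2)
  frames_b <- lapply(frames_a, function(fr) sweep(fr, 2, shift, `+`))
  meta <- data.frame(name = c(paste0("L", 1:4), paste0("R", 1:10)),
                     element = "C", resid = 1L, residue = "x",
                     role = rep(c("ligand", "receptor"), c(4, 10)))
  ta <- trajectory(frames_a, 1:8, meta)
  tb <- trajectory(frames_b, 1:8, meta)
  expect_equal(ligand_rmsf(ta, fit = 5:14), ligand_rmsf(tb, fit = 5:14),
               tolerance = 1e-9)
})

test_that("the stability filter partitions poses at the threshold", {
  rmsf <- c(p1 = 0.6, p2 = 0.8, p3 = 1.2)
  out <- stability_filter(rmsf, 1.0)
  expect_setequal(out$retained, c("p1", "p2"))
  expect_setequal(out$discarded, "p3")
  all_ok <- stability_filter(c(a = 0.1, b = 0.9), 1.0)
  expect_length(all_ok$discarded, 0)
  expect_equal(out$report$verdict, c("retained", "retained", "discarded"))
})

test_that("the filter recovers planted stable/drifting labels", {
  pp <- make_pocket_and_poses(seed = 21, n_decoy = 9, displacement = 2.5)
  stable <- rep(c(TRUE, FALSE), c(4, 6))
  trs <- make_trajectories(pp$poses, stable, seed = 22)
  rmsf <- vapply(trs, function(tr) ligand_rmsf(traj_window(tr, 10)),
                 numeric(1))
  out <- stability_filter(rmsf, 1.0)
  ids <- vapply(pp$poses, `[[`, character(1), "id")
  expect_setequal(out$retained, ids[stable])
  expect_setequal(out$discarded, ids[!stable])
})
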