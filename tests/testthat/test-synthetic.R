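test_that("generators are pure functions of seed and parameters", {
  a <- make_pocket_and_poses(seed = 51, n_decoy = 5)
  b <- make_pocket_and_poses(seed = 51, n_decoy = 5)
  expect_identical(a, b)
  c <- make_pocket_and_poses(seed = 52, n_decoy = 5)
  expect_false(identical(coords(a$poses[[2]]$structure),
                         coords(c$poses[[2]]$structure)))
  t1 <- make_titration(1, 100, cv = 0.1, seed = 3)
  t2 <- make_titration(1, 100, cv = 0.1, seed = 3)
  expect_identical(t1, t2)
})

test_that("decoys are displaced by at least the requested amount", {
  pp <- make_pocket_and_poses(seed = 53, n_decoy = 20, displacement = 2.5)
  d <- vapply(pp$poses[-1], function(x) pose_rmsd(pp$planted, x),
              numeric(1))
  expect_true(all(d >= 2.5))
  solo <- make_pocket_and_poses(seed = 54, n_decoy = 0)
  expect_length(solo$poses, 1)
  expect_error(make_pocket_and_poses(seed = 55, displacement = 0),
               "displacement")
})

test_that("trajectory generator honours the planted noise model", {
  pp <- make_pocket_and_poses(seed = 56, n_decoy = 1)
  # sigma = 0, no drift -> RMSF exactly 0
  tr0 <- make_trajectories(pp$poses, c(TRUE, TRUE), sigma = 1e-12,
                           seed = 57)
  expect_lt(ligand_rmsf(tr0[[1]]), 1e-9)
  # mean RMSF tracks sigma * sqrt(3); doubling sigma doubles RMSF
  m_rmsf <- function(sigma) {
    vals <- vapply(1:20, function(s) {
      tr <- make_trajectories(pp$poses[1], TRUE, sigma = sigma,
                              length_ns = 20, seed = 100 + s)
      ligand_rmsf(traj_window(tr[[1]], 10))
    }, numeric(1))
    mean(vals)
  }
  r1 <- m_rmsf(0.231)
  r2 <- m_rmsf(0.462)
  expect_equal(r1, 0.231 * sqrt(3), tolerance = 0.1)
  expect_equal(r2 / r1, 2, tolerance = 0.1)
})

test_that("the titration ladder has 16 geometric points from 400 to 0.00256 nM", {
  lad <- titration_ladder()
  expect_length(lad, 16)
  expect_equal(lad[1], 400)
  expect_equal(lad[16], 0.00256)
  expect_equal(sd(diff(log(lad))), 0, tolerance = 1e-12)
})

test_that("noiseless titrations lie exactly on the one-site curve", {
  s <- make_titration(0.13, 3000, cv = 0, seed = 58)
  mu <- 3000 * s$data$conc_nM / (0.13 + s$data$conc_nM)
  expect_equal(s$data$rfu, mu, tolerance = 1e-12)
  expect_error(make_titration(1, 100, cv = -0.1, seed = 1), "CV")
})

test_that("the planted wild-type KD is recovered from noisy titrations", {
  errs <- vapply(1:50, function(s) {
    f <- fit_one_site(make_titration(0.13, 3000, cv = 0.1, seed = s))
    abs(f$fit$kd - 0.13) / 0.13
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("alanine panels plant fold changes and undetectable mutants", {
  pan <- make_alanine_panel(
    wt_kd = c(G5 = 0.13),
    mutant_effects = list(A = 1.0, B = "undetectable",
                          C = "undetectable", D = 1000),
    cv = 0.05, seed = 59)
  wt <- lapply(pan$wt, fit_one_site)
  mu <- lapply(pan$mutants, function(m) lapply(m, fit_one_site))
  tab <- fold_change_table(wt, mu)
  expect_setequal(tab$mutant[tab$class == "undetectable"], c("B", "C"))
  expect_equal(tab$ddG[tab$mutant == "A"], 0, tolerance = 0.15)
  expect_equal(tab$ddG[tab$mutant == "D"],
               1.987e-3 * 298.15 * log(1000), tolerance = 0.3)
})

test_that("synthetic glycomes carry their planted core/extension labels", {
  coret <- parse_glycan("Neu5Ac(a2-6)GalNAc(a1-")
  gl <- make_glycome(coret, n_with_core = 5, n_without = 3, n_bare = 1,
                     seed = 60)
  expect_equal(nrow(gl$truth), 9)
  for (k in seq_len(nrow(gl$truth))) {
    has <- length(match_core(gl$glycome[[gl$truth$glycan_id[k]]],
                             coret)) > 0
    expect_equal(has, gl$truth$has_core[k])
  }
  # n_without = 0 -> every entry contains the core
  all_core <- make_glycome(coret, n_with_core = 4, n_without = 0, seed = 61)
  hits <- vapply(all_core$glycome,
                 function(g) length(match_core(g, coret)) > 0, logical(1))
  expect_true(all(hits))
})

test_that("ground truth serializes to JSON", {
  path <- tempfile(fileext = ".json")
  write_ground_truth(list(seed = 1, planted_id = "X"), path)
  back <- jsonlite::read_json(path)
  expect_equal(back$planted_id, "X")
})
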