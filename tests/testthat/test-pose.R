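test_that("campaign bookkeeping reproduces the funnel counts in closed form", {
  tab <- expected_counts()
  cnt <- function(stage) tab$count[tab$stage == stage]
  expect_equal(cnt("rotamers"), 6)
  expect_equal(cnt("rigid_generated_per_model"), 6 * 25 * 20)
  expect_equal(cnt("rigid_generated_per_model"), 3000)
  expect_equal(cnt("generated_per_model"), 6000)
  expect_equal(cnt("total_screened"), 12000)
  expect_equal(cnt("rigid_retained_per_model"), 120)
  expect_equal(cnt("flexible_retained_per_model"), 50)
  expect_equal(cnt("retained_total"), 340)
})

test_that("degenerate campaigns count correctly and invalid ones error", {
  one <- campaign_config(models = 1,
                         rigid = list(rotamers = 1, snapshots = 1,
                                      poses_per_run = 1, keep_clusters = 1),
                         flexible = list(rotamers = 1, snapshots = 1,
                                         poses_per_run = 1, top_n = 1))
  tab <- expected_counts(one)
  expect_equal(tab$count[tab$stage == "rigid_generated_per_model"], 1)
  bad <- campaign_config(models = 0)
  expect_error(expected_counts(bad), "positive integers")
})

test_that("pose RMSD has the rigid-translation closed form and is symmetric", {
  poses <- random_pose_set(2, seed = 1)
  a <- poses[[1]]
  b <- a
  b$structure <- transform_structure(a$structure, t = c(3, 0, 0))
  expect_equal(pose_rmsd(a, b), 3.0, tolerance = 1e-12)
  expect_equal(pose_rmsd(a, a), 0.0)
  set.seed(2)
  for (k in 1:5) {
    p <- random_pose_set(2, seed = k)
    expect_equal(pose_rmsd(p[[1]], p[[2]]), pose_rmsd(p[[2]], p[[1]]))
  }
})

test_that("a missing selection atom is reported by name", {
  poses <- random_pose_set(2, seed = 3)
  expect_error(pose_rmsd(poses[[1]], poses[[2]], selection = c("1 C1", "1 ZZ")),
               "missing selection atoms: 1 ZZ")
})

test_that("clustering chains poses through intermediate neighbours", {
  base <- random_pose_set(1, seed = 4)[[1]]
  shift <- function(p, dx, id, score) {
    p$structure <- transform_structure(p$structure, t = c(dx, 0, 0))
    p$id <- id
    p$score <- score
    p
  }
  a <- shift(base, 0, "a", -7.1)
  b <- shift(base, 1.0, "b", -8.0)   # a-b 1.0, b-c 1.5, a-c 2.5
  c <- shift(base, 2.5, "c", -6.5)
  cl <- cluster_poses(list(a, b, c), eps = 2)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, c("a", "b", "c"))
  expect_equal(cl[[1]]$best_id, "b")
  expect_equal(cl[[1]]$best_score, -8.0)
})

test_that("well-separated poses form singletons and populations sum to n", {
  poses <- random_pose_set(50, seed = 5, spread = 30)
  cl <- cluster_poses(poses, eps = 2)
  pops <- vapply(cl, `[[`, numeric(1), "population")
  expect_equal(sum(pops), 50)
  expect_true(all(pops == 1))
  expect_error(cluster_poses(list(), 2), "no poses")
  expect_error(cluster_poses(poses, 2, minpoints = 4), "minpoints = 1")
})

test_that("clustering equals the brute-force single-linkage partition", {
  for (seed in 1:6) {
    poses <- random_pose_set(40, seed = seed, spread = 2.5)
    cl <- cluster_poses(poses, eps = 2)
    n <- length(poses)
    D <- matrix(0, n, n)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- pose_rmsd(poses[[i]], poses[[j]])
      }
    }
    oracle <- brute_components(D, 2)
    ids <- vapply(poses, function(p) p$id, character(1))
    got <- canonical_partition(lapply(cl, `[[`, "members"))
    want <- canonical_partition(split(ids, oracle))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("clustering is invariant to input order", {
  poses <- random_pose_set(30, seed = 7, spread = 2.5)
  cl1 <- cluster_poses(poses, eps = 2)
  set.seed(8)
  cl2 <- cluster_poses(sample(poses), eps = 2)
  expect_equal(lapply(cl1, `[[`, "members"), lapply(cl2, `[[`, "members"))
  expect_equal(vapply(cl1, `[[`, character(1), "best_id"),
               vapply(cl2, `[[`, character(1), "best_id"))
})

test_that("representatives are the best-scoring cluster members, truncated", {
  poses <- random_pose_set(12, seed = 9, spread = 40)
  cl <- cluster_poses(poses, eps = 2)
  reps <- select_representatives(cl, poses, keep_clusters = 20)
  expect_length(reps, 12)  # fewer clusters than requested -> all returned
  reps5 <- select_representatives(cl, poses, keep_clusters = 5)
  expect_length(reps5, 5)
  # a multi-member cluster yields its minimum-score member
  tight <- random_pose_set(3, seed = 10, spread = 0.1)
  tight[[1]]$score <- -7.1; tight[[2]]$score <- -8.0; tight[[3]]$score <- -6.5
  cl2 <- cluster_poses(tight, eps = 2)
  rep <- select_representatives(cl2, tight, 1)[[1]]
  expect_equal(rep$score, -8.0)
})

test_that("top-N selection sorts by score with stable id tie-break", {
  poses <- random_pose_set(3, seed = 11)
  poses[[1]]$score <- -5; poses[[2]]$score <- -9; poses[[3]]$score <- -7
  top <- select_top_n(poses, 2)
  expect_equal(vapply(top, `[[`, numeric(1), "score"), c(-9, -7))
  expect_length(select_top_n(poses, 10), 3)
  expect_error(select_top_n(poses, 0), "positive")
})
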