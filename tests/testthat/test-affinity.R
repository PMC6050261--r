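test_that("noiseless titrations recover the planted KD essentially exactly", {
  s <- fit_one_site(make_titration(10, 1000, cv = 0, seed = 1))
  expect_false(s$fit$undetectable)
  expect_equal(s$fit$kd, 10, tolerance = 1e-3 / 10)  # within 0.01 nM
  expect_equal(s$fit$bmax, 1000, tolerance = 1e-6)
  # on the fitted curve, B at C = KD equals Bmax / 2
  expect_equal(s$fit$bmax * s$fit$kd / (s$fit$kd + s$fit$kd),
               s$fit$bmax / 2)
})

test_that("fitting validates its inputs", {
  short <- titration_series("g", "g", conc_nM = c(1, 2, 3),
                            rfu = c(10, 20, 30))
  expect_error(fit_one_site(short), "at least 4 distinct")
  neg <- titration_series("g", "g", conc_nM = c(1, 2, 4, 8, 16),
                          rfu = c(-5, 20, 30, 40, 45))
  expect_warning(fit_one_site(neg), "clipped")
})

test_that("flat near-zero signal is flagged undetectable with no KD", {
  set.seed(9)
  conc <- rep(titration_ladder(), each = 4)
  flat <- titration_series("g", "g", conc,
                           rlnorm(length(conc), log(2), 0.8))
  f <- fit_one_site(flat)
  expect_true(f$fit$undetectable)
  expect_true(is.na(f$fit$kd))
})

test_that("relative RFU ranking follows the hand-ranked example", {
  df <- expand.grid(glycan_id = c("A", "B"),
                    concentration = c(30, 12, 6, 2.4), rep = 1:4)
  df$rfu <- ifelse(df$glycan_id == "A", 100, 50)
  out <- relative_rfu_rank(df)
  expect_equal(out$mean_rank[out$glycan_id == "A"], 1)
  expect_equal(out$mean_rank[out$glycan_id == "B"], 2)
  expect_equal(out$sem_rank, c(0, 0))
  expect_equal(out$mean_pct, c(100, 50))
  # four concentrations -> SEM across 4 values reported
  expect_equal(ncol(out), 5)
})

test_that("relative ranking is invariant to per-concentration scaling", {
  set.seed(4)
  df <- expand.grid(glycan_id = letters[1:5],
                    concentration = c(30, 12, 6, 2.4), rep = 1:2)
  df$rfu <- runif(nrow(df), 10, 1000)
  scaled <- df
  for (cc in unique(df$concentration)) {
    scaled$rfu[scaled$concentration == cc] <-
      scaled$rfu[scaled$concentration == cc] * runif(1, 0.1, 10)
  }
  expect_equal(relative_rfu_rank(df)$mean_rank,
               relative_rfu_rank(scaled)$mean_rank)
})

test_that("ranking drops all-zero concentrations with a warning", {
  df <- expand.grid(glycan_id = c("A", "B"), concentration = c(30, 12),
                    rep = 1:2)
  df$rfu <- ifelse(df$concentration == 12, 0,
                   ifelse(df$glycan_id == "A", 100, 50))
  expect_warning(out <- relative_rfu_rank(df), "all-zero")
  expect_equal(out$mean_rank, c(1, 2))
})

test_that("ddG evaluates RT ln(KD ratio) and is antisymmetric", {
  expect_equal(ddG(10, 10), 0)
  # worked example on the printed wild-type/variant KDs: independent
  # log-ratio oracle
  oracle <- 1.987e-3 * 298.15 * (log(132) - log(0.13))
  expect_equal(ddG(132, 0.13), oracle, tolerance = 1e-12)
  expect_equal(round(ddG(132, 0.13), 2), 4.10)
  expect_equal(ddG(3, 7), -ddG(7, 3))
  expect_error(ddG(-1, 5), "positive")
})

test_that("ddG obeys the chain rule", {
  set.seed(5)
  for (k in 1:20) {
    kds <- runif(3, 0.01, 500)
    expect_equal(ddG(kds[1], kds[3]),
                 ddG(kds[1], kds[2]) + ddG(kds[2], kds[3]),
                 tolerance = 1e-9)
  }
})

test_that("mutant classification follows the sign convention", {
  expect_equal(classify_mutant(3.0), "destabilizing")
  expect_equal(classify_mutant(0.0), "minimal")
  expect_equal(classify_mutant(-1.2), "stabilizing")
  expect_equal(classify_mutant(NA), "undetectable")
  expect_equal(classify_mutant(c(0.4, -0.5)), c("minimal", "minimal"))
})

test_that("fold-change tables propagate undetectable fits and find the key residue", {
  pan <- make_alanine_panel(
    wt_kd = c(G5 = 0.13, G27 = 1.0),
    mutant_effects = list(S31A = 1.1, W52A = "undetectable", W91A = 500),
    cv = 0.05, seed = 6)
  wt <- lapply(pan$wt, fit_one_site)
  mu <- lapply(pan$mutants, function(m) lapply(m, fit_one_site))
  tab <- fold_change_table(wt, mu)
  expect_equal(tab$class[tab$mutant == "W52A"],
               rep("undetectable", 2))
  expect_true(all(is.na(tab$ddG[tab$mutant == "W52A"])))
  # the planted 500x key residue has the largest measurable ddG
  expect_equal(tab$mutant[which.max(tab$ddG)], "W91A")
  expect_equal(max(tab$ddG, na.rm = TRUE), 1.987e-3 * 298.15 * log(500),
               tolerance = 0.3)
  m <- ddG_matrix(tab)
  expect_equal(dim(m), c(3, 2))
})

test_that("a 10x fold change maps to RT ln 10 and identity maps to zero", {
  mk <- function(kd) {
    s <- fit_one_site(make_titration(kd, 2000, cv = 0, seed = 7))
    s
  }
  wt <- list(G = mk(2))
  tab <- fold_change_table(wt, list(M10 = list(G = mk(20)),
                                    Msame = list(G = mk(2))))
  expect_equal(tab$fold_change[tab$mutant == "M10"], 10, tolerance = 1e-4)
  expect_equal(tab$ddG[tab$mutant == "M10"], 1.987e-3 * 298.15 * log(10),
               tolerance = 1e-4)
  expect_equal(tab$ddG[tab$mutant == "Msame"], 0, tolerance = 1e-6)
  expect_warning(
    fold_change_table(wt, list(M = list(G = mk(2), H = mk(3)))),
    "absent from the wild-type")
})
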