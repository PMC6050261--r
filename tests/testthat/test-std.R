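test_that("normalization scales to percent of maximum and is idempotent", {
  ds <- normalize_std(c(H1 = 2.0, H2 = 1.0))
  expect_equal(ds$data$intensity, c(100, 50))
  expect_equal(normalize_std(c(H1 = 5))$data$intensity, 100)
  again <- normalize_std(stats::setNames(ds$data$intensity, ds$data$label))
  expect_equal(again$data$intensity, ds$data$intensity)
  expect_identical(ds$data$label, c("H1", "H2"))  # order preserved
  expect_error(normalize_std(c(a = 0, b = 0)), "no reference signal")
  expect_error(normalize_std(c(a = 1, a = 2)), "unique")
})

test_that("the proximity model gives the r^-6 closed form", {
  sys <- two_proton_system(dA = 3, dB = 6)
  pred <- predict_std(sys$receptor, sys$ligand, cutoff = 8)
  ia <- pred$data$intensity[pred$data$label == "Lig1.HA"]
  ib <- pred$data$intensity[pred$data$label == "Lig1.HB"]
  expect_equal(ia, 100)
  expect_equal(ib, 100 / 2^6, tolerance = 1e-12)  # (6/3)^-6 ratio = 1/64
  # raw integrals carry the same 64:1 ratio
  ra <- pred$data$integral[pred$data$label == "Lig1.HA"]
  rb <- pred$data$integral[pred$data$label == "Lig1.HB"]
  expect_equal(ra / rb, 64, tolerance = 1e-12)
})

test_that("protons with no receptor neighbour within the cutoff score zero", {
  sys <- two_proton_system(dA = 3, dB = 20)
  pred <- predict_std(sys$receptor, sys$ligand, cutoff = 8)
  expect_equal(pred$data$intensity[pred$data$label == "Lig1.HB"], 0)
  noH <- structure3d(data.frame(name = "O1", element = "O", resid = 1L,
                                residue = "Lig", x = 0, y = 0, z = 0))
  expect_error(predict_std(sys$receptor, noH), "no protons")
})

test_that("a pose entirely out of contact predicts all-zero intensities", {
  sys <- two_proton_system(dA = 50, dB = 60)
  pred <- predict_std(sys$receptor, sys$ligand, cutoff = 8)
  expect_true(all(pred$data$intensity == 0))
  ref <- normalize_std(c(`Lig1.HA` = 100, `Lig1.HB` = 50, `Lig1.HX` = 10))
  # agreement with any experimental dataset is undefined, not an error
  sys3 <- two_proton_system(dA = 50, dB = 60)
  sys3$ligand$atoms <- rbind(sys3$ligand$atoms,
                             data.frame(name = "HX", element = "H",
                                        resid = 1L, residue = "Lig",
                                        x = 70, y = 0, z = 0))
  out <- std_agreement(predict_std(sys3$receptor, sys3$ligand), ref)
  expect_true(out$undefined)
})

test_that("predictions are invariant under rigid transformation of the complex", {
  pp <- make_pocket_and_poses(seed = 31, n_decoy = 0)
  p1 <- predict_std(pp$receptor, pp$planted$structure)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  rec2 <- transform_structure(pp$receptor, R, c(5, -2, 7))
  lig2 <- transform_structure(pp$planted$structure, R, c(5, -2, 7))
  p2 <- predict_std(rec2, lig2)
  expect_equal(p1$data$intensity, p2$data$intensity, tolerance = 1e-6)
})

test_that("buried methyl protons carry the strongest predicted signal", {
  # the synthetic pocket hugs the acetamido/glycerol face of the antigen,
  # mirroring the dominant acetamido STD signal of the real complex
  pp <- make_pocket_and_poses(seed = 32, n_decoy = 0)
  pred <- predict_std(pp$receptor, pp$planted$structure)
  top <- pred$data$label[which.max(pred$data$intensity)]
  contact_faces <- c("H9", "HMN5", "H8", "H3")
  expect_true(any(vapply(contact_faces, grepl, logical(1), x = top)))
})

test_that("agreement scoring matches the closed-form Pearson cases", {
  e <- normalize_std(c(a = 100, b = 50, c = 0))
  expect_equal(std_agreement(e, e)$score, 1.0)
  rev <- normalize_std(c(a = 0, b = 50, c = 100))
  expect_equal(std_agreement(rev, e)$score, -1.0, tolerance = 1e-12)
  # label-keyed matching: permuting label order changes nothing
  perm <- normalize_std(c(c = 0, a = 100, b = 50))
  expect_equal(std_agreement(perm, e)$score, 1.0)
})

test_that("agreement is scale-invariant in the experimental integrals", {
  set.seed(3)
  vals <- runif(6, 1, 10)
  names(vals) <- paste0("h", 1:6)
  pred <- normalize_std(runif(6, 1, 10) |> stats::setNames(paste0("h", 1:6)))
  s1 <- std_agreement(pred, normalize_std(vals))$score
  s2 <- std_agreement(pred, normalize_std(vals * 37.5))$score
  expect_equal(s1, s2)
})

test_that("agreement errors and flags degenerate inputs", {
  a <- normalize_std(c(x = 1, y = 2))
  expect_error(std_agreement(a, a), "at least 3 shared")
  flat <- normalize_std(c(a = 5, b = 5, c = 5))
  ref <- normalize_std(c(a = 100, b = 50, c = 1))
  out <- std_agreement(flat, ref)
  expect_true(out$undefined)
  expect_true(is.na(out$score))
})

test_that("the final ranking filters on thresholds and orders by agreement", {
  cards <- data.frame(pose_id = c("A", "B", "C", "D"),
                      rescore = c(-9.5, -7.9, -8.1, -6.0),
                      agreement = c(0.74, 0.68, 0.63, 0.95),
                      rmsf = c(0.6, 0.8, 0.9, 1.8))
  out <- final_ranking(cards, rmsf_max = 1.0)
  expect_equal(out$top, "A")  # D excluded by RMSF despite best agreement
  expect_equal(out$selection$pose_id, c("A", "B", "C"))
  single <- final_ranking(cards[2, ], rmsf_max = 1.0)
  expect_equal(single$top, "B")
  none <- final_ranking(cards, rmsf_max = 0.0)
  expect_true(none$empty)
  expect_true(is.na(none$top))
})

test_that("ranking by agreement recovers the planted pose against displaced decoys", {
  pp <- make_pocket_and_poses(seed = 33, n_decoy = 8, displacement = 2)
  expref <- make_std_reference(pp$receptor, pp$planted$structure,
                               cv = 0.1, seed = 34)
  ag <- vapply(pp$poses, function(p) {
    std_agreement(predict_std(pp$receptor, p$structure), expref)$score
  }, numeric(1))
  names(ag) <- vapply(pp$poses, `[[`, character(1), "id")
  expect_equal(names(which.max(ag)), pp$truth$planted_id)
})
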