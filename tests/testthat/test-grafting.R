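core <- parse_glycan("Neu5Ac(a2-6)GalNAc(a1-")

test_that("a glycan equal to the core yields one extension-free match", {
  m <- match_core(core, core)
  expect_length(m, 1)
  expect_equal(nrow(m[[1]]$extensions), 0)
  expect_equal(unname(m[[1]]$mapping[as.character(core$root)]), core$root)
})

test_that("branch points at Neu5Ac O8 and GalNAc O3 are enumerated as extensions", {
  g <- parse_glycan("Neu5Ac(a2-8)Neu5Ac(a2-6)[Gal(b1-3)]GalNAc(a1-")
  m <- match_core(g, core)
  expect_length(m, 1)
  expect_setequal(m[[1]]$extensions$label,
                  c("Neu5Ac#1:O8", "GalNAc#2:O3"))
})

test_that("residue identity is strict: a Neu5Gc terminal never matches a Neu5Ac core", {
  g <- parse_glycan("Neu5Gc(a2-6)GalNAc(a1-")
  expect_length(match_core(g, core), 0)
})

test_that("match_core agrees with the brute-force embedding enumerator", {
  glycans <- list(
    parse_glycan("Neu5Ac(a2-6)GalNAc(a1-"),
    parse_glycan("Neu5Gc(a2-6)GalNAc(a1-"),
    parse_glycan("Neu5Ac(a2-8)Neu5Ac(a2-6)[Gal(b1-3)]GalNAc(a1-"),
    parse_glycan("Gal(b1-3)GalNAc(a1-"),
    parse_glycan("Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-"),
    parse_glycan("Neu5Ac(a2-6)GalNAc(a1-3)Gal(b1-"),
    parse_glycan("Neu5Ac(a2-3)Gal(b1-"))
  cores <- list(core, parse_glycan("Gal(b1-"),
                parse_glycan("Neu5Ac(a2-"))
  for (g in glycans) {
    for (co in cores) {
      got <- lapply(match_core(g, co), `[[`, "mapping")
      want <- brute_embeddings(g, co)
      expect_equal(length(got), length(want))
      if (length(got) > 0) {
        norm <- function(ms) {
          ms <- lapply(ms, function(m) m[order(as.integer(names(m)))])
          ms[order(vapply(ms, `[[`, numeric(1), 1))]
        }
        expect_equal(norm(got), norm(want), ignore_attr = TRUE)
      }
    }
  }
})

test_that("a ligand in open space has no occluded positions", {
  pp <- make_pocket_and_poses(seed = 41, n_decoy = 0)
  empty_receptor <- structure3d(data.frame(
    name = "C1", element = "C", resid = 1L, residue = "pocket",
    x = 999, y = 999, z = 999))
  om <- occlusion_map(empty_receptor, pp$planted$structure, pp$core_tree)
  expect_length(om, 0)
  expect_gt(length(attr(om, "all_positions")), 0)
})

test_that("the synthetic pocket occludes exactly the planted positions", {
  pp <- make_pocket_and_poses(seed = 42, n_decoy = 0)
  om <- occlusion_map(pp$receptor, pp$planted$structure, pp$core_tree)
  expect_setequal(as.character(om), pp$occluded)
  # glycerol arm and GalNAc O3/O4 blocked; aglycon direction open
  expect_true("Neu5Ac#1:O8" %in% om)
  expect_true("GalNAc#2:O3" %in% om)
  expect_false("GalNAc#2:O1" %in% om)
})

test_that("grafting the bare core onto a clash-free pose fits with zero clash", {
  pp <- make_pocket_and_poses(seed = 43, n_decoy = 0)
  m <- match_core(core, core)[[1]]
  v <- graft(m, core, pp$core_tree, pp$planted$structure, pp$receptor)
  expect_true(v$fits)
  expect_equal(v$clash_score, 0)
})

test_that("extensions at occluded positions never fit; open positions do", {
  pp <- make_pocket_and_poses(seed = 44, n_decoy = 0)
  blocked <- parse_glycan("Neu5Ac(a2-8)Neu5Ac(a2-6)GalNAc(a1-")
  mb <- match_core(blocked, core)[[1]]
  vb <- graft(mb, blocked, pp$core_tree, pp$planted$structure, pp$receptor)
  expect_false(vb$fits)
  expect_gt(vb$clash_score, 0)
  expect_true("Neu5Ac#1:O8" %in% vb$blocking)
  # reducing-end continuation grows into open solvent
  open <- parse_glycan("Neu5Ac(a2-6)GalNAc(a1-3)Gal(b1-")
  mo <- match_core(open, core)[[1]]
  vo <- graft(mo, open, pp$core_tree, pp$planted$structure, pp$receptor)
  expect_true(vo$fits)
})

test_that("adding an extension never decreases the minimal clash score", {
  pp <- make_pocket_and_poses(seed = 45, n_decoy = 0)
  bare <- graft(match_core(core, core)[[1]], core, pp$core_tree,
                pp$planted$structure, pp$receptor)
  ext <- parse_glycan("Gal(b1-3)GalNAc(a1-")
  stn_ext <- parse_glycan("Neu5Ac(a2-6)[Gal(b1-3)]GalNAc(a1-")
  ve <- graft(match_core(stn_ext, core)[[1]], stn_ext, pp$core_tree,
              pp$planted$structure, pp$receptor)
  expect_gte(ve$clash_score, bare$clash_score)
})

test_that("graft verdicts are invariant under rigid motion of the whole complex", {
  pp <- make_pocket_and_poses(seed = 46, n_decoy = 0)
  g <- parse_glycan("Neu5Ac(a2-8)Neu5Ac(a2-6)GalNAc(a1-")
  m <- match_core(g, core)[[1]]
  v1 <- graft(m, g, pp$core_tree, pp$planted$structure, pp$receptor)
  R <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3)
  t <- c(-4, 9, 2)
  v2 <- graft(m, g, pp$core_tree,
              transform_structure(pp$planted$structure, R, t),
              transform_structure(pp$receptor, R, t))
  expect_equal(v1$fits, v2$fits)
  expect_equal(v1$clash_score, v2$clash_score, tolerance = 1e-6)
})

test_that("the glycome screen reports matched/fitting/blocked counts", {
  pp <- make_pocket_and_poses(seed = 47, n_decoy = 0)
  # empty glycome
  empty <- screen_glycome(list(), pp$receptor, pp$planted$structure,
                          pp$core_tree)
  expect_equal(unname(empty$summary["matched"]), 0)
  # a bare-core entry fits; occluded-extension entries do not
  gl <- make_glycome(pp$core_tree, n_with_core = 4, n_without = 2,
                     n_bare = 1, seed = 48)
  scr <- screen_glycome(gl$glycome, pp$receptor, pp$planted$structure,
                        pp$core_tree)
  expect_equal(unname(scr$summary["n_glycans"]), 7)
  expect_equal(unname(scr$summary["matched"]), 5)
  expect_equal(unname(scr$summary["fitting"]), 1)   # only the bare core
  expect_equal(unname(scr$summary["blocked"]), 4)
  bare_id <- gl$truth$glycan_id[gl$truth$has_core &
                                  is.na(gl$truth$extension)]
  expect_true(scr$per_glycan$fits[scr$per_glycan$glycan_id == bare_id])
})
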