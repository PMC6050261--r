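# Synthetic-data generators with known ground truth for every pipeline
# input: a toy binding pocket with controlled occlusion geometry, pose
# ensembles with a planted true pose, trajectories with planted
# stable/drifting labels, microarray titrations with planted KD/Bmax,
# alanine panels with planted fold changes, reference STD datasets, and
# mini-glycomes with planted core/extension labels.
#
# Every generator is a pure function of (seed, parameters): it seeds the
# RNG itself, so regeneration with the same arguments is identical.

#' The 16-point titration ladder used on the arrays
#'
#' Geometric dilution series between 400 and 0.00256 nM.
#'
#' @return numeric vector of 16 concentrations in nM, descending.
#' @export
titration_ladder <- function() {
  400 * (0.00256 / 400)^((0:15) / 15)
}

#' Synthetic binding pocket with a planted pose and decoy ensemble
#'
#' Builds the antigen at a chosen rotamer, surrounds it with a pocket of
#' pseudo-atoms: blocker atoms sealing the designated occluded attachment
#' positions (by default the sialic-acid glycerol arm O7/O8/O9 and the
#' GalNAc O3/O4, with the aglycon direction and Neu5Ac O4 left open), and
#' carbon-proton contact pairs near the buried ligand atoms (the
#' acetamido methyl, the glycerol arm and the GalNAc O3 face) so the
#' planted pose has a distinctive predicted STD signature. Decoys are
#' rigid-body copies displaced by at least `displacement` (rotation about
#' the centroid plus translation, which bounds the coordinate RMSD from
#' below by the translation length).
#'
#' @param seed RNG seed.
#' @param n_decoy number of decoy poses.
#' @param displacement minimum decoy displacement in Angstrom (> 0).
#' @param core text form of the antigen (default sialyl-Tn).
#' @param rotamer index of the true rotamer (default 3).
#' @param n_planted_copies jittered repeats of the planted pose in the
#'   ensemble, emulating a docking run re-finding the true pose.
#' @return list: `receptor` (`structure3d`), `core_tree`, `torsions`
#'   (true `torsion_set`), `planted` (`pose_record`), `poses` (planted +
#'   copies + decoys), `occluded` (position labels), `truth`.
#' @export
make_pocket_and_poses <- function(seed, n_decoy = 50, displacement = 2.5,
                                  core = "Neu5Ac(a2-6)GalNAc(a1-",
                                  rotamer = 3, n_planted_copies = 0) {
  if (displacement <= 0) stop("displacement must be > 0", call. = FALSE)
  if (n_decoy < 0) stop("n_decoy must be >= 0", call. = FALSE)
  set.seed(seed)
  tree <- parse_glycan(core)
  rots <- enumerate_rotamers(tree)
  tors <- rots[[rotamer]]
  lig <- build_structure(tree, tors)

  # occluded positions: glycerol arm + GalNAc O3/O4 (position labels are
  # resolved against the tree so the defaults follow the residue ids)
  sia <- tree$residues$id[tree$residues$name %in% c("Neu5Ac", "Neu5Gc")][1]
  gal <- tree$root
  occl <- list(c(sia, 7L), c(sia, 8L), c(sia, 9L),
               c(gal, 3L), c(gal, 4L))
  occl_labels <- vapply(occl, function(p) .position_label(tree, p[1], p[2]),
                        character(1))

  pocket <- list()
  addatom <- function(name, element, p) {
    pocket[[length(pocket) + 1]] <<- data.frame(
      name = name, element = element, resid = 1L, residue = "pocket",
      x = p[1], y = p[2], z = p[3])
  }
  k <- 0
  for (p in occl) {
    geo <- .attachment_geometry(lig, tree, p[1], p[2])
    v <- .unit(geo$Op - geo$Cp)
    k <- k + 1
    addatom(paste0("B", k), "C", geo$Op + 1.43 * v)
    addatom(paste0("D", k), "C", geo$Op + 2.80 * v)
  }
  # contact C-H pairs near buried ligand atoms -> strong STD there
  centroid <- colMeans(coords(lig))
  contact_atoms <- c("C11", "C8")  # acetamido methyls, glycerol C8
  ca <- lig$atoms[lig$atoms$name %in% contact_atoms |
                    (lig$atoms$resid == gal & lig$atoms$name == "C3"), ]
  for (i in seq_len(nrow(ca))) {
    p0 <- unlist(ca[i, c("x", "y", "z")])
    u <- .unit(p0 - centroid)
    k <- k + 1
    addatom(paste0("P", k), "C", p0 + 3.4 * u)
    addatom(paste0("Q", k), "H", p0 + 2.4 * u)
  }
  receptor <- structure3d(do.call(rbind, pocket))

  planted <- pose_record(id = "SYN.TRUE.1", structure = lig,
                         model = "SYN", protocol = "rigid",
                         rotamer = rotamer, snapshot = 1L, score = -9.5)
  poses <- list(planted)
  if (n_planted_copies > 0) {
    for (j in seq_len(n_planted_copies)) {
      cp <- lig
      coords(cp) <- coords(cp) + matrix(stats::rnorm(3 * nrow(cp$atoms),
                                                     sd = 0.15),
                                        ncol = 3)
      poses[[length(poses) + 1]] <- pose_record(
        id = sprintf("SYN.TRUE.%d", j + 1), structure = cp, model = "SYN",
        protocol = "rigid", rotamer = rotamer, snapshot = j + 1L,
        score = -9.3 + 0.05 * j)
    }
  }
  for (j in seq_len(n_decoy)) {
    R <- .random_rotation()
    tdir <- .unit(stats::rnorm(3))
    tmag <- stats::runif(1, displacement, displacement + 4)
    dec <- lig
    xyz <- coords(lig)
    ctr <- colMeans(xyz)
    coords(dec) <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2,
                         ctr + tdir * tmag, `+`)
    poses[[length(poses) + 1]] <- pose_record(
      id = sprintf("SYN.DEC.%d", j), structure = dec, model = "SYN",
      protocol = "rigid", rotamer = rotamer, snapshot = j,
      score = stats::runif(1, -9.2, -4.0))
  }
  list(receptor = receptor, core_tree = tree, torsions = tors,
       planted = poses[[1]], poses = poses, occluded = occl_labels,
       truth = list(seed = seed, planted_id = "SYN.TRUE.1",
                    displacement = displacement,
                    occluded = occl_labels))
}

#' Synthetic trajectories with planted stable/drifting labels
#'
#' Stable poses jitter isotropically about their start (expected mean
#' RMSF approximately sigma * sqrt(3) under the per-coordinate Gaussian
#' model); unstable poses additionally drift linearly along a random
#' direction, emulating a ligand repositioning in the binding site.
#'
#' @param poses list of `pose_record` objects.
#' @param stable logical vector (one per pose): planted stability label.
#' @param sigma per-coordinate jitter SD in Angstrom (default 0.231,
#'   i.e. mean RMSF about 0.4 A).
#' @param drift_rate drift speed of unstable poses in A/ns (default 0.8).
#' @param length_ns trajectory length in ns (default 20).
#' @param dt_ns frame spacing in ns (default 1).
#' @param seed RNG seed.
#' @return named list of `trajectory` objects keyed by pose id.
#' @export
make_trajectories <- function(poses, stable, sigma = 0.231,
                              drift_rate = 0.8, length_ns = 20, dt_ns = 1,
                              seed = 1) {
  stopifnot(length(stable) == length(poses))
  if (sigma < 0 || length_ns <= 0 || dt_ns <= 0) {
    stop("sigma, length_ns and dt_ns must be positive", call. = FALSE)
  }
  set.seed(seed)
  times <- seq(0, length_ns, by = dt_ns)
  out <- list()
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    X <- coords(p$structure)
    meta <- data.frame(name = p$structure$atoms$name,
                       element = p$structure$atoms$element,
                       resid = p$structure$atoms$resid,
                       residue = p$structure$atoms$residue,
                       role = "ligand")
    u <- .unit(stats::rnorm(3))
    frames <- lapply(times, function(t) {
      fr <- X + matrix(stats::rnorm(length(X), sd = sigma), ncol = 3)
      if (!stable[i]) fr <- sweep(fr, 2, u * drift_rate * t, `+`)
      fr
    })
    out[[p$id]] <- trajectory(frames, times, meta)
  }
  out
}

# Mean-one multiplicative lognormal noise factors.
.lognormal_noise <- function(n, cv) {
  if (cv < 0) stop("noise CV must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Synthetic one-site titration series
#'
#' RFU = Bmax C / (KD + C) times mean-one lognormal noise, over the
#' 16-point 400-0.00256 nM ladder with replicate spots.
#'
#' @param true_kd planted KD in nM (> 0).
#' @param bmax planted Bmax in RFU (> 0).
#' @param ladder concentration ladder in nM.
#' @param cv multiplicative noise coefficient of variation (>= 0).
#' @param replicates replicate spots per concentration (default 4).
#' @param seed RNG seed.
#' @param glycan_id,glycan_name identifiers for the series.
#' @return a `titration_series`.
#' @export
make_titration <- function(true_kd, bmax, ladder = titration_ladder(),
                           cv = 0.1, replicates = 4, seed = 1,
                           glycan_id = "G1", glycan_name = "glycan") {
  stopifnot(true_kd > 0, bmax > 0)
  set.seed(seed)
  conc <- rep(ladder, each = replicates)
  mu <- bmax * conc / (true_kd + conc)
  rfu <- mu * .lognormal_noise(length(conc), cv)
  s <- titration_series(glycan_id, glycan_name, conc, rfu)
  s$truth <- list(kd = true_kd, bmax = bmax, cv = cv, seed = seed)
  s
}

#' Synthetic alanine-scan panel
#'
#' Generates a wild-type titration panel plus one panel per mutant, with
#' each mutant's KD scaled by its planted fold change; mutants marked
#' `"undetectable"` emit flat low-level noise instead of a binding curve,
#' emulating mutations that abolish binding.
#'
#' @param wt_kd named numeric vector: wild-type KD (nM) per glycan id.
#' @param mutant_effects named list: mutant label -> either a single
#'   value/`"undetectable"` applied to all glycans, or a named vector per
#'   glycan.
#' @param bmax Bmax used for all series.
#' @param cv noise CV.
#' @param replicates replicate spots per concentration.
#' @param seed RNG seed.
#' @return list with `wt` (named list of `titration_series`), `mutants`
#'   (named list of named lists), `truth`.
#' @export
make_alanine_panel <- function(wt_kd, mutant_effects, bmax = 3000,
                               cv = 0.1, replicates = 4, seed = 1) {
  set.seed(seed)
  ladder <- titration_ladder()
  sub_seed <- function() sample.int(.Machine$integer.max - 1, 1)
  wt <- list()
  for (g in names(wt_kd)) {
    wt[[g]] <- make_titration(wt_kd[[g]], bmax, ladder, cv, replicates,
                              seed = sub_seed(), glycan_id = g)
  }
  mutants <- list()
  for (m in names(mutant_effects)) {
    eff <- mutant_effects[[m]]
    mutants[[m]] <- list()
    for (g in names(wt_kd)) {
      e <- if (length(eff) == 1 && is.null(names(eff))) eff else eff[[g]]
      if (identical(e, "undetectable")) {
        set.seed(sub_seed())
        conc <- rep(ladder, each = replicates)
        rfu <- stats::rlnorm(length(conc), meanlog = log(2), sdlog = 0.8)
        s <- titration_series(g, g, conc, rfu)
        s$truth <- list(kd = NA_real_, undetectable = TRUE)
        mutants[[m]][[g]] <- s
      } else {
        e <- as.numeric(e)
        if (e <= 0) stop("fold changes must be positive", call. = FALSE)
        mutants[[m]][[g]] <- make_titration(wt_kd[[g]] * e, bmax, ladder,
                                            cv, replicates,
                                            seed = sub_seed(),
                                            glycan_id = g)
      }
    }
  }
  list(wt = wt, mutants = mutants,
       truth = list(wt_kd = wt_kd, mutant_effects = mutant_effects,
                    seed = seed))
}

#' Reference STD dataset generated from a posed ligand
#'
#' Computes the proximity-model prediction for the supplied pose (or
#' trajectory frames) and perturbs it with mean-one lognormal noise,
#' producing an "experimental-style" dataset whose ground truth is the
#' generating pose.
#'
#' @param receptor receptor `structure3d`.
#' @param ligand `structure3d` or list of frames.
#' @param cv noise CV (default 0.1).
#' @param seed RNG seed.
#' @param cutoff STD proximity cutoff in Angstrom.
#' @return an `std_dataset`.
#' @export
make_std_reference <- function(receptor, ligand, cv = 0.1, seed = 1,
                               cutoff = 8) {
  set.seed(seed)
  pred <- predict_std(receptor, ligand, cutoff)
  raw <- pred$data$integral * .lognormal_noise(nrow(pred$data), cv)
  normalize_std(stats::setNames(raw, pred$data$label))
}

#' Synthetic glycome with planted core and extension labels
#'
#' Entries that contain the antigen core carry one extra residue grafted
#' at positions drawn from `positions` (position labels as produced by
#' [occlusion_map()], e.g. `"Neu5Ac#1:O8"`); the remaining entries are
#' core-free sialoglycans. Glycan ids are glycomeDB-style integers.
#'
#' @param core a `glycan_tree` (the antigen).
#' @param n_with_core,n_without entry counts (>= 0).
#' @param positions character vector of position labels extensions are
#'   drawn from; `"bare"` entries (the naked core) may be requested via
#'   `n_bare`.
#' @param n_bare number of entries equal to the bare core (default 0).
#' @param seed RNG seed.
#' @return list: `glycome` (named list of `glycan_tree`), `truth` (data
#'   frame: glycan_id, has_core, extension label or NA).
#' @export
make_glycome <- function(core, n_with_core, n_without,
                         positions = c("Neu5Ac#1:O8", "GalNAc#2:O3"),
                         n_bare = 0, seed = 1) {
  if (n_with_core < 0 || n_without < 0 || n_bare < 0) {
    stop("entry counts must be >= 0", call. = FALSE)
  }
  set.seed(seed)
  n_total <- n_with_core + n_without + n_bare
  ids <- as.character(sample(1000:99999, n_total))
  decoys <- c("Neu5Gc(a2-6)GalNAc(a1-", "Neu5Ac(a2-3)Gal(b1-",
              "Gal(b1-3)GalNAc(a1-", "Neu5Gc(a2-3)Gal(b1-",
              "Neu5Ac(a2-6)Gal(b1-")
  parse_pos <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z0-9]+)#([0-9]+):O([0-9]+)$", lab))[[1]]
    if (length(m) == 0) stop("bad position label: ", lab, call. = FALSE)
    list(resid = as.integer(m[3]), pos = as.integer(m[4]))
  }
  extend_core <- function(lab) {
    p <- parse_pos(lab)
    res <- core$residues
    parent_name <- res$name[res$id == p$resid]
    sial_parent <- grepl("^Neu", parent_name)
    new_id <- max(res$id) + 1L
    if (p$pos == 1L) {
      # reducing-end continuation: new residue becomes the root and the
      # old root hangs from its O3
      add <- data.frame(id = new_id, name = "Gal", anomer = "b",
                        ano_pos = 1L, mods = "")
      ed <- rbind(core$edges,
                  data.frame(child = core$root, parent = new_id,
                             child_pos = res$ano_pos[res$id == core$root],
                             parent_pos = 3L))
      return(.new_glycan_tree(rbind(res, add), ed, root = new_id))
    }
    if (sial_parent) {
      add <- data.frame(id = new_id, name = "Neu5Ac", anomer = "a",
                        ano_pos = 2L, mods = "")
      cp <- 2L
    } else {
      add <- data.frame(id = new_id, name = "Gal", anomer = "b",
                        ano_pos = 1L, mods = "")
      cp <- 1L
    }
    ed <- rbind(core$edges,
                data.frame(child = new_id, parent = p$resid,
                           child_pos = cp, parent_pos = p$pos))
    .new_glycan_tree(rbind(res, add), ed, root = core$root)
  }
  glycome <- list()
  truth <- list()
  k <- 0
  for (i in seq_len(n_with_core)) {
    k <- k + 1
    lab <- positions[1 + (i - 1) %% length(positions)]
    glycome[[ids[k]]] <- extend_core(lab)
    truth[[k]] <- data.frame(glycan_id = ids[k], has_core = TRUE,
                             extension = lab)
  }
  for (i in seq_len(n_bare)) {
    k <- k + 1
    glycome[[ids[k]]] <- core
    truth[[k]] <- data.frame(glycan_id = ids[k], has_core = TRUE,
                             extension = NA_character_)
  }
  for (i in seq_len(n_without)) {
    k <- k + 1
    glycome[[ids[k]]] <- parse_glycan(decoys[1 + (i - 1) %% length(decoys)])
    truth[[k]] <- data.frame(glycan_id = ids[k], has_core = FALSE,
                             extension = NA_character_)
  }
  list(glycome = glycome,
       truth = do.call(rbind, truth))
}

#' Write ground truth to a JSON file
#' @param truth a list or data frame of planted ground-truth values.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
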