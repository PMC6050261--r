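# End-to-end funnel on synthetic data: enumerate -> dock (simulated) ->
# cluster -> select -> stability -> STD agreement -> final ranking, with
# per-stage reports and a serializable configuration.

#' Pipeline configuration
#'
#' Collects every campaign count and threshold the funnel uses. The
#' defaults are the full campaign shape: 2 receptor models, rigid
#' protocol 6 rotamers x 25 snapshots x 20 poses keeping the top-scoring
#' member of the 20 most populated clusters per rotamer, flexible
#' protocol 150 snapshots x 20 poses keeping the top 50 by score;
#' clustering at 2 A, stability filtering at mean ligand RMSF 1.0 A over
#' the last 10 ns, STD proximity cutoff 8 A.
#'
#' @param seed master RNG seed for the synthetic inputs.
#' @param campaign campaign counts, see [campaign_config()].
#' @param eps,minpoints clustering parameters (A; see [cluster_poses()]).
#' @param rmsf_max stability threshold in A.
#' @param rescore_max docking-rescore threshold in kcal/mol.
#' @param std_cutoff STD proximity cutoff in A.
#' @param last_ns stability/STD analysis window in ns.
#' @param traj_length_ns,traj_dt_ns synthetic trajectory length and frame
#'   spacing in ns.
#' @param n_stable number of poses planted as stable in the synthetic
#'   trajectories (the planted true pose is always one of them).
#' @param displacement minimum decoy displacement in A.
#' @param sigma,drift_rate synthetic jitter SD (A) and drift rate (A/ns).
#' @param std_cv noise CV of the synthetic experimental STD dataset.
#' @param temperature assay temperature in K.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            campaign = campaign_config(),
                            eps = 2.0, minpoints = 1,
                            rmsf_max = 1.0, rescore_max = 0,
                            std_cutoff = 8, last_ns = 10,
                            traj_length_ns = 20, traj_dt_ns = 1,
                            n_stable = 80, displacement = 2.5,
                            sigma = 0.231, drift_rate = 0.8,
                            std_cv = 0.1, temperature = 298.15) {
  cfg <- list(seed = seed, campaign = campaign, eps = eps,
              minpoints = minpoints, rmsf_max = rmsf_max,
              rescore_max = rescore_max, std_cutoff = std_cutoff,
              last_ns = last_ns, traj_length_ns = traj_length_ns,
              traj_dt_ns = traj_dt_ns, n_stable = n_stable,
              displacement = displacement, sigma = sigma,
              drift_rate = drift_rate, std_cv = std_cv,
              temperature = temperature)
  thr <- c(cfg$eps, cfg$minpoints, cfg$rmsf_max, cfg$std_cutoff,
           cfg$last_ns, cfg$traj_length_ns, cfg$traj_dt_ns)
  if (any(thr <= 0)) stop("thresholds must be positive", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration to a key-value (YAML) file
#' @param config a `pipeline_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration written by [write_config()]
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# Random rigid decoy transform of a structure about its centroid plus a
# translation of at least `displacement`.
.decoy_of <- function(struct, displacement) {
  R <- .random_rotation()
  xyz <- coords(struct)
  ctr <- colMeans(xyz)
  t <- .unit(stats::rnorm(3)) * stats::runif(1, displacement,
                                             displacement + 4)
  coords(struct) <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + t, `+`)
  struct
}

#' Run the full synthetic funnel
#'
#' Generates a synthetic pocket and docking campaign with a planted true
#' pose, then runs the complete selection funnel: per-rotamer clustering
#' and representative selection for the rigid protocol, top-N selection
#' for the flexible protocol, trajectory stability filtering on the last
#' `last_ns` ns, predicted-vs-experimental STD agreement, and the final
#' combined ranking. Deterministic per seed.
#'
#' @param config a `pipeline_config`.
#' @param outdir optional directory for per-stage CSVs, the funnel-count
#'   table, ground truth JSON and the selected pose PDB.
#' @return list of class `pipeline_result`: `funnel` (stage counts),
#'   `cards` (per-surviving-pose score card), `ranking`, `selected`
#'   (pose id or NA), `planted` (true pose id), `recovered` (logical),
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  base <- make_pocket_and_poses(seed = config$seed %% 100000 + 1,
                                n_decoy = 0,
                                displacement = config$displacement)
  tree <- base$core_tree
  receptor <- base$receptor
  true_rot <- base$planted$rotamer
  rots <- enumerate_rotamers(tree)
  built <- lapply(rots, function(r) build_structure(tree, r))

  camp <- config$campaign
  .validate_campaign(camp)
  models <- paste0("M", seq_len(camp$models))
  planted_model <- models[length(models)]

  set.seed(config$seed %% 100000 + 2)
  poses <- list()
  planted_id <- NULL
  n_copies <- 5L
  for (m in models) {
    idx <- 0L
    for (r in seq_len(camp$rigid$rotamers)) {
      for (s in seq_len(camp$rigid$snapshots)) {
        for (j in seq_len(camp$rigid$poses_per_run)) {
          idx <- idx + 1L
          id <- sprintf("%s.R.%d", m, idx)
          planted_here <- m == planted_model && r == true_rot &&
            s <= n_copies && j == 1L
          if (planted_here) {
            st <- base$planted$structure
            if (s > 1L) {
              coords(st) <- coords(st) +
                matrix(stats::rnorm(3 * nrow(st$atoms), sd = 0.15), ncol = 3)
            }
            score <- -9.5 + 0.05 * (s - 1)
            if (s == 1L) planted_id <- id
          } else {
            st <- .decoy_of(built[[min(r, length(built))]],
                            config$displacement)
            score <- stats::runif(1, -9.2, -4.0)
          }
          poses[[id]] <- pose_record(id, st, model = m, protocol = "rigid",
                                     rotamer = r, snapshot = s,
                                     score = score)
        }
      }
    }
    idx <- 0L
    for (r in seq_len(camp$flexible$rotamers)) {
      for (s in seq_len(camp$flexible$snapshots)) {
        for (j in seq_len(camp$flexible$poses_per_run)) {
          idx <- idx + 1L
          id <- sprintf("%s.F.%d", m, idx)
          st <- .decoy_of(built[[1]], config$displacement)
          poses[[id]] <- pose_record(id, st, model = m,
                                     protocol = "flexible", rotamer = r,
                                     snapshot = s,
                                     score = stats::runif(1, -9.2, -4.0))
        }
      }
    }
  }
  n_generated <- length(poses)

  # rigid: cluster per (model, rotamer), keep top-cluster representatives
  retained <- list()
  for (m in models) {
    for (r in seq_len(camp$rigid$rotamers)) {
      sub <- Filter(function(p) p$model == m && p$protocol == "rigid" &&
                      p$rotamer == r, poses)
      cl <- cluster_poses(sub, eps = config$eps,
                          minpoints = config$minpoints)
      retained <- c(retained,
                    select_representatives(cl, sub,
                                           camp$rigid$keep_clusters))
    }
    sub <- Filter(function(p) p$model == m && p$protocol == "flexible",
                  poses)
    retained <- c(retained, select_top_n(sub, camp$flexible$top_n))
  }
  n_retained <- length(retained)

  # protonate once on clean geometry: trajectory frames then carry
  # hydrogens, so STD prediction never re-derives bonds from jittered
  # coordinates
  retained <- lapply(retained, function(p) {
    p$structure <- add_hydrogens(p$structure)
    p
  })

  # stability: the planted pose plus the best-scoring decoys are stable
  ids <- vapply(retained, function(p) p$id, character(1))
  scores <- vapply(retained, function(p) p$score, numeric(1))
  stable <- rep(FALSE, n_retained)
  ord <- order(scores, ids)
  stable[ord[seq_len(min(config$n_stable, n_retained))]] <- TRUE
  stable[ids == planted_id] <- TRUE
  trajs <- make_trajectories(retained, stable, sigma = config$sigma,
                             drift_rate = config$drift_rate,
                             length_ns = config$traj_length_ns,
                             dt_ns = config$traj_dt_ns,
                             seed = config$seed %% 100000 + 3)
  rmsf <- vapply(trajs, function(tr) {
    ligand_rmsf(traj_window(tr, config$last_ns))
  }, numeric(1))
  filt <- stability_filter(rmsf, config$rmsf_max)
  survivors <- retained[ids %in% filt$retained]
  n_stable_out <- length(survivors)

  # STD: synthetic experimental dataset from the planted pose trajectory
  frame_structs <- function(p) {
    tr <- traj_window(trajs[[p$id]], config$last_ns)
    lapply(tr$frames, function(fr) {
      st <- p$structure
      coords(st) <- fr
      st
    })
  }
  planted_pose <- retained[[match(planted_id, ids)]]
  experimental <- make_std_reference(receptor, frame_structs(planted_pose),
                                     cv = config$std_cv,
                                     seed = config$seed %% 100000 + 4,
                                     cutoff = config$std_cutoff)
  cards <- do.call(rbind, lapply(survivors, function(p) {
    pred <- predict_std(receptor, frame_structs(p),
                        cutoff = config$std_cutoff)
    ag <- std_agreement(pred, experimental)
    data.frame(pose_id = p$id, rescore = p$score,
               agreement = ag$score, rmsf = unname(rmsf[p$id]))
  }))
  if (is.null(cards)) {
    cards <- data.frame(pose_id = character(0), rescore = numeric(0),
                        agreement = numeric(0), rmsf = numeric(0))
  }
  ranking <- final_ranking(cards, rmsf_max = config$rmsf_max,
                           rescore_max = config$rescore_max)
  n_final <- if (ranking$empty) 0L else 1L

  funnel <- data.frame(
    stage = c("generated", "retained_after_selection", "stable",
              "final_selection"),
    count = c(n_generated, n_retained, n_stable_out, n_final))

  result <- structure(list(funnel = funnel, cards = cards,
                           ranking = ranking, selected = ranking$top,
                           planted = planted_id,
                           recovered = identical(ranking$top, planted_id),
                           config = config),
                      class = "pipeline_result")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(funnel, file.path(outdir, "funnel_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(filt$report, file.path(outdir, "stability_report.csv"),
                     row.names = FALSE)
    utils::write.csv(cards, file.path(outdir, "score_cards.csv"),
                     row.names = FALSE)
    meta <- do.call(rbind, lapply(retained, function(p) {
      data.frame(pose_id = p$id, model = p$model, protocol = p$protocol,
                 rotamer = p$rotamer, snapshot = p$snapshot,
                 score = p$score)
    }))
    utils::write.csv(meta, file.path(outdir, "retained_poses.csv"),
                     row.names = FALSE)
    write_ground_truth(list(seed = config$seed, planted_id = planted_id,
                            stable_ids = ids[stable]),
                       file.path(outdir, "ground_truth.json"))
    if (!ranking$empty) {
      sel <- retained[[match(ranking$top, ids)]]
      write_pdb(sel$structure, file.path(outdir, "selected_pose.pdb"))
    }
    write_config(config, file.path(outdir, "config.yaml"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Synthetic docking funnel\n")
  for (k in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-25s %d\n", x$funnel$stage[k], x$funnel$count[k]))
  }
  cat(sprintf("  selected: %s (planted %s) -> %s\n",
              x$selected, x$planted,
              if (x$recovered) "recovered" else "NOT recovered"))
  invisible(x)
}
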