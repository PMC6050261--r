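# Docking-campaign bookkeeping and the pose funnel: pose-pose RMSD,
# density-based clustering (eps = 2 A, minpoints = 1, i.e. connected
# components of the rmsd <= eps graph), representative selection, and
# top-N selection by docking score.

#' Construct a PoseRecord
#'
#' @param id pose identifier, conventionally `"<model>.<R|F>.<index>"`.
#' @param structure ligand `structure3d` in the (pre-aligned) receptor
#'   frame.
#' @param model receptor homology-model tag.
#' @param protocol `"rigid"` or `"flexible"`.
#' @param rotamer,snapshot integer provenance indices.
#' @param score docking score in kcal/mol (lower is better).
#' @return object of class `pose_record`.
#' @export
pose_record <- function(id, structure, model = NA_character_,
                        protocol = NA_character_, rotamer = NA_integer_,
                        snapshot = NA_integer_, score = NA_real_) {
  stopifnot(inherits(structure, "structure3d"))
  if (!is.na(score) && !is.finite(score)) {
    stop("pose score must be finite", call. = FALSE)
  }
  structure(list(id = id, structure = structure, model = model,
                 protocol = protocol, rotamer = as.integer(rotamer),
                 snapshot = as.integer(snapshot), score = score),
            class = "pose_record")
}

#' @export
print.pose_record <- function(x, ...) {
  cat(sprintf("<pose %s: model %s, %s, rotamer %s, snapshot %s, score %.2f>\n",
              x$id, x$model, x$protocol, x$rotamer, x$snapshot, x$score))
  invisible(x)
}

#' Closed-form docking-campaign pose counts
#'
#' Computes generated and retained pose counts per stage of a two-protocol
#' docking campaign: per model, the rigid protocol generates
#' rotamers x snapshots x poses-per-run poses and retains the best pose of
#' the top `keep_clusters` clusters per rotamer; the flexible protocol
#' generates rotamers x snapshots x poses-per-run poses and retains the
#' `top_n` best-scoring.
#'
#' @param config list with `models` (count) and per-protocol lists
#'   `rigid` / `flexible`, each holding `rotamers`, `snapshots`,
#'   `poses_per_run`, and `keep_clusters` (rigid) or `top_n` (flexible).
#'   Defaults are the full campaign (2 models; rigid 6 x 25 x 20 keeping
#'   20 clusters per rotamer; flexible 1 x 150 x 20 keeping the top 50).
#' @return data frame with columns `stage` and `count`.
#' @examples
#' expected_counts()  # 12,000 screened, 340 retained
#' @export
expected_counts <- function(config = campaign_config()) {
  .validate_campaign(config)
  rg <- config$rigid
  fx <- config$flexible
  rigid_gen <- rg$rotamers * rg$snapshots * rg$poses_per_run
  flex_gen <- fx$rotamers * fx$snapshots * fx$poses_per_run
  rigid_keep <- rg$rotamers * rg$keep_clusters
  flex_keep <- fx$top_n
  data.frame(
    stage = c("rotamers",
              "rigid_generated_per_model", "flexible_generated_per_model",
              "generated_per_model", "total_screened",
              "rigid_retained_per_model", "flexible_retained_per_model",
              "retained_total"),
    count = c(rg$rotamers,
              rigid_gen, flex_gen,
              rigid_gen + flex_gen,
              (rigid_gen + flex_gen) * config$models,
              rigid_keep, flex_keep,
              (rigid_keep + flex_keep) * config$models))
}

#' Default campaign configuration
#' @param models number of receptor homology models.
#' @param rigid,flexible per-protocol count lists (see [expected_counts()]).
#' @return campaign config list.
#' @export
campaign_config <- function(models = 2,
                            rigid = list(rotamers = 6, snapshots = 25,
                                         poses_per_run = 20,
                                         keep_clusters = 20),
                            flexible = list(rotamers = 1, snapshots = 150,
                                            poses_per_run = 20, top_n = 50)) {
  list(models = models, rigid = rigid, flexible = flexible)
}

.validate_campaign <- function(config) {
  counts <- c(config$models,
              unlist(config$rigid), unlist(config$flexible))
  if (any(counts != round(counts)) || any(counts <= 0)) {
    stop("campaign counts must be positive integers", call. = FALSE)
  }
  invisible(config)
}

# Matched coordinate matrix for a selection of atom names (heavy atoms by
# default), ordered by (resid, name); errors list missing atoms.
.pose_coords <- function(pose, selection = NULL) {
  a <- pose$structure$atoms
  if (is.null(selection)) {
    a <- a[a$element != "H", , drop = FALSE]
  } else {
    key <- paste(a$resid, a$name)
    want <- selection
    missing <- setdiff(want, key)
    if (length(missing) > 0) {
      stop("pose ", pose$id, " is missing selection atoms: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    a <- a[match(want, key), , drop = FALSE]
    return(as.matrix(a[, c("x", "y", "z")]))
  }
  a <- a[order(a$resid, a$name), , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Canonical heavy-atom selection key of a pose.
.pose_selection <- function(pose) {
  a <- pose$structure$atoms
  a <- a[a$element != "H", , drop = FALSE]
  a <- a[order(a$resid, a$name), , drop = FALSE]
  paste(a$resid, a$name)
}

#' RMSD between two poses
#'
#' Plain coordinate RMSD over the shared selection (ligand heavy atoms by
#' default), with no re-superposition: poses are assumed to live in a
#' common, pre-aligned receptor frame.
#'
#' @param a,b `pose_record` objects.
#' @param selection character vector of `"resid name"` atom keys, or NULL
#'   for all heavy atoms.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b, selection = NULL) {
  if (is.null(selection)) selection <- .pose_selection(a)
  .rmsd_xyz(.pose_coords(a, selection), .pose_coords(b, selection))
}

#' Cluster poses by RMSD connectivity
#'
#' Density-based clustering with `minpoints = 1` and no sieving, which is
#' exactly the partition into connected components of the graph whose
#' edges join poses with RMSD <= `eps`. Clusters are sorted by population
#' (descending), ties broken by better best member score, then by the
#' best member's id.
#'
#' @param poses list of `pose_record` objects (>= 1).
#' @param eps RMSD cutoff in Angstrom (default 2.0).
#' @param minpoints must be 1 (the no-noise regime used throughout).
#' @param selection optional atom-key selection (see [pose_rmsd()]).
#' @return list of clusters; each has `members` (pose ids), `population`,
#'   `best_score` and `best_id`.
#' @export
cluster_poses <- function(poses, eps = 2.0, minpoints = 1, selection = NULL) {
  if (length(poses) == 0) stop("no poses to cluster", call. = FALSE)
  if (minpoints != 1) {
    stop("only minpoints = 1 (no-noise DBSCAN / connected components) is supported",
         call. = FALSE)
  }
  ids <- vapply(poses, function(p) p$id, character(1))
  if (anyDuplicated(ids) > 0) {
    stop("pose ids must be unique within an ensemble", call. = FALSE)
  }
  if (is.null(selection)) selection <- .pose_selection(poses[[1]])
  X <- t(vapply(poses, function(p) as.numeric(t(.pose_coords(p, selection))),
                numeric(3 * length(selection))))
  natoms <- length(selection)
  D <- as.matrix(stats::dist(X)) / sqrt(natoms)
  hit <- which(D <= eps & upper.tri(D), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(poses), directed = FALSE)
  if (nrow(hit) > 0) {
    g <- igraph::add_edges(g, as.vector(t(hit)))
  }
  comp <- igraph::components(g)$membership
  scores <- vapply(poses, function(p) p$score, numeric(1))
  clusters <- lapply(unique(comp), function(k) {
    idx <- which(comp == k)
    ord <- idx[order(scores[idx], ids[idx])]
    list(members = ids[ord], population = length(idx),
         best_score = scores[ord[1]], best_id = ids[ord[1]],
         member_idx = ord)
  })
  pop <- vapply(clusters, `[[`, numeric(1), "population")
  bs <- vapply(clusters, `[[`, numeric(1), "best_score")
  bid <- vapply(clusters, `[[`, character(1), "best_id")
  clusters[order(-pop, bs, bid)]
}

#' Representative poses from sorted clusters
#'
#' Takes the best-docking-score member of each of the first
#' `keep_clusters` clusters (all clusters if fewer exist).
#'
#' @param clusters output of [cluster_poses()].
#' @param poses the pose list the clusters refer to.
#' @param keep_clusters number of clusters to keep (default 20).
#' @return list of `pose_record` objects.
#' @export
select_representatives <- function(clusters, poses, keep_clusters = 20) {
  ids <- vapply(poses, function(p) p$id, character(1))
  keep <- clusters[seq_len(min(keep_clusters, length(clusters)))]
  lapply(keep, function(cl) poses[[match(cl$best_id, ids)]])
}

#' Top-N poses by docking score
#'
#' @param poses list of `pose_record` objects.
#' @param n number of poses to keep (lowest scores); ties broken by id.
#' @return list of `pose_record` objects.
#' @export
select_top_n <- function(poses, n = 50) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  scores <- vapply(poses, function(p) p$score, numeric(1))
  ids <- vapply(poses, function(p) p$id, character(1))
  ord <- order(scores, ids)
  poses[ord[seq_len(min(n, length(poses)))]]
}
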