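# Trajectory container, RMSD time series and the ligand-RMSF stability
# filter: poses whose mean ligand heavy-atom RMSF over the final window
# of simulation exceeds 1.0 A are discarded as unstable.

#' Construct a Trajectory
#'
#' @param frames list of n_atoms x 3 coordinate matrices (one per frame),
#'   or a 3-D array `[atoms, 3, frames]`.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param atoms atom metadata data frame with columns `name`, `element`,
#'   `resid`, `residue` and `role` (`"ligand"` or `"receptor"`).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, times, atoms) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  stopifnot(is.list(frames), length(frames) == length(times))
  n <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, integer(1)) == n)) {
    stop("all frames must have the same atom count", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  need <- c("name", "element", "resid", "residue", "role")
  if (!all(need %in% names(atoms)) || nrow(atoms) != n) {
    stop("atom metadata must have columns ", paste(need, collapse = ", "),
         " and one row per atom", call. = FALSE)
  }
  structure(list(frames = frames, times = as.numeric(times), atoms = atoms),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %d atoms, %.3g-%.3g ns>\n",
              length(x$frames), nrow(x$atoms),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Final-window view of a trajectory
#'
#' Keeps the frames with time strictly greater than `t_end - last_ns`,
#' preserving order: the analysis window the stability filter operates on.
#'
#' @param traj a `trajectory`.
#' @param last_ns window length in ns (default 10).
#' @return a `trajectory` restricted to the window.
#' @export
traj_window <- function(traj, last_ns = 10) {
  span <- max(traj$times) - min(traj$times)
  if (span < last_ns) {
    stop(sprintf("trajectory span (%.3g ns) is shorter than the requested window (%g ns)",
                 span, last_ns), call. = FALSE)
  }
  keep <- traj$times > max(traj$times) - last_ns
  trajectory(traj$frames[keep], traj$times[keep], traj$atoms)
}

.sel_index <- function(traj, selection) {
  if (is.null(selection)) {
    which(traj$atoms$role == "ligand" & traj$atoms$element != "H")
  } else if (is.logical(selection)) {
    which(selection)
  } else {
    as.integer(selection)
  }
}

#' Per-frame RMSD against a reference frame
#'
#' Each frame is first best-fit superposed onto the reference over the
#' `fit` atom subset (receptor atoms; the ligand never enters the fit),
#' then RMSD is measured over `selection`. With `fit = NULL` frames are
#' taken as already co-aligned.
#'
#' @param traj a `trajectory`.
#' @param reference frame index (default 1) or an n_atoms x 3 matrix.
#' @param selection atom indices / logical mask; default ligand heavy
#'   atoms.
#' @param fit atom indices for the superposition subset, or NULL.
#' @return data frame with columns `time` (ns) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = 1, selection = NULL, fit = NULL) {
  sel <- .sel_index(traj, selection)
  if (length(sel) == 0) stop("empty selection", call. = FALSE)
  ref <- if (is.matrix(reference)) reference else traj$frames[[reference]]
  rmsds <- vapply(traj$frames, function(fr) {
    if (!is.null(fit) && length(fit) >= 3) {
      k <- .kabsch(fr[fit, , drop = FALSE], ref[fit, , drop = FALSE])
      fr <- .apply_kabsch(fr, k)
    }
    .rmsd_xyz(fr[sel, , drop = FALSE], ref[sel, , drop = FALSE])
  }, numeric(1))
  data.frame(time = traj$times, rmsd = rmsds)
}

#' Mean ligand RMSF over a trajectory window
#'
#' Per-atom root-mean-square deviation from that atom's time-averaged
#' position, averaged (unweighted) over the selection.
#'
#' @param traj a `trajectory` (>= 2 frames), typically a
#'   [traj_window()] view.
#' @param selection atom indices / logical mask; default ligand heavy
#'   atoms.
#' @param fit optional atom indices to superpose each frame on the first
#'   frame before measuring (receptor subset), or NULL for pre-aligned
#'   frames.
#' @return mean RMSF in Angstrom.
#' @export
ligand_rmsf <- function(traj, selection = NULL, fit = NULL) {
  if (n_frames(traj) < 2) {
    stop("RMSF needs at least two frames", call. = FALSE)
  }
  sel <- .sel_index(traj, selection)
  if (length(sel) == 0) stop("empty selection", call. = FALSE)
  frames <- traj$frames
  if (!is.null(fit) && length(fit) >= 3) {
    ref <- frames[[1]]
    frames <- lapply(frames, function(fr) {
      k <- .kabsch(fr[fit, , drop = FALSE], ref[fit, , drop = FALSE])
      .apply_kabsch(fr, k)
    })
  }
  arr <- vapply(frames, function(fr) fr[sel, , drop = FALSE],
                matrix(0, length(sel), 3))
  if (length(sel) == 1) arr <- array(arr, dim = c(1, 3, length(frames)))
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply((arr - array(mean_pos, dim = dim(arr)))^2, c(1, 3), sum)
  per_atom <- sqrt(rowMeans(dev2))
  mean(per_atom)
}

#' Stability filter on per-pose RMSF values
#'
#' Partitions poses into retained (mean ligand RMSF <= threshold) and
#' discarded.
#'
#' @param rmsf named numeric vector of mean ligand RMSF per pose id.
#' @param threshold RMSF cutoff in Angstrom (default 1.0).
#' @return list with `retained`, `discarded` (character id vectors) and
#'   `report` (data frame: pose_id, rmsf, verdict).
#' @export
stability_filter <- function(rmsf, threshold = 1.0) {
  stopifnot(is.numeric(rmsf), !is.null(names(rmsf)))
  verdict <- ifelse(rmsf <= threshold, "retained", "discarded")
  list(retained = names(rmsf)[verdict == "retained"],
       discarded = names(rmsf)[verdict == "discarded"],
       report = data.frame(pose_id = names(rmsf), rmsf = unname(rmsf),
                           verdict = verdict))
}

#' Write a trajectory to a multi-model PDB file
#' @param traj a `trajectory`.
#' @param path output file.
#' @export
write_trajectory_pdb <- function(traj, path) {
  base <- data.frame(name = traj$atoms$name, element = traj$atoms$element,
                     resid = traj$atoms$resid, residue = traj$atoms$residue,
                     x = 0, y = 0, z = 0)
  structs <- lapply(traj$frames, function(fr) {
    base$x <- fr[, 1]; base$y <- fr[, 2]; base$z <- fr[, 3]
    structure3d(base)
  })
  write_pdb(structs, path)
}
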